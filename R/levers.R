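# Jaw lever stage: per-muscle, per-bite-point bite forces, mechanical
# advantage, and surface-area-scaled cross-taxon comparisons.

#' Bite force transmitted to a bite point
#'
#' `Fbite = Fres * inlever / outlever`: the third-class lever relation of the
#' mandible, with moment arms measured from the jaw joint.
#'
#' @param fres Resultant muscle force(s), N.
#' @param inlever Muscle insertion moment arm(s), mm.
#' @param outlever Bite-point moment arm(s), mm (positive).
#' @return Bite force(s) in newtons.
#' @examples
#' bite_force(27.3, 19.8, 90.4)  # 6.0 N
#' @export
bite_force <- function(fres, inlever, outlever) {
  if (any(!is.finite(outlever)) || any(outlever <= 0))
    stop("outlever must be positive")
  fres * inlever / outlever
}

#' Assemble a bite-force table
#'
#' Crosses every adductor's resultant force and inlever with every bite
#' point's outlever. Bilateral summation is already embodied in `fres_N`
#' (see [muscle_force()]); nothing is re-doubled here. The per-muscle
#' percentage contribution is identical across bite points because the
#' common outlever cancels.
#'
#' @param forces A [force_table()] result (needs `muscle` and `fres_N`), or
#'   any data frame with those columns. A depressor row (`mDM`) is ignored.
#' @param inlever Named numeric: inlever (mm) per adductor muscle.
#' @param outlever Named numeric: outlever (mm) per bite point, e.g.
#'   `c(anterior = , mid_palate = , posterior = )`.
#' @return An object of class `bite_force_table`: list with `fbite` (muscle x
#'   bite-point matrix, N), `totals` (per point, N), `contribution_pct` (per
#'   muscle), `mechanical_advantage` (per point), plus the levers and `fres`.
#' @export
bite_table <- function(forces, inlever, outlever) {
  stopifnot(is.data.frame(forces), all(c("muscle", "fres_N") %in% names(forces)))
  forces <- forces[forces$muscle != "mDM", , drop = FALSE]
  if (nrow(forces) == 0) stop("no adductor records")
  if (length(outlever) < 1) stop("at least one bite point required")
  if (is.null(names(outlever)))
    names(outlever) <- paste0("point", seq_along(outlever))
  miss <- setdiff(forces$muscle, names(inlever))
  if (length(miss))
    stop("missing inlever for muscle(s): ", paste(miss, collapse = ", "))
  inl <- inlever[forces$muscle]
  fres <- stats::setNames(forces$fres_N, forces$muscle)
  fb <- outer(fres * inl, 1 / outlever)
  dimnames(fb) <- list(forces$muscle, names(outlever))
  bite_force_table(fb, fres, inlever = inl, outlever = outlever)
}

#' Construct a bite-force table from explicit per-cell values
#'
#' Low-level constructor used by [bite_table()] and for tables transcribed
#' from published sources: given the per-muscle, per-point bite forces and
#' the per-muscle resultant forces it attaches totals, contributions and
#' mechanical advantage.
#'
#' @param fbite Muscle x bite-point matrix of bite forces, N.
#' @param fres Named per-muscle resultant forces, N.
#' @param inlever,outlever Optional lever sets, mm.
#' @return An object of class `bite_force_table`.
#' @export
bite_force_table <- function(fbite, fres, inlever = NULL, outlever = NULL) {
  fbite <- as.matrix(fbite)
  stopifnot(all(is.finite(fbite)), length(fres) == nrow(fbite))
  totals <- colSums(fbite)
  tot_fres <- sum(fres)
  contribution <- if (sum(fbite[, 1]) > 0)
    100 * fbite[, 1] / sum(fbite[, 1]) else rep(0, nrow(fbite))
  structure(list(fbite = fbite,
                 totals = totals,
                 contribution_pct = stats::setNames(contribution, rownames(fbite)),
                 mechanical_advantage =
                   if (tot_fres > 0) totals / tot_fres else rep(NA_real_, length(totals)),
                 fres = fres, inlever = inlever, outlever = outlever),
            class = "bite_force_table")
}

#' @export
print.bite_force_table <- function(x, digits = 1, ...) {
  cat("Bite-force table (N):\n")
  m <- cbind(round(x$fbite, digits),
             `contribution_%` = round(x$contribution_pct, digits))
  print(m)
  cat("Totals:", paste(sprintf("%s = %.1f", names(x$totals), x$totals),
                       collapse = ", "), "\n")
  cat("Mechanical advantage:",
      paste(sprintf("%s = %.3f", names(x$totals), x$mechanical_advantage),
            collapse = ", "), "\n")
  invisible(x)
}

#' Mechanical advantage per bite point
#'
#' Defined as the total bite force delivered at a bite point divided by the
#' total resultant muscle force: `MA = sum(Fbite) / sum(Fres)`, equivalently
#' the Fres-weighted mean of inlever/outlever ratios.
#'
#' @param table A [bite_force_table()].
#' @return Named numeric MA per bite point.
#' @export
mechanical_advantage <- function(table) {
  stopifnot(inherits(table, "bite_force_table"))
  tot_fres <- sum(table$fres)
  if (tot_fres <= 0) stop("total resultant force is zero")
  table$totals / tot_fres
}

#' Bite force relative to a surface-area-scaled prediction
#'
#' How much greater a taxon's bite force is than the value predicted by
#' scaling a reference taxon's bite force by the ratio of cranial surface
#' areas: `100 * (F_t / (F_ref * A_t / A_ref) - 1)` percent.
#'
#' @param fbite_target,fbite_reference Bite forces, N.
#' @param area_target,area_reference Cranial surface areas, square mm.
#' @return Percent greater than the isometric-scaling prediction.
#' @export
scaled_comparison <- function(fbite_target, fbite_reference,
                              area_target, area_reference) {
  vals <- c(fbite_target, fbite_reference, area_target, area_reference)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all forces and areas must be positive")
  100 * (fbite_target / (fbite_reference * area_target / area_reference) - 1)
}

#' Total muscle CSA relative to cranial surface area
#'
#' @param total_csa Summed adductor cross-sectional area, square mm.
#' @param cranial_surface_area Cranial surface area, square mm.
#' @return Dimensionless ratio.
#' @export
relative_csa <- function(total_csa, cranial_surface_area) {
  stopifnot(is.finite(total_csa), total_csa > 0,
            is.finite(cranial_surface_area), cranial_surface_area > 0)
  total_csa / cranial_surface_area
}
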