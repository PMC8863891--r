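# Dry-skull force stage: muscle contraction force from cross-sectional area,
# resultant vertical force on the mandible from the insertion angles, and the
# assembled per-taxon force table with totals and contributions.

#' Canonical adductor muscle names
#'
#' The eight jaw adductors of the archosaur adductor chamber plus the jaw
#' depressor `mDM`. The depressor is carried through the tables but always
#' excluded from adduction sums and contributions.
#' @export
MUSCLE_NAMES <- c("mAMEM", "mAMEP", "mAMES", "mAMP",
                  "mPSTs", "mPSTp", "mPTd", "mPTv", "mDM")

#' Force model parameters
#'
#' @param stress_sigma Isometric muscle stress, N per square mm. Default 0.3.
#' @param correction_factor Dimensionless scalar (>= 1) compensating for
#'   systematic underestimation of force by the dry-skull method, chiefly
#'   unmodelled pennation. Default 1.5; set to 1 for uncorrected forces.
#' @param bilateral If `TRUE` (default) forces are summed over both sides of
#'   the skull, i.e. doubled relative to a single reconstructed side.
#' @return A list of class `force_parameters`.
#' @export
force_parameters <- function(stress_sigma = 0.3, correction_factor = 1.5,
                             bilateral = TRUE) {
  stopifnot(is.finite(stress_sigma), stress_sigma > 0,
            is.finite(correction_factor), correction_factor >= 1,
            is.logical(bilateral), length(bilateral) == 1)
  structure(list(stress_sigma = stress_sigma,
                 correction_factor = correction_factor,
                 bilateral = bilateral),
            class = "force_parameters")
}

#' Muscle contraction force from volume and length
#'
#' `Fmus = CSA * sigma * correction`, with `CSA = volume / length`, doubled
#' when `bilateral` is set (both sides of the skull contribute to the bite).
#' The bilateral doubling is applied here once and never again downstream.
#'
#' @param volume Muscle volume(s), cubic mm.
#' @param length Muscle length(s), mm (positive).
#' @param params A [force_parameters()].
#' @return Contraction force(s) in newtons.
#' @examples
#' muscle_force(19580.5, 58.7)  # 300.2 N
#' @export
muscle_force <- function(volume, length, params = force_parameters()) {
  stopifnot(inherits(params, "force_parameters"))
  if (any(!is.finite(length)) || any(length <= 0))
    stop("muscle length must be positive")
  if (any(!is.finite(volume)) || any(volume < 0))
    stop("muscle volume must be non-negative")
  f <- (volume / length) * params$stress_sigma * params$correction_factor
  if (params$bilateral) f <- 2 * f
  f
}

#' Resultant vertical force acting on the mandible
#'
#' `Fres = Fmus * cos(alpha) * cos(beta)`: the contraction force resolved
#' through the sagittal (`alpha`) and coronal (`beta`) insertion angles.
#'
#' @param fmus Contraction force(s), N.
#' @param alpha,beta Insertion angles, degrees, each in \[0, 90).
#' @return Resultant force(s) in newtons.
#' @examples
#' resultant_force(30.9, 27.6, 4.4)  # 27.3 N
#' @export
resultant_force <- function(fmus, alpha, beta) {
  if (any(!is.finite(c(alpha, beta))) || any(c(alpha, beta) < 0) ||
      any(c(alpha, beta) >= 90))
    stop("insertion angles must lie in [0, 90) degrees for an adductor")
  fmus * cos(alpha * pi / 180) * cos(beta * pi / 180)
}

.check_muscle_table <- function(muscles) {
  need <- c("muscle", "volume_mm3", "length_mm", "alpha_deg", "beta_deg")
  miss <- setdiff(need, names(muscles))
  if (length(miss))
    stop("muscle table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(muscles$muscle))
    stop("duplicated muscle names in table")
  invisible(muscles)
}

#' Build the per-taxon force table
#'
#' Takes a measurement table (one row per muscle: `muscle`, `volume_mm3`,
#' `length_mm`, `alpha_deg`, `beta_deg`) and appends `fmus_N`, `fres_N` and
#' the percentage contribution of each adductor to the Fmus and Fres totals.
#' A depressor row (`mDM`) gets forces but is excluded from sums and carries
#' `NA` contributions.
#'
#' @param muscles Data frame of muscle measurements.
#' @param params A [force_parameters()].
#' @return The input data frame with force columns appended and an attribute
#'   `totals`: `list(volume_mm3, fmus_N, fres_N)` summed over adductors.
#' @export
force_table <- function(muscles, params = force_parameters()) {
  .check_muscle_table(muscles)
  if (nrow(muscles) == 0) stop("empty muscle table")
  adductor <- muscles$muscle != "mDM"
  if (!any(adductor)) stop("force table needs at least one adductor record")
  muscles$fmus_N <- muscle_force(muscles$volume_mm3, muscles$length_mm, params)
  muscles$fres_N <- resultant_force(muscles$fmus_N,
                                    muscles$alpha_deg, muscles$beta_deg)
  tot_fmus <- sum(muscles$fmus_N[adductor])
  tot_fres <- sum(muscles$fres_N[adductor])
  muscles$contribution_fmus_pct <-
    ifelse(adductor, 100 * muscles$fmus_N / tot_fmus, NA_real_)
  muscles$contribution_fres_pct <-
    ifelse(adductor, 100 * muscles$fres_N / tot_fres, NA_real_)
  attr(muscles, "totals") <- list(volume_mm3 = sum(muscles$volume_mm3[adductor]),
                                  fmus_N = tot_fmus, fres_N = tot_fres)
  attr(muscles, "force_parameters") <- params
  muscles
}
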