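# Gape kinematics: rigid rotation of the mandible about the jaw-joint axis,
# strain tracking of straight-cylinder muscle proxies, and detection of the
# optimal-tension and maximum-tension gape limits.

#' Strain limits of muscle tension
#'
#' Sarcomere cross-bridge overlap constrains the strain range over which a
#' muscle can produce tension: maximal tetanic contraction is possible up to
#' about 130% of resting length and any tension up to about 170%.
#'
#' @param optimal Optimal-tension strain ratio, default 1.3.
#' @param maximum Maximum-tension strain ratio, default 1.7.
#' @return A list of class `strain_limits`.
#' @export
strain_limits <- function(optimal = 1.3, maximum = 1.7) {
  stopifnot(is.finite(optimal), is.finite(maximum),
            optimal > 1, maximum > optimal)
  structure(list(optimal = optimal, maximum = maximum),
            class = "strain_limits")
}

#' Straight-cylinder muscle proxy
#'
#' A muscle is represented during jaw opening by one or two straight segments
#' joining the anteriormost ("1") and posteriormost ("2") extent of its origin
#' (cranium-fixed) and insertion (mandible-fixed) sites.
#'
#' @param id Cylinder label, e.g. `"mPTv1"` for the anteriormost mPTv segment.
#' @param origin Cranium-fixed attachment, length-3 mm.
#' @param insertion Mandible-fixed attachment, length-3 mm.
#' @return A list of class `muscle_cylinder`.
#' @export
muscle_cylinder <- function(id, origin, insertion) {
  origin <- .as_point3(origin, "cylinder origin")
  insertion <- .as_point3(insertion, "cylinder insertion")
  if (all(origin == insertion))
    stop("cylinder '", id, "': origin and insertion coincide")
  structure(list(id = as.character(id), origin = origin, insertion = insertion),
            class = "muscle_cylinder")
}

#' Rigid rotation about an axis through two points
#'
#' Rotates 3D point(s) about the line through `axis_a` and `axis_b` by
#' `theta` degrees (right-handed about the `axis_a -> axis_b` direction),
#' using the axis-angle (Rodrigues) map.
#'
#' @param point Length-3 coordinate or k x 3 matrix.
#' @param axis_a,axis_b Distinct points defining the rotation axis.
#' @param theta Rotation angle, degrees.
#' @return Rotated coordinate(s), same shape as `point`.
#' @export
rotate_about_axis <- function(point, axis_a, axis_b, theta) {
  a <- .as_point3(axis_a, "axis point a")
  b <- .as_point3(axis_b, "axis point b")
  k <- b - a
  nk <- sqrt(sum(k^2))
  if (nk == 0) stop("degenerate rotation axis: axis points coincide")
  k <- k / nk
  was_vec <- is.null(dim(point))
  p <- if (was_vec) matrix(.as_point3(point), 1) else as.matrix(point)
  th <- theta * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  out <- sweep(sweep(p, 2, a) %*% t(R), 2, a, `+`)
  if (was_vec) as.numeric(out) else out
}

#' Jaw model for gape kinematics
#'
#' A bilateral jaw whose mandible rotates rigidly about the mediolateral axis
#' through the two jaw-joint centres. Muscle cylinder origins stay fixed to
#' the cranium; insertions rotate with the mandible. Coordinates describe the
#' resting pose (jaw open by `resting_gape` degrees), at which all adductor
#' strains are defined to be 1.
#'
#' @param joint_left,joint_right Jaw-joint centres, length-3 mm. With a single
#'   midline joint, pass only `joint_left` and a pure mediolateral (+y) axis
#'   through it is assumed (a message is emitted).
#' @param adductors List of [muscle_cylinder()] jaw closers.
#' @param depressor Optional [muscle_cylinder()] for the jaw opener `mDM`
#'   (excluded from gape-limit detection; reported post hoc).
#' @param resting_gape Resting gape angle, degrees (default 5): the pose of
#'   the supplied coordinates.
#' @param step Opening-cycle sampling increment, degrees (default 0.5).
#' @param sense `+1` or `-1` to force the opening rotation sense; `NULL`
#'   (default) auto-detects the sense that stretches the adductors.
#' @return A list of class `jaw_model`.
#' @export
jaw_model <- function(joint_left, joint_right = NULL, adductors,
                      depressor = NULL, resting_gape = 5, step = 0.5,
                      sense = NULL) {
  joint_left <- .as_point3(joint_left, "joint_left")
  if (is.null(joint_right)) {
    message("single jaw joint supplied: assuming mediolateral (+y) rotation axis")
    joint_right <- joint_left + c(0, 1, 0)
  } else {
    joint_right <- .as_point3(joint_right, "joint_right")
    if (all(joint_left == joint_right)) stop("joint points must be distinct")
  }
  stopifnot(is.list(adductors), length(adductors) >= 1,
            all(vapply(adductors, inherits, TRUE, "muscle_cylinder")),
            is.null(depressor) || inherits(depressor, "muscle_cylinder"),
            is.finite(resting_gape), resting_gape >= 0,
            is.finite(step), step > 0)
  ids <- vapply(adductors, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicated cylinder ids")
  names(adductors) <- ids
  model <- structure(list(joint_left = joint_left, joint_right = joint_right,
                          adductors = adductors, depressor = depressor,
                          resting_gape = resting_gape, step = step,
                          sense = NA_real_),
                     class = "jaw_model")
  model$sense <- if (is.null(sense)) .opening_sense(model) else {
    stopifnot(sense %in% c(-1, 1))
    sense
  }
  model
}

# Total adductor length after rotating insertions by delta degrees (signed).
.adductor_length_sum <- function(model, delta) {
  sum(vapply(model$adductors, function(cyl) {
    ins <- rotate_about_axis(cyl$insertion, model$joint_left,
                             model$joint_right, delta)
    sqrt(sum((cyl$origin - ins)^2))
  }, numeric(1)))
}

# Opening must stretch the jaw closers: pick the rotation sense that
# lengthens the adductor set for a small positive angle.
.opening_sense <- function(model) {
  eps <- 1e-3
  l0 <- .adductor_length_sum(model, 0)
  up <- .adductor_length_sum(model, eps) - l0
  dn <- .adductor_length_sum(model, -eps) - l0
  if (up > 0 && up >= dn) return(1)
  if (dn > 0) return(-1)
  stop("ambiguous jaw-opening sense (adductors shorten both ways); ",
       "supply sense = +1 or -1 explicitly")
}

.cylinder_lengths <- function(model, theta) {
  delta <- model$sense * (theta - model$resting_gape)
  cyls <- model$adductors
  if (!is.null(model$depressor))
    cyls <- c(cyls, stats::setNames(list(model$depressor),
                                    model$depressor$id))
  vapply(cyls, function(cyl) {
    ins <- rotate_about_axis(cyl$insertion, model$joint_left,
                             model$joint_right, delta)
    sqrt(sum((cyl$origin - ins)^2))
  }, numeric(1))
}

#' Strain factor of every muscle cylinder at a gape angle
#'
#' Strain is the cylinder's length at gape `theta` divided by its length at
#' the resting gape; all adductor strains equal 1 exactly at
#' `theta = resting_gape`. The depressor (if present, named by its id) uses
#' the same geometry and typically shortens as the jaw opens.
#'
#' @param model A [jaw_model()].
#' @param theta Gape angle, degrees.
#' @return Named numeric strain factor per cylinder.
#' @export
cylinder_strain <- function(model, theta) {
  stopifnot(inherits(model, "jaw_model"), is.finite(theta))
  l0 <- .cylinder_lengths(model, model$resting_gape)
  if (any(l0 == 0)) stop("cylinder with zero resting length")
  .cylinder_lengths(model, theta) / l0
}

#' Locate the optimal and maximum gape limits
#'
#' Steps the gape from `resting_gape` in increments of `model$step` and
#' reports the first sampled angle at which any adductor cylinder's strain
#' reaches the optimal limit, and likewise the maximum limit. Limits are
#' detected on the sampling grid (no sub-step interpolation), mirroring
#' keyframe-based opening cycles. The depressor is excluded from detection;
#' its elongation factors from shortest (maximum gape) to optimal gape and to
#' resting gape are reported as a post-hoc plausibility check.
#'
#' @param model A [jaw_model()].
#' @param limits A [strain_limits()].
#' @param max_theta Abort the scan at this angle, degrees (default 180).
#' @return An object of class `gape_result`: `theta_optimal`, `theta_maximum`
#'   (degrees, grid multiples), `constraining_cylinder_opt` / `_max` (ids;
#'   ties all reported, lexicographically sorted), `strain_trace` (matrix,
#'   one row per sampled angle incl. the depressor), `depressor_factors`
#'   (`optimal` and `resting` elongation relative to maximum-gape length),
#'   and `open_ended` (`TRUE` if no crossing occurred by `max_theta`).
#' @export
find_gape_limits <- function(model, limits = strain_limits(),
                             max_theta = 180) {
  stopifnot(inherits(model, "jaw_model"), inherits(limits, "strain_limits"))
  thetas <- seq(model$resting_gape, max_theta, by = model$step)
  s0 <- cylinder_strain(model, model$resting_gape)
  trace <- vapply(thetas, function(th) cylinder_strain(model, th), s0)
  trace <- if (is.null(dim(trace)))
    matrix(trace, ncol = 1, dimnames = list(NULL, names(s0)))
  else t(trace)
  rownames(trace) <- formatC(thetas, format = "fg")
  add_ids <- names(model$adductors)
  add <- trace[, add_ids, drop = FALSE]
  first_cross <- function(limit) {
    hit <- which(apply(add >= limit, 1, any))
    if (!length(hit)) return(NULL)
    i <- hit[1]
    list(theta = thetas[i],
         cylinders = sort(colnames(add)[add[i, ] >= limit]))
  }
  opt <- first_cross(limits$optimal)
  mx <- first_cross(limits$maximum)
  open_ended <- is.null(opt) || is.null(mx)
  if (open_ended)
    warning(sprintf(paste0("no strain crossing by %.1f degrees; ",
                           "gape limit reported as open-ended"), max_theta))
  dep <- c(optimal = NA_real_, resting = NA_real_)
  if (!is.null(model$depressor) && !is.null(mx)) {
    dm <- model$depressor$id
    len_max <- .cylinder_lengths(model, mx$theta)[dm]
    len_opt <- .cylinder_lengths(model, if (is.null(opt)) mx$theta else opt$theta)[dm]
    len_rest <- .cylinder_lengths(model, model$resting_gape)[dm]
    dep <- c(optimal = unname(len_opt / len_max),
             resting = unname(len_rest / len_max))
  }
  # keep the trace up to just past the maximum crossing (or the full scan)
  keep <- if (is.null(mx)) length(thetas) else which(thetas == mx$theta)
  structure(list(theta_optimal = if (is.null(opt)) NA_real_ else opt$theta,
                 theta_maximum = if (is.null(mx)) NA_real_ else mx$theta,
                 constraining_cylinder_opt = if (is.null(opt)) character() else opt$cylinders,
                 constraining_cylinder_max = if (is.null(mx)) character() else mx$cylinders,
                 strain_trace = trace[seq_len(keep), , drop = FALSE],
                 theta_grid = thetas[seq_len(keep)],
                 depressor_factors = dep,
                 resting_gape = model$resting_gape,
                 step = model$step,
                 limits = limits,
                 open_ended = open_ended,
                 max_scanned = max_theta),
            class = "gape_result")
}

#' @export
print.gape_result <- function(x, ...) {
  if (x$open_ended) {
    cat(sprintf("Gape limits: open-ended (no crossing by %.1f deg)\n",
                x$max_scanned))
  } else {
    cat(sprintf("Optimal gape (strain %.2f): %.1f deg, constrained by %s\n",
                x$limits$optimal, x$theta_optimal,
                paste(x$constraining_cylinder_opt, collapse = ", ")))
    cat(sprintf("Maximum gape (strain %.2f): %.1f deg, constrained by %s\n",
                x$limits$maximum, x$theta_maximum,
                paste(x$constraining_cylinder_max, collapse = ", ")))
  }
  if (!all(is.na(x$depressor_factors)))
    cat(sprintf("Depressor elongation (vs maximum gape): %.2f at optimal, %.2f at rest\n",
                x$depressor_factors[["optimal"]], x$depressor_factors[["resting"]]))
  invisible(x)
}

#' Bar chart of cylinder strains at the gape limits
#'
#' @param x A `gape_result`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.gape_result <- function(x, ...) {
  at <- function(theta) x$strain_trace[which(x$theta_grid == theta), ]
  m <- rbind(optimal = at(x$theta_optimal), maximum = at(x$theta_maximum))
  graphics::barplot(m, beside = TRUE, las = 2,
                    ylab = "strain factor",
                    legend.text = rownames(m), ...)
  graphics::abline(h = c(1, x$limits$optimal, x$limits$maximum),
                   lty = c(1, 2, 3))
  invisible(x)
}

#' Write a strain trace as CSV
#'
#' One row per sampled gape angle, one column per cylinder; suitable for
#' re-plotting strain-versus-gape charts.
#'
#' @param result A `gape_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_strain_trace <- function(result, path) {
  stopifnot(inherits(result, "gape_result"))
  df <- data.frame(theta_deg = result$theta_grid,
                   result$strain_trace, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Transverse jaw clearance at a gape angle
#'
#' Euclidean gap between an opposing pair of anterior bite points (one
#' mandible-fixed, one cranium-fixed) when the jaw is opened to `theta`
#' degrees; the mandibular point is rotated by `theta - resting_gape`
#' relative to the supplied (resting-pose) coordinates. Bounds the maximum
#' transverse dimension of a food item the jaws can admit.
#'
#' @param model A [jaw_model()].
#' @param theta Gape angle, degrees (>= 0).
#' @param anterior_bite_point_mandible,anterior_bite_point_cranium
#'   Length-3 coordinates at the model's resting pose, mm.
#' @return Clearance in mm.
#' @export
jaw_clearance <- function(model, theta, anterior_bite_point_mandible,
                          anterior_bite_point_cranium) {
  stopifnot(inherits(model, "jaw_model"), is.finite(theta), theta >= 0)
  bm <- .as_point3(anterior_bite_point_mandible, "mandibular bite point")
  bc <- .as_point3(anterior_bite_point_cranium, "cranial bite point")
  delta <- model$sense * (theta - model$resting_gape)
  bm <- rotate_about_axis(bm, model$joint_left, model$joint_right, delta)
  sqrt(sum((bm - bc)^2))
}
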