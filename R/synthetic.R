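# Synthetic jaw generator: fully parameterised bilateral jaw models and
# muscle measurement tables with known ground truth, so every pipeline stage
# can be exercised and round-tripped without any external data.

# Run code with a private, seeded RNG stream; the caller's RNG state is
# untouched.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic taxon
#'
#' @param n_muscles Number of adductor muscles (>= 1).
#' @param seed Integer seed; the same spec yields byte-identical output.
#' @param target_fmus Optional numeric vector (length `n_muscles`) of
#'   bilateral contraction forces (N) the generated volumes must reproduce.
#' @param target_bite_total Optional anterior-bite-point total bite force (N)
#'   to hit exactly (volumes are scaled; incompatible with `target_fmus`).
#' @param target_inlever,target_outlever Optional lever targets, mm
#'   (`target_inlever` length `n_muscles`; `target_outlever` named per bite
#'   point, strictly decreasing anterior to posterior).
#' @param skull_length Skull bounding-box length, mm (default 100).
#' @param joint_separation Mediolateral distance between jaw joints, mm.
#' @param resting_gape,step Gape-cycle parameters, degrees (defaults 5, 0.5).
#' @param params [force_parameters()] assumed when converting force targets
#'   to volumes.
#' @return A list of class `synthetic_taxon_spec`.
#' @export
synthetic_taxon_spec <- function(n_muscles = 8, seed = 1,
                                 target_fmus = NULL,
                                 target_bite_total = NULL,
                                 target_inlever = NULL,
                                 target_outlever = NULL,
                                 skull_length = 100,
                                 joint_separation = 20,
                                 resting_gape = 5, step = 0.5,
                                 params = force_parameters()) {
  stopifnot(n_muscles >= 1, is.finite(skull_length), skull_length > 0,
            is.finite(joint_separation), joint_separation > 0,
            inherits(params, "force_parameters"))
  if (!is.null(target_fmus) && !is.null(target_bite_total))
    stop("give target_fmus or target_bite_total, not both")
  if (!is.null(target_fmus)) {
    stopifnot(length(target_fmus) == n_muscles)
    if (any(target_fmus <= 0)) stop("target_fmus implies non-positive volume")
  }
  if (!is.null(target_bite_total) && target_bite_total <= 0)
    stop("target_bite_total must be positive")
  if (!is.null(target_inlever)) stopifnot(length(target_inlever) == n_muscles,
                                          all(target_inlever > 0))
  if (!is.null(target_outlever)) {
    stopifnot(all(target_outlever > 0), !is.null(names(target_outlever)))
    if (is.unsorted(rev(target_outlever), strictly = TRUE))
      stop("target outlevers must strictly decrease anterior -> posterior")
  }
  structure(list(n_muscles = n_muscles, seed = seed,
                 target_fmus = target_fmus,
                 target_bite_total = target_bite_total,
                 target_inlever = target_inlever,
                 target_outlever = target_outlever,
                 skull_length = skull_length,
                 joint_separation = joint_separation,
                 resting_gape = resting_gape, step = step,
                 params = params),
            class = "synthetic_taxon_spec")
}

#' Generate a synthetic taxon
#'
#' Places a bilateral jaw (mediolateral joint axis, anterior towards +x,
#' dorsal +z) inside a skull-sized bounding box: per-muscle origin and
#' insertion anchors, bite points, and a retroarticular depressor. Muscle
#' volumes are assigned so that measuring the generated geometry and running
#' it through the force and lever stages recovers any force targets exactly
#' (round-trip identity). All randomness is driven by `spec$seed` through a
#' private RNG stream.
#'
#' @param spec A [synthetic_taxon_spec()].
#' @return List with `model` (a [jaw_model()] with anterior/posterior
#'   cylinders per muscle), `muscles` (measurement table for
#'   [force_table()]), `landmarks` (the landmark data frame dialect),
#'   `inlever`, `outlever`, `bite_points` and `truth` (the forces and bite
#'   totals implied by the generated geometry, computed by direct formula).
#' @export
make_taxon <- function(spec) {
  stopifnot(inherits(spec, "synthetic_taxon_spec"))
  .with_seed(spec$seed, {
    L <- spec$skull_length
    n <- spec$n_muscles
    names_m <- if (n <= 8) .fixture_muscles[seq_len(n)] else
      c(.fixture_muscles, paste0("mX", seq_len(n - 8)))[seq_len(n)]
    joint_left <- c(0, -spec$joint_separation / 2, 0)
    joint_right <- c(0, spec$joint_separation / 2, 0)
    joint_mid <- c(0, 0, 0)

    # insertions low on the mandible, origins high in the adductor chamber
    ins <- cbind(x = stats::runif(n, 0.10 * L, 0.40 * L),
                 y = stats::runif(n, -0.05 * L, 0.05 * L),
                 z = stats::runif(n, -0.05 * L, 0.05 * L))
    ori <- cbind(x = ins[, 1] + stats::runif(n, -0.15 * L, 0.15 * L),
                 y = ins[, 2] + stats::runif(n, -0.08 * L, 0.08 * L),
                 z = stats::runif(n, 0.45 * L, 0.60 * L))
    if (!is.null(spec$target_inlever)) {
      # rescale each insertion about the joint centre to hit the target arm
      for (i in seq_len(n)) {
        v <- ins[i, ] - joint_mid
        ins[i, ] <- joint_mid + v * spec$target_inlever[i] / sqrt(sum(v^2))
      }
    }
    outlever <- if (!is.null(spec$target_outlever)) spec$target_outlever else
      c(anterior = 0.95 * L, mid_palate = 0.70 * L, posterior = 0.55 * L)
    bite_points <- cbind(x = as.numeric(outlever), y = 0, z = 0)
    rownames(bite_points) <- names(outlever)

    # measured quantities, via the geometry module itself
    len <- vapply(seq_len(n),
                  function(i) path_length(rbind(ori[i, ], ins[i, ])),
                  numeric(1))
    ang <- t(vapply(seq_len(n),
                    function(i) insertion_angles(ori[i, ], ins[i, ]),
                    c(alpha = 0, beta = 0)))
    inlever <- vapply(seq_len(n), function(i)
      lever_lengths(joint_mid, ins[i, ], bite_points)$inlever, numeric(1))
    names(inlever) <- names_m

    sig <- spec$params$stress_sigma * spec$params$correction_factor *
      if (spec$params$bilateral) 2 else 1
    vol <- if (!is.null(spec$target_fmus)) spec$target_fmus * len / sig else
      stats::runif(n, 500, 20000) * (L / 100)^3
    fmus <- vol / len * sig
    fres <- fmus * cos(ang[, "alpha"] * pi / 180) * cos(ang[, "beta"] * pi / 180)
    bite_totals <- vapply(outlever,
                          function(ol) sum(fres * inlever / ol), numeric(1))
    if (!is.null(spec$target_bite_total)) {
      scale <- spec$target_bite_total / bite_totals[[1]]
      vol <- vol * scale; fmus <- fmus * scale; fres <- fres * scale
      bite_totals <- bite_totals * scale
    }

    muscles <- data.frame(muscle = names_m, volume_mm3 = vol, length_mm = len,
                          alpha_deg = ang[, "alpha"], beta_deg = ang[, "beta"],
                          row.names = NULL)

    # gape proxies: anterior/posterior cylinder pair per muscle
    dx <- 0.03 * L
    adductors <- unlist(lapply(seq_len(n), function(i) {
      list(muscle_cylinder(paste0(names_m[i], "1"),
                           ori[i, ] - c(dx, 0, 0), ins[i, ] - c(dx, 0, 0)),
           muscle_cylinder(paste0(names_m[i], "2"),
                           ori[i, ] + c(dx, 0, 0), ins[i, ] + c(dx, 0, 0)))
    }), recursive = FALSE)
    depressor <- muscle_cylinder("mDM",
                                 origin = c(-0.05 * L, 0, 0.30 * L),
                                 insertion = c(-0.08 * L, 0, 0))
    model <- jaw_model(joint_left, joint_right, adductors, depressor,
                       resting_gape = spec$resting_gape, step = spec$step)

    landmarks <- do.call(rbind, c(
      lapply(seq_len(n), function(i) {
        data.frame(taxon = "synthetic", side = "L",
                   muscle = names_m[i],
                   role = c("origin", "insertion"),
                   anchor = "centroid",
                   x = c(ori[i, 1], ins[i, 1]),
                   y = c(ori[i, 2], ins[i, 2]),
                   z = c(ori[i, 3], ins[i, 3]))
      }),
      list(data.frame(taxon = "synthetic", side = c("L", "R"),
                      muscle = NA, role = "joint", anchor = "centroid",
                      x = 0, y = c(joint_left[2], joint_right[2]), z = 0),
           data.frame(taxon = "synthetic", side = "L", muscle = NA,
                      role = "bite", anchor = rownames(bite_points),
                      x = bite_points[, 1], y = bite_points[, 2],
                      z = bite_points[, 3]))))
    rownames(landmarks) <- NULL

    list(model = model, muscles = muscles, landmarks = landmarks,
         inlever = inlever, outlever = outlever, bite_points = bite_points,
         truth = list(fmus = stats::setNames(fmus, names_m),
                      fres = stats::setNames(fres, names_m),
                      bite_totals = bite_totals))
  })
}

#' Planar single-cylinder gape model with a closed-form strain law
#'
#' Builds a jaw whose single adductor lies in the sagittal plane: origin at
#' polar angle `initial_angle` (degrees above the insertion ray) and radius
#' `r_origin` from the joint, insertion at radius `r_insertion`. Its length
#' during opening obeys the law of cosines,
#' \deqn{l(\theta)^2 = r_o^2 + r_i^2 - 2 r_o r_i \cos(\phi_0 + \theta - \theta_{rest}),}
#' so the exact gape angle for any strain limit is recoverable by inversion —
#' the analytic oracle for the grid-based scan in [find_gape_limits()].
#' A geometry whose adductor would shorten on opening (e.g.
#' `initial_angle = 180`) is flagged with attribute `non_adductor` and built
#' with a forced positive sense.
#'
#' @param r_origin,r_insertion Radii from the joint axis, mm.
#' @param initial_angle Enclosed angle between origin and insertion rays at
#'   the resting pose, degrees.
#' @param resting_gape,step Gape-cycle parameters, degrees.
#' @return A [jaw_model()] (attribute `non_adductor` set when degenerate).
#' @export
make_planar_gape_model <- function(r_origin, r_insertion, initial_angle,
                                   resting_gape = 5, step = 0.5) {
  stopifnot(r_origin > 0, r_insertion > 0)
  phi <- initial_angle * pi / 180
  origin <- c(r_origin * cos(phi), 0, r_origin * sin(phi))
  insertion <- c(r_insertion, 0, 0)
  cyl <- muscle_cylinder("adductor1", origin, insertion)
  tryCatch(
    jaw_model(c(0, -5, 0), c(0, 5, 0), list(cyl),
              resting_gape = resting_gape, step = step),
    error = function(e) {
      m <- jaw_model(c(0, -5, 0), c(0, 5, 0), list(cyl),
                     resting_gape = resting_gape, step = step, sense = 1)
      attr(m, "non_adductor") <- TRUE
      warning("planar model is not an adductor geometry: ",
              conditionMessage(e), call. = FALSE)
      m
    })
}

#' Analytic gape angle at which a planar model reaches a strain limit
#'
#' Inverts the law-of-cosines strain law of [make_planar_gape_model()].
#'
#' @param r_origin,r_insertion,initial_angle,resting_gape Model parameters
#'   as in [make_planar_gape_model()].
#' @param strain Strain factor to invert for (e.g. 1.3).
#' @return Exact crossing angle in degrees, or `NA` if the strain is never
#'   reached.
#' @export
planar_strain_crossing <- function(r_origin, r_insertion, initial_angle,
                                   strain, resting_gape = 5) {
  phi <- initial_angle * pi / 180
  l0sq <- r_origin^2 + r_insertion^2 - 2 * r_origin * r_insertion * cos(phi)
  cosv <- (r_origin^2 + r_insertion^2 - strain^2 * l0sq) /
    (2 * r_origin * r_insertion)
  if (cosv < -1) return(NA_real_)
  resting_gape + (acos(pmin(1, cosv)) - phi) * 180 / pi
}

#' Closed tube-like mesh of prescribed volume
#'
#' Builds a closed, consistently oriented prism (an n-gon tube with capped
#' ends) whose divergence-theorem volume equals `volume_target` by
#' construction, then applies a seed-driven rigid rotation and translation.
#' Exercises [mesh_volume()] against a known value.
#'
#' @param volume_target Enclosed volume, cubic mm.
#' @param length Tube length, mm.
#' @param seed Integer seed (controls cross-section, phase and pose).
#' @return A [trimesh()].
#' @export
make_muscle_mesh <- function(volume_target, length, seed = 1) {
  stopifnot(volume_target > 0, length > 0)
  .with_seed(seed, {
    n <- sample(20:40, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    area <- volume_target / length
    r <- sqrt(2 * area / (n * sin(2 * pi / n)))
    ang <- phase + 2 * pi * (seq_len(n) - 1) / n
    ring0 <- cbind(r * cos(ang), r * sin(ang), 0)
    ring1 <- cbind(r * cos(ang), r * sin(ang), length)
    verts <- rbind(ring0, ring1, c(0, 0, 0), c(0, 0, length))
    c0 <- 2L * n + 1L; c1 <- 2L * n + 2L
    i <- seq_len(n); j <- c(seq_len(n)[-1], 1L)
    faces <- rbind(
      cbind(i, j, n + j),            # side, lower triangles
      cbind(i, n + j, n + i),        # side, upper triangles
      cbind(j, i, c0),               # bottom cap (outward -z)
      cbind(n + i, n + j, c1))       # top cap (outward +z)
    mesh <- trimesh(verts, faces)
    # random rigid pose (volume-preserving)
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    theta <- stats::runif(1, 0, 360)
    v <- rotate_about_axis(mesh$vertices, c(0, 0, 0), axis, theta)
    v <- sweep(v, 2, stats::runif(3, -50, 50), `+`)
    trimesh(v, mesh$faces)
  })
}
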