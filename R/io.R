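# Table and model I/O: CSV/JSON muscle and lever tables, the landmark
# dialect, and JSON jaw models.

#' Read a muscle measurement/force table
#'
#' CSV or JSON with one row per muscle; required columns `muscle`,
#' `volume_mm3`, `length_mm`, `alpha_deg`, `beta_deg`; force columns
#' (`fmus_N`, `fres_N`, contributions) are carried if present.
#'
#' @param path CSV or JSON file path.
#' @return Data frame.
#' @export
read_muscle_table <- function(path) {
  df <- .read_table_any(path)
  .check_muscle_table(df)
}

.read_table_any <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path)
  if (tolower(tools::file_ext(path)) == "json")
    as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a table as CSV or JSON (by extension)
#'
#' @param df Data frame.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_table_any <- function(df, path) {
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  else utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a lever table
#'
#' CSV/JSON with columns `muscle`, `inlever_mm`, and one `outlever_mm.<bite
#' point>` column per bite point (constant within column), or the pair
#' `bite_point`/`outlever_mm` in long form alongside the per-muscle rows.
#'
#' @param path CSV or JSON path.
#' @return List with named `inlever` (per muscle) and `outlever` (per bite
#'   point), mm.
#' @export
read_lever_table <- function(path) {
  df <- .read_table_any(path)
  if (!"muscle" %in% names(df) || !"inlever_mm" %in% names(df))
    stop("lever table needs columns muscle and inlever_mm")
  rows <- !is.na(df$inlever_mm)
  inlever <- stats::setNames(df$inlever_mm[rows], df$muscle[rows])
  ocols <- grep("^outlever_mm\\.", names(df), value = TRUE)
  if (length(ocols)) {
    outlever <- vapply(ocols, function(cn) df[[cn]][which(!is.na(df[[cn]]))[1]],
                       numeric(1))
    names(outlever) <- sub("^outlever_mm\\.", "", ocols)
  } else if (all(c("bite_point", "outlever_mm") %in% names(df))) {
    keep <- !is.na(df$outlever_mm) & !is.na(df$bite_point)
    outlever <- stats::setNames(df$outlever_mm[keep], df$bite_point[keep])
    outlever <- outlever[!duplicated(names(outlever))]
  } else stop("lever table needs outlever_mm.<point> columns or ",
              "bite_point/outlever_mm")
  if (any(inlever <= 0) || any(outlever <= 0))
    stop("levers must be positive")
  list(inlever = inlever, outlever = outlever)
}

#' Write a lever table (wide CSV layout)
#'
#' @param inlever Named per-muscle inlevers, mm.
#' @param outlever Named per-bite-point outlevers, mm.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lever_table <- function(inlever, outlever, path) {
  df <- data.frame(muscle = names(inlever), inlever_mm = as.numeric(inlever))
  for (bp in names(outlever)) df[[paste0("outlever_mm.", bp)]] <- outlever[[bp]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read 3D landmarks
#'
#' CSV (or a JSON array of records) with columns `taxon`, `side` (L/R),
#' `muscle`, `role` (origin/insertion/joint/bite), `anchor`
#' (anterior/posterior/centroid or a bite-point label), `x`, `y`, `z` (mm).
#'
#' @param path CSV or JSON path.
#' @return Data frame of landmarks.
#' @export
read_landmarks <- function(path) {
  df <- .read_table_any(path)
  need <- c("taxon", "side", "muscle", "role", "anchor", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite landmark coordinates")
  df
}

#' Build a jaw model from a landmark table
#'
#' Joints come from `role == "joint"` rows (sides L/R); each muscle's
#' anterior/posterior origin and insertion anchors become one cylinder each
#' (`<muscle>1` anterior, `<muscle>2` posterior); a muscle named `mDM`
#' becomes the depressor (its centroid or anterior anchors are used).
#'
#' @param landmarks Data frame as from [read_landmarks()].
#' @param resting_gape,step,sense Passed to [jaw_model()].
#' @return A [jaw_model()].
#' @export
jaw_model_from_landmarks <- function(landmarks, resting_gape = 5, step = 0.5,
                                     sense = NULL) {
  lm <- landmarks
  pt <- function(rows) {
    if (!nrow(rows)) return(NULL)
    colMeans(rows[, c("x", "y", "z"), drop = FALSE])
  }
  joints <- lm[lm$role == "joint", , drop = FALSE]
  if (!nrow(joints)) stop("no joint landmarks")
  jl <- pt(joints[joints$side == "L", , drop = FALSE])
  jr <- pt(joints[joints$side == "R", , drop = FALSE])
  if (is.null(jl)) jl <- pt(joints)
  muscles <- setdiff(unique(lm$muscle[lm$role %in% c("origin", "insertion")]), NA)
  cyl_for <- function(m, anchor, tag) {
    o <- pt(lm[lm$muscle %in% m & lm$role == "origin" &
                 lm$anchor == anchor, , drop = FALSE])
    i <- pt(lm[lm$muscle %in% m & lm$role == "insertion" &
                 lm$anchor == anchor, , drop = FALSE])
    if (is.null(o) || is.null(i)) return(NULL)
    muscle_cylinder(paste0(m, tag), o, i)
  }
  adductors <- list(); depressor <- NULL
  for (m in muscles) {
    cyls <- Filter(Negate(is.null),
                   list(cyl_for(m, "anterior", "1"),
                        cyl_for(m, "posterior", "2"),
                        cyl_for(m, "centroid", "")))
    if (!length(cyls))
      stop("muscle '", m, "' lacks matched origin/insertion anchors")
    if (m == "mDM") {
      depressor <- cyls[[1]]
      depressor$id <- "mDM"
    } else adductors <- c(adductors, cyls)
  }
  jaw_model(jl, jr, adductors, depressor,
            resting_gape = resting_gape, step = step, sense = sense)
}

#' Measure muscle geometry and levers from landmarks
#'
#' For each muscle with centroid (or averaged anterior/posterior) origin and
#' insertion anchors: straight-line length, sagittal/coronal insertion
#' angles, and the inlever from the joint centre; outlevers come from the
#' `role == "bite"` rows (labelled by their `anchor`).
#'
#' @param landmarks Data frame as from [read_landmarks()].
#' @param frame An [anatomical_frame()].
#' @return List with `muscles` (data frame: `muscle`, `length_mm`,
#'   `alpha_deg`, `beta_deg`, `inlever_mm`) and `outlever` (named, mm).
#' @export
measure_landmarks <- function(landmarks, frame = anatomical_frame()) {
  lm <- landmarks
  pt <- function(rows) colMeans(rows[, c("x", "y", "z"), drop = FALSE])
  joints <- lm[lm$role == "joint", , drop = FALSE]
  if (!nrow(joints)) stop("no joint landmarks")
  joint <- pt(joints)
  bites <- lm[lm$role == "bite", , drop = FALSE]
  bp <- if (nrow(bites)) {
    m <- as.matrix(bites[, c("x", "y", "z")])
    rownames(m) <- bites$anchor
    m
  } else NULL
  muscles <- setdiff(unique(lm$muscle[lm$role %in% c("origin", "insertion")]), NA)
  rows <- lapply(muscles, function(m) {
    o <- pt(lm[lm$muscle %in% m & lm$role == "origin", , drop = FALSE])
    i <- pt(lm[lm$muscle %in% m & lm$role == "insertion", , drop = FALSE])
    ang <- insertion_angles(o, i, frame)
    data.frame(muscle = m,
               length_mm = path_length(rbind(o, i)),
               alpha_deg = ang[["alpha"]], beta_deg = ang[["beta"]],
               inlever_mm = lever_lengths(joint, i, rbind(joint + 1))$inlever)
  })
  out <- do.call(rbind, rows)
  outlever <- if (!is.null(bp)) lever_lengths(joint, joint + 1, bp)$outlever
  list(muscles = out, outlever = outlever)
}

#' Read/write a jaw model as JSON
#'
#' The JSON layout mirrors [jaw_model()]: `joint_left`, `joint_right`,
#' `resting_gape`, `step`, optional `sense`, and `cylinders` — an array of
#' `{id, role (adductor|depressor), origin, insertion}` records.
#'
#' @param path JSON file path.
#' @return A [jaw_model()].
#' @export
read_jaw_model <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  cyls <- lapply(j$cylinders, function(cl)
    c(list(muscle_cylinder(cl$id, unlist(cl$origin), unlist(cl$insertion))),
      role = cl$role %||% "adductor"))
  roles <- vapply(cyls, `[[`, "", "role")
  adductors <- lapply(cyls[roles != "depressor"], `[[`, 1L)
  depressor <- if (any(roles == "depressor"))
    cyls[[which(roles == "depressor")[1]]][[1L]] else NULL
  jaw_model(unlist(j$joint_left), unlist(j$joint_right), adductors, depressor,
            resting_gape = j$resting_gape %||% 5,
            step = j$step %||% 0.5,
            sense = j$sense)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_jaw_model
#' @param model A [jaw_model()].
#' @return `write_jaw_model`: `path`, invisibly.
#' @export
write_jaw_model <- function(model, path) {
  stopifnot(inherits(model, "jaw_model"))
  cyl_rec <- function(cyl, role)
    list(id = cyl$id, role = role,
         origin = cyl$origin, insertion = cyl$insertion)
  cyls <- lapply(model$adductors, cyl_rec, role = "adductor")
  if (!is.null(model$depressor))
    cyls <- c(cyls, list(cyl_rec(model$depressor, "depressor")))
  jsonlite::write_json(
    list(joint_left = model$joint_left, joint_right = model$joint_right,
         resting_gape = model$resting_gape, step = model$step,
         sense = model$sense, cylinders = unname(cyls)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
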