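# Geometric measurement: closed-mesh volumetrics, path lengths, 3D insertion
# angles and lever arms measured in a skull-fixed anatomical frame.

#' Skull-fixed anatomical reference frame
#'
#' Defines the three anatomical axes used to resolve muscle lines of action.
#' The sagittal plane is spanned by the anteroposterior and dorsoventral axes,
#' the coronal plane by the mediolateral and dorsoventral axes, and the
#' dorsoventral axis is the "vertical" against which the insertion angles
#' \eqn{\alpha} (sagittal) and \eqn{\beta} (coronal) are measured.
#'
#' @param anteroposterior,mediolateral,dorsoventral Numeric length-3 axis
#'   vectors; they are normalised and must be mutually orthogonal (within
#'   1e-9) and right-handed.
#' @param origin Numeric length-3 frame origin, mm.
#' @return An object of class `anatomical_frame`.
#' @examples
#' fr <- anatomical_frame()  # x anterior, y left, z dorsal
#' @export
anatomical_frame <- function(anteroposterior = c(1, 0, 0),
                             mediolateral = c(0, 1, 0),
                             dorsoventral = c(0, 0, 1),
                             origin = c(0, 0, 0)) {
  ax <- lapply(list(ap = anteroposterior, ml = mediolateral, dv = dorsoventral),
               function(v) {
    v <- as.numeric(v)
    stopifnot(length(v) == 3, all(is.finite(v)))
    n <- sqrt(sum(v^2))
    if (n == 0) stop("anatomical frame axis has zero length")
    v / n
  })
  dots <- c(sum(ax$ap * ax$ml), sum(ax$ap * ax$dv), sum(ax$ml * ax$dv))
  if (any(abs(dots) > 1e-9)) stop("anatomical frame axes are not orthogonal")
  if (sum(.cross3(ax$ap, ax$ml) * ax$dv) < 0)
    stop("anatomical frame is not right-handed (ap x ml must point dorsally)")
  structure(list(ap = ax$ap, ml = ax$ml, dv = ax$dv,
                 origin = as.numeric(origin)),
            class = "anatomical_frame")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || !all(is.finite(p)))
    stop(sprintf("%s must be a finite length-3 coordinate", what))
  p
}

#' Triangle mesh
#'
#' A minimal triangle-mesh container: an n x 3 vertex matrix (mm) and an
#' m x 3 integer face matrix of 1-based vertex indices.
#'
#' @param vertices Numeric matrix, n x 3.
#' @param faces Integer matrix, m x 3 (1-based indices into `vertices`).
#' @return An object of class `trimesh`.
#' @seealso [mesh_volume()], [read_mesh()]
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || !all(is.finite(vertices)))
    stop("vertices must be a finite n x 3 matrix")
  if (ncol(faces) != 3) stop("faces must be an m x 3 index matrix")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Directed half-edges of every triangle, as a character key "a>b".
.mesh_halfedges <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  list(from = from, to = to)
}

#' Validate that a mesh is closed and consistently oriented
#'
#' A mesh encloses a volume only if every undirected edge is shared by exactly
#' two triangles with opposite winding, i.e. every directed half-edge appears
#' exactly once and so does its reverse.
#'
#' @param mesh A [trimesh()].
#' @return `TRUE` invisibly; otherwise an error naming offending edges.
#' @export
check_mesh_closed <- function(mesh) {
  he <- .mesh_halfedges(mesh)
  fwd <- paste(he$from, he$to, sep = ">")
  rev <- paste(he$to, he$from, sep = ">")
  dup <- fwd[duplicated(fwd)]
  if (length(dup))
    stop("mesh not closed: duplicated half-edges (non-manifold or flipped): ",
         paste(utils::head(unique(dup), 5L), collapse = ", "))
  unmatched <- setdiff(fwd, rev)
  if (length(unmatched))
    stop("mesh not closed: boundary edges ",
         paste(utils::head(unmatched, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Computes the enclosed volume by the divergence theorem as the sum of signed
#' tetrahedron volumes spanned by each triangle and the origin,
#' orientation-normalised to be non-negative. The mesh must be closed and
#' consistently oriented (checked; see [check_mesh_closed()]).
#'
#' @param mesh A [trimesh()].
#' @return Volume in cubic millimetres.
#' @examples
#' cube <- trimesh(
#'   rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
#'         c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)),
#'   rbind(c(1,3,2), c(1,4,3), c(5,6,7), c(5,7,8),
#'         c(1,2,6), c(1,6,5), c(2,3,7), c(2,7,6),
#'         c(3,4,8), c(3,8,7), c(4,1,5), c(4,5,8)))
#' mesh_volume(cube)  # 1
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  check_mesh_closed(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c) per face
  cx <- b[, 2] * cc[, 3] - b[, 3] * cc[, 2]
  cy <- b[, 3] * cc[, 1] - b[, 1] * cc[, 3]
  cz <- b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
  abs(sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz)) / 6
}

#' Length of a polyline
#'
#' Sum of consecutive Euclidean segment lengths; with two points this is the
#' straight-line (chord) muscle length.
#'
#' @param points Numeric matrix (k x 3, k >= 2) or list of length-3 points.
#' @return Length in mm.
#' @examples
#' path_length(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))  # 7
#' @export
path_length <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("path_length needs at least 2 points")
  if (ncol(points) != 3 || !all(is.finite(points)))
    stop("points must be finite 3D coordinates")
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Sagittal and coronal insertion angles of a muscle line of action
#'
#' The line of action runs from the insertion centroid towards the origin
#' centroid. `alpha` is the angle between the dorsoventral (vertical) axis and
#' the projection of the line of action onto the sagittal plane; `beta` is the
#' same for the coronal plane. Both are folded into \[0, 90\] degrees (their
#' cosines feed the resultant-force resolution, so sign is irrelevant). A
#' projection that vanishes (line of action orthogonal to the plane) yields a
#' 0-degree angle and a `degenerate` attribute.
#'
#' @param origin_centroid,insertion_centroid Length-3 coordinates, mm.
#' @param frame An [anatomical_frame()].
#' @return Named numeric `c(alpha = , beta = )` in degrees.
#' @export
insertion_angles <- function(origin_centroid, insertion_centroid,
                             frame = anatomical_frame()) {
  stopifnot(inherits(frame, "anatomical_frame"))
  o <- .as_point3(origin_centroid, "origin centroid")
  i <- .as_point3(insertion_centroid, "insertion centroid")
  v <- o - i
  if (all(v == 0)) stop("origin and insertion centroids coincide")
  a <- sum(v * frame$ap)   # anteroposterior component
  m <- sum(v * frame$ml)   # mediolateral component
  d <- sum(v * frame$dv)   # dorsoventral component
  degen <- c(alpha = (a == 0 && d == 0), beta = (m == 0 && d == 0))
  alpha <- if (degen[["alpha"]]) 0 else atan2(abs(a), abs(d)) * 180 / pi
  beta  <- if (degen[["beta"]])  0 else atan2(abs(m), abs(d)) * 180 / pi
  out <- c(alpha = alpha, beta = beta)
  if (any(degen)) attr(out, "degenerate") <- names(degen)[degen]
  out
}

#' Inlever and outlever moment-arm distances
#'
#' Straight-line 3D Euclidean distances from the jaw joint to a muscle
#' insertion point (inlever) and to each bite point (outlevers). Callers
#' wanting sagittal-projected levers should project the coordinates first.
#'
#' @param joint_center Length-3 jaw-joint coordinate, mm.
#' @param insertion_point Length-3 muscle insertion coordinate, mm.
#' @param bite_points Matrix (k x 3) or list of bite-point coordinates.
#' @return List with `inlever` (mm) and named numeric `outlever` (mm).
#' @export
lever_lengths <- function(joint_center, insertion_point, bite_points) {
  j <- .as_point3(joint_center, "joint center")
  ins <- .as_point3(insertion_point, "insertion point")
  if (is.list(bite_points) && !is.data.frame(bite_points))
    bite_points <- do.call(rbind, bite_points)
  bp <- as.matrix(bite_points)
  if (ncol(bp) != 3 || !all(is.finite(bp)))
    stop("bite points must be finite 3D coordinates")
  out <- sqrt(colSums((t(bp) - j)^2))
  names(out) <- rownames(bp)
  list(inlever = sqrt(sum((ins - j)^2)), outlever = out)
}

#' Muscle geometry record
#'
#' Bundles a muscle's measured volume, length and insertion angles; the
#' physiological cross-sectional area proxy is `csa = volume / length`.
#'
#' @param volume Muscle volume, cubic mm (non-negative).
#' @param length Muscle length, mm (positive).
#' @param alpha,beta Insertion angles in the sagittal and coronal planes,
#'   degrees, each in \[0, 90).
#' @return A list of class `muscle_geometry` with fields `volume`, `length`,
#'   `csa`, `alpha`, `beta`.
#' @export
muscle_geometry <- function(volume, length, alpha = 0, beta = 0) {
  stopifnot(is.finite(volume), volume >= 0,
            is.finite(length), length > 0,
            is.finite(alpha), alpha >= 0, alpha < 90,
            is.finite(beta), beta >= 0, beta < 90)
  structure(list(volume = volume, length = length, csa = volume / length,
                 alpha = alpha, beta = beta),
            class = "muscle_geometry")
}

#' Read a triangle mesh from an ASCII OBJ or PLY file
#'
#' Supports the vertex/face subset of Wavefront OBJ (`v`, `f`, with optional
#' `v/vt/vn` index syntax) and ASCII PLY. Quad faces are fan-triangulated on
#' read; higher-order polygons are rejected.
#'
#' @param path Path to a `.obj` or `.ply` file.
#' @return A [trimesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = .read_obj(path),
         ply = .read_ply(path),
         stop("unsupported mesh format '", ext, "' (use OBJ or PLY)"))
}

.fan_triangulate <- function(idx) {
  if (length(idx) < 3) stop("face with fewer than 3 vertices")
  if (length(idx) > 4) stop("faces with more than 4 vertices are unsupported")
  if (length(idx) == 3) matrix(idx, 1)
  else rbind(idx[c(1, 2, 3)], idx[c(1, 3, 4)])
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  verts <- list(); faces <- list()
  for (tk in toks) {
    if (!length(tk)) next
    if (tk[1] == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(tk[2:4])
    } else if (tk[1] == "f") {
      idx <- as.integer(vapply(strsplit(tk[-1], "/"), `[`, "", 1L))
      faces[[length(faces) + 1L]] <- .fan_triangulate(idx)
    }
  }
  if (!length(verts)) stop("no vertices in OBJ file ", path)
  if (!length(faces)) stop("no faces in OBJ file ", path)
  trimesh(do.call(rbind, verts), do.call(rbind, faces))
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format[[:space:]]+ascii", hdr)))
    stop("only ASCII PLY is supported")
  elems <- regmatches(hdr, regexec("^element[[:space:]]+(\\w+)[[:space:]]+(\\d+)", hdr))
  elems <- Filter(length, elems)
  counts <- stats::setNames(as.integer(vapply(elems, `[`, "", 3L)),
                            vapply(elems, `[`, "", 2L))
  if (!all(c("vertex", "face") %in% names(counts)))
    stop("PLY must declare vertex and face elements")
  body <- strsplit(trimws(lines[(hdr_end + 1L):length(lines)]), "[[:space:]]+")
  body <- Filter(length, body)
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  if (length(body) < nv + nf) stop("truncated PLY body")
  verts <- t(vapply(body[seq_len(nv)],
                    function(tk) as.numeric(tk[1:3]), numeric(3)))
  faces <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(tk) {
    k <- as.integer(tk[1])
    .fan_triangulate(as.integer(tk[1 + seq_len(k)]) + 1L)  # PLY is 0-based
  }))
  trimesh(verts, faces)
}

#' Write a triangle mesh as ASCII OBJ
#'
#' @param mesh A [trimesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  v <- sprintf("v %.9g %.9g %.9g",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}
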