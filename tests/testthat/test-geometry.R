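# Mesh volumetrics, path lengths, insertion angles and lever arms.

test_that("mesh_volume is exact on boxes and errors on open meshes", {
  expect_equal(mesh_volume(cube_mesh()), 1)
  expect_equal(mesh_volume(cube_mesh(scale = 2.5, shift = c(10, -4, 3))),
               2.5^3)
  open_cube <- cube_mesh()
  open_cube$faces <- open_cube$faces[-1, ]
  expect_error(mesh_volume(open_cube), "not closed")
  flipped <- cube_mesh()
  flipped$faces[2, ] <- flipped$faces[2, c(2, 1, 3)]
  expect_error(mesh_volume(flipped), "not closed")
})

test_that("mesh_volume converges to the sphere volume", {
  r <- 10
  vols <- vapply(1:4, function(s) mesh_volume(icosphere_mesh(r, s)),
                 numeric(1))
  errs <- abs(vols - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  expect_lt(errs[4], 0.01)
  expect_true(all(diff(errs) < 0))  # monotone convergence to the closed form
  expect_equal(vols[4], 4188.79, tolerance = 0.01)
})

test_that("mesh_volume is rigid-motion invariant and additive over parts", {
  mesh <- icosphere_mesh(5, 2)
  v0 <- mesh_volume(mesh)
  rot <- trimesh(rotate_about_axis(mesh$vertices, c(1, 2, 3), c(4, -1, 0), 73.2),
                 mesh$faces)
  expect_equal(mesh_volume(rot), v0, tolerance = 1e-12)
  # two disjoint cubes in one mesh: volume of the union equals the sum
  a <- cube_mesh()
  b <- cube_mesh(scale = 2, shift = c(5, 5, 5))
  union <- trimesh(rbind(a$vertices, b$vertices),
                   rbind(a$faces, b$faces + nrow(a$vertices)))
  expect_equal(mesh_volume(union), 1 + 8)
})

test_that("OBJ and PLY round-trip through the readers", {
  mesh <- cube_mesh(scale = 3)
  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh(mesh, obj)
  back <- read_mesh(obj)
  expect_equal(back$vertices, mesh$vertices, ignore_attr = TRUE)
  expect_equal(mesh_volume(back), 27)
  # quad OBJ gets fan-triangulated
  quad_obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), quad_obj)
  quad <- read_mesh(quad_obj)
  expect_identical(nrow(quad$faces), 2L)
  # minimal ASCII PLY tetrahedron
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3"), ply)
  expect_equal(mesh_volume(read_mesh(ply)), 1 / 6, tolerance = 1e-12)
})

test_that("path_length sums Euclidean segments", {
  expect_equal(path_length(rbind(c(0, 0, 0), c(0, 0, 43.4))), 43.4)
  expect_equal(path_length(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))), 7)
  expect_error(path_length(rbind(c(0, 0, 0))), "at least 2")
  set.seed(11)
  pts <- matrix(rnorm(30), ncol = 3)
  hand <- sum(vapply(2:10, function(i) sqrt(sum((pts[i, ] - pts[i - 1, ])^2)),
                     numeric(1)))
  expect_equal(path_length(pts), hand, tolerance = 1e-14)
})

test_that("insertion angles match the acos oracle and fold into [0, 90]", {
  expect_equal(insertion_angles(c(0, 0, 10), c(0, 0, 0)),
               c(alpha = 0, beta = 0))
  expect_equal(insertion_angles(c(10, 0, 10), c(0, 0, 0)),
               c(alpha = 45, beta = 0))
  set.seed(21)
  for (i in 1:100) {
    o <- rnorm(3, sd = 20); ins <- rnorm(3, sd = 20)
    if (all(o == ins)) next
    got <- insertion_angles(o, ins)
    expect_equal(got, angles_acos_oracle(o, ins), tolerance = 1e-9)
    expect_true(all(got >= 0 & got <= 90))
  }
})

test_that("insertion angles are scale invariant and flag degeneracy", {
  o <- c(3, 2, 9); i <- c(1, -1, 0.5)
  expect_equal(insertion_angles(o * 7.3, i * 7.3), insertion_angles(o, i),
               tolerance = 1e-12)
  # line of action purely mediolateral: sagittal projection vanishes
  res <- insertion_angles(c(0, 5, 0), c(0, 0, 0))
  expect_equal(res[["alpha"]], 0)
  expect_equal(res[["beta"]], 90)
  expect_true("alpha" %in% attr(res, "degenerate"))
  expect_error(insertion_angles(c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("lever arms are 3D joint distances", {
  lv <- lever_lengths(c(0, 0, 0), c(19.8, 0, 0), rbind(c(90.4, 0, 0)))
  expect_equal(lv$inlever, 19.8)
  expect_equal(unname(lv$outlever), 90.4)
  expect_equal(lever_lengths(c(1, 2, 3), c(1, 2, 3),
                             rbind(c(0, 0, 0)))$inlever, 0)
  set.seed(31)
  j <- rnorm(3); ins <- rnorm(3); bp <- matrix(rnorm(9), 3)
  lv <- lever_lengths(j, ins, bp)
  expect_equal(lv$inlever, sqrt(sum((ins - j)^2)))
  expect_equal(unname(lv$outlever),
               apply(bp, 1, function(p) sqrt(sum((p - j)^2))))
})

test_that("muscle_geometry enforces the csa identity and invariants", {
  g <- muscle_geometry(1492.1, 43.4, 27.6, 4.4)
  expect_equal(g$csa * g$length, g$volume, tolerance = 1e-15)
  expect_error(muscle_geometry(100, 0), "length")
  expect_error(muscle_geometry(100, 10, alpha = 90), "alpha")
  expect_error(anatomical_frame(mediolateral = c(1, 0.1, 0)), "orthogonal")
  expect_error(anatomical_frame(dorsoventral = c(0, 0, -1)), "right-handed")
})
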