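# Test-only geometry builders and independent oracles.

# Unit cube as a closed, outward-oriented triangle mesh, optionally scaled
# and translated.
cube_mesh <- function(scale = 1, shift = c(0, 0, 0)) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (z = 0, normal -z)
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(2, 3, 7), c(2, 7, 6),   # x = 1
             c(3, 4, 8), c(3, 8, 7),   # y = 1
             c(4, 1, 5), c(4, 5, 8))   # x = 0
  trimesh(sweep(v * scale, 2, shift, `+`), f)
}

# Icosphere: icosahedron subdivided n times, vertices pushed to radius r.
icosphere_mesh <- function(r = 1, subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  norm_r <- function(m) m * r / sqrt(rowSums(m^2))
  v <- norm_r(v)
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(sort(c(i, j)), collapse = "_")
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, norm_r(matrix((v[i, ] + v[j, ]) / 2, 1)))
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    f <- do.call(rbind, lapply(seq_len(nrow(f)), function(k) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      rbind(c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }))
  }
  trimesh(v, f)
}

# Independent rotation oracle: quaternion conjugation q p q*.
quaternion_rotate <- function(p, axis_a, axis_b, theta_deg) {
  k <- axis_b - axis_a
  k <- k / sqrt(sum(k^2))
  h <- theta_deg * pi / 180 / 2
  q <- c(cos(h), sin(h) * k)
  qmul <- function(a, b) c(
    a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
  pq <- c(0, p - axis_a)
  qc <- c(q[1], -q[2:4])
  axis_a + qmul(qmul(q, pq), qc)[2:4]
}

# Independent angle oracle: acos of the dot product between the vertical
# axis and the normalised in-plane projection of the line of action.
angles_acos_oracle <- function(origin, insertion, frame = anatomical_frame()) {
  v <- origin - insertion
  comp <- c(ap = sum(v * frame$ap), ml = sum(v * frame$ml),
            dv = sum(v * frame$dv))
  one <- function(inplane) {
    proj <- c(inplane, comp[["dv"]])
    if (all(proj == 0)) return(0)
    ang <- acos(min(1, abs(proj[2]) / sqrt(sum(proj^2)))) * 180 / pi
    ang
  }
  c(alpha = one(comp[["ap"]]), beta = one(comp[["ml"]]))
}

# Printed-table fixture of a single taxon as force_table() input.
fixture_measurements <- function(taxon) {
  oviraptor_fixtures()[[taxon]]$muscle_table[
    , c("muscle", "volume_mm3", "length_mm", "alpha_deg", "beta_deg")]
}
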