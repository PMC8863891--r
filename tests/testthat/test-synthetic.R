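# Synthetic taxon generator: determinism, parameter recovery, mesh targets,
# and fixture integrity.

test_that("make_taxon is deterministic in the seed", {
  a <- make_taxon(synthetic_taxon_spec(seed = 123))
  b <- make_taxon(synthetic_taxon_spec(seed = 123))
  c <- make_taxon(synthetic_taxon_spec(seed = 124))
  expect_identical(a$muscles, b$muscles)
  expect_identical(a$landmarks, b$landmarks)
  expect_false(identical(a$muscles$volume_mm3, c$muscles$volume_mm3))
  # generator leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_taxon(synthetic_taxon_spec(seed = 1)))
  expect_identical(runif(1), before)
})

test_that("the pipeline recovers seeded force targets (round trip)", {
  target <- c(30, 45, 120, 18, 9, 14, 52, 70)
  spec <- synthetic_taxon_spec(n_muscles = 8, seed = 77, target_fmus = target)
  tx <- make_taxon(spec)
  ft <- force_table(tx$muscles)
  expect_equal(ft$fmus_N, target, tolerance = 1e-9)
  expect_equal(unname(ft$fres_N), unname(tx$truth$fres), tolerance = 1e-9)
  bt <- bite_table(ft, tx$inlever, tx$outlever)
  expect_equal(unname(bt$totals), unname(tx$truth$bite_totals),
               tolerance = 1e-9)
})

test_that("a target anterior bite total is hit exactly", {
  spec <- synthetic_taxon_spec(seed = 3, target_bite_total = 53.0)
  tx <- make_taxon(spec)
  bt <- bite_table(force_table(tx$muscles), tx$inlever, tx$outlever)
  expect_equal(unname(bt$totals[[1]]), 53.0, tolerance = 1e-6)
})

test_that("measurements re-derived from landmarks match the emitted table", {
  tx <- make_taxon(synthetic_taxon_spec(seed = 15))
  meas <- measure_landmarks(tx$landmarks)
  m <- meas$muscles[match(tx$muscles$muscle, meas$muscles$muscle), ]
  expect_equal(m$length_mm, tx$muscles$length_mm, tolerance = 1e-9)
  expect_equal(m$alpha_deg, tx$muscles$alpha_deg, tolerance = 1e-9)
  expect_equal(m$beta_deg, tx$muscles$beta_deg, tolerance = 1e-9)
  expect_equal(unname(m$inlever_mm), unname(tx$inlever), tolerance = 1e-9)
  expect_equal(meas$outlever[names(tx$outlever)], tx$outlever,
               tolerance = 1e-9)
})

test_that("single-muscle degenerate case: inlever = outlever gives fbite = fres", {
  spec <- synthetic_taxon_spec(n_muscles = 1, seed = 6,
                               target_inlever = 40,
                               target_outlever = c(anterior = 40))
  tx <- make_taxon(spec)
  ft <- force_table(tx$muscles)
  bt <- bite_table(ft, tx$inlever, tx$outlever)
  expect_equal(unname(bt$totals[[1]]), ft$fres_N, tolerance = 1e-12)
})

test_that("generated geometry stays finite and inside the bounding box", {
  for (seed in 1:5) {
    tx <- make_taxon(synthetic_taxon_spec(seed = seed, skull_length = 80))
    xyz <- as.matrix(tx$landmarks[, c("x", "y", "z")])
    expect_true(all(is.finite(xyz)))
    expect_true(all(abs(xyz) <= 80))
  }
})

test_that("infeasible targets are rejected", {
  expect_error(synthetic_taxon_spec(target_fmus = c(rep(10, 7), -5)),
               "non-positive volume")
  expect_error(synthetic_taxon_spec(target_fmus = 1:3), "length")
  expect_error(synthetic_taxon_spec(target_bite_total = -2), "positive")
  expect_error(synthetic_taxon_spec(target_fmus = rep(10, 8),
                                    target_bite_total = 50), "not both")
  expect_error(synthetic_taxon_spec(
    target_outlever = c(anterior = 50, posterior = 60)), "decrease")
})

test_that("make_muscle_mesh hits the volume target with a closed mesh", {
  for (seed in c(1, 2)) {
    mesh <- make_muscle_mesh(1492.1, 43.4, seed = seed)
    expect_silent(check_mesh_closed(mesh))
    expect_equal(mesh_volume(mesh), 1492.1, tolerance = 0.005)
  }
  m1 <- make_muscle_mesh(1000, 50, seed = 1)
  m2 <- make_muscle_mesh(1000, 50, seed = 2)
  expect_false(isTRUE(all.equal(dim(m1$vertices), dim(m2$vertices))) &&
                 isTRUE(all.equal(m1$vertices, m2$vertices)))
})

test_that("fixture tables are internally consistent as printed", {
  fx <- oviraptor_fixtures()
  expect_identical(names(fx),
                   c("Incisivosaurus", "Citipati", "Khaan", "Conchoraptor"))
  expect_equal(fx$Citipati$muscle_table$volume_mm3[
    fx$Citipati$muscle_table$muscle == "mAMES"], 19580.5)
  expect_equal(unname(fx$Khaan$gape), c(20.5, 40.0))
  expect_equal(unname(fx$Conchoraptor$bite_totals), c(106.7, 119.0, 157.0))
  for (tx in names(fx)) {
    f <- fx[[tx]]
    # printed per-muscle values column-sum to the printed totals (0.1 quantum)
    expect_equal(sum(f$muscle_table$volume_mm3), f$sums$volume,
                 tolerance = 0.5 / f$sums$volume)
    expect_equal(sum(f$muscle_table$fmus_N), f$sums$fmus,
                 tolerance = 0.5 / f$sums$fmus)
    expect_equal(sum(f$muscle_table$fres_N), f$sums$fres,
                 tolerance = 0.5 / f$sums$fres)
    expect_equal(unname(colSums(f$levers$fbite)), unname(f$bite_totals),
                 tolerance = 0.5 / min(f$bite_totals))
    # printed MA equals printed bite totals over printed Fres total
    expect_equal(unname(f$bite_totals / f$sums$fres), unname(f$ma),
                 tolerance = 0.002)
    expect_true(all(diff(unname(f$levers$outlever)) < 0))
  }
})
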