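# Bite forces, the bite table, mechanical advantage and scaled comparisons.

test_that("bite_force evaluates the lever relation", {
  expect_equal(bite_force(27.3, 19.8, 90.4), 6.0, tolerance = 0.05 / 6)
  expect_equal(bite_force(42.7, 33, 33), 42.7)
  expect_error(bite_force(10, 5, 0), "outlever")
  expect_error(bite_force(10, 5, -2), "outlever")
})

test_that("bite_table matches a naive per-cell loop oracle", {
  fx <- oviraptor_fixtures()$Khaan
  ft <- force_table(fixture_measurements("Khaan"))
  bt <- bite_table(ft, fx$levers$inlever, fx$levers$outlever)
  # independent naive accumulation
  for (bp in names(fx$levers$outlever)) {
    tot <- 0
    for (i in seq_len(nrow(ft))) {
      tot <- tot + ft$fres_N[i] * fx$levers$inlever[[ft$muscle[i]]] /
        fx$levers$outlever[[bp]]
    }
    expect_equal(bt$totals[[bp]], tot, tolerance = 1e-12)
  }
  expect_equal(unname(colSums(bt$fbite)), unname(bt$totals))
})

test_that("per-muscle contribution is identical across bite points", {
  fx <- oviraptor_fixtures()$Conchoraptor
  ft <- force_table(fixture_measurements("Conchoraptor"))
  bt <- bite_table(ft, fx$levers$inlever, fx$levers$outlever)
  per_point <- apply(bt$fbite, 2, function(col) 100 * col / sum(col))
  for (j in seq_len(ncol(per_point)))
    expect_equal(per_point[, j], bt$contribution_pct, tolerance = 1e-12)
  # totals rise monotonically as outlevers shrink anterior -> posterior
  expect_true(all(diff(unname(bt$totals)) > 0))
})

test_that("bite_table handles degenerate and erroneous inputs", {
  ft <- force_table(fixture_measurements("Incisivosaurus"))
  ft$fres_N <- 0
  bt <- bite_table(ft, oviraptor_fixtures()$Incisivosaurus$levers$inlever,
                   c(anterior = 90.4))
  expect_true(all(bt$fbite == 0))
  expect_error(mechanical_advantage(bt), "zero")
  ft2 <- force_table(fixture_measurements("Incisivosaurus"))
  expect_error(bite_table(ft2, c(mAMEM = 19.8), c(anterior = 90.4)),
               "mAMEP")
})

test_that("mechanical advantage is the fres-weighted lever ratio", {
  one <- data.frame(muscle = "mAMES", fres_N = 77)
  bt <- bite_table(one, c(mAMES = 24), c(anterior = 96, posterior = 48))
  expect_equal(unname(mechanical_advantage(bt)), c(24 / 96, 24 / 48))
  fx <- oviraptor_fixtures()$Incisivosaurus
  ft <- force_table(fixture_measurements("Incisivosaurus"))
  bt <- bite_table(ft, fx$levers$inlever, fx$levers$outlever)
  ma <- mechanical_advantage(bt)
  weighted <- vapply(names(fx$levers$outlever), function(bp)
    sum(ft$fres_N * fx$levers$inlever[ft$muscle] / fx$levers$outlever[[bp]]) /
      sum(ft$fres_N), numeric(1))
  expect_equal(ma, weighted, tolerance = 1e-12)
  expect_true(all(ma > 0 & ma < 1))
})

test_that("scaled comparison and relative CSA behave as ratios", {
  expect_equal(scaled_comparison(10, 10, 100, 100), 0)
  expect_equal(scaled_comparison(20, 10, 100, 100), 100)
  expect_equal(scaled_comparison(20, 10, 200, 100), 0)
  expect_error(scaled_comparison(-1, 10, 1, 1), "positive")
  expect_equal(relative_csa(100, 10000), 1e-2)
  expect_equal(relative_csa(100, 20000), relative_csa(100, 10000) / 2)
})
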