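test_that("direct experiment reports are well formed and reproducible", {
  rep1 <- run_direct_experiment(5, 2, 1000, seed = 42)
  rep2 <- run_direct_experiment(5, 2, 1000, seed = 42)
  expect_s3_class(rep1, "mc_report")
  expect_identical(rep1$stats, rep2$stats)   # bit-reproducible given a seed
  rep3 <- run_direct_experiment(5, 2, 1000, seed = 43)
  expect_false(identical(rep1$stats, rep3$stats))
  st <- rep1$stats
  expect_named(st, c("name", "n", "i", "R", "mean", "se", "theory", "z",
                     "pass"))
  expect_true(all(st$R == 1000))
  expect_true(all(st$se > 0))
  expect_identical(rep1$exceedances, sum(!st$pass))
  expect_equal(sum(st$name == "s_i"), 4)
  expect_equal(sum(st$name == "t_i"), 4)
})

test_that("a zero mutation rate gives a degenerate but passing report", {
  rep <- run_direct_experiment(4, 0, 200, seed = 7)
  srows <- rep$stats[rep$stats$name %in% c("s_i", "S"), ]
  expect_true(all(srows$mean == 0))
  expect_true(all(srows$pass))
})

test_that("growth experiment checks every step and reports star statistics", {
  rep <- run_growth_experiment(2, 6, 3, 400, seed = 99)
  expect_identical(rep$extras$recurrence_checked, 400L * 4L)
  st <- rep$stats
  expect_true(all(c("s_i", "s_star", "star_fraction", "ext_mutations")
                  %in% st$name))
  ## star rows exist at every intermediate size with the right class range
  for (n in 2:5) {
    expect_equal(sum(st$name == "s_star" & st$n == n), n - 1L)
    expect_equal(st$theory[st$name == "s_star" & st$n == n],
                 rep(3 / n, n - 1L))
    fr <- st[st$name == "star_fraction" & st$n == n, ]
    expect_equal(fr$theory, fr$i / n)
  }
  expect_equal(st$theory[st$name == "ext_mutations"], 3 / (2:5))
})

test_that("equivalence experiment scores both arms and their difference", {
  rep <- run_equivalence_experiment(5, 2, 800, seed = 12)
  st <- rep$stats
  expect_equal(sum(st$name == "s_i_diff"), 4)
  expect_true(all(st$theory[st$name == "s_i_diff"] == 0))
  expect_true(all(c("t_MRCA_direct", "t_MRCA_grown", "t_MRCA_diff")
                  %in% st$name))
  expect_s3_class(rep$extras$chisq, "htest")
  expect_true(mc_passed(rep))
})

test_that("experiments refuse unreliable replicate counts", {
  expect_error(run_direct_experiment(5, 2, 50, seed = 1),
               class = "coalgrow_parameter_error")
  expect_error(run_growth_experiment(2, 4, 1, 10, seed = 1),
               class = "coalgrow_parameter_error")
  expect_error(run_equivalence_experiment(2, 1, 1000, seed = 1),
               class = "coalgrow_parameter_error")
})
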