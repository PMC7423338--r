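test_that("the mixture generator labels and separates its components", {
  set.seed(31)
  s0 <- generate_cells(200, active_fraction = 0)
  expect_true(all(!s0$active))
  s1 <- generate_cells(200, active_fraction = 1)
  expect_true(all(s1$active))
  s <- generate_cells(1000, active_fraction = 0.05)
  # realized activation count is binomial around n * f
  expect_lt(abs(sum(s$active) - 50), 3 * sqrt(1000 * 0.05 * 0.95))
  expect_true(all(s$intensity > 0))
  # 10x separation of component medians with the default parameters
  expect_gt(median(s$intensity[s$active]),
            5 * median(s$intensity[!s$active]))
  expect_error(generate_cells(10, 1.5), "active_fraction")
  expect_error(generate_cells(10, 0.5,
                              active_params = list(meanlog = log(10),
                                                   sdlog = 0.3)),
               "exceed")
})

test_that("link_ensemble maps zero-state cells onto pure background", {
  ens <- run_ensemble(build_feedback_only(list(A3 = 0, A1 = 0)),
                      input_spec("BisDC", "point", list(value = 0)),
                      n_cells = 400, root_seed = 23)
  set.seed(77)
  fs <- link_ensemble(ens, gain = 150)
  expect_true(all(!fs$active))
  set.seed(78)
  ref <- rlnorm(400, log(400), 0.25)
  expect_gt(suppressWarnings(ks.test(fs$intensity, ref))$p.value, 0.01)
  # zero gain collapses any ensemble onto the background
  ens2 <- run_ensemble(build_feedback_only(), default_inputs("feedback_only"),
                       n_cells = 400, root_seed = 23)
  set.seed(79)
  fs2 <- link_ensemble(ens2, gain = 0)
  expect_gt(suppressWarnings(ks.test(fs2$intensity, ref))$p.value, 0.01)
})

test_that("linked bistable ensembles keep an input-invariant active median", {
  model <- build_kickstart()
  med <- active_frac <- numeric(2)
  for (i in 1:2) {
    lev <- c(1, 4)[i]
    ens <- run_ensemble(model,
                        input_spec("BisR", "uniform", list(min = 0, max = 16),
                                   scale_multiplier = lev),
                        n_cells = 3000, root_seed = 29)
    set.seed(50 + i)
    fs <- link_ensemble(ens)
    med[i] <- median(fs$intensity[fs$active])
    active_frac[i] <- mean(fs$active)
  }
  expect_gt(active_frac[2], 1.5 * active_frac[1])
  expect_lt(abs(med[2] / med[1] - 1), 0.1)
})

test_that("ranking at the estimated breakpoint recovers the true labels", {
  set.seed(41)
  s <- generate_cells(1000, active_fraction = 0.1)
  est <- qq_subpopulation_estimate(s)
  cut <- sort(s$intensity)[round(est$breakpoint_quantile * est$n)]
  recovered <- s$intensity > cut
  expect_gt(sum(recovered & s$active) / sum(s$active), 0.9)
})

test_that("qq estimator tracks the true fraction and is monotone", {
  # pure background yields (essentially) no estimated subpopulation
  set.seed(43)
  bg <- generate_cells(1000, active_fraction = 0)
  expect_lte(qq_subpopulation_estimate(bg)$estimated_fraction, 0.01)
  # short calibration sweep (the acceptance suite runs the full one)
  means <- vapply(c(0.02, 0.05, 0.2), function(f) {
    mean(vapply(1:20, function(r) {
      set.seed(100 * r + round(1000 * f))
      qq_subpopulation_estimate(generate_cells(1000, f))$estimated_fraction
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(max(abs(means - c(0.02, 0.05, 0.2))), 0.02)
  # half-active samples are still resolved (background fit window intact)
  set.seed(47)
  s5 <- generate_cells(1000, active_fraction = 0.5)
  expect_lt(abs(qq_subpopulation_estimate(s5)$estimated_fraction - 0.5),
            0.05)
  expect_error(qq_subpopulation_estimate(c(-1, 2, 3)), "positive")
  expect_warning(qq_subpopulation_estimate(rlnorm(50, 6, 0.2)), "noisy")
})

test_that("percentile summary uses the interpolating convention", {
  expect_equal(percentile_summary(c(1, 2, 3, 4), q = 0.5), 2.5)
  expect_equal(percentile_summary(rep(7, 20), q = 0.9), 7)
  expect_error(percentile_summary(numeric(0)), "empty")
  expect_error(percentile_summary(1:10, q = 1), "in \\(0, 1\\)")
  # a 5% activated tail moves the 99th percentile far more than the 75th
  set.seed(53)
  bg <- generate_cells(4000, 0)
  mix <- generate_cells(4000, 0.05)
  gap <- median(mix$intensity[mix$active]) - median(bg$intensity)
  d75 <- percentile_summary(mix, 0.75) - percentile_summary(bg, 0.75)
  d99 <- percentile_summary(mix, 0.99) - percentile_summary(bg, 0.99)
  expect_lt(d75, gap)
  expect_gt(d99, gap)
})
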