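test_that("classify_states partitions at exactly zero", {
  s <- classify_states(c(0, 0, 5, 3))
  expect_equal(s$zero_fraction, 0.5)
  expect_equal(s$positive_count, 2L)
  expect_equal(s$positive_median, 4)
  expect_equal(s$zero_fraction + s$positive_count / s$n, 1)
  # all-zero input: positive statistics are absent, not fabricated
  s0 <- classify_states(rep(0, 10))
  expect_equal(s0$zero_fraction, 1)
  expect_true(is.na(s0$positive_median))
  expect_error(classify_states(numeric(0)), "non-empty")
  # the zero bar is its own histogram bin
  expect_equal(s$histogram$counts[1], 2)
})

test_that("classify_states is scale-covariant in the positive part", {
  set.seed(42)
  v <- rpois(500, 6)
  for (c in c(0.5, 3)) {
    s1 <- classify_states(v)
    s2 <- classify_states(c * v, bin_width = c)
    expect_equal(s2$zero_fraction, s1$zero_fraction)
    expect_equal(s2$positive_median, c * s1$positive_median)
  }
})

test_that("zero-state fraction responds monotonically to loop rates", {
  inp <- default_inputs("feedback_only")
  sweep1 <- function(pname, mult) {
    g <- data.frame(v = default_params()[[pname]] * mult)
    names(g) <- pname
    parameter_sweep(build_feedback_only, g, inp, n_cells = 1500,
                    root_seed = 5)
  }
  mult <- c(0.2, 1, 5)
  # stronger binding rescues more cells; faster unbinding/decay kills more
  sa1 <- sweep1("A1", mult)
  expect_true(all(diff(sa1$zero_fraction) < 0))
  sa4 <- sweep1("A4", mult)
  expect_true(all(diff(sa4$zero_fraction) > 0))
  expect_error(parameter_sweep(build_feedback_only, data.frame(),
                               inp), "empty")
})

test_that("unbinding and degradation variants lower the positive level", {
  inp <- default_inputs("feedback_only")
  base <- classify_states(cell_values(
    run_ensemble(build_feedback_only(), inp, 3000, root_seed = 5),
    "end", "BisDC"))
  a4 <- classify_states(cell_values(
    run_ensemble(build_feedback_only(list(A4 = 0.3)), inp, 3000,
                 root_seed = 5), "end", "BisDC"))
  a2 <- classify_states(cell_values(
    run_ensemble(build_feedback_only(list(A2 = 2)), inp, 3000,
                 root_seed = 5), "end", "BisDC"))
  expect_lt(a4$positive_median, base$positive_median)
  expect_lt(a2$positive_median, base$positive_median)
})

test_that("dose-response rises in fraction but not in positive level", {
  dr <- dose_response(input_levels = c(0.25, 1, 4), n_cells = 2500,
                      root_seed = 11)
  expect_true(all(diff(dr$positive_fraction) > 0))
  meds <- dr$positive_median[dr$positive_fraction >= 0.05]
  expect_lt(max(meds) / min(meds) - 1, 0.1)
  # no kickstart regulator at all: nothing can activate
  m <- build_kickstart()
  e0 <- run_ensemble(m, input_spec("BisR", "point", list(value = 0)),
                     n_cells = 200, root_seed = 2)
  expect_true(all(cell_values(e0, "end", "BisDC") == 0))
  expect_error(dose_response(input_levels = 1), "increasing")
})

test_that("bimodal input raises the zero fraction at equal mean", {
  bim <- bimodal_input_response(
    bimodal_spec = input_spec("BisR", "bimodal",
                              list(zero_weight = 0.5, active_mean = 16)),
    n_cells = 3000, root_seed = 13)
  expect_equal(unname(bim$input_mean["bimodal"]),
               unname(bim$input_mean["uniform"]))
  expect_gt(bim$zero_fraction_diff, 2 * bim$zero_fraction_diff_se)
  # positive level is set by the feedback, not by the input shape
  expect_lt(abs(bim$bimodal$positive_median / bim$uniform$positive_median
                - 1), 0.1)
  # degenerate all-zero mixture
  e <- run_ensemble(build_kickstart(),
                    input_spec("BisR", "bimodal",
                               list(zero_weight = 1, active_mean = 16)),
                    n_cells = 100, root_seed = 1)
  expect_equal(classify_states(cell_values(e, "end", "BisDC"))$zero_fraction,
               1)
})

test_that("cascade bimodality appears at both regulator nodes", {
  ens <- run_ensemble(build_full_cascade(), default_inputs("full_cascade"),
                      n_cells = 3000, windows = list(BisR = c(10, 20)),
                      root_seed = 17)
  cb <- cascade_bimodality(ens)
  expect_gt(cb$BisR$zero_fraction, 0)
  expect_lt(cb$BisR$zero_fraction, 1)
  # no kickstart implies no feedback output, cell by cell
  bisr <- cell_values(ens, "int", "BisR", c(10, 20))
  bisdc <- cell_values(ens, "end", "BisDC")
  expect_equal(sum(bisr == 0 & bisdc > 0), 0)
  # without any TciR the cascade is silent
  e0 <- run_ensemble(build_full_cascade(),
                     input_spec("TciR", "point", list(value = 0)),
                     n_cells = 100, windows = list(BisR = c(10, 20)),
                     root_seed = 1)
  cb0 <- cascade_bimodality(e0)
  expect_equal(cb0$BisR$zero_fraction, 1)
  expect_equal(cb0$BisDC$zero_fraction, 1)
  expect_error(cascade_bimodality(ens, window = c(30, 40)), "no recorded")
})

test_that("compare_feedback is reflexive and direction-correct", {
  inp <- default_inputs("full_cascade")
  e1 <- run_ensemble(build_full_cascade(include_late = TRUE,
                                        late_stability = "unstable"),
                     inp, n_cells = 2500, root_seed = 19)
  e0 <- run_ensemble(build_full_cascade(include_feedback = FALSE,
                                        include_late = TRUE,
                                        late_stability = "unstable"),
                     inp, n_cells = 2500, root_seed = 19)
  self <- compare_feedback(e1, e1)
  expect_equal(self$median_ratio, 1)
  cmp <- compare_feedback(e1, e0)
  expect_gt(cmp$median_ratio, 1)
  # slower decay accumulates more protein at matched production
  es <- run_ensemble(build_full_cascade(include_feedback = FALSE,
                                        include_late = TRUE,
                                        late_stability = "stable"),
                     inp, n_cells = 2500, root_seed = 19)
  s_st <- classify_states(cell_values(es, "end", "Late"))
  s_un <- classify_states(cell_values(e0, "end", "Late"))
  expect_gt(s_st$positive_median, s_un$positive_median)
  expect_error(compare_feedback(e1, run_ensemble(build_feedback_only(),
    default_inputs("feedback_only"), 10, t_end = 50, root_seed = 1)),
    "t_end")
})
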