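test_that("propensities follow the mass-action / occupancy rules", {
  m <- build_feedback_only(list(A1 = 0.01, A4 = 0.3, n = 2))
  a <- propensities(c(BisDC = 8), m)
  # 28 distinct dimers from 8 free monomers at rate 0.01 each
  expect_equal(unname(a["bind:P_alpA:BisDC"]), 0.01 * choose(8, 2))
  expect_equal(unname(a["bind:P_alpA:BisDC"]), 0.28)
  expect_equal(unname(a["degrade:BisDC"]), 0.3 * 8)
  # below the oligomer order no complex can form
  a1 <- propensities(c(BisDC = 1), m)
  expect_equal(unname(a1["bind:P_alpA:BisDC"]), 0)
  # while bound: no further binding, unbinding and production active
  ab <- propensities(c(BisDC = 8), m, occupancy = 1L)
  expect_equal(unname(ab["bind:P_alpA:BisDC"]), 0)
  expect_equal(unname(ab["unbind:P_alpA:BisDC"]),
               default_params()$A2)
  expect_equal(unname(ab["produce:P_alpA:BisDC"]), 4)
  # degradation propensity is linear in the free count
  expect_equal(unname(propensities(c(BisDC = 10), m)["degrade:BisDC"]), 3.0)
})

test_that("the zero state is absorbing and reproducible", {
  m <- build_feedback_only()
  tr <- simulate_cell(m, c(BisDC = 0), t_end = 50, seed = 1)
  expect_equal(length(tr$times), 1L)  # no events at all
  expect_true(tr$absorbed)
  expect_equal(endpoint(tr, "BisDC", 50), 0L)
  # bit-identical event sequences from the same seed
  t1 <- simulate_cell(m, c(BisDC = 8), t_end = 100, seed = 42)
  t2 <- simulate_cell(m, c(BisDC = 8), t_end = 100, seed = 42)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$counts, t2$counts)
  expect_error(simulate_cell(m, c(BisDC = 8), t_end = -1), "positive")
})

test_that("path queries are right-continuous and integrals exact", {
  # piecewise-constant path: 2 on [0,15), 4 on [15,20]
  tr <- fake_trajectory(times = c(0, 15), counts = c(2L, 4L), t_end = 20)
  expect_equal(endpoint(tr, "X", 0), 2L)
  expect_equal(endpoint(tr, "X", 14.99), 2L)
  expect_equal(endpoint(tr, "X", 15), 4L)  # post-event convention
  expect_equal(integrate_species(tr, "X", 10, 20), 2 * 5 + 4 * 5)
  expect_equal(integrate_species(tr, "X", 0, 20), 2 * 15 + 4 * 5)
  # constant path
  tc <- fake_trajectory(times = 0, counts = 2L, t_end = 30)
  expect_equal(integrate_species(tc, "X", 10, 20), 20)
  # zero path
  tz <- fake_trajectory(times = 0, counts = 0L, t_end = 30)
  expect_equal(integrate_species(tz, "X", 0, 30), 0)
  expect_error(integrate_species(tr, "X", 10, 25), "t_end")
  expect_error(endpoint(tr, "Y", 5), "unknown species")
})

test_that("simulated trajectories conserve monomers across binding", {
  m <- build_feedback_only()
  n <- default_params()$n
  tr <- simulate_cell(m, c(BisDC = 8), t_end = 100, seed = 7)
  total <- tr$counts[, "BisDC"] + n * (tr$occupancy[, "P_alpA"] > 0)
  steps <- diff(total)
  ch <- tr$channels[-1]
  # bind/unbind leave the monomer total unchanged; production +1; decay -1
  expect_true(all(steps[grepl("^bind|^unbind", ch)] == 0))
  expect_true(all(steps[grepl("^produce", ch)] == 1))
  expect_true(all(steps[grepl("^degrade", ch)] == -1))
  # a positive endpoint implies at least one production event
  if (endpoint(tr, "BisDC", 100) > 0) {
    expect_gt(sum(grepl("^produce", ch)), 0)
  }
})

test_that("a pure death process matches its closed-form decay", {
  # E[X_t] = x0 * exp(-rate * t); x0 = 8, rate = 0.3, t = 10 -> 0.398
  m <- pure_death_model(rate = 0.3)
  ens <- run_ensemble(m, input_spec("X", "point", list(value = 8)),
                      n_cells = 10000, t_end = 10, root_seed = 101)
  x <- cell_values(ens, "end", "X")
  mu <- 8 * exp(-3)
  # each cell is a binomial thinning: var = x0 p (1 - p)
  se <- sqrt(8 * exp(-3) * (1 - exp(-3)) / 10000)
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("birth-death equilibrium is Poisson(k/gamma)", {
  m <- birth_death_model(k = 2, gamma = 0.5)
  ens <- run_ensemble(m, input_spec("X", "point", list(value = 0)),
                      n_cells = 10000, t_end = 30, root_seed = 202)
  x <- cell_values(ens, "end", "X")
  lambda <- 2 / 0.5
  kmax <- max(x)
  obs <- tabulate(x + 1L, nbins = kmax + 1L)
  p <- stats::dpois(0:kmax, lambda)
  p[kmax + 1L] <- p[kmax + 1L] + stats::ppois(kmax, lambda,
                                              lower.tail = FALSE)
  # pool sparse upper bins so all expected counts exceed 5
  keep <- which(10000 * p >= 5)
  cut <- max(keep)
  obs2 <- c(obs[seq_len(cut - 1L)], sum(obs[cut:(kmax + 1L)]))
  p2 <- c(p[seq_len(cut - 1L)], sum(p[cut:(kmax + 1L)]))
  gof <- stats::chisq.test(obs2, p = p2)
  expect_gt(gof$p.value, 0.01)
})

test_that("waiting times of a constant-propensity channel are exponential", {
  m <- pure_birth_model(k = 1)
  tr <- simulate_cell(m, c(X = 0), t_end = 10000, seed = 303)
  gaps <- diff(tr$times)
  expect_gt(length(gaps), 9000)
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})
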