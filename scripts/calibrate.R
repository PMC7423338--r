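#!/usr/bin/env Rscript
# Calibration procedure behind the shipped defaults in default_params() and
# the qq-estimator envelope width. Re-running prints the readouts that the
# defaults were chosen against:
#
#   1. bare feedback loop (binomial mean-8 input): clearly bimodal output
#      (zero fraction well inside (0.05, 0.95), separated positive mode);
#   2. zero-fraction monotone in A1 (down), A2/A4 (up);
#   3. kickstarted loop: positive fraction grows >= 5-fold over the input
#      grid while the positive median stays within 10%;
#   4. bimodal vs equal-mean uniform input: clearly higher zero fraction;
#   5. full cascade: positive-state percentage inside the empirical 3-5%
#      transfer-competent range, no cell with a silent BisR window but a
#      positive BisDC endpoint, and a feedback/no-feedback late-protein
#      contrast with non-overlapping bootstrap intervals;
#   6. qq estimator: median absolute error of the recovered subpopulation
#      fraction across a seeded grid, for candidate envelope widths k.
#
# Usage: Rscript scripts/calibrate.R [n_cells]

suppressPackageStartupMessages(library(icebistab))
n <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(n)) n <- 5000L

cat("== 1. bare feedback loop ==\n")
ens <- run_ensemble(build_feedback_only(), default_inputs("feedback_only"),
                    n_cells = n, root_seed = 1)
print(classify_states(cell_values(ens, "end", "BisDC")))

cat("\n== 2. rate monotonicity ==\n")
for (pname in c("A1", "A2", "A4")) {
  mult <- if (pname == "A4") c(0.25, 0.5, 1, 1.5, 2) else c(0.25, 0.5, 1, 2, 4)
  g <- data.frame(v = default_params()[[pname]] * mult)
  names(g) <- pname
  sw <- parameter_sweep(build_feedback_only, g,
                        default_inputs("feedback_only"),
                        n_cells = n, root_seed = 1)
  cat(pname, ": zero fraction", round(sw$zero_fraction, 3), "\n")
}

cat("\n== 3. dose response ==\n")
dr <- dose_response(input_levels = c(0.125, 0.25, 0.5, 1, 2, 4),
                    n_cells = n, root_seed = 1)
print(dr[, c("level", "positive_fraction", "positive_median")])

cat("\n== 4. bimodal vs uniform input ==\n")
bim <- bimodal_input_response(
  bimodal_spec = input_spec("BisR", "bimodal",
                            list(zero_weight = 0.5, active_mean = 16)),
  n_cells = n, root_seed = 1)
cat("zero fraction: bimodal", round(bim$bimodal$zero_fraction, 3),
    "uniform", round(bim$uniform$zero_fraction, 3),
    "diff", round(bim$zero_fraction_diff, 3), "\n")

cat("\n== 5. full cascade ==\n")
for (s in 1:2) {
  ens <- run_ensemble(build_full_cascade(), default_inputs("full_cascade"),
                      n_cells = n, t_end = 100,
                      windows = list(BisR = c(10, 20)), root_seed = s)
  bisr <- cell_values(ens, "int", "BisR", c(10, 20))
  bisdc <- cell_values(ens, "end", "BisDC")
  cat(sprintf("seed %d: positive %.2f%%, silent-window violations %d\n",
              s, 100 * mean(bisdc > 0), sum(bisr == 0 & bisdc > 0)))
}
for (stab in c("stable", "unstable")) {
  e1 <- run_ensemble(build_full_cascade(include_late = TRUE,
                                        late_stability = stab),
                     default_inputs("full_cascade"), n_cells = n,
                     root_seed = 1)
  e0 <- run_ensemble(build_full_cascade(include_feedback = FALSE,
                                        include_late = TRUE,
                                        late_stability = stab),
                     default_inputs("full_cascade"), n_cells = n,
                     root_seed = 1)
  cmp <- compare_feedback(e1, e0, seed = 1)
  cat(stab, "late protein: with-feedback CI",
      round(cmp$with_feedback$ci, 1), "| without",
      round(cmp$without_feedback$ci, 1), "\n")
}

cat("\n== 6. qq estimator envelope width ==\n")
grid <- c(0.01, 0.02, 0.05, 0.1, 0.2)
for (k in c(1.5, 2, 2.5, 3)) {
  stats <- vapply(grid, function(f) {
    errs <- vapply(1:100, function(r) {
      set.seed(1000 * r + round(1000 * f))
      qq_subpopulation_estimate(generate_cells(1000, f),
                                k = k)$estimated_fraction - f
    }, numeric(1))
    c(mae = median(abs(errs)), bias = mean(errs))
  }, numeric(2))
  cat("k =", k, " MAE:", round(stats["mae", ], 4),
      " bias:", round(stats["bias", ], 4), "\n")
}
cat("shipped default: k = 2\n")
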