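#' Partition per-cell output into zero and positive states
#'
#' The operational bistability readout: a cell is in the \emph{zero} state
#' when its per-cell value (endpoint count or window integral) is exactly
#' 0, and in the \emph{positive} state otherwise; no threshold above zero
#' is applied. Positive-subpopulation statistics (median, IQR) are computed
#' over positive cells only and reported as \code{NA} when the positive set
#' is empty. The histogram uses integer-aligned unit bins so the zero bar
#' is its own bin.
#'
#' @param values Nonnegative per-cell scalars.
#' @param bin_width Histogram bin width (default 1, integer-aligned).
#' @return An object of class \code{"subpop_summary"}: \code{n},
#'   \code{zero_fraction}, \code{zero_fraction_se} (normal-approximation
#'   standard error), \code{positive_count}, \code{positive_median},
#'   \code{positive_iqr}, \code{histogram} (list of \code{breaks},
#'   \code{counts}).
#' @examples
#' classify_states(c(0, 0, 5, 3))
#' @export
classify_states <- function(values, bin_width = 1) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (any(is.na(values)) || any(values < 0)) {
    stop("values must be nonnegative and non-missing", call. = FALSE)
  }
  n <- length(values)
  zero <- sum(values == 0)
  pos <- values[values > 0]
  zf <- zero / n
  breaks <- seq(-bin_width / 2,
                max(values, 0) + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  structure(list(
    n = n,
    zero_fraction = zf,
    zero_fraction_se = sqrt(zf * (1 - zf) / n),
    positive_count = length(pos),
    positive_median = if (length(pos)) stats::median(pos) else NA_real_,
    positive_mean = if (length(pos)) mean(pos) else NA_real_,
    positive_iqr = if (length(pos)) stats::IQR(pos) else NA_real_,
    histogram = list(breaks = h$breaks, counts = h$counts),
    bin_width = bin_width), class = "subpop_summary")
}

#' @export
print.subpop_summary <- function(x, ...) {
  cat(sprintf(
    "<subpop_summary> n = %d | zero %.3f (se %.4f) | positive %d, median %s, IQR %s\n",
    x$n, x$zero_fraction, x$zero_fraction_se, x$positive_count,
    format(x$positive_median), format(x$positive_iqr)))
  invisible(x)
}

#' @export
as.data.frame.subpop_summary <- function(x, ...) {
  data.frame(n = x$n, zero_fraction = x$zero_fraction,
             zero_fraction_se = x$zero_fraction_se,
             positive_count = x$positive_count,
             positive_median = x$positive_median,
             positive_mean = x$positive_mean,
             positive_iqr = x$positive_iqr)
}

#' Seeded bootstrap confidence interval for the positive-state median
#'
#' @param values Nonnegative per-cell scalars.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling stream.
#' @return Named numeric vector \code{c(lower, median, upper)}; all
#'   \code{NA} when no cell is positive.
#' @export
positive_median_ci <- function(values, n_boot = 1000L, level = 0.95,
                               seed = 1L) {
  pos <- values[values > 0]
  if (!length(pos)) {
    return(c(lower = NA_real_, median = NA_real_, upper = NA_real_))
  }
  set.seed(seed)
  meds <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(pos, replace = TRUE))
  }, numeric(1))
  qs <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(lower = qs[1], median = stats::median(pos), upper = qs[2])
}

#' Sweep rate parameters of a preset builder
#'
#' Runs one seeded ensemble per grid point and summarises the zero/positive
#' partition of the chosen output species endpoint, the readout behind the
#' binding/unbinding/degradation-rate dependence of the non-activated
#' fraction. The same root seed is used at every grid point so points
#' differ only through the parameters.
#'
#' @param builder Preset builder taking a \code{params} list, e.g.
#'   [build_feedback_only()].
#' @param param_grid Data frame with one column per swept parameter
#'   (\code{A1}, \code{A2}, ...) and one row per grid point.
#' @param input_specs As in [run_ensemble()].
#' @param n_cells Cells per grid point.
#' @param species Output species classified at \code{t_end}.
#' @param t_end,root_seed As in [run_ensemble()].
#' @return Data frame: the grid columns plus the [classify_states()]
#'   summary columns.
#' @export
parameter_sweep <- function(builder, param_grid, input_specs,
                            n_cells = 5000, species = "BisDC",
                            t_end = 100, root_seed = 1L) {
  stopifnot(is.function(builder), is.data.frame(param_grid))
  if (nrow(param_grid) == 0L) stop("empty parameter grid", call. = FALSE)
  out <- vector("list", nrow(param_grid))
  for (i in seq_len(nrow(param_grid))) {
    params <- as.list(param_grid[i, , drop = FALSE])
    model <- builder(params)
    ens <- run_ensemble(model, input_specs, n_cells = n_cells, t_end = t_end,
                        root_seed = root_seed)
    s <- classify_states(cell_values(ens, "end", species))
    out[[i]] <- cbind(param_grid[i, , drop = FALSE], as.data.frame(s))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dose-response curve of the kickstarted feedback loop
#'
#' The analog-to-digital readout: for each input level (a scale multiplier
#' applied to the base input distribution, i.e. a relative starting level
#' of the kickstart regulator), runs a seeded ensemble and records the
#' fraction of cells in the positive state and the positive-subpopulation
#' median of the output species at \code{t_end}. Under the feedback
#' architecture the fraction grows with the input level while the positive
#' median stays put.
#'
#' @param builder Preset builder taking a \code{params} list; default
#'   [build_kickstart()].
#' @param input_levels Increasing positive scale multipliers (at least 2).
#' @param base_input Base [input_spec()] scaled by each level; defaults to
#'   the shipped kickstart input (uniform-integer BisR on \{0..16\}).
#' @param params Rate overrides passed to \code{builder}.
#' @param n_cells,t_end,root_seed As in [run_ensemble()].
#' @param species Output species (default \code{"BisDC"}).
#' @return An object of class \code{"dose_response"}: data frame with one
#'   row per level (\code{level}, \code{positive_fraction},
#'   \code{positive_fraction_se}, \code{positive_median},
#'   \code{zero_fraction}, ...).
#' @export
dose_response <- function(builder = build_kickstart, input_levels,
                          base_input = NULL, params = NULL,
                          n_cells = 10000, t_end = 100, root_seed = 1L,
                          species = "BisDC") {
  if (length(input_levels) < 2L || any(diff(input_levels) <= 0)) {
    stop("input_levels must be >= 2 increasing values", call. = FALSE)
  }
  if (any(input_levels < 0)) stop("input_levels must be nonnegative",
                                  call. = FALSE)
  if (is.null(base_input)) base_input <- default_inputs("kickstart")[[1]]
  model <- builder(params)
  rows <- vector("list", length(input_levels))
  for (i in seq_along(input_levels)) {
    lev <- input_levels[i]
    spec <- if (lev == 0) {
      input_spec(base_input$species, "point", list(value = 0))
    } else {
      input_spec(base_input$species, base_input$family, base_input$params,
                 scale_multiplier = base_input$scale_multiplier * lev)
    }
    ens <- run_ensemble(model, list(spec), n_cells = n_cells, t_end = t_end,
                        root_seed = root_seed)
    s <- classify_states(cell_values(ens, "end", species))
    rows[[i]] <- cbind(data.frame(level = lev,
                                  input_mean = input_mean(spec),
                                  positive_fraction = 1 - s$zero_fraction,
                                  positive_fraction_se = s$zero_fraction_se),
                       as.data.frame(s))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("dose_response", "data.frame")
  res
}

#' Bimodal versus equal-mean uniform input
#'
#' Compares the output of a kickstarted loop under a bimodal input (a
#' zero-mass component plus an active Poisson component) against a
#' uniform-integer input of equal mean, at matched seeds: the bimodal
#' input yields a higher zero-state fraction while the positive-state
#' median is set by the feedback and stays comparable.
#'
#' @param builder Preset builder; default [build_kickstart()].
#' @param bimodal_spec An [input_spec()] with family \code{"bimodal"}.
#' @param params,n_cells,t_end,root_seed,species As in [dose_response()].
#' @return List with the two [classify_states()] summaries
#'   (\code{$bimodal}, \code{$uniform}), the matched input means, and the
#'   zero-fraction difference with its Monte-Carlo standard error.
#' @export
bimodal_input_response <- function(builder = build_kickstart, bimodal_spec,
                                   params = NULL, n_cells = 10000,
                                   t_end = 100, root_seed = 1L,
                                   species = "BisDC") {
  stopifnot(inherits(bimodal_spec, "input_spec"),
            bimodal_spec$family == "bimodal")
  m <- input_mean(bimodal_spec)
  uniform_spec <- input_spec(bimodal_spec$species, "uniform",
                             list(min = 0, max = round(2 * m)))
  model <- builder(params)
  summarize <- function(spec) {
    ens <- run_ensemble(model, list(spec), n_cells = n_cells, t_end = t_end,
                        root_seed = root_seed)
    classify_states(cell_values(ens, "end", species))
  }
  sb <- summarize(bimodal_spec)
  su <- summarize(uniform_spec)
  list(bimodal = sb, uniform = su,
       input_mean = c(bimodal = m, uniform = input_mean(uniform_spec)),
       zero_fraction_diff = sb$zero_fraction - su$zero_fraction,
       zero_fraction_diff_se = sqrt(sb$zero_fraction_se^2 +
                                      su$zero_fraction_se^2))
}

#' Per-node bistability of the full cascade
#'
#' Summarises the zero/positive partition at both cascade nodes: BisR on
#' its time integral over the recorded window (default \code{[10, 20]})
#' and BisDC on its endpoint count at \code{t_end}.
#'
#' @param ensemble A full-cascade [run_ensemble()] result whose
#'   \code{windows} recorded the BisR integral.
#' @param window BisR integration window, default \code{c(10, 20)}.
#' @return List of two [classify_states()] summaries, \code{$BisR} and
#'   \code{$BisDC}.
#' @export
cascade_bimodality <- function(ensemble, window = c(10, 20)) {
  stopifnot(inherits(ensemble, "ensemble_result") ||
              is.data.frame(ensemble))
  bisr <- cell_values(ensemble, "int", "BisR", window = window)
  bisdc <- cell_values(ensemble, "end", "BisDC")
  list(BisR = classify_states(bisr),
       BisDC = classify_states(bisdc))
}

#' Late-protein output with versus without the BisDC feedback
#'
#' Compares matched ensembles of architectures differing only in the
#' presence of the BisDC autoregulatory configuration: among activated
#' cells (positive late-protein endpoint), the feedback sustains BisDC and
#' therefore yields higher late-protein output. Reports
#' positive-subpopulation medians, their seeded bootstrap confidence
#' intervals and the with/without ratio. When an arm has no activated
#' cell its output is reported as 0 with a degenerate interval.
#'
#' @param with_fb,without_fb [run_ensemble()] results of the same cascade
#'   with and without the feedback configuration (same \code{t_end}).
#' @param late_species Late-protein species name (default \code{"Late"}).
#' @param n_boot,level,seed Bootstrap settings, see [positive_median_ci()].
#' @return List: per-arm medians and CIs, activated fractions, and
#'   \code{median_ratio} (with / without).
#' @export
compare_feedback <- function(with_fb, without_fb, late_species = "Late",
                             n_boot = 1000L, level = 0.95, seed = 1L) {
  stopifnot(inherits(with_fb, "ensemble_result"),
            inherits(without_fb, "ensemble_result"))
  if (with_fb$t_end != without_fb$t_end) {
    stop("ensembles must share t_end", call. = FALSE)
  }
  arm <- function(ens) {
    v <- cell_values(ens, "end", late_species)
    ci <- positive_median_ci(v, n_boot = n_boot, level = level, seed = seed)
    if (is.na(ci["median"])) ci <- c(lower = 0, median = 0, upper = 0)
    list(summary = classify_states(v), ci = ci,
         activated_fraction = mean(v > 0))
  }
  w <- arm(with_fb)
  wo <- arm(without_fb)
  ratio <- if (wo$ci[["median"]] > 0) w$ci[["median"]] / wo$ci[["median"]]
           else Inf
  if (w$ci[["median"]] == 0 && wo$ci[["median"]] == 0) ratio <- 1
  list(with_feedback = w, without_feedback = wo, median_ratio = ratio)
}
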