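#' Generate synthetic single-cell fluorescence data
#'
#' Emulates the statistical structure of a single-cell reporter readout:
#' every cell carries a right-skewed (log-normal) background intensity in
#' arbitrary units, and a minority \emph{activated} subpopulation draws
#' from a brighter log-normal component whose median does not depend on
#' how large the subpopulation is. Activation labels are stored so the
#' ground truth is recoverable.
#'
#' @param n Number of cells.
#' @param active_fraction Probability that a cell is activated, in
#'   \code{[0, 1]}.
#' @param background_params,active_params Named lists with \code{meanlog}
#'   and \code{sdlog} of the log-normal components; the activated location
#'   must exceed the background location. Defaults give a background
#'   median of about 400 AU and a 10-fold brighter activated component.
#' @return An object of class \code{"fluor_sample"}: data frame with
#'   \code{cell}, \code{intensity} (AU), \code{active} (logical), plus the
#'   generator parameters and the true activated fraction as attributes.
#' @export
generate_cells <- function(n, active_fraction,
                           background_params = list(meanlog = log(400),
                                                    sdlog = 0.25),
                           active_params = list(meanlog = log(4000),
                                                sdlog = 0.35)) {
  stopifnot(is.numeric(n), n >= 1)
  if (!is.numeric(active_fraction) || active_fraction < 0 ||
      active_fraction > 1) {
    stop("active_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (p in list(background_params, active_params)) {
    if (!all(c("meanlog", "sdlog") %in% names(p)) || p$sdlog <= 0) {
      stop("component params need meanlog and positive sdlog", call. = FALSE)
    }
  }
  if (active_params$meanlog <= background_params$meanlog) {
    stop("activated location must exceed background location", call. = FALSE)
  }
  n <- as.integer(n)
  active <- stats::runif(n) < active_fraction
  intensity <- numeric(n)
  nb <- sum(!active)
  intensity[!active] <- stats::rlnorm(nb, background_params$meanlog,
                                      background_params$sdlog)
  intensity[active] <- stats::rlnorm(n - nb, active_params$meanlog,
                                     active_params$sdlog)
  out <- data.frame(cell = seq_len(n), intensity = intensity,
                    active = active)
  structure(out, class = c("fluor_sample", "data.frame"),
            true_active_fraction = active_fraction,
            background_params = background_params,
            active_params = active_params)
}

#' Map a simulated ensemble onto fluorescence intensities
#'
#' The model-to-measurement bridge: each cell's intensity is a background
#' draw (cell autofluorescence and detection noise, log-normal) plus
#' \code{gain} arbitrary units per molecule of the chosen species at the
#' endpoint. Zero-state cells therefore sample the pure background
#' distribution, and positive-state cells form the activated subpopulation.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param species Species whose endpoint count is converted (default
#'   \code{"BisDC"}).
#' @param gain AU per molecule (default 150).
#' @param background_params Log-normal background, as in
#'   [generate_cells()].
#' @return A \code{"fluor_sample"} whose \code{active} label marks cells
#'   with a positive endpoint count.
#' @export
link_ensemble <- function(ensemble, species = "BisDC", gain = 150,
                          background_params = list(meanlog = log(400),
                                                   sdlog = 0.25)) {
  counts <- cell_values(ensemble, "end", species)
  if (!is.numeric(gain) || gain < 0) stop("gain must be nonnegative",
                                          call. = FALSE)
  n <- length(counts)
  bg <- stats::rlnorm(n, background_params$meanlog, background_params$sdlog)
  out <- data.frame(cell = seq_len(n), intensity = bg + gain * counts,
                    active = counts > 0)
  structure(out, class = c("fluor_sample", "data.frame"),
            true_active_fraction = mean(counts > 0),
            background_params = background_params,
            gain = gain, species = species)
}

#' Quantile-quantile subpopulation estimate
#'
#' Estimates the activated-subpopulation fraction of a fluorescence sample
#' from its ordered intensities: a reference background distribution is
#' fitted to the lower part of the empirical quantiles (a straight-line
#' fit on the quantile-quantile plot over the lowest \code{fit_window}
#' fraction of cells), a deviation envelope is drawn at the fitted
#' quantile plus \code{k} fitted spreads, and the breakpoint is the first
#' order statistic above which at least \code{persist} of the
#' higher-ranked cells exceed the envelope. The estimated fraction is one
#' minus the breakpoint quantile.
#'
#' @param sample A \code{"fluor_sample"} or positive numeric vector of
#'   intensities (at least 100 cells; behaviour below that is noisy and
#'   the function warns).
#' @param reference Background family: \code{"lognormal"} (default, for
#'   right-skewed intensity data) or \code{"normal"}.
#' @param fit_window Fraction of lowest-ranked cells used for the
#'   background fit (default 0.5).
#' @param k Envelope width in fitted spread units (default 2; fixed by the
#'   calibration suite in \code{scripts/calibrate.R}).
#' @param persist Required exceedance fraction above the breakpoint
#'   (default 0.95).
#' @return An object of class \code{"subpop_estimate"}:
#'   \code{estimated_fraction}, \code{breakpoint_quantile}, and
#'   diagnostics (reference parameters, fit residuals, envelope
#'   exceedances).
#' @export
qq_subpopulation_estimate <- function(sample, reference = c("lognormal",
                                                            "normal"),
                                      fit_window = 0.5, k = 2,
                                      persist = 0.95) {
  reference <- match.arg(reference)
  x <- if (inherits(sample, "fluor_sample")) sample$intensity else sample
  if (!length(x) || any(is.na(x))) stop("empty or missing intensities",
                                        call. = FALSE)
  if (any(x <= 0)) stop("intensities must be positive", call. = FALSE)
  n <- length(x)
  if (n < 100) warning("fewer than 100 cells: estimate will be noisy")
  stopifnot(fit_window > 0, fit_window <= 1, k >= 0,
            persist > 0, persist <= 1)
  xs <- sort(x)
  y <- if (reference == "lognormal") log(xs) else xs
  p <- (seq_len(n) - 0.5) / n
  z <- stats::qnorm(p)
  m <- max(10L, floor(fit_window * n))
  fit <- stats::lm.fit(cbind(1, z[seq_len(m)]), y[seq_len(m)])
  mu <- fit$coefficients[1]
  sigma <- max(fit$coefficients[2], .Machine$double.eps)
  envelope <- mu + sigma * z + k * sigma
  exceed <- y > envelope
  # fraction of cells at or above each rank that exceed the envelope
  suffix <- rev(cumsum(rev(exceed))) / (n - seq_len(n) + 1)
  idx <- which(suffix >= persist)
  if (length(idx)) {
    b <- idx[1]
    # counting only envelope-exceeding cells above the breakpoint removes
    # the upward bias the persistence allowance would otherwise introduce
    frac <- sum(exceed[b:n]) / n
    breakpoint_q <- (b - 1) / n
  } else {
    frac <- 0
    breakpoint_q <- 1
  }
  structure(list(
    estimated_fraction = frac,
    breakpoint_quantile = breakpoint_q,
    n = n,
    reference = reference,
    reference_params = c(location = unname(mu), spread = unname(sigma)),
    k = k, persist = persist, fit_window = fit_window,
    fit_residuals = unname(fit$residuals),
    n_exceed = sum(exceed)), class = "subpop_estimate")
}

#' @export
print.subpop_estimate <- function(x, ...) {
  cat(sprintf(
    "<subpop_estimate> fraction %.4f (breakpoint quantile %.4f, n = %d, %s reference)\n",
    x$estimated_fraction, x$breakpoint_quantile, x$n, x$reference))
  invisible(x)
}

#' Skew-robust percentile summary of a fluorescence sample
#'
#' Empirical quantile with linear interpolation between order statistics
#' (the convention of [stats::quantile()] type 7). The 75th percentile is
#' the standard per-culture summary for strongly right-skewed reporter
#' distributions, where the median of a mostly-dark population hides the
#' activated tail and the mean is dominated by it.
#'
#' @param sample A \code{"fluor_sample"} or numeric vector.
#' @param q Quantile in (0, 1); default 0.75.
#' @return The empirical q-quantile.
#' @examples
#' percentile_summary(c(1, 2, 3, 4), q = 0.5)  # 2.5
#' @export
percentile_summary <- function(sample, q = 0.75) {
  x <- if (inherits(sample, "fluor_sample")) sample$intensity else sample
  if (!length(x)) stop("empty sample", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must lie in (0, 1)", call. = FALSE)
  }
  unname(stats::quantile(x, q, type = 7))
}

#' Write a per-cell intensity table as CSV
#'
#' @param sample A \code{"fluor_sample"}.
#' @param path Output CSV path (columns: cell, intensity, active when
#'   ground truth is known).
#' @return Invisibly, \code{path}.
#' @export
write_fluor_sample <- function(sample, path) {
  stopifnot(inherits(sample, "fluor_sample"))
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE)
  invisible(path)
}
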