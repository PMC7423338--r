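#' Per-cell initial-copy-number distribution
#'
#' Describes how many copies of a regulator each simulated cell starts
#' with. Families: \code{"binomial"} (params \code{size}, \code{prob};
#' the shipped mean-8 input is binomial(16, 0.5)), \code{"uniform"}
#' (integer-uniform on \code{\{min..max\}}), \code{"bimodal"} (zero with
#' probability \code{zero_weight}, otherwise Poisson with mean
#' \code{active_mean}) and \code{"point"} (params \code{value}). Draws are
#' multiplied by \code{scale_multiplier} (the dose-response knob) and
#' rounded half-up to an integer.
#'
#' @param species Species the draw initializes.
#' @param family One of \code{"binomial"}, \code{"uniform"},
#'   \code{"bimodal"}, \code{"point"}.
#' @param params Named list of family parameters (see Details above).
#' @param scale_multiplier Positive scalar applied to every draw.
#' @return An object of class \code{"input_spec"}.
#' @export
input_spec <- function(species, family = c("binomial", "uniform", "bimodal",
                                           "point"),
                       params = list(), scale_multiplier = 1) {
  family <- match.arg(family)
  stopifnot(is.character(species), length(species) == 1L, is.list(params))
  if (!is.numeric(scale_multiplier) || length(scale_multiplier) != 1L ||
      scale_multiplier <= 0) {
    stop("scale_multiplier must be a positive scalar", call. = FALSE)
  }
  need <- switch(family,
                 binomial = c("size", "prob"),
                 uniform = c("min", "max"),
                 bimodal = c("zero_weight", "active_mean"),
                 point = "value")
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("family '", family, "' requires params: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ok <- switch(family,
    binomial = params$size >= 0 && params$size == round(params$size) &&
      params$prob >= 0 && params$prob <= 1,
    uniform = params$min >= 0 && params$max >= params$min &&
      params$min == round(params$min) && params$max == round(params$max),
    bimodal = params$zero_weight >= 0 && params$zero_weight <= 1 &&
      params$active_mean >= 0,
    point = params$value >= 0 && params$value == round(params$value))
  if (!isTRUE(ok)) stop("invalid params for family '", family, "'",
                        call. = FALSE)
  structure(list(species = species, family = family,
                 params = params[need],
                 scale_multiplier = as.numeric(scale_multiplier)),
            class = "input_spec")
}

#' Expected value of an input distribution
#' @param spec An [input_spec()].
#' @return Closed-form mean of the scaled distribution (before integer
#'   rounding).
#' @export
input_mean <- function(spec) {
  stopifnot(inherits(spec, "input_spec"))
  p <- spec$params
  base <- switch(spec$family,
                 binomial = p$size * p$prob,
                 uniform = (p$min + p$max) / 2,
                 bimodal = (1 - p$zero_weight) * p$active_mean,
                 point = p$value)
  base * spec$scale_multiplier
}

#' Sample initial copy numbers
#'
#' Draws from the family of an [input_spec()], scales by its
#' \code{scale_multiplier} and rounds half-up to nonnegative integers.
#' Uses the current R random number generator state.
#'
#' @param spec An [input_spec()].
#' @param n Number of draws.
#' @return Integer vector of length \code{n}.
#' @export
sample_initial <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "input_spec"), n >= 1)
  p <- spec$params
  raw <- switch(spec$family,
    binomial = stats::rbinom(n, size = p$size, prob = p$prob),
    uniform = sample.int(p$max - p$min + 1L, n, replace = TRUE) + p$min - 1L,
    bimodal = ifelse(stats::runif(n) < p$zero_weight, 0L,
                     stats::rpois(n, p$active_mean)),
    point = rep(p$value, n))
  as.integer(floor(raw * spec$scale_multiplier + 0.5))
}

derive_cell_seed <- function(root_seed, cell) {
  # deterministic per-cell stream seed; keeps within 32-bit signed range
  (as.numeric(root_seed) + 48271 * as.numeric(cell)) %% 2147483647
}

#' Run an N-cell ensemble
#'
#' Simulates \code{n_cells} independent cells of a network model, each from
#' its own deterministically derived seed (so results are reproducible from
#' the root seed and independent of execution order). Initial copies are
#' drawn per cell from the given input specifications; all other species
#' start at 0. Records per cell the initial counts, the endpoint counts at
#' \code{t_end}, and the exact time integrals over any requested windows.
#'
#' @param model A [network_model()].
#' @param input_specs List of [input_spec()] objects (at most one per
#'   species), or a single \code{input_spec}.
#' @param n_cells Positive integer ensemble size (the shipped analyses use
#'   10,000 cells).
#' @param t_end Simulation horizon (default 100 time units).
#' @param windows Named list of \code{c(t0, t1)} windows keyed by species,
#'   e.g. \code{list(BisR = c(10, 20))}, each integrated exactly.
#' @param root_seed Integer root seed of the ensemble.
#' @return An object of class \code{"ensemble_result"} whose \code{$cells}
#'   data frame has one row per cell: \code{cell}, \code{seed},
#'   \code{init_<species>}, \code{end_<species>},
#'   \code{int_<species>_<t0>_<t1>}.
#' @export
run_ensemble <- function(model, input_specs, n_cells, t_end = 100,
                         windows = list(), root_seed = 1L) {
  stopifnot(inherits(model, "network_model"),
            is.numeric(n_cells), n_cells >= 1)
  if (inherits(input_specs, "input_spec")) input_specs <- list(input_specs)
  stopifnot(all(vapply(input_specs, inherits, logical(1), "input_spec")))
  if (!is.numeric(t_end) || t_end <= 0) {
    stop("t_end must be positive", call. = FALSE)
  }
  net <- compile_network(model)
  sp <- net$species
  in_sp <- vapply(input_specs, `[[`, character(1), "species")
  if (anyDuplicated(in_sp)) {
    stop("at most one input_spec per species", call. = FALSE)
  }
  if (length(setdiff(in_sp, sp))) {
    stop("input_spec references unknown species: ",
         paste(setdiff(in_sp, sp), collapse = ", "), call. = FALSE)
  }
  w_species <- integer(0); w_t0 <- numeric(0); w_t1 <- numeric(0)
  w_names <- character(0)
  if (length(windows)) {
    stopifnot(!is.null(names(windows)), all(names(windows) %in% sp))
    for (nm in names(windows)) {
      w <- windows[[nm]]
      if (length(w) != 2L || w[1] < 0 || w[2] > t_end || w[1] >= w[2]) {
        stop("window for ", nm, " must satisfy 0 <= t0 < t1 <= t_end",
             call. = FALSE)
      }
      w_species <- c(w_species, match(nm, sp))
      w_t0 <- c(w_t0, w[1]); w_t1 <- c(w_t1, w[2])
      w_names <- c(w_names, sprintf("int_%s_%g_%g", nm, w[1], w[2]))
    }
  }
  n_cells <- as.integer(n_cells)
  S <- length(sp)
  init <- matrix(0L, n_cells, S, dimnames = list(NULL, sp))
  endm <- matrix(0L, n_cells, S)
  integ <- matrix(0, n_cells, length(w_names))
  seeds <- vapply(seq_len(n_cells), function(i) derive_cell_seed(root_seed, i),
                  numeric(1))
  for (i in seq_len(n_cells)) {
    set.seed(seeds[i])
    x0 <- rep(0L, S)
    for (spec in input_specs) {
      x0[match(spec$species, sp)] <- sample_initial(spec, 1L)
    }
    res <- cpp_ssa(net, x0, t_end, w_species, w_t0, w_t1, FALSE, 5e6)
    init[i, ] <- x0
    endm[i, ] <- res$end_counts
    if (length(w_names)) integ[i, ] <- res$integrals
  }
  cells <- data.frame(cell = seq_len(n_cells), seed = seeds)
  for (j in seq_len(S)) cells[[paste0("init_", sp[j])]] <- init[, j]
  for (j in seq_len(S)) cells[[paste0("end_", sp[j])]] <- endm[, j]
  for (j in seq_along(w_names)) cells[[w_names[j]]] <- integ[, j]
  structure(list(cells = cells, n_cells = n_cells,
                 model_label = model$label, t_end = t_end,
                 windows = windows, root_seed = root_seed,
                 input_specs = input_specs, species = sp),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", x$model_label, ": ", x$n_cells,
      " cells, t_end = ", x$t_end, ", root seed ", x$root_seed, "\n", sep = "")
  invisible(x)
}

#' Write an ensemble as CSV plus a JSON sidecar
#'
#' The CSV holds one row per cell; the sidecar records the model label,
#' seeds, windows, input specifications and package version, sufficient to
#' re-run the ensemble.
#'
#' @param ensemble An [run_ensemble()] result.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   \code{.json} suffix.
#' @return Invisibly, the sidecar path.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  utils::write.csv(ensemble$cells, path, row.names = FALSE)
  sidecar <- paste0(sub("\\.csv$", "", path), ".json")
  meta <- list(
    model_label = ensemble$model_label,
    n_cells = ensemble$n_cells,
    t_end = ensemble$t_end,
    root_seed = ensemble$root_seed,
    windows = ensemble$windows,
    input_specs = lapply(ensemble$input_specs, unclass),
    package_version = as.character(utils::packageVersion("icebistab")))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an ensemble CSV written by [write_ensemble()]
#'
#' @param path CSV path.
#' @return A list with the per-cell data frame (\code{$cells}) and, when
#'   the JSON sidecar is present, its metadata (\code{$meta}).
#' @export
read_ensemble <- function(path) {
  cells <- utils::read.csv(path)
  sidecar <- paste0(sub("\\.csv$", "", path), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  list(cells = cells, meta = meta)
}

#' Extract a per-cell scalar from an ensemble
#'
#' @param ensemble An [run_ensemble()] result or a data frame of cells.
#' @param what \code{"end"} for the endpoint count of \code{species}, or
#'   \code{"int"} for its integral over \code{window}.
#' @param species Species name.
#' @param window \code{c(t0, t1)}; required for \code{what = "int"}.
#' @return Numeric vector, one value per cell.
#' @export
cell_values <- function(ensemble, what = c("end", "int"), species,
                        window = NULL) {
  what <- match.arg(what)
  cells <- if (inherits(ensemble, "ensemble_result")) ensemble$cells
           else ensemble
  col <- if (what == "end") paste0("end_", species)
         else {
           stopifnot(length(window) == 2L)
           sprintf("int_%s_%g_%g", species, window[1], window[2])
         }
  if (!col %in% names(cells)) {
    stop("ensemble has no recorded column '", col, "'", call. = FALSE)
  }
  cells[[col]]
}
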