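channel_labels <- function(net) {
  lab <- character(0)
  for (c in seq_along(net$cfg_prom)) {
    base <- paste0(net$promoters[net$cfg_prom[c]], ":",
                   net$species[net$cfg_act[c]])
    lab <- c(lab, paste0(c("bind:", "unbind:", "produce:"), base))
  }
  c(lab,
    paste0("degrade:", net$species),
    paste0("basal:", net$promoters))
}

#' Per-channel reaction propensities of a state
#'
#' Computes the instantaneous rate of every compiled reaction channel given
#' free-monomer counts and promoter occupancy. The binding propensity of an
#' activator configuration with oligomer order \code{n} and binding
#' constant \code{A1} is \code{A1 * choose(x, n)} (one binding event per
#' distinct oligomer formable from \code{x} free monomers) while the
#' promoter is free; unbinding and production are zero-order in the counts
#' and fire only while bound in that configuration; degradation is
#' first-order in the free monomer count. An all-zero vector signals an
#' absorbed state.
#'
#' @param counts Named nonnegative integer vector of free-monomer counts
#'   (one entry per model species).
#' @param model A [network_model()].
#' @param occupancy Named integer vector, one entry per promoter copy:
#'   0 for free, or the (model-wide) index of the occupying activator
#'   configuration. Defaults to all free.
#' @return Named numeric vector of propensities, one per channel.
#' @examples
#' m <- build_feedback_only(list(A1 = 0.01, n = 2))
#' propensities(c(BisDC = 8), m)  # binding = 0.01 * choose(8, 2)
#' @export
propensities <- function(counts, model, occupancy = NULL) {
  net <- compile_network(model)
  x <- resolve_counts(counts, net$species)
  P <- length(net$promoters)
  if (is.null(occupancy)) {
    occ <- rep(0L, P)
  } else {
    stopifnot(length(occupancy) == P)
    occ <- as.integer(occupancy)
  }
  a <- numeric(0)
  for (c in seq_along(net$cfg_prom)) {
    p <- net$cfg_prom[c]
    bind <- if (occ[p] == 0L)
      net$cfg_bind[c] * choose(x[net$cfg_act[c]], net$cfg_n[c]) else 0
    unbind <- if (occ[p] == c) net$cfg_unbind[c] else 0
    produce <- if (occ[p] == c) net$cfg_prod_rate[c] else 0
    a <- c(a, bind, unbind, produce)
  }
  a <- c(a, net$deg * x,
         ifelse(occ == 0L, net$prom_basal, 0))
  stats::setNames(a, channel_labels(net))
}

resolve_counts <- function(counts, species) {
  x <- rep(0L, length(species))
  if (is.null(counts)) return(x)
  if (!is.null(names(counts))) {
    unknown <- setdiff(names(counts), species)
    if (length(unknown)) {
      stop("unknown species in initial counts: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    x[match(names(counts), species)] <- as.integer(counts)
  } else {
    stopifnot(length(counts) == length(species))
    x <- as.integer(counts)
  }
  if (any(is.na(x) | x < 0)) {
    stop("initial counts must be nonnegative integers", call. = FALSE)
  }
  x
}

#' Simulate one cell with the Gillespie direct method
#'
#' Runs an exact continuous-time realization of the compiled reaction
#' network: exponential waiting times at the total propensity, channels
#' chosen proportionally to their propensity. The simulation terminates at
#' \code{t_end}, or earlier when the total propensity reaches zero (the
#' absorbed state is then held constant to \code{t_end}). Counts at event
#' times are right-continuous (post-event values). The run is fully
#' reproducible from \code{(model, initial_counts, seed)}.
#'
#' @param model A [network_model()].
#' @param initial_counts Named vector of initial free-monomer counts;
#'   unnamed species start at 0.
#' @param t_end Positive simulation horizon in model time units.
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the realization is reproducible.
#' @param max_events Guard against runaway models (error past this count).
#' @return An object of class \code{"trajectory"}: event times (starting at
#'   0), post-event count and occupancy matrices, fired channel labels, and
#'   \code{t_end}.
#' @seealso [endpoint()], [integrate_species()], [run_ensemble()]
#' @export
simulate_cell <- function(model, initial_counts = NULL, t_end = 100,
                          seed = NULL, max_events = 5e6) {
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    stop("t_end must be a positive scalar", call. = FALSE)
  }
  net <- compile_network(model)
  x0 <- resolve_counts(initial_counts, net$species)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ssa(net, x0, t_end, integer(0), numeric(0), numeric(0),
                 TRUE, max_events)
  lab <- channel_labels(net)
  counts <- res$counts
  colnames(counts) <- net$species
  occ <- res$occupancy
  colnames(occ) <- net$promoters
  structure(list(
    times = res$times,
    counts = counts,
    occupancy = occ,
    channels = c(NA_character_, lab[res$channels[-1] + 1L]),
    t_end = t_end,
    absorbed = res$absorbed,
    species = net$species,
    model_label = model$label), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$model_label, ": ", length(x$times) - 1L,
      " events over [0, ", x$t_end, "]",
      if (x$absorbed) " (absorbed)" else "", "\n", sep = "")
  invisible(x)
}

traj_species_col <- function(trajectory, species) {
  j <- match(species, trajectory$species)
  if (is.na(j)) stop("unknown species: ", species, call. = FALSE)
  j
}

#' Species count at a time point
#'
#' Right-continuous path query: at an event time the post-event count is
#' returned.
#'
#' @param trajectory A [simulate_cell()] result.
#' @param species Species name.
#' @param t Query time in \code{[0, t_end]}.
#' @return Nonnegative integer count.
#' @export
endpoint <- function(trajectory, species, t) {
  stopifnot(inherits(trajectory, "trajectory"))
  j <- traj_species_col(trajectory, species)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > trajectory$t_end) {
    stop("t must lie in [0, t_end]", call. = FALSE)
  }
  i <- findInterval(t, trajectory$times)
  unname(trajectory$counts[i, j])
}

#' Time integral of a species count
#'
#' Exact integral of the piecewise-constant count path over
#' \code{[t0, t1]}, e.g. the BisR activity integrated over the
#' \code{[10, 20]} observation window of the full cascade.
#'
#' @inheritParams endpoint
#' @param t0,t1 Window bounds, \code{0 <= t0 < t1 <= t_end}.
#' @return Nonnegative scalar integral (count x time units).
#' @export
integrate_species <- function(trajectory, species, t0, t1) {
  stopifnot(inherits(trajectory, "trajectory"))
  j <- traj_species_col(trajectory, species)
  if (!is.numeric(t0) || !is.numeric(t1) || t0 < 0 || t1 > trajectory$t_end ||
      t0 >= t1) {
    stop("window must satisfy 0 <= t0 < t1 <= t_end", call. = FALSE)
  }
  tt <- c(trajectory$times, trajectory$t_end)
  total <- 0
  for (i in seq_len(length(tt) - 1L)) {
    lo <- max(tt[i], t0)
    hi <- min(tt[i + 1L], t1)
    if (hi > lo) total <- total + unname(trajectory$counts[i, j]) * (hi - lo)
  }
  total
}

#' Tidy event table of a trajectory
#'
#' One row per recorded event (plus the initial state at time 0) with the
#' fired channel, post-event species counts and promoter occupancy states.
#'
#' @param x A [simulate_cell()] result.
#' @param ... Unused.
#' @return A data frame suitable for CSV export.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  occ <- as.data.frame(x$occupancy)
  names(occ) <- paste0("occ_", colnames(x$occupancy))
  cnt <- as.data.frame(x$counts)
  names(cnt) <- paste0("count_", colnames(x$counts))
  cbind(data.frame(time = x$times, channel = x$channels,
                   stringsAsFactors = FALSE), cnt, occ)
}
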