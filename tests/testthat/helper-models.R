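# Small reference models used across tests.

# linear death process: no promoters, one species decaying at `rate`
pure_death_model <- function(rate = 0.3) {
  network_model(species = list(species_spec("X", degradation_rate = rate)),
                promoters = list(), label = "pure_death")
}

# birth-death process via a constant basal production channel:
# stationary distribution is Poisson(k / gamma)
birth_death_model <- function(k = 2, gamma = 0.5) {
  network_model(
    species = list(species_spec("X", degradation_rate = gamma)),
    promoters = list(promoter_spec("P", configs = list(), basal_rate = k,
                                   basal_product = "X")),
    label = "birth_death")
}

# single constant-propensity channel: pure birth at rate k, no decay
pure_birth_model <- function(k = 1) {
  network_model(
    species = list(species_spec("X", degradation_rate = 0)),
    promoters = list(promoter_spec("P", configs = list(), basal_rate = k,
                                   basal_product = "X")),
    label = "pure_birth")
}

# hand-built trajectory for path-query tests (bypasses the simulator)
fake_trajectory <- function(times, counts, t_end, species = "X") {
  structure(list(
    times = times,
    counts = matrix(counts, ncol = 1, dimnames = list(NULL, species)),
    occupancy = matrix(0L, length(times), 0),
    channels = rep(NA_character_, length(times)),
    t_end = t_end, absorbed = FALSE,
    species = species, model_label = "fake"), class = "trajectory")
}
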