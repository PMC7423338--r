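#' Default rate parameters for the shipped network presets
#'
#' Rates are per arbitrary time unit; the observation horizon of all shipped
#' analyses is 100 time units. A-prefixed parameters attach to the BisDC
#' autoregulatory feedback node at \code{P_alpA} (\code{A1} binding,
#' \code{A2} unbinding, \code{A3} production, \code{A4} BisDC degradation);
#' \code{C5} is the cascade production rate of BisR at \code{P_bisR};
#' \code{B}-parameters govern the transient BisR kickstart of \code{P_alpA}
#' and \code{T}-parameters the TciR occupancy of \code{P_bisR};
#' \code{L}-parameters the BisDC-dependent late gene. Values were fixed once
#' by the calibration procedure in \code{scripts/calibrate.R} so that the
#' bare feedback loop gives a clearly bimodal output from binomial
#' (mean 8) input and the default full cascade places 3--5\% of cells in
#' the positive state; see \code{vignette("bistable-cascade-model")}.
#'
#' @return Named list of rate constants and oligomer orders.
#' @export
default_params <- function() {
  list(
    # BisDC autoregulatory feedback at P_alpA
    A1 = 0.02,   # BisDC oligomer binding to P_alpA
    A2 = 0.5,    # unbinding
    A3 = 4,      # BisDC production while BisDC-bound
    A4 = 0.15,   # BisDC degradation (free monomers)
    n  = 2L,     # oligomer order (monomers per binding complex), all nodes
    # BisR kickstart of P_alpA
    B1 = 0.1,    # BisR oligomer binding to P_alpA
    B2 = 1,      # unbinding
    B3 = 3,      # BisDC production while BisR-bound
    bisr_deg = 0.15,
    # TciR occupancy of P_bisR and BisR production (cascade node)
    T1 = 6e-4,   # TciR oligomer binding to P_bisR (the rare gating event)
    T2 = 0,      # unbinding: occupancy is effectively irreversible on the
                 # 100-unit horizon once TciR has bound
    C5 = 0.6,    # BisR production while TciR-bound
    tcir_deg = 0.3,
    # BisDC-dependent late gene
    L1 = 0.005,  # BisDC oligomer binding to P_late
    L2 = 0.5,    # unbinding
    L3 = 3,      # late-protein production while bound
    late_deg_stable = 0.02,
    late_deg_unstable = 0.3
  )
}

merge_params <- function(params) {
  defaults <- default_params()
  if (is.null(params)) return(defaults)
  stopifnot(is.list(params))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(params)] <- params
  defaults
}

#' Bare BisDC autoregulatory feedback loop
#'
#' The minimal bistability-generating subnetwork: a single species BisDC
#' whose oligomer activates \code{P_alpA}, which in turn produces BisDC.
#' Started from a nonzero BisDC input the loop either sustains itself
#' (positive state) or stochastically decays to the absorbing zero state.
#'
#' @param params Named list overriding entries of [default_params()]
#'   (uses \code{A1}, \code{A2}, \code{A3}, \code{A4}, \code{n}).
#' @return A [network_model()] labelled \code{"feedback_only"}, compiling
#'   to four reaction channels (bind, unbind, produce, degrade).
#' @examples
#' n_channels(build_feedback_only())        # 4
#' n_channels(build_feedback_only(list(A4 = 0.3)))
#' @export
build_feedback_only <- function(params = NULL) {
  p <- merge_params(params)
  network_model(
    species = list(species_spec("BisDC", degradation_rate = p$A4)),
    promoters = list(promoter_spec("P_alpA", list(
      activator_config("BisDC", n = p$n, binding_rate = p$A1,
                       unbinding_rate = p$A2, production_rate = p$A3)))),
    label = "feedback_only")
}

#' BisR-kickstarted feedback loop
#'
#' Adds the upstream kickstart: a BisR pulse (initial copies only, no
#' production channel, first-order decay) can occupy \code{P_alpA} and
#' prime BisDC production; thereafter the BisDC feedback sustains the
#' positive state. The two activator configurations of \code{P_alpA}
#' (BisR-bound, BisDC-bound) are mutually exclusive.
#'
#' @inheritParams build_feedback_only
#' @return A [network_model()] labelled \code{"kickstart"} with species
#'   BisR and BisDC (8 channels: 2 degradations + 2 x bind/unbind/produce).
#' @export
build_kickstart <- function(params = NULL) {
  p <- merge_params(params)
  network_model(
    species = list(
      species_spec("BisR", degradation_rate = p$bisr_deg),
      species_spec("BisDC", degradation_rate = p$A4)),
    promoters = list(promoter_spec("P_alpA", list(
      activator_config("BisR", n = p$n, binding_rate = p$B1,
                       unbinding_rate = p$B2, production_rate = p$B3,
                       product = "BisDC"),
      activator_config("BisDC", n = p$n, binding_rate = p$A1,
                       unbinding_rate = p$A2, production_rate = p$A3)))),
    label = "kickstart")
}

#' Full TciR -> BisR -> BisDC cascade
#'
#' The complete transfer-competence cascade: TciR (initial distribution
#' only) occupies \code{P_bisR} and produces BisR at rate \code{C5}; BisR
#' kickstarts \code{P_alpA}; BisDC feeds back on \code{P_alpA} (when
#' \code{include_feedback}) and, when \code{include_late}, drives a
#' downstream late gene whose stability is selected by
#' \code{late_stability}.
#'
#' @inheritParams build_feedback_only
#' @param include_feedback Keep the BisDC autoregulatory configuration on
#'   \code{P_alpA}? \code{FALSE} reproduces the feedback-ablated
#'   architecture.
#' @param include_late Add the BisDC-dependent late gene node?
#' @param late_stability \code{"stable"} (low degradation) or
#'   \code{"unstable"} (high degradation) late protein.
#' @return A [network_model()] labelled by the chosen architecture.
#' @export
build_full_cascade <- function(params = NULL, include_feedback = TRUE,
                               include_late = FALSE,
                               late_stability = c("stable", "unstable")) {
  p <- merge_params(params)
  late_stability <- match.arg(late_stability)
  stopifnot(isTRUE(include_feedback) || isFALSE(include_feedback),
            isTRUE(include_late) || isFALSE(include_late))

  species <- list(
    species_spec("TciR", degradation_rate = p$tcir_deg),
    species_spec("BisR", degradation_rate = p$bisr_deg),
    species_spec("BisDC", degradation_rate = p$A4))
  alpA_cfgs <- list(
    activator_config("BisR", n = p$n, binding_rate = p$B1,
                     unbinding_rate = p$B2, production_rate = p$B3,
                     product = "BisDC"))
  if (include_feedback) {
    alpA_cfgs <- c(alpA_cfgs, list(
      activator_config("BisDC", n = p$n, binding_rate = p$A1,
                       unbinding_rate = p$A2, production_rate = p$A3)))
  }
  promoters <- list(
    promoter_spec("P_bisR", list(
      activator_config("TciR", n = p$n, binding_rate = p$T1,
                       unbinding_rate = p$T2, production_rate = p$C5,
                       product = "BisR"))),
    promoter_spec("P_alpA", alpA_cfgs))
  if (include_late) {
    late_deg <- if (late_stability == "stable") p$late_deg_stable
                else p$late_deg_unstable
    species <- c(species, list(species_spec("Late", degradation_rate = late_deg)))
    promoters <- c(promoters, list(promoter_spec("P_late", list(
      activator_config("BisDC", n = p$n, binding_rate = p$L1,
                       unbinding_rate = p$L2, production_rate = p$L3,
                       product = "Late")))))
  }
  label <- paste0("full_cascade",
                  if (!include_feedback) "_nofb" else "",
                  if (include_late) paste0("_late_", late_stability) else "")
  network_model(species = species, promoters = promoters, label = label)
}

#' Build a shipped preset by name
#'
#' @param preset One of \code{"feedback_only"}, \code{"kickstart"},
#'   \code{"full_cascade"}, \code{"full_cascade_nofb"},
#'   \code{"full_cascade_late_stable"}, \code{"full_cascade_late_unstable"},
#'   \code{"full_cascade_nofb_late_stable"},
#'   \code{"full_cascade_nofb_late_unstable"}.
#' @param params Named list of rate overrides, see [default_params()].
#' @return A [network_model()].
#' @export
build_preset <- function(preset, params = NULL) {
  switch(preset,
    feedback_only = build_feedback_only(params),
    kickstart = build_kickstart(params),
    full_cascade = build_full_cascade(params),
    full_cascade_nofb = build_full_cascade(params, include_feedback = FALSE),
    full_cascade_late_stable =
      build_full_cascade(params, include_late = TRUE,
                         late_stability = "stable"),
    full_cascade_late_unstable =
      build_full_cascade(params, include_late = TRUE,
                         late_stability = "unstable"),
    full_cascade_nofb_late_stable =
      build_full_cascade(params, include_feedback = FALSE,
                         include_late = TRUE, late_stability = "stable"),
    full_cascade_nofb_late_unstable =
      build_full_cascade(params, include_feedback = FALSE,
                         include_late = TRUE, late_stability = "unstable"),
    stop("unknown preset: ", preset, call. = FALSE))
}

#' Shipped default input distributions per preset
#'
#' The feedback-only loop starts from binomially distributed BisDC copies
#' with mean 8 (16 trials at probability 0.5); the kickstarted loop from a
#' uniform-integer BisR pulse on \{0..16\}; the full cascade from a
#' uniform-integer TciR distribution on \{0..16\} (means within the per-cell
#' range typically measured for bacterial transcription factors).
#'
#' @param preset Preset name as in [build_preset()].
#' @return Named list of [input_spec()] objects keyed by species.
#' @export
default_inputs <- function(preset) {
  if (preset == "feedback_only") {
    list(BisDC = input_spec("BisDC", "binomial", list(size = 16, prob = 0.5)))
  } else if (preset == "kickstart") {
    list(BisR = input_spec("BisR", "uniform", list(min = 0, max = 16)))
  } else if (startsWith(preset, "full_cascade")) {
    list(TciR = input_spec("TciR", "uniform", list(min = 0, max = 16)))
  } else {
    stop("unknown preset: ", preset, call. = FALSE)
  }
}
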