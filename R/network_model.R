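#' Species specification
#'
#' Declares one molecular species of a regulatory network together with its
#' first-order degradation rate (the \code{A4}-class parameter). Degradation
#' acts on free monomers only; monomers sequestered in a promoter-bound
#' oligomer are protected until unbinding (see
#' \code{vignette("bistable-cascade-model")}).
#'
#' @param name Species identifier (e.g. \code{"BisDC"}).
#' @param degradation_rate Nonnegative per-time degradation rate constant.
#' @return An object of class \code{"species_spec"}.
#' @seealso [promoter_spec()], [network_model()]
#' @export
species_spec <- function(name, degradation_rate = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(degradation_rate) || length(degradation_rate) != 1L ||
      is.na(degradation_rate) || degradation_rate < 0) {
    stop("degradation_rate must be a single nonnegative number", call. = FALSE)
  }
  structure(list(name = name, degradation_rate = as.numeric(degradation_rate)),
            class = "species_spec")
}

#' Activator configuration of a promoter
#'
#' One way a promoter can be occupied: an oligomer of \code{n} monomers of
#' \code{activator} binds at rate \code{binding_rate} (the \code{A1}-class
#' constant, applied to the number of distinct oligomers
#' \eqn{\choose{x}{n}} formable from \code{x} free monomers), unbinds at
#' \code{unbinding_rate} (\code{A2}), and while bound drives production of
#' \code{product} at \code{production_rate} (\code{A3} for the feedback
#' node, \code{C5} for the cascade node).
#'
#' @param activator Species whose oligomer binds the promoter.
#' @param n Oligomer order (number of monomers in the binding complex),
#'   positive integer. Default 2 (a typical dimeric transcription factor).
#' @param binding_rate,unbinding_rate,production_rate Nonnegative rate
#'   constants per arbitrary time unit.
#' @param product Species produced while this configuration occupies the
#'   promoter. Defaults to \code{activator} (autoregulation).
#' @return An object of class \code{"activator_config"}.
#' @export
activator_config <- function(activator, n = 2L, binding_rate, unbinding_rate,
                             production_rate, product = activator) {
  stopifnot(is.character(activator), length(activator) == 1L,
            is.character(product), length(product) == 1L)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("oligomer order n must be a positive integer", call. = FALSE)
  }
  for (nm in c("binding_rate", "unbinding_rate", "production_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(nm, " must be a single nonnegative number", call. = FALSE)
    }
  }
  structure(list(activator = activator, n = as.integer(n),
                 binding_rate = as.numeric(binding_rate),
                 unbinding_rate = as.numeric(unbinding_rate),
                 production_rate = as.numeric(production_rate),
                 product = product),
            class = "activator_config")
}

#' Promoter specification
#'
#' A promoter (operator) with mutually exclusive occupancy: at any time each
#' promoter copy is either free or bound by exactly one activator oligomer
#' from one of its \code{configs}. An optional basal production channel fires
#' only while the promoter is free.
#'
#' @param name Promoter identifier (e.g. \code{"P_alpA"}).
#' @param configs List of [activator_config()] objects.
#' @param copies Positive integer number of identical promoter copies
#'   (default 1: a single chromosomal/ICE copy per cell).
#' @param basal_rate Nonnegative production rate while free (default 0,
#'   i.e. the promoter is silent without activation).
#' @param basal_product Species produced by the basal channel; required when
#'   \code{basal_rate > 0}.
#' @return An object of class \code{"promoter_spec"}.
#' @export
promoter_spec <- function(name, configs = list(), copies = 1L,
                          basal_rate = 0, basal_product = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.list(configs))
  if (!all(vapply(configs, inherits, logical(1), "activator_config"))) {
    stop("configs must be a list of activator_config objects", call. = FALSE)
  }
  if (!is.numeric(copies) || length(copies) != 1L || copies < 1 ||
      copies != round(copies)) {
    stop("copies must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(basal_rate) || length(basal_rate) != 1L ||
      is.na(basal_rate) || basal_rate < 0) {
    stop("basal_rate must be a single nonnegative number", call. = FALSE)
  }
  if (basal_rate > 0 && is.null(basal_product)) {
    stop("basal_product must name a species when basal_rate > 0",
         call. = FALSE)
  }
  structure(list(name = name, configs = configs, copies = as.integer(copies),
                 basal_rate = as.numeric(basal_rate),
                 basal_product = basal_product),
            class = "promoter_spec")
}

#' Regulatory network model
#'
#' Bundles species and promoters into a reaction-network description from
#' which stochastic simulation channels are compiled: per promoter
#' activator-config one binding, one unbinding and one production channel;
#' per species with positive degradation rate one degradation channel; per
#' promoter with positive basal rate one basal production channel.
#'
#' @param species List of [species_spec()] objects.
#' @param promoters List of [promoter_spec()] objects.
#' @param label Configuration name carried through ensembles and outputs.
#' @return An object of class \code{"network_model"}.
#' @examples
#' m <- network_model(
#'   species = list(species_spec("BisDC", degradation_rate = 0.1)),
#'   promoters = list(promoter_spec("P_alpA", list(
#'     activator_config("BisDC", n = 2, binding_rate = 0.05,
#'                      unbinding_rate = 0.5, production_rate = 3)))),
#'   label = "feedback_only")
#' validate_network(m)
#' @export
network_model <- function(species, promoters, label = "custom") {
  stopifnot(is.list(species), is.list(promoters),
            is.character(label), length(label) == 1L)
  if (!all(vapply(species, inherits, logical(1), "species_spec"))) {
    stop("species must be a list of species_spec objects", call. = FALSE)
  }
  if (!all(vapply(promoters, inherits, logical(1), "promoter_spec"))) {
    stop("promoters must be a list of promoter_spec objects", call. = FALSE)
  }
  m <- structure(list(species = species, promoters = promoters, label = label),
                 class = "network_model")
  bad <- validate_network(m)
  if (length(bad)) {
    stop("invalid network model:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  m
}

#' Species names of a model
#' @param model A [network_model()].
#' @return Character vector of species names.
#' @export
species_names <- function(model) {
  vapply(model$species, `[[`, character(1), "name")
}

#' Validate a network model
#'
#' Checks structural soundness without raising: duplicate species or
#' promoter names, negative rates, non-integer or non-positive oligomer
#' orders, and activator/product references to undeclared species.
#'
#' @param model A \code{network_model} (or a bare list with the same shape).
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_network <- function(model) {
  out <- character(0)
  sp <- vapply(model$species, function(s) s$name, character(1))
  if (anyDuplicated(sp)) {
    out <- c(out, paste0("duplicate species name: ",
                         paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  }
  pn <- vapply(model$promoters, function(p) p$name, character(1))
  if (anyDuplicated(pn)) {
    out <- c(out, paste0("duplicate promoter name: ",
                         paste(unique(pn[duplicated(pn)]), collapse = ", ")))
  }
  for (s in model$species) {
    if (is.na(s$degradation_rate) || s$degradation_rate < 0) {
      out <- c(out, paste0("species ", s$name, ": negative degradation_rate"))
    }
  }
  for (p in model$promoters) {
    if (p$basal_rate < 0) {
      out <- c(out, paste0("promoter ", p$name, ": negative basal_rate"))
    }
    if (p$basal_rate > 0 && !(p$basal_product %in% sp)) {
      out <- c(out, paste0("promoter ", p$name, ": basal_product '",
                           p$basal_product, "' not a declared species"))
    }
    for (cfg in p$configs) {
      if (!(cfg$activator %in% sp)) {
        out <- c(out, paste0("promoter ", p$name, ": activator '",
                             cfg$activator, "' not a declared species"))
      }
      if (!(cfg$product %in% sp)) {
        out <- c(out, paste0("promoter ", p$name, ": product '",
                             cfg$product, "' not a declared species"))
      }
      for (nm in c("binding_rate", "unbinding_rate", "production_rate")) {
        if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
          out <- c(out, paste0("promoter ", p$name, " (activator ",
                               cfg$activator, "): negative ", nm))
        }
      }
      if (cfg$n < 1 || cfg$n != round(cfg$n)) {
        out <- c(out, paste0("promoter ", p$name, " (activator ",
                             cfg$activator, "): oligomer order must be a ",
                             "positive integer"))
      }
    }
  }
  out
}

# Flatten a model into parallel vectors for the compiled SSA core.
# Promoter copies > 1 are expanded into independent occupancy slots.
compile_network <- function(model) {
  sp <- species_names(model)
  cfg_prom <- integer(0); cfg_act <- integer(0); cfg_n <- integer(0)
  cfg_bind <- numeric(0); cfg_unbind <- numeric(0); cfg_prod_rate <- numeric(0)
  cfg_product <- integer(0)
  prom_basal <- numeric(0); prom_basal_product <- integer(0)
  prom_names <- character(0)
  slot <- 0L
  for (p in model$promoters) {
    for (copy in seq_len(p$copies)) {
      slot <- slot + 1L
      prom_names <- c(prom_names,
                      if (p$copies > 1L) paste0(p$name, ".", copy) else p$name)
      prom_basal <- c(prom_basal, p$basal_rate)
      prom_basal_product <- c(prom_basal_product,
                              if (p$basal_rate > 0)
                                match(p$basal_product, sp) else NA_integer_)
      for (cfg in p$configs) {
        cfg_prom <- c(cfg_prom, slot)
        cfg_act <- c(cfg_act, match(cfg$activator, sp))
        cfg_n <- c(cfg_n, cfg$n)
        cfg_bind <- c(cfg_bind, cfg$binding_rate)
        cfg_unbind <- c(cfg_unbind, cfg$unbinding_rate)
        cfg_prod_rate <- c(cfg_prod_rate, cfg$production_rate)
        cfg_product <- c(cfg_product, match(cfg$product, sp))
      }
    }
  }
  list(
    species = sp,
    deg = vapply(model$species, `[[`, numeric(1), "degradation_rate"),
    promoters = prom_names,
    cfg_prom = cfg_prom, cfg_act = cfg_act, cfg_n = cfg_n,
    cfg_bind = cfg_bind, cfg_unbind = cfg_unbind,
    cfg_prod_rate = cfg_prod_rate, cfg_product = cfg_product,
    prom_basal = prom_basal, prom_basal_product = prom_basal_product
  )
}

#' Number of stochastic reaction channels of a model
#'
#' Three channels (bind, unbind, produce) per promoter-copy
#' activator-configuration, one degradation channel per species with a
#' positive degradation rate, and one basal production channel per
#' promoter copy with a positive basal rate.
#'
#' @param model A [network_model()].
#' @return Integer channel count.
#' @export
n_channels <- function(model) {
  net <- compile_network(model)
  3L * length(net$cfg_prom) + sum(net$deg > 0) + sum(net$prom_basal > 0)
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$label, "\n", sep = "")
  cat("  species:  ",
      paste(sprintf("%s (deg %.3g)", species_names(x),
                    vapply(x$species, `[[`, numeric(1), "degradation_rate")),
            collapse = ", "), "\n", sep = "")
  for (p in x$promoters) {
    cat("  promoter ", p$name,
        if (p$copies > 1L) sprintf(" x%d", p$copies) else "", ":\n", sep = "")
    for (cfg in p$configs) {
      cat(sprintf(
        "    %s_%d  bind %.3g / unbind %.3g -> %s @ %.3g\n",
        cfg$activator, cfg$n, cfg$binding_rate, cfg$unbinding_rate,
        cfg$product, cfg$production_rate))
    }
    if (p$basal_rate > 0) {
      cat(sprintf("    basal -> %s @ %.3g\n", p$basal_product, p$basal_rate))
    }
  }
  cat("  channels: ", n_channels(x), "\n", sep = "")
  invisible(x)
}
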