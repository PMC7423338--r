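#' Run configuration
#'
#' A complete, serialisable description of a simulation run: preset name,
#' rate overrides, input distributions, ensemble size, horizon, recorded
#' windows and root seed. A configuration round-trips losslessly through
#' YAML ([write_run_config()] / [read_run_config()]) and re-executes to
#' identical outputs.
#'
#' @param preset Preset name, see [build_preset()].
#' @param params Named list of rate overrides (may be empty).
#' @param inputs List of [input_spec()] objects; \code{NULL} uses
#'   [default_inputs()] for the preset.
#' @param n_cells,t_end,windows,seed As in [run_ensemble()].
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(preset, params = list(), inputs = NULL,
                       n_cells = 10000, t_end = 100, windows = list(),
                       seed = 1L) {
  build_preset(preset, if (length(params)) params else NULL)  # validates
  if (is.null(inputs)) inputs <- default_inputs(preset)
  if (inherits(inputs, "input_spec")) inputs <- list(inputs)
  stopifnot(all(vapply(inputs, inherits, logical(1), "input_spec")),
            is.numeric(n_cells), n_cells >= 1,
            is.numeric(t_end), t_end > 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(preset = preset, params = params, inputs = inputs,
                 n_cells = as.integer(n_cells), t_end = as.numeric(t_end),
                 windows = windows, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration as YAML
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return Invisibly, \code{path}.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$inputs <- lapply(config$inputs, unclass)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  inputs <- lapply(obj$inputs, function(i) {
    input_spec(i$species, i$family, i$params,
               scale_multiplier = i$scale_multiplier)
  })
  windows <- lapply(obj$windows, unlist)
  run_config(obj$preset, params = obj$params, inputs = inputs,
             n_cells = obj$n_cells, t_end = obj$t_end,
             windows = windows, seed = obj$seed)
}

#' Simulate an ensemble from a run configuration
#'
#' Builds the preset, runs the seeded ensemble, and (when \code{outdir} is
#' given) writes \code{ensemble.csv}, its JSON sidecar and a
#' \code{config.yaml} that re-executes to identical outputs.
#'
#' @param config A [run_config()] or path to a YAML configuration.
#' @param outdir Optional output directory (created if missing).
#' @param quiet Suppress the progress message to stderr?
#' @return The [run_ensemble()] result, invisibly when writing.
#' @export
run_simulate <- function(config, outdir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  model <- build_preset(config$preset,
                        if (length(config$params)) config$params else NULL)
  if (!quiet) {
    message(sprintf("simulating %s: %d cells to t = %g (seed %d)",
                    model$label, config$n_cells, config$t_end, config$seed))
  }
  ens <- run_ensemble(model, config$inputs, n_cells = config$n_cells,
                      t_end = config$t_end, windows = config$windows,
                      root_seed = config$seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_ensemble(ens, file.path(outdir, "ensemble.csv"))
    write_run_config(config, file.path(outdir, "config.yaml"))
    return(invisible(ens))
  }
  ens
}

#' Analyse a stored or in-memory ensemble
#'
#' Dispatches to the analysis operations: \code{"classify"} runs
#' [classify_states()] on the endpoint (or window integral) of a species;
#' \code{"cascade"} runs [cascade_bimodality()]; \code{"qq_estimate"} runs
#' [qq_subpopulation_estimate()] on a per-cell intensity table;
#' \code{"dose_response"} rebuilds the preset recorded in the ensemble
#' sidecar and runs [dose_response()] over \code{options$levels}. Results
#' are returned and, when \code{out} is given, written as JSON (plus CSV
#' for tabular results).
#'
#' @param input Path to an \code{ensemble.csv} (with JSON sidecar), a
#'   per-cell intensity CSV for \code{"qq_estimate"}, or an
#'   [run_ensemble()] result.
#' @param analysis One of \code{"classify"}, \code{"cascade"},
#'   \code{"qq_estimate"}, \code{"dose_response"}.
#' @param options Named list of analysis options (\code{species},
#'   \code{window}, \code{levels}, \code{k}, ...).
#' @param out Optional output path stem (without extension).
#' @return The analysis result object.
#' @export
run_analyze <- function(input, analysis = c("classify", "cascade",
                                            "qq_estimate", "dose_response"),
                        options = list(), out = NULL) {
  analysis <- match.arg(analysis)
  res <- switch(analysis,
    classify = {
      cells <- analysis_cells(input)
      species <- options$species %||% "BisDC"
      vals <- if (!is.null(options$window)) {
        cell_values(cells, "int", species, window = options$window)
      } else cell_values(cells, "end", species)
      classify_states(vals)
    },
    cascade = {
      cells <- analysis_cells(input)
      cascade_bimodality(cells, window = options$window %||% c(10, 20))
    },
    qq_estimate = {
      x <- if (is.character(input)) utils::read.csv(input)$intensity
           else if (inherits(input, "fluor_sample")) input$intensity
           else input
      qq_subpopulation_estimate(x, k = options$k %||% 2,
                                fit_window = options$fit_window %||% 0.5,
                                persist = options$persist %||% 0.95)
    },
    dose_response = {
      if (!is.character(input)) {
        stop("dose_response analysis needs an ensemble path with sidecar",
             call. = FALSE)
      }
      meta <- read_ensemble(input)$meta
      if (is.null(meta)) stop("missing JSON sidecar next to ", input,
                              call. = FALSE)
      base <- meta$input_specs[[1]]
      dose_response(
        builder = function(p) build_preset(meta$model_label, p),
        input_levels = options$levels %||% c(0.25, 0.5, 1, 2, 4),
        base_input = input_spec(base$species, base$family, base$params,
                                scale_multiplier = base$scale_multiplier),
        n_cells = options$n_cells %||% meta$n_cells,
        t_end = meta$t_end, root_seed = meta$root_seed)
    })
  if (!is.null(out)) {
    write_analysis(res, out)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analysis_cells <- function(input) {
  if (is.character(input)) {
    if (!file.exists(input)) stop("no such file: ", input, call. = FALSE)
    read_ensemble(input)$cells
  } else if (inherits(input, "ensemble_result")) {
    input$cells
  } else if (is.data.frame(input)) {
    input
  } else stop("unsupported input", call. = FALSE)
}

write_analysis <- function(res, out) {
  to_plain <- function(x) {
    if (inherits(x, "subpop_summary") || inherits(x, "subpop_estimate")) {
      unclass(x)
    } else if (is.list(x) && !is.data.frame(x))

      lapply(x, to_plain)
    else x
  }
  if (is.data.frame(res)) {
    utils::write.csv(res, paste0(out, ".csv"), row.names = FALSE)
    jsonlite::write_json(res, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  } else {
    jsonlite::write_json(to_plain(res), paste0(out, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Reproduce a shipped figure-style analysis
#'
#' End-to-end drivers for the package's headline analyses with shipped
#' defaults, writing summaries, per-cell tables and a re-executable
#' configuration sidecar per panel:
#' \describe{
#'   \item{\code{"6B"}}{bare feedback loop from binomial (mean 8) BisDC
#'     input: histogram with an explicit zero bar.}
#'   \item{\code{"6C"}}{kickstarted loop under increasing uniform BisR
#'     means and a bimodal BisR input.}
#'   \item{\code{"6D"}}{full cascade: BisR integral over \code{[10, 20]}
#'     and BisDC endpoint at two TciR input means.}
#'   \item{\code{"6E"}}{late-protein output with/without feedback for
#'     stable and unstable late protein.}
#'   \item{\code{"7D"}}{dose-response of the positive fraction over
#'     relative BisR starting levels.}
#' }
#'
#' @param panel One of \code{"6B"}, \code{"6C"}, \code{"6D"}, \code{"6E"},
#'   \code{"7D"}.
#' @param outdir Output directory.
#' @param n_cells Ensemble size per condition (default 10,000).
#' @param seed Root seed.
#' @param quiet Suppress progress messages?
#' @return The panel's result object, invisibly.
#' @export
reproduce_panel <- function(panel, outdir, n_cells = 10000, seed = 1L,
                            quiet = FALSE) {
  panels <- c("6B", "6C", "6D", "6E", "7D")
  if (!is.character(panel) || length(panel) != 1L || !(panel %in% panels)) {
    stop("unknown panel; choose one of ", paste(panels, collapse = ", "),
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(panel,
    "6B" = {
      cfg <- run_config("feedback_only", n_cells = n_cells, seed = seed)
      ens <- run_simulate(cfg, outdir = outdir, quiet = quiet)
      s <- classify_states(cell_values(ens, "end", "BisDC"))
      write_analysis(s, file.path(outdir, "summary_6B"))
      s
    },
    "6C" = {
      model <- build_kickstart()
      means <- c(1, 2, 4, 8, 16, 32)
      rows <- lapply(means, function(m) {
        ens <- run_ensemble(model,
                            list(input_spec("BisR", "uniform",
                                            list(min = 0, max = 2 * m))),
                            n_cells = n_cells, root_seed = seed)
        cbind(data.frame(input_mean = m),
              as.data.frame(classify_states(cell_values(ens, "end",
                                                        "BisDC"))))
      })
      tab <- do.call(rbind, rows)
      bim <- bimodal_input_response(
        bimodal_spec = input_spec("BisR", "bimodal",
                                  list(zero_weight = 0.5, active_mean = 16)),
        n_cells = n_cells, root_seed = seed)
      utils::write.csv(tab, file.path(outdir, "summary_6C_uniform.csv"),
                       row.names = FALSE)
      write_analysis(bim, file.path(outdir, "summary_6C_bimodal"))
      list(uniform = tab, bimodal = bim)
    },
    "6D" = {
      out <- list()
      for (m in c(4, 16)) {
        cfg <- run_config("full_cascade",
                          inputs = list(input_spec("TciR", "uniform",
                                                   list(min = 0,
                                                        max = 2 * m))),
                          n_cells = n_cells, windows = list(BisR = c(10, 20)),
                          seed = seed)
        ens <- run_simulate(cfg, outdir = file.path(outdir,
                                                    paste0("tcir_mean_", m)),
                            quiet = quiet)
        out[[paste0("tcir_mean_", m)]] <- cascade_bimodality(ens)
      }
      write_analysis(out, file.path(outdir, "summary_6D"))
      out
    },
    "6E" = {
      out <- list()
      for (stab in c("stable", "unstable")) {
        ens_fb <- run_ensemble(
          build_full_cascade(include_late = TRUE, late_stability = stab),
          default_inputs("full_cascade"), n_cells = n_cells,
          root_seed = seed)
        ens_no <- run_ensemble(
          build_full_cascade(include_feedback = FALSE, include_late = TRUE,
                             late_stability = stab),
          default_inputs("full_cascade"), n_cells = n_cells,
          root_seed = seed)
        out[[stab]] <- compare_feedback(ens_fb, ens_no, seed = seed)
      }
      write_analysis(out, file.path(outdir, "summary_6E"))
      out
    },
    "7D" = {
      dr <- dose_response(input_levels = c(0.125, 0.25, 0.5, 1, 2, 4),
                          n_cells = n_cells, root_seed = seed)
      utils::write.csv(dr, file.path(outdir, "dose_response_7D.csv"),
                       row.names = FALSE)
      dr
    })
  invisible(res)
}
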