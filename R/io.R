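#' Load an experiment configuration
#'
#' Reads a YAML experiment configuration, applies the default parameter
#' set with any overrides layered on top, validates everything (unknown
#' keys and parameter names are rejected, a seed is required) and returns
#' an [experiment_spec()].
#'
#' @param path Path to a YAML file.
#' @return An [experiment_spec()].
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  spec_from_config(cfg, source = path)
}

spec_from_config <- function(cfg, source = "config") {
  known <- c("name", "seed", "days", "nights", "sequences", "params",
             "gates", "hc_to_ctx", "morning_test_hour", "train_hour",
             "sleep_hour")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown key(s) in ", source, ": ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must provide a seed")

  params <- do.call(model_params, validate_overrides(cfg$params))
  gates <- if (is.null(cfg$gates)) plasticity_gates() else {
    bad <- setdiff(names(cfg$gates),
                   c("hc_learning_wake", "hc_learning_sleep",
                     "ctx_learning_wake", "ctx_learning_sleep"))
    if (length(bad)) stop("unknown gate(s): ", paste(bad, collapse = ", "))
    do.call(plasticity_gates, cfg$gates)
  }
  nights <- unlist(cfg$nights %||% integer())

  experiment_spec(name = cfg$name %||% "experiment",
                  seed = cfg$seed,
                  days = cfg$days %||% list(),
                  nights = nights,
                  sequences = cfg$sequences,
                  params = params, gates = gates,
                  hc_to_ctx = cfg$hc_to_ctx %||% TRUE,
                  morning_test_hour = cfg$morning_test_hour %||% 8,
                  train_hour = cfg$train_hour %||% 9,
                  sleep_hour = cfg$sleep_hour %||% 23)
}

validate_overrides <- function(overrides) {
  if (is.null(overrides)) return(list())
  valid <- names(formals(model_params))
  bad <- setdiff(names(overrides), valid)
  if (length(bad))
    stop("unknown model parameter(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(valid, collapse = ", "))
  overrides
}

#' Shipped experiment presets
#'
#' `preset_names()` lists the packaged experiment presets; `load_preset()`
#' loads one as an [experiment_spec()], optionally overriding its seed.
#' The presets are: `baseline` (one sequence, four nights of sleep),
#' `lesion` (hippocampus-to-cortex feedback off from the start),
#' `salience_two_seq` (two sequences, one practiced daily),
#' `competition` (the unpracticed sequence tested daily while the other
#' is practiced), `hc_sleep_off` (hippocampal learning disabled in
#' sleep), and `overlap` (two sequences sharing their third item).
#'
#' @param name Preset name.
#' @param seed Optional integer overriding the preset's seed.
#' @return `load_preset()` returns an [experiment_spec()];
#'   `preset_names()` a character vector.
#' @export
load_preset <- function(name, seed = NULL) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "seqconsol")
  if (!nzchar(path))
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "))
  spec <- load_experiment_config(path)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  spec
}

#' @rdname load_preset
#' @export
preset_names <- function() {
  dir <- system.file("extdata", "presets", package = "seqconsol")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Serialize an experiment spec to YAML
#'
#' Inverse of [load_experiment_config()] for the declarative fields
#' (parameter values are written only where they differ from defaults).
#'
#' @param spec An [experiment_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(spec, path) {
  defaults <- model_params()
  pr <- list()
  for (nm in setdiff(names(formals(model_params)), "decay_time_unit")) {
    if (!identical(spec$params[[nm]], eval(formals(model_params)[[nm]])) &&
        !identical(spec$params[[nm]], defaults[[nm]]))
      pr[[nm]] <- spec$params[[nm]]
  }
  days <- lapply(spec$days, function(d) {
    out <- list()
    if (length(d$train))
      out$train <- lapply(d$train, function(b)
        list(seq = paste(b$seq, collapse = ""), trials = b$trials))
    if (length(d$morning_tests)) out$morning_tests <- as.list(d$morning_tests)
    if (length(d$evening_tests)) out$evening_tests <- as.list(d$evening_tests)
    out
  })
  cfg <- list(name = spec$name, seed = spec$seed, days = days,
              nights = as.list(spec$nights))
  if (!spec$hc_to_ctx) cfg$hc_to_ctx <- FALSE
  g <- spec$gates
  g_off <- Filter(Negate(isTRUE), unclass(g))
  if (length(g_off)) cfg$gates <- g_off
  if (length(pr)) cfg$params <- pr
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a result bundle to disk
#'
#' Serializes a [run_experiment()] result to a directory of plain-text
#' files: `recalls.csv`, `replays.csv`, `replay_crossings.csv`,
#' `weights.csv` (sampled forward-link trajectories), `salience.csv`
#' (per-epoch snapshots), `summary.json` (per-day recall metrics,
#' per-night replay shares, final weights) and `manifest.json` (name,
#' seed, item catalog, timestamps).
#'
#' @param result A `consolidation_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w9 <- function(df, f) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 9)
    write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  if (!is.null(result$recalls)) w9(result$recalls, "recalls.csv")
  if (!is.null(result$replays)) w9(result$replays, "replays.csv")
  if (!is.null(result$replay_crossings))
    w9(result$replay_crossings, "replay_crossings.csv")
  if (!is.null(result$weights)) w9(result$weights, "weights.csv")
  sal <- do.call(rbind, lapply(result$snapshots, function(sn)
    data.frame(time = sn$time, label = sn$label,
               item = names(sn$salience), s = unname(sn$salience),
               stringsAsFactors = FALSE)))
  if (!is.null(sal)) w9(sal, "salience.csv")

  jsonlite::write_json(summarize_result(result),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(name = result$spec$name, seed = result$spec$seed,
                   items = result$final_state$catalog,
                   sequences = lapply(result$spec$sequences, paste, collapse = ""),
                   final_clock = result$final_state$clock,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Summary tables for a result
#'
#' Per-test recall metrics, per-night replay shares and the final mean
#' forward-link weight of every sequence in each region.
#'
#' @param result A `consolidation_result`.
#' @return A list of plain data structures (suitable for JSON).
#' @export
summarize_result <- function(result) {
  st <- if (!is.null(result$replays))
    replay_statistics(result$replays, result$spec$sequences) else NULL
  fin <- result$final_state
  endpoints <- list()
  for (nm in names(result$spec$sequences)) {
    s <- result$spec$sequences[[nm]]
    if (length(s) < 2) next
    i <- item_index(fin, s[-length(s)])
    j <- item_index(fin, s[-1])
    idx <- cbind(i, j)
    endpoints[[nm]] <- list(ctx_mean_forward_w = mean(fin$ctx$W[idx]),
                            hc_mean_forward_w = mean(fin$hc$W[idx]))
  }
  list(name = result$spec$name, seed = result$spec$seed,
       recalls = result$recalls,
       replay_shares = if (!is.null(st)) st$shares else NULL,
       replay_durations = if (!is.null(st)) st$durations else NULL,
       final_weights = endpoints)
}
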