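# Layered run configuration: CLI > config file > protocol defaults.

#' Protocol defaults per mode
#'
#' The GPCR protocol: 8 sequence clusters + 16 extra cluster sequences,
#' top 4 state-matched templates, 50 models, no recycling, same-subfamily
#' templates excluded. The kinase protocol is identical but takes 20
#' templates and does not exclude the subfamily. The MSA-only variant
#' (16 clusters + 32 extra, no templates) is available as
#' `msa_mode = "shallow"` with `n_clusters = 16, n_extra = 32` and an
#' empty template plan.
#'
#' @param mode `"gpcr"` or `"kinase"`.
#' @return named list of default settings.
#' @export
default_config <- function(mode = c("gpcr", "kinase")) {
  mode <- match.arg(mode)
  base <- list(
    mode = mode,
    gpcr_state = if (mode == "gpcr") "Active" else NULL,
    dfg = "all", ac_helix = "all", salt_bridge = "all",
    k = if (mode == "kinase") 20L else 4L,
    exclude_same_subfamily = (mode == "gpcr"),
    randomize = FALSE,
    min_rank_score = 0, min_seq_identity = 0,
    signaling_as_active = TRUE,
    n_models = 50L,
    n_clusters = 8L, n_extra = 16L,
    msa_mode = "shallow",
    speach_window = 10L,
    recycles = 0L,
    plddt_floor = 40, rg_ceiling = 2.5,
    sigma = 0.5,
    predictor = "mock",
    query_subfamily = "",
    seed = 0L)
  base
}

#' Resolve a run configuration from CLI arguments, file and defaults
#'
#' Precedence is CLI arguments > config file (YAML) > mode defaults.
#' Unknown keys in either layer are an error (listing the offenders), so
#' typos never silently fall back to defaults. The resolved list
#' round-trips through [write_run_config()]: re-feeding a run's echoed
#' config reproduces the run bit-for-bit with the mock predictor.
#'
#' @param cli_args named list of overrides (highest precedence).
#' @param config_file optional YAML file.
#' @param mode optional mode override; otherwise taken from `cli_args`,
#'   then the file, then `"gpcr"`.
#' @return a `run_config` list; `$query` holds the derived [state_query()].
#' @export
resolve_config <- function(cli_args = list(), config_file = NULL, mode = NULL) {
  file_cfg <- if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    yaml::read_yaml(config_file)
  } else list()
  mode <- mode %||% cli_args$mode %||% file_cfg$mode %||% "gpcr"
  defaults <- default_config(mode)
  known <- names(defaults)
  for (layer in list(file = file_cfg, cli = cli_args)) {
    unknown <- setdiff(names(layer), known)
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(utils::modifyList(defaults, file_cfg), cli_args)
  cfg$mode <- mode
  cfg$k <- as.integer(cfg$k); cfg$n_models <- as.integer(cfg$n_models)
  cfg$query <- state_query(
    mode = cfg$mode, gpcr_state = cfg$gpcr_state,
    dfg = cfg$dfg, ac_helix = cfg$ac_helix, salt_bridge = cfg$salt_bridge,
    k = cfg$k, exclude_same_subfamily = cfg$exclude_same_subfamily,
    randomize = cfg$randomize, min_rank_score = cfg$min_rank_score,
    min_seq_identity = cfg$min_seq_identity,
    signaling_as_active = cfg$signaling_as_active, seed = cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Echo a resolved configuration to YAML
#'
#' The written file is itself a valid `config_file` for
#' [resolve_config()], which is how a run manifest reproduces a run.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- unclass(config)
  flat$query <- NULL
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Run the full biased-prediction pipeline from a configuration
#'
#' Convenience wrapper tying the stages together: template planning, MSA
#' intervention, ensemble generation with the configured predictor, and
#' the unfolded-model filter. Writes one PDB per surviving model plus a
#' JSON run manifest when `out_dir` is given.
#'
#' @param config a `run_config` from [resolve_config()].
#' @param query_seq query sequence.
#' @param msa_obj an [msa()] or `NULL`.
#' @param records annotation `template_records`.
#' @param out_dir optional output directory.
#' @return list with `models` (post-filter), `run` (the raw
#'   `ensemble_run`), `discarded`, and output paths when written.
#' @export
run_pipeline <- function(config, query_seq, msa_obj, records, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  run <- run_ensemble(query_seq, msa_obj, records, config$query,
                      n_models = config$n_models,
                      msa_mode = config$msa_mode,
                      n_clusters = config$n_clusters,
                      n_extra = config$n_extra,
                      speach_window = config$speach_window,
                      recycles = config$recycles, seed = config$seed,
                      query_subfamily = config$query_subfamily,
                      sigma = config$sigma)
  kept <- discard_unfolded(run, plddt_floor = config$plddt_floor,
                           rg_ceiling = config$rg_ceiling)
  out <- list(models = kept, run = run, discarded = attr(kept, "discarded"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$model_paths <- vapply(kept, function(m) {
      p <- file.path(out_dir, sprintf("model_%03d.pdb", m$model_index))
      write_structure(m$coords, p)
      p
    }, character(1))
    manifest <- list(
      config = { flat <- unclass(config); flat$query <- NULL; flat },
      models = run$manifest,
      discarded = out$discarded)
    out$manifest_path <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(manifest, out$manifest_path, auto_unbox = TRUE,
                         dataframe = "rows", pretty = TRUE)
    write_run_config(config, file.path(out_dir, "run_config.yaml"))
  }
  out
}
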