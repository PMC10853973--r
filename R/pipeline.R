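# Pipeline orchestration: simulate -> ingest -> fit-curves -> model ->
# evaluate-gain, with a validated YAML config, per-stage derived seeds,
# checksum-based resumability and a run log.

.default_config <- function() {
  list(
    seed = 1L,
    n_species = 300L,
    p_dup = 0.05,
    ce = list(anchor_low = c(600, 50), anchor_high = c(2000, 135),
              ceiling = 200, floor = 1,
              grid = list(start = 6.25, stop = 175, step = 6.25)),
    eligibility = list(min_consecutive = 4L, min_points = 5L),
    modeling = list(delta_r2 = 0.01, alpha = 0.05),
    smart_ce = list(mode = "loo", channels = c("byonic", "pglyco_glycan")),
    out_dir = "glycoce_run"
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config file, injects defaults for omitted keys, rejects
#' unknown keys, and schema-checks values (positive ceiling, valid grid
#' bounds, known channels and mode). Call with `path = NULL` for the
#' default configuration.
#'
#' @param path YAML file path, or NULL for defaults.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user)
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config error on ", dQuote("seed"), ": integer required")
  if (cfg$n_species < 1) stop("config error on ", dQuote("n_species"))
  if (cfg$ce$ceiling <= 0)
    stop("config error on ", dQuote("ce.ceiling"), ": must be positive")
  g <- cfg$ce$grid
  if (g$start <= 0 || g$step <= 0 || g$stop < g$start)
    stop("config error on ", dQuote("ce.grid"))
  if (!cfg$smart_ce$mode %in% c("loo", "insample"))
    stop("config error on ", dQuote("smart_ce.mode"))
  bad <- setdiff(cfg$smart_ce$channels, SCORE_CHANNELS)
  if (length(bad))
    stop("config error on ", dQuote("smart_ce.channels"), ": ",
         paste(bad, collapse = ", "))
  # materialize the derived objects once
  cfg$calibration <- ce_calibration(cfg$ce$anchor_low, cfg$ce$anchor_high,
                                    cfg$ce$ceiling, cfg$ce$floor)
  cfg$grid <- sweep_grid(g$start, g$stop, g$step)
  cfg$policy <- eligibility_policy(min_consecutive =
                                     cfg$eligibility$min_consecutive,
                                   min_points = cfg$eligibility$min_points)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  plain <- cfg[setdiff(names(cfg), c("calibration", "grid", "policy"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(plain), tmp)
  unname(tools::md5sum(tmp))
}

files_md5 <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(character(0))
  unname(tools::md5sum(sort(paths)))
}

#' Run the full pipeline
#'
#' Executes simulate, ingest, fit-curves, model and evaluate-gain in
#' order, writing all stage outputs plus `meta.json` under the configured
#' output directory. Stages whose outputs already exist with matching
#' checksums (same config hash) are skipped, so interrupted runs resume
#' and corrupted intermediates are recomputed. Each stage derives its own
#' seed from the root seed so re-running one stage does not perturb the
#' others. Identical config and seed give byte-identical outputs.
#'
#' @param config A `pipeline_config` from [validate_config()].
#' @param quiet Suppress the stage log (written to stderr).
#' @return Invisible list of stage outputs (`score_table`, `optima`,
#'   `model`, `gains`, paths).
#' @export
run_pipeline <- function(config = validate_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message("[glycoCE] ", sprintf(...))
  hash <- config_hash(config)
  meta_path <- file.path(out_dir, "meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  if (!identical(meta$config_hash, unname(hash))) meta <- list()
  meta$config_hash <- unname(hash)
  meta$seed <- config$seed
  meta$stages <- as.list(meta$stages)

  fresh <- function(stage, paths) {
    sums <- files_md5(paths)
    length(sums) == length(paths) &&
      identical(unname(unlist(meta$stages[[stage]])), unname(sums))
  }
  record_stage <- function(stage, paths) {
    meta$stages[[stage]] <<- files_md5(paths)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  }

  # stage 1: simulate
  reports_dir <- file.path(out_dir, "reports")
  grid_files <- file.path(reports_dir,
                          c(sprintf("run_%06.2fpct.tsv",
                                    as.numeric(config$grid)),
                            "manifest.tsv"))
  if (fresh("simulate", grid_files)) {
    log_msg("simulate: outputs up to date, skipping")
  } else {
    log_msg("simulate: %d species at %d sweep settings",
            config$n_species, length(config$grid))
    sim <- synthetic_cohort(config$n_species, seed = config$seed,
                            grid = config$grid, cal = config$calibration,
                            p_dup = config$p_dup)
    emit_reports(sim$records, reports_dir, config$grid)
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record_stage("simulate", grid_files)
  }

  # stage 2: ingest
  manifest <- read_run_manifest(file.path(reports_dir, "manifest.tsv"))
  records <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    read_report(file.path(reports_dir,
                          paste0(manifest$run_id[i], ".tsv")),
                "normalized")
  }))
  table <- aggregate_best_per_run(records)
  log_msg("ingest: %d records -> %d after per-run deduplication",
          nrow(records), nrow(table))

  # stage 3: fit curves
  optima_path <- file.path(out_dir, "optima.tsv")
  curves <- build_curves(table, config$calibration, config$grid)
  if (fresh("fit_curves", optima_path)) {
    log_msg("fit-curves: output up to date, skipping")
    optima <- utils::read.delim(optima_path, stringsAsFactors = FALSE)
  } else {
    optima <- fit_optima(curves, config$policy)
    log_msg("fit-curves: %d curves, %d eligible+converged optima",
            length(curves), nrow(optima))
    utils::write.table(optima, optima_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record_stage("fit_curves", optima_path)
  }

  # stage 4: model
  features <- utils::read.delim(file.path(out_dir, "features.tsv"),
                                stringsAsFactors = FALSE)
  model_path <- file.path(out_dir, "model.json")
  if (fresh("model", model_path)) {
    log_msg("model: output up to date, skipping")
    model <- jsonlite::read_json(model_path, simplifyVector = TRUE)
  } else {
    model <- suppressWarnings(
      model_report(optima, features, config$modeling$delta_r2,
                   config$modeling$alpha))
    jsonlite::write_json(model, model_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = 8, force = TRUE)
    record_stage("model", model_path)
    log_msg("model: %d channels modeled", length(model))
  }

  # stage 5: evaluate gain
  gain_path <- file.path(out_dir, "gain.json")
  if (fresh("gain", gain_path)) {
    log_msg("evaluate-gain: output up to date, skipping")
    gains <- jsonlite::read_json(gain_path, simplifyVector = TRUE)
  } else {
    gains <- lapply(config$smart_ce$channels, function(ch) {
      g <- tryCatch(
        evaluate_gain(curves, optima, features, ch,
                      mode = config$smart_ce$mode,
                      cal = config$calibration),
        error = function(e) NULL)
      if (is.null(g)) return(NULL)
      g$per_species <- NULL
      unclass(g)
    })
    names(gains) <- config$smart_ce$channels
    gains <- gains[!vapply(gains, is.null, logical(1))]
    jsonlite::write_json(gains, gain_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = 8)
    record_stage("gain", gain_path)
    log_msg("evaluate-gain: %d channel(s) evaluated", length(gains))
  }

  invisible(list(out_dir = out_dir, score_table = table, optima = optima,
                 model = model, gains = gains,
                 paths = list(optima = optima_path, model = model_path,
                              gain = gain_path, meta = meta_path)))
}

#' Command-line entry point
#'
#' Thin dispatcher for `Rscript -e 'glycoCE::glycoce_main()' <command>`.
#' Commands: `run-all` (the full pipeline) and `validate` (config check).
#' Exit codes: 0 ok, 2 config error, 3 stage failure.
#'
#' @param args Command-line arguments; defaults to `commandArgs(TRUE)`.
#' @param exit Call `quit()` with the status (set by the CLI wrapper;
#'   leave FALSE when calling from R).
#' @return Exit status, invisibly.
#' @export
glycoce_main <- function(args = commandArgs(trailingOnly = TRUE),
                         exit = FALSE) {
  finish <- function(status) {
    if (exit) quit(status = status, save = "no")
    invisible(status)
  }
  if (!length(args)) {
    message("usage: glycoce_main() <run-all|validate> [--config FILE]")
    return(finish(2))
  }
  cmd <- args[1]
  cfg_path <- if ("--config" %in% args)
    args[which(args == "--config") + 1L] else NULL
  cfg <- tryCatch(validate_config(cfg_path), error = function(e) {
    message("config error: ", conditionMessage(e)); NULL
  })
  if (is.null(cfg)) return(finish(2))
  if (cmd == "validate") {
    message("config OK")
    return(finish(0))
  }
  if (cmd != "run-all") {
    message("unknown command: ", cmd)
    return(finish(2))
  }
  res <- tryCatch(run_pipeline(cfg), error = function(e) {
    message("stage failure: ", conditionMessage(e)); NULL
  })
  finish(if (is.null(res)) 3 else 0)
}
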