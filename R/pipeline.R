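read_table_arg <- function(x, what) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_stage("io", "missing ", what, " file: ", x)
    return(utils::read.csv(x, stringsAsFactors = FALSE))
  }
  stop_stage("io", what, " must be a data.frame or a CSV path")
}

#' Run configuration for the evaluation pipeline
#'
#' @param records records table or CSV path (see [score_records()] for
#'   required columns; also needs `city`, `category`, `project_id`,
#'   `channel`, `production_region`).
#' @param consumption,hazards,channels,region_city_map config tables or
#'   CSV paths (see [weight_config()]).
#' @param variable_spec table or CSV path naming the auxiliary variables
#'   for the factor analysis; defaults to [campaign_variable_spec()]
#'   applied to the records.
#' @param home_region home region label for production-region
#'   classification.
#' @param k,retention,threshold,r,transform see [fadm_params()].
#' @param point_parse see [simple_qualification_degree()].
#' @param scaling `"minmax"` or `"raw"`, see [index_report()].
#' @param seed integer seed (the pipeline itself is deterministic; the
#'   seed is recorded in the manifest and used by `simulate`).
#' @param out optional output directory; when set, [run_pipeline()]
#'   writes scored.csv, indexes.csv, comparison_*.json, famd_summary.json
#'   and manifest.json there.
#' @param permissive passed to [weight_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(records, consumption, hazards, channels,
                       region_city_map = NULL, variable_spec = NULL,
                       home_region = "region_X",
                       k = 100, retention = "cumulative", threshold = 0.8,
                       r = NULL, transform = "increasing",
                       point_parse = "clamped", scaling = "minmax",
                       seed = 1L, out = NULL, permissive = FALSE) {
  structure(list(records = records, consumption = consumption,
                 hazards = hazards, channels = channels,
                 region_city_map = region_city_map,
                 variable_spec = variable_spec, home_region = home_region,
                 k = k, retention = retention, threshold = threshold, r = r,
                 transform = transform, point_parse = point_parse,
                 scaling = scaling, seed = seed, out = out,
                 permissive = permissive),
            class = "run_config")
}

#' Run the full evaluation pipeline
#'
#' Orchestrates scoring, weighting, the mixed-data factor analysis,
#' aggregation and comparison: each record's test result is scored
#' against its limits; the consumption, hazard, channel and region
#' weights are attached; per-sample FADM weights come from the factor
#' analysis of the auxiliary variables; comprehensive degrees (FADM and
#' expert baseline) are aggregated by city and by food category into
#' 0-100 indexes; and each grouping's two index series are compared with
#' a paired t-test. Deterministic given the inputs and seed.
#'
#' @param config a [run_config()].
#' @return object of class `fsindex_result`: list with `scored` (record
#'   table with `Q`, weights, `q_bar_fadm`, `q_bar_expert`), `indexes`
#'   (long data.frame over unit x method for both groupings),
#'   `comparisons` (named list of [paired_t()] results for `city` and
#'   `category`), `famd` (the factor model), `logs`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  logs <- character(0)

  records <- read_table_arg(config$records, "records")
  consumption <- read_table_arg(config$consumption, "consumption table")
  hazards <- read_table_arg(config$hazards, "hazards table")
  channels <- read_table_arg(config$channels, "channels table")
  region_map <- if (is.null(config$region_city_map)) NULL else
    read_table_arg(config$region_city_map, "region map")

  for (nm in c("city", "category", "project_id", "channel",
               "production_region")) {
    if (!nm %in% names(records)) {
      stop_stage("io", "records table lacks column '", nm, "'")
    }
  }

  scored <- score_records(records, point_parse = config$point_parse)
  logs <- c(logs, paste0("qualification: ", scored$log))
  rec <- scored$records

  wcfg <- weight_config(consumption, hazards, channels,
                        region_city_map = region_map,
                        permissive = config$permissive)
  wc <- wcfg$consumption_weights[as.character(rec$category)]
  unknown_cat <- is.na(wc)
  if (any(unknown_cat)) {
    logs <- c(logs, sprintf(
      "weights: excluded %d record(s) with unknown food category",
      sum(unknown_cat)))
    rec <- rec[!unknown_cat, , drop = FALSE]
    wc <- wc[!unknown_cat]
  }
  if (!nrow(rec)) stop_stage("weights", "no scorable records remain")
  rec$w_consumption <- unname(wc)
  rec$w_hazard <- hazard_weight(rec$project_id, wcfg)
  rec$w_channel <- channel_weight(rec$channel, wcfg)
  rec$w_region <- region_weight(rec$production_region, rec$city,
                                config$home_region, wcfg)

  spec <- if (is.null(config$variable_spec)) campaign_variable_spec(rec) else
    read_table_arg(config$variable_spec, "variable spec")
  if (!nrow(spec)) stop_stage("famd", "variable spec names no variables")
  params <- fadm_params(k = config$k, retention = config$retention,
                        threshold = config$threshold, r = config$r,
                        transform = config$transform)
  design <- encode_mixed(rec, spec)
  logs <- c(logs, paste0("famd: ", design$log))
  model <- famd_decompose(design, params)
  rec$w_fadm <- fadm_weight(model, params)

  rec$q_bar_fadm <- comprehensive_degree(rec$Q, rec$w_consumption,
                                         rec$w_hazard, rec$w_channel,
                                         rec$w_region, rec$w_fadm)
  rec$q_bar_expert <- expert_baseline_degree(rec$Q, rec$w_consumption,
                                             rec$w_hazard, rec$w_channel,
                                             rec$w_region)

  reports <- list()
  comparisons <- list()
  for (grouping in c("city", "category")) {
    rep_fadm <- index_report(rec$q_bar_fadm, rec[[grouping]],
                             method = "fadm", scaling = config$scaling)
    rep_exp <- index_report(rec$q_bar_expert, rec[[grouping]],
                            method = "expert", scaling = config$scaling)
    rep_fadm$grouping <- grouping
    rep_exp$grouping <- grouping
    reports[[grouping]] <- rbind(rep_fadm, rep_exp)
    stopifnot(identical(rep_fadm$unit, rep_exp$unit))
    comparisons[[grouping]] <- paired_t(rep_fadm$index, rep_exp$index)
  }
  indexes <- do.call(rbind, reports)
  row.names(indexes) <- NULL

  result <- structure(list(scored = rec, indexes = indexes,
                           comparisons = comparisons, famd = model,
                           excluded = scored$excluded, logs = logs,
                           config = config),
                      class = "fsindex_result")
  if (!is.null(config$out)) write_result(result, config$out)
  result
}

comparison_as_list <- function(ct) {
  list(t = ct$t_stat, p = ct$p_value, n = ct$n,
       mean_diff = ct$mean_diff, sd_diff = ct$sd_diff,
       verdict = if (ct$significant) "significant" else "not significant",
       alpha = ct$alpha)
}

#' Write pipeline outputs to a run directory
#'
#' Emits `scored.csv`, `indexes.csv`, one `comparison_<grouping>.json`
#' per grouping, `famd_summary.json`, and a `manifest.json` recording the
#' parameters, package version and input checksums. All outputs are
#' deterministic for a given input and configuration.
#'
#' @param result a [run_pipeline()] result.
#' @param out output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_result <- function(result, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$scored, file.path(out, "scored.csv"),
                   row.names = FALSE)
  utils::write.csv(result$indexes, file.path(out, "indexes.csv"),
                   row.names = FALSE)
  for (grouping in names(result$comparisons)) {
    jsonlite::write_json(comparison_as_list(result$comparisons[[grouping]]),
                         file.path(out, sprintf("comparison_%s.json", grouping)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  model <- result$famd
  jsonlite::write_json(list(
    lambda1_quant = model$lambda1_quant,
    lambda1_qual = model$lambda1_qual,
    n_factors = length(model$d),
    n_retained = model$n_retained,
    variance_contributions = model$variance_contributions),
    file.path(out, "famd_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg <- result$config
  checksum <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      unname(tools::md5sum(x))
    } else {
      "in-memory"
    }
  }
  manifest <- list(
    package = "fsindex",
    version = as.character(utils::packageVersion("fsindex")),
    parameters = list(k = cfg$k, retention = cfg$retention,
                      threshold = cfg$threshold, transform = cfg$transform,
                      point_parse = cfg$point_parse, scaling = cfg$scaling,
                      home_region = cfg$home_region, seed = cfg$seed),
    inputs = list(records = checksum(cfg$records),
                  consumption = checksum(cfg$consumption),
                  hazards = checksum(cfg$hazards),
                  channels = checksum(cfg$channels)),
    n_scored = nrow(result$scored),
    n_excluded = nrow(result$excluded),
    logs = result$logs)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.fsindex_result <- function(x, ...) {
  cat("Food safety evaluation result\n")
  cat(sprintf("  scored samples: %d (excluded %d)\n",
              nrow(x$scored), nrow(x$excluded)))
  for (grouping in names(x$comparisons)) {
    ct <- x$comparisons[[grouping]]
    cat(sprintf("  %s: %d units; FADM vs expert paired t = %.3f, p = %.3f\n",
                grouping, ct$n, ct$t_stat, ct$p_value))
  }
  invisible(x)
}

#' Write a generated campaign to a directory of CSV files
#'
#' @param campaign a [generate_campaign()] result.
#' @param out output directory.
#' @return `out`, invisibly.
#' @export
write_campaign <- function(campaign, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- c(records = "records.csv", consumption = "consumption.csv",
             hazards = "hazards.csv", channels = "channels.csv",
             projects = "projects.csv", region_city_map = "region_map.csv")
  for (nm in names(files)) {
    utils::write.csv(campaign[[nm]], file.path(out, files[[nm]]),
                     row.names = FALSE)
  }
  invisible(out)
}

#' Locate the bundled example campaign
#'
#' A small (n = 200) synthetic campaign ships with the package so the
#' pipeline can be exercised without generating data.
#'
#' @return path to the fixture directory.
#' @export
example_campaign_dir <- function() {
  system.file("extdata", "campaign200", package = "fsindex", mustWork = TRUE)
}
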