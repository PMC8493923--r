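#' Pipeline run configuration
#'
#' Collects the paths, selections and thresholds shared by the pipeline
#' commands [cmd_generate()], [cmd_score()] and [cmd_compare()]. These
#' functions are the file-in/file-out surface of the package: each reads
#' and writes CSV and is deterministic given the seed and inputs.
#'
#' @param out_dir output directory (created if absent).
#' @param input named character vector of survey CSV paths per tier; filled
#'   in by [cmd_generate()] when it runs first.
#' @param registry an [item_registry].
#' @param frameworks,methods,tiers subsets to run.
#' @param seed integer seed for generation.
#' @param universal_threshold,rare_threshold,wide_threshold diagnostic
#'   thresholds (defaults 0.97, 0.40, 0.90).
#' @param config a [synthetic_config()] for generation; defaults to
#'   [preset_observed_regime()] at `seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("cbready_run_"),
                       input = NULL,
                       registry = builtin_item_registry(),
                       frameworks = c("SARA", "DHS", "WHO_standards"),
                       methods = c("simple", "weighted", "pca"),
                       tiers = c("hospital", "health_centre_clinic"),
                       seed = 1L,
                       universal_threshold = 0.97,
                       rare_threshold = 0.40,
                       wide_threshold = 0.90,
                       config = NULL) {
  thr <- c(universal_threshold, rare_threshold, wide_threshold)
  if (any(thr < 0 | thr > 1)) {
    stop_cbready("thresholds must lie in [0, 1]", "cbready_config_error")
  }
  frameworks <- match.arg(frameworks, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  tiers <- match.arg(tiers, several.ok = TRUE)
  structure(list(
    out_dir = out_dir, input = input, registry = registry,
    frameworks = frameworks, methods = methods, tiers = tiers,
    seed = as.integer(seed),
    universal_threshold = universal_threshold,
    rare_threshold = rare_threshold,
    wide_threshold = wide_threshold,
    config = config %||% preset_observed_regime(seed)
  ), class = "run_config")
}

ensure_out_dir <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  cfg$out_dir
}

#' Generate synthetic survey files
#'
#' Writes one survey CSV per requested tier plus a metadata JSON recording
#' the seed and configuration.
#'
#' @param cfg a [run_config()].
#' @return the updated `run_config` (with `input` pointing at the written
#'   files), invisibly.
#' @export
cmd_generate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ensure_out_dir(cfg)
  cohort <- generate_cohort(cfg$config, cfg$registry)
  paths <- character(0)
  for (tr in cfg$tiers) {
    sub <- cohort[cohort$tier == tr, , drop = FALSE]
    class(sub) <- c("facility_survey", "data.frame")
    p <- file.path(cfg$out_dir, sprintf("survey_%s.csv", tr))
    write_facility_survey(sub, p)
    paths[tr] <- p
  }
  meta <- list(seed = cfg$seed, tiers = cfg$tiers,
               n = as.list(table(cohort$tier)),
               generated = unname(paths))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "generate_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_synthetic_config(cfg$config, file.path(cfg$out_dir, "synthetic_config.json"))
  cfg$input <- paths
  invisible(cfg)
}

read_inputs <- function(cfg) {
  if (is.null(cfg$input)) {
    stop_cbready("no input surveys; run cmd_generate or set cfg$input",
                 "cbready_config_error")
  }
  lapply(cfg$input, read_facility_survey, registry = cfg$registry)
}

#' Score all requested indices and write a long-format scores CSV
#'
#' One row per facility x framework x method with the composite score,
#' applicable-item count and any domain scores.
#'
#' @param cfg a [run_config()] with `input` set.
#' @return list of `readiness_battery` objects per tier, invisibly; the CSV
#'   is written to `scores.csv` in the output directory.
#' @export
cmd_score <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ensure_out_dir(cfg)
  surveys <- read_inputs(cfg)
  rows <- list()
  batteries <- list()
  for (tr in names(surveys)) {
    if (nrow(surveys[[tr]]) == 0) {
      stop_cbready(sprintf("empty survey for tier %s", tr),
                   "cbready_format_error")
    }
    bat <- readiness_battery(surveys[[tr]], cfg$registry,
                             frameworks = cfg$frameworks,
                             methods = cfg$methods)
    batteries[[tr]] <- bat
    for (nm in names(bat)) {
      sc <- bat[[nm]]$scores
      base <- data.frame(
        facility_id = sc$facility_id, tier = tr,
        framework = bat[[nm]]$framework, method = bat[[nm]]$method,
        score = sc$score, n_applicable = sc$n_applicable,
        stringsAsFactors = FALSE
      )
      for (dc in grep("^domain_", names(sc), value = TRUE)) base[[dc]] <- sc[[dc]]
      rows[[length(rows) + 1]] <- base
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA_real_
    r[, all_cols]
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(cfg$out_dir, "scores.csv"), row.names = FALSE)
  invisible(batteries)
}

#' Run the comparison battery and write report files
#'
#' Writes `comparison_<tier>.csv` (one row per index, comparison-table
#' column order), `agreement_<tier>.csv` (pairwise Bland-Altman set) and,
#' when `plots = TRUE`, one difference-vs-mean plot file per index pair.
#'
#' @param cfg a [run_config()] with `input` set.
#' @param plots write PDF agreement plots (default `FALSE`).
#' @return named list of [compare_all()] reports per tier, invisibly.
#' @export
cmd_compare <- function(cfg, plots = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  ensure_out_dir(cfg)
  surveys <- read_inputs(cfg)
  reports <- list()
  for (tr in names(surveys)) {
    bat <- readiness_battery(surveys[[tr]], cfg$registry,
                             frameworks = cfg$frameworks,
                             methods = cfg$methods)
    rep <- compare_all(bat, surveys[[tr]])
    reports[[tr]] <- rep
    utils::write.csv(rep$table,
                     file.path(cfg$out_dir, sprintf("comparison_%s.csv", tr)),
                     row.names = FALSE)
    if (!is.null(rep$agreement)) {
      utils::write.csv(rep$agreement,
                       file.path(cfg$out_dir, sprintf("agreement_%s.csv", tr)),
                       row.names = FALSE)
    }
    if (plots && length(bat) >= 2) {
      pdf_path <- file.path(cfg$out_dir, sprintf("bland_altman_%s.pdf", tr))
      grDevices::pdf(pdf_path, width = 6, height = 5)
      nm <- names(bat)
      for (i in seq_len(length(bat) - 1)) {
        for (j in (i + 1):length(bat)) {
          plot(bland_altman(bat[[i]], bat[[j]]))
        }
      }
      grDevices::dev.off()
    }
  }
  invisible(reports)
}
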