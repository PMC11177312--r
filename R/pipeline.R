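config_defaults <- function() {
  list(
    system = "DUCG",
    seed = 1L,
    n_reads = 10000L,
    construct = list(
      handle5 = "ACGACTCTAGCA",
      template_len = 6L,
      loop = "TTGGTGAGTCCGTAACCAAC"
    ),
    model = list(
      template_dist = NULL,
      propensity = NULL,
      p_ext_initial = 0.5,
      p_ext_after_match = 0.7,
      p_ext_after_mismatch = 0.12,
      post_mismatch_error_boost = 3,
      seq_error_rate = 0.001,
      rt_error_rate = 0
    ),
    filters = list(
      max_anchor_mismatches = 1L,
      min_quality = 20L
    ),
    stats = list(
      m_positions = 1:4,
      stalling_position = 1L
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0) {
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' A single flat YAML file governs every pipeline stage: the chemistry
#' system, the construct layout, the copying-model parameters used by the
#' simulator, the read filters and the statistic windows. Unknown keys
#' are rejected, and the resolved configuration is serialized into each
#' output directory for provenance.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_config(config_defaults(), config)
  cfg$system_obj <- chemistry_system(cfg$system)
  cfg$spec <- construct_spec(cfg$construct$handle5,
                             cfg$construct$template_len,
                             cfg$construct$loop)
  model_args <- cfg$model
  if (!is.null(model_args$propensity)) {
    model_args$propensity <- do.call(rbind, model_args$propensity)
  }
  cfg$model_obj <- do.call(copying_model, c(
    list(system = cfg$system_obj, seed = cfg$seed), model_args
  ))
  structure(cfg, class = "pipeline_config")
}

write_config <- function(cfg, out_dir) {
  keep <- setdiff(names(cfg), c("system_obj", "spec", "model_obj"))
  plain <- unclass(cfg)[keep]
  yaml::write_yaml(plain, file.path(out_dir, "config.yaml"))
}

#' Run the simulate stage
#'
#' Simulates a sequencing library under the configured copying model and
#' writes `reads.fastq`, `truth.tsv` and the resolved `config.yaml` into
#' `out_dir`.
#'
#' @param config A [pipeline_config()], path or list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the truth tibble.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_library(
    cfg$model_obj, cfg$spec, cfg$n_reads,
    fastq = file.path(out_dir, "reads.fastq"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_config(cfg, out_dir)
  message(sprintf("simulate: wrote %d reads (%s system) to %s",
                  nrow(sim), cfg$system, out_dir))
  invisible(sim)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analyze stage
#'
#' Processes a FASTQ library through region extraction, filtering and
#' classification, computes the full [fidelity_report()], and writes one
#' TSV per table plus `report.json`, `reads.tsv` (per-read results) and
#' `summary.json` (read accounting) into `out_dir`.
#'
#' @inheritParams run_simulate
#' @param fastq Path to the FASTQ file to analyze.
#' @return The `fidelity_report`, invisibly.
#' @export
run_analyze <- function(config, fastq, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  processed <- process_library(
    fastq, cfg$spec, cfg$system_obj,
    max_anchor_mismatches = cfg$filters$max_anchor_mismatches,
    min_quality = cfg$filters$min_quality
  )
  summary <- processing_summary(processed)
  message(sprintf("analyze: %d reads in, %d pass",
                  sum(summary$n_reads),
                  sum(summary$n_reads[summary$status == "pass"])))
  report <- fidelity_report(
    processed, cfg$system_obj,
    m_positions = cfg$stats$m_positions,
    stalling_position = cfg$stats$stalling_position
  )
  write_tsv(processed, file.path(out_dir, "reads.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", pretty = TRUE)
  for (tab in c("position_frequencies", "product_base_distribution",
                "bridged_distribution", "mismatch_composition",
                "tp_pair_distribution", "per_mismatch_stalling")) {
    if (!is.null(report[[tab]])) {
      write_tsv(report[[tab]], file.path(out_dir, paste0(tab, ".tsv")))
    }
  }
  write_fidelity_report(report, file.path(out_dir, "report.json"))
  write_config(cfg, out_dir)
  invisible(report)
}

#' Serialize and restore a fidelity report
#'
#' @param report A [fidelity_report()].
#' @param path JSON file path.
#' @return `read_fidelity_report()` returns the restored
#'   `fidelity_report`.
#' @export
write_fidelity_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fidelity_report
#' @export
read_fidelity_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tables <- c("position_frequencies", "product_base_distribution",
              "bridged_distribution", "mismatch_composition",
              "tp_pair_distribution", "extension_past_pair",
              "per_mismatch_stalling", "post_mismatch_error")
  for (tab in tables) {
    if (!is.null(raw[[tab]])) raw[[tab]] <- tibble::as_tibble(raw[[tab]])
  }
  raw$m_positions <- as.integer(raw$m_positions)
  structure(raw, class = "fidelity_report")
}

#' Run the compare stage
#'
#' Computes [system_ratio()] tables between two analyzed libraries
#' (numerator over denominator, typically DUCG over AUCG) and writes one
#' TSV per ratio table into `out_dir`.
#'
#' @param report_num,report_den `fidelity_report` objects or paths to
#'   `report.json` files from [run_analyze()].
#' @param out_dir Output directory.
#' @return The `system_ratio` object, invisibly.
#' @export
run_compare <- function(report_num, report_den, out_dir) {
  if (is.character(report_num)) report_num <- read_fidelity_report(report_num)
  if (is.character(report_den)) report_den <- read_fidelity_report(report_den)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ratios <- system_ratio(report_num, report_den)
  for (tab in c("product_base", "tp_pair", "bridged")) {
    if (!is.null(ratios[[tab]])) {
      write_tsv(ratios[[tab]], file.path(out_dir, paste0("ratio_", tab, ".tsv")))
    }
  }
  message(sprintf("compare: %s / %s ratio tables written to %s",
                  ratios$system_num, ratios$system_den, out_dir))
  invisible(ratios)
}

#' Run a kinetics fit on a tabular input
#'
#' Reads a TSV and dispatches to the requested fitter:
#' `"first_order"` expects columns `time`, `fraction`;
#' `"michaelis_menten"` expects `concentration`, `kobs`. The fit report
#' (tidy coefficients plus one-row summary) is written as JSON.
#'
#' @param fit `"first_order"` or `"michaelis_menten"`.
#' @param table Path to the input TSV.
#' @param out Path for the JSON fit report (optional).
#' @return The fit object, invisibly.
#' @export
run_kinetics <- function(fit = c("first_order", "michaelis_menten"),
                         table, out = NULL) {
  fit <- match.arg(fit)
  data <- utils::read.delim(table)
  obj <- switch(fit,
                first_order = fit_first_order(data),
                michaelis_menten = fit_michaelis_menten(data))
  if (!is.null(out)) {
    jsonlite::write_json(
      list(model = fit, coefficients = tidy(obj), summary = glance(obj)),
      out, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(obj)
}
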