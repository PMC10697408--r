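PIPELINE_KEYS <- c("table", "taxonomy", "metadata", "output_dir", "threshold",
                   "source_day", "top_n", "rarefaction", "provenance")
RAREFACTION_KEYS <- c("max_depth", "step", "iterations", "seed", "metric", "base")

suggest_key <- function(key, known) {
  hit <- agrep(key, known, max.distance = 0.3, value = TRUE)
  if (length(hit)) sprintf(" (did you mean '%s'?)", hit[[1L]]) else ""
}

check_known_keys <- function(cfg, known, where) {
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    fmt_stop("unknown %s key '%s'%s", where, unknown[[1L]],
             suggest_key(unknown[[1L]], known))
  }
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, applies defaults, and type/range-checks every
#' field. Unknown keys are rejected with a nearest-match suggestion so a
#' typo cannot silently fall back to a default.
#'
#' Recognised keys: `table`, `taxonomy`, `metadata` (required input paths),
#' `output_dir`, `threshold` (default 0.01), `source_day` (default 14),
#' `top_n` (default 15), `rarefaction` (`max_depth` 10000, `step` 500,
#' `iterations` 10, `seed` 1, `metric` "shannon", `base` 2), and a
#' free-form `provenance` note block (e.g. upstream denoiser truncation
#' lengths).
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) fmt_stop("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) fmt_stop("config must be a YAML mapping")
  check_known_keys(cfg, PIPELINE_KEYS, "config")
  for (k in c("table", "taxonomy", "metadata")) {
    if (is.null(cfg[[k]])) fmt_stop("config missing required input path '%s'", k)
  }
  rar <- cfg$rarefaction %||% list()
  check_known_keys(rar, RAREFACTION_KEYS, "rarefaction")
  config <- list(
    table = as.character(cfg$table),
    taxonomy = as.character(cfg$taxonomy),
    metadata = as.character(cfg$metadata),
    output_dir = as.character(cfg$output_dir %||% "nukasv_out"),
    threshold = as.numeric(cfg$threshold %||% 0.01),
    source_day = as.integer(cfg$source_day %||% 14L),
    top_n = as.integer(cfg$top_n %||% 15L),
    rarefaction = list(
      max_depth = as.integer(rar$max_depth %||% 10000L),
      step = as.integer(rar$step %||% 500L),
      iterations = as.integer(rar$iterations %||% 10L),
      seed = as.integer(rar$seed %||% 1L),
      metric = as.character(rar$metric %||% "shannon"),
      base = as.numeric(rar$base %||% 2)
    ),
    provenance = cfg$provenance
  )
  if (is.na(config$threshold) || config$threshold <= 0 || config$threshold >= 1) {
    fmt_stop("config field 'threshold' must lie in (0, 1); got %s",
             format(config$threshold))
  }
  if (is.na(config$source_day) || config$source_day < 0) {
    fmt_stop("config field 'source_day' must be a non-negative integer")
  }
  if (is.na(config$top_n) || config$top_n < 1) {
    fmt_stop("config field 'top_n' must be >= 1")
  }
  if (!config$rarefaction$metric %in% c("shannon", "observed_features")) {
    fmt_stop("config field 'rarefaction.metric' must be 'shannon' or 'observed_features'")
  }
  for (k in c("max_depth", "step", "iterations", "seed")) {
    if (is.na(config$rarefaction[[k]]) || config$rarefaction[[k]] < 1) {
      fmt_stop("config field 'rarefaction.%s' must be a positive integer", k)
    }
  }
  class(config) <- "pipeline_config"
  config
}

# short stable hash of the config for output provenance headers
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

pkg_version <- function() {
  as.character(utils::packageVersion("nukasv"))
}

write_report_tsv <- function(df, path, header_lines) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full shared-ASV pipeline
#'
#' Binds every stage end-to-end: read and align the three inputs, remove
#' organelle/unassigned ASVs, summarise genus-level composition (top-N +
#' remainder), compute per-sample alpha diversity and a rarefaction curve,
#' and compute the shared-ASV timecourse, taxonomic breakdown and
#' persistence summary. All tables are written as TSV under
#' `config$output_dir` with a provenance header (tool version + config
#' hash, no timestamps, so identical configs and inputs give byte-identical
#' outputs). Any stage failure aborts with a stage-labelled message and
#' removes partial outputs.
#'
#' @param config A `pipeline_config` from [validate_config()], or a path to
#'   a YAML config.
#' @return Invisibly, a `pipeline_bundle` list with elements `dataset`,
#'   `filter_report`, `composition`, `alpha`, `rarefaction`, `timecourse`,
#'   `breakdown`, `persistence`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  written <- character()
  cleanup <- function() unlink(written)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      fmt_stop("[%s] %s", name, conditionMessage(e))
    })
  }
  banner <- function(...) message("== ", sprintf(...))
  hash <- config_hash(config)
  hdr <- c(
    sprintf("nukasv %s", pkg_version()),
    sprintf("config_hash=%s", hash),
    if (!is.null(config$provenance)) {
      sprintf("provenance: %s", paste(deparse(config$provenance), collapse = " "))
    }
  )
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_report_tsv(df, p, hdr)
    written <<- c(written, p)
    p
  }

  banner("input: reading feature table, taxonomy, metadata")
  table <- stage("feature_table", read_feature_table(config$table))
  tax <- stage("taxonomy", read_taxonomy(config$taxonomy))
  meta <- stage("metadata", read_metadata(config$metadata))
  dataset <- stage("align", align_dataset(table, meta, tax))
  banner("aligned: %d features x %d samples", nrow(dataset$table), ncol(dataset$table))

  banner("filter: removing chloroplast/mitochondria/unassigned ASVs")
  filt <- stage("filter", filter_organelle_unassigned(dataset$table, tax))
  if (is.null(filt$table)) fmt_stop("[filter] no features retained")
  banner("filter: removed %d feature(s), retained %d",
         nrow(filt$report$removed), nrow(filt$table))
  emit(filt$report$removed, "filter_report_features.tsv")
  emit(data.frame(
    `sample-id` = names(filt$report$reads_removed),
    reads_removed = as.integer(filt$report$reads_removed),
    reads_retained = as.integer(filt$report$reads_retained),
    check.names = FALSE
  ), "filter_report_reads.tsv")

  rel <- stage("relative", to_relative(filt$table))

  banner("composition: genus collapse + top-%d summary", config$top_n)
  comp <- stage("composition", {
    top_n_summary(collapse_genus(rel, tax), n = config$top_n)
  })
  comp_df <- data.frame(genus = rownames(comp),
                        as.data.frame(unclass_matrix(comp), check.names = FALSE),
                        check.names = FALSE)
  emit(comp_df, "genus_composition.tsv")

  banner("diversity: alpha diversity and rarefaction curve")
  alpha <- stage("diversity", alpha_diversity(filt$table, base = config$rarefaction$base))
  emit(alpha, "alpha_diversity.tsv")
  curve <- stage("rarefaction", rarefaction_curve(
    filt$table, metric = config$rarefaction$metric,
    max_depth = config$rarefaction$max_depth, step = config$rarefaction$step,
    iterations = config$rarefaction$iterations, seed = config$rarefaction$seed,
    base = config$rarefaction$base
  ))
  emit(as.data.frame(curve), "rarefaction_curve.tsv")

  banner("shared-asv: timecourse at threshold %.4g, source day %d",
         config$threshold, config$source_day)
  tc <- stage("shared_asv", shared_timecourse(
    rel, dataset$meta, threshold = config$threshold,
    source_day = config$source_day
  ))
  banner("shared-asv: %d pair(s), %d unpaired skin sample(s)",
         sum(!is.na(tc$source_sample)), sum(is.na(tc$source_sample)))
  emit(data.frame(
    subject = tc$subject, day = tc$day, timepoint = tc$timepoint,
    phase = tc$phase, source_sample = tc$source_sample,
    sink_sample = tc$sink_sample, threshold = tc$threshold,
    n_shared = tc$n_shared,
    shared_proportion_percent = tc$shared_proportion_percent,
    stringsAsFactors = FALSE
  ), "shared_timecourse.tsv")

  breakdown <- stage("breakdown", shared_taxa_breakdown(tc, rel, tax))
  emit(breakdown, "shared_breakdown.tsv")
  persistence <- stage("persistence", persistence_summary(tc))
  emit(persistence, "persistence.tsv")

  cfg_path <- file.path(out_dir, "config_echo.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, null = "null")
  written <- c(written, cfg_path)
  banner("done: %d output file(s) in %s", length(written), out_dir)

  invisible(structure(
    list(
      dataset = dataset, filter_report = filt$report, composition = comp,
      alpha = alpha, rarefaction = curve, timecourse = tc,
      breakdown = breakdown, persistence = persistence, paths = written
    ),
    class = "pipeline_bundle"
  ))
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf(
    "<pipeline_bundle> %d output file(s); %d pair rows; %d feature(s) filtered\n",
    length(x$paths), nrow(x$timecourse), nrow(x$filter_report$removed)
  ))
  invisible(x)
}
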