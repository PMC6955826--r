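#' Write / read a time-course set as delimited text
#'
#' Values go to a tab-separated file (first row = RSN labels, one row per
#' time point, full precision); sampling interval, neuronal flags, group,
#' subject and seed go to a YAML sidecar at `<path>.meta.yaml`.
#'
#' @param tcs A [timecourse_set()].
#' @param path Output file path for the values table.
#' @return `write_timecourses()` returns `path` invisibly;
#'   `read_timecourses()` returns a [timecourse_set()].
#' @export
write_timecourses <- function(tcs, path) {
  if (!inherits(tcs, "timecourse_set")) {
    abort("`tcs` must be a timecourse_set", class = "fnconn_invalid_argument")
  }
  df <- as.data.frame(tcs$values)
  write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(sampling_interval = tcs$sampling_interval,
               neuronal = as.list(tcs$neuronal),
               group = tcs$group, subject = tcs$subject,
               seed = tcs$seed)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_timecourses
#' @param path File to read.
#' @param sampling_interval,neuronal Used when no sidecar metadata file is
#'   present.
#' @export
read_timecourses <- function(path, sampling_interval = 2, neuronal = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("time-course file not found: %s", path),
          class = "fnconn_file_not_found")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    abort("duplicate component labels in time-course file",
          class = "fnconn_schema_error")
  }
  df <- read.delim(path, check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    abort("time-course file has non-numeric or ragged content",
          class = "fnconn_schema_error")
  }
  group <- NA_character_; subject <- NA_character_; seed <- NA_integer_
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    sampling_interval <- meta$sampling_interval
    neuronal <- unlist(meta$neuronal)[header]
    group <- meta$group %||% NA_character_
    subject <- meta$subject %||% NA_character_
    seed <- meta$seed %||% NA_integer_
  }
  timecourse_set(as.matrix(df), sampling_interval = sampling_interval,
                 neuronal = neuronal, group = group, subject = subject,
                 seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tidy table as tab-separated text
#'
#' @param records Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the cohort to simulate
#' (or directories of time-course files to read), the lag window, the
#' edge-retention rule, and the group-comparison settings. Unknown fields
#' are rejected so typos fail loudly.
#'
#' @param cohort A [cohort_spec()] to simulate, or `NULL` when reading
#'   `input_dir`.
#' @param input_dir Directory of per-subject time-course files (written by
#'   [write_timecourses()]), organised as `<group>/<subject>.tsv`; ignored
#'   when `cohort` is given.
#' @param out_dir Output directory for result tables.
#' @param max_lag Lag window half-width in samples.
#' @param edge_rule An [edge_rule_surrogate()] or [edge_rule_fixed()].
#' @param pairs Group pairs for [compare_groups()].
#' @param alpha,family Significance settings for [compare_groups()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL, out_dir = NULL,
                            max_lag = 3, edge_rule = edge_rule_surrogate(),
                            pairs = default_group_pairs(), alpha = 0.05,
                            family = 10) {
  if (is.null(cohort) && is.null(input_dir)) {
    abort("either `cohort` or `input_dir` must be given",
          class = "fnconn_invalid_argument")
  }
  structure(
    list(cohort = cohort, input_dir = input_dir, out_dir = out_dir,
         max_lag = max_lag, edge_rule = edge_rule, pairs = pairs,
         alpha = alpha, family = family),
    class = "pipeline_config"
  )
}

read_cohort_dir <- function(input_dir) {
  if (!dir.exists(input_dir)) {
    abort(sprintf("input directory not found: %s", input_dir),
          class = "fnconn_file_not_found")
  }
  groups <- list.dirs(input_dir, recursive = FALSE)
  if (length(groups) == 0L) {
    abort(sprintf("no group subdirectories under %s", input_dir),
          class = "fnconn_file_not_found")
  }
  cohort <- lapply(groups, function(g) {
    files <- list.files(g, pattern = "\\.tsv$", full.names = TRUE)
    lapply(files, read_timecourses)
  })
  names(cohort) <- basename(groups)
  labels <- lapply(unlist(cohort, recursive = FALSE),
                   function(tcs) colnames(tcs$values))
  if (length(unique(labels)) > 1L) {
    abort("inconsistent RSN label sets across subjects",
          class = "fnconn_schema_error")
  }
  cohort
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, computes the FNC matrix and the five
#' nodal network measures plus their network averages for every subject,
#' compares the groups with Welch t tests, and optionally writes the tidy
#' metric and comparison tables. The run is a pure function of the
#' configuration: rerunning the same config reproduces the outputs
#' byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `fnc_run_report` with elements `metrics` (long
#'   tibble), `comparison` ([compare_groups()] table), `paths` (written
#'   files), `config`, and `session` (package version and timestamp-free
#'   run parameters).
#' @export
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_subjects = c(HC = 3, MCS = 3, UWS = 3),
#'                     n_timepoints = 64, seed = 1)
#' cfg <- pipeline_config(cohort = spec,
#'                        edge_rule = edge_rule_fixed(0.4),
#'                        pairs = c("HC-UWS"))
#' report <- run_pipeline(cfg)
#' report$comparison
#' }
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config",
          class = "fnconn_invalid_argument")
  }
  cohort <- if (!is.null(config$cohort)) {
    generate_cohort(config$cohort)
  } else {
    read_cohort_dir(config$input_dir)
  }
  metrics <- cohort_metrics(cohort, max_lag = config$max_lag,
                            edge_rule = config$edge_rule)
  pairs <- intersect_pairs(config$pairs, names(cohort))
  comparison <- compare_groups(metrics, pairs = pairs,
                               alpha = config$alpha,
                               family = config$family)
  paths <- character()
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                                recursive = TRUE)
    paths <- c(
      metrics = write_table(metrics,
                            file.path(config$out_dir, "metrics.tsv")),
      comparison = write_table(comparison,
                               file.path(config$out_dir, "comparison.tsv"))
    )
  }
  structure(
    list(metrics = metrics, comparison = comparison, paths = paths,
         config = config,
         session = list(package_version =
                          as.character(utils::packageVersion("fnconn")),
                        seed = if (!is.null(config$cohort))
                          config$cohort$seed else NA_integer_,
                        max_lag = config$max_lag,
                        edge_rule = config$edge_rule)),
    class = "fnc_run_report"
  )
}

# keep only pairs whose members exist in the cohort
intersect_pairs <- function(pairs, groups) {
  ok <- vapply(pairs, function(p) {
    tryCatch({ resolve_pair_members(p, groups); TRUE },
             error = function(e) FALSE)
  }, logical(1))
  if (!any(ok)) {
    abort("no requested group pair is present in the cohort",
          class = "fnconn_invalid_argument")
  }
  pairs[ok]
}

#' @export
print.fnc_run_report <- function(x, ...) {
  cat(sprintf(
    "<fnc_run_report> %d subjects, %d comparisons (%d significant)\n",
    length(unique(x$metrics$subject)), nrow(x$comparison),
    sum(x$comparison$significant)))
  invisible(x)
}
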