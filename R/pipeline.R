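#' Run the full zone-specificity pipeline
#'
#' Executes the stages in their analysis order — low-expression filtering on
#' raw-library CPM, TMM normalization of the kept transcripts, one-vs-rest
#' negative-binomial exact tests, and composite membership coding — and
#' optionally writes all artifacts (results TSV, factors TSV, category TSV,
#' QC report TSV, run manifest JSON) to a directory. The run is a pure
#' function of the counts, the configuration and the seed: identical inputs
#' give byte-identical outputs.
#'
#' @param counts A [zone_count_table()], or a path to a counts file
#'   readable by [read_counts()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param format Counts file format when `counts` is a path.
#' @param verbose Print one log line per stage.
#' @return An object of class `zone_pipeline_result`: list with `table`,
#'   `kept_ids`, `norm`, `records`, `codes`, `summary`, `qc`, `manifest`.
#' @examples
#' sim <- simulate_zone_counts(simulation_config(n_transcripts = 300, seed = 7))
#' res <- run_pipeline(sim$table, run_config(seed = 7))
#' res$manifest$counts
#' @export
run_pipeline <- function(counts, config = run_config(), out_dir = NULL,
                         format = c("tsv", "mtx"), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  format <- match.arg(format)
  say <- function(...) if (verbose) message(...)
  set.seed(config$seed)

  input_path <- NULL
  if (is.character(counts)) {
    input_path <- counts
    counts <- tryCatch(read_counts(counts, format = format),
                       error = function(e) stop("stage 'read' failed: ",
                                                conditionMessage(e)))
  }
  if (!inherits(counts, "zone_count_table"))
    stop("stage 'read' failed: counts must be a zone_count_table or a file path")
  table <- counts
  detected <- nrow(table$counts)
  say("read: ", detected, " transcripts x ", ncol(table$counts), " zones")

  raw_cpm <- compute_cpm(table, table$library_sizes)
  keep <- tryCatch(filter_low_expression(raw_cpm, config$cpm_cutoff),
                   error = function(e) stop("stage 'filter' failed: ",
                                            conditionMessage(e)))
  if (length(keep) == 0)
    stop("stage 'filter' failed: no transcript reaches ", config$cpm_cutoff,
         " CPM in any zone")
  kept_table <- subset_transcripts(table, keep)
  say("filter: kept ", length(keep), " of ", detected,
      " transcripts at CPM >= ", config$cpm_cutoff)

  norm <- tryCatch(normalize_zones(kept_table, trim_m = config$trim_m,
                                   trim_a = config$trim_a),
                   error = function(e) stop("stage 'normalize' failed: ",
                                            conditionMessage(e)))
  say("normalize: TMM factors ",
      paste(round(norm$normalization_factors, 3), collapse = ", "))

  records <- tryCatch(one_vs_rest_tests(kept_table, norm, config),
                      error = function(e) stop("stage 'test' failed: ",
                                               conditionMessage(e)))
  say("test: ", nrow(records), " (transcript, zone) exact tests")

  codes <- assign_membership_all(records, norm$cpm, alpha = config$alpha)
  summary <- summarize_categories(codes)
  say("membership: ", summary$n_restricted, " restricted transcripts in ",
      summary$n_categories, " categories")

  qc <- tryCatch(cutoff_diagnostic(table,
                                   candidate_cutoffs =
                                     unique(c(0, config$cpm_cutoff))),
                 error = function(e) stop("stage 'qc' failed: ",
                                          conditionMessage(e)))

  manifest <- list(
    tool = paste0("axiszone ", as.character(utils::packageVersion("axiszone"))),
    seed = config$seed,
    config = unclass(config),
    input = list(path = if (is.null(input_path)) NA else input_path,
                 md5 = if (is.null(input_path)) NA
                       else unname(tools::md5sum(input_path))),
    counts = list(detected = detected,
                  kept = length(keep),
                  tested = length(unique(records$transcript_id)),
                  restricted = summary$n_restricted))

  result <- structure(list(table = table,
                           kept_ids = kept_table$transcript_ids,
                           norm = norm, records = records, codes = codes,
                           summary = summary, qc = qc, manifest = manifest),
                      class = "zone_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.zone_pipeline_result <- function(x, ...) {
  m <- x$manifest$counts
  cat("zone pipeline run:", m$detected, "detected ->", m$kept, "kept ->",
      m$restricted, "axially restricted\n")
  print(x$summary)
  invisible(x)
}

# Writes all artifacts with fixed formats so reruns are byte-identical.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(out_dir, name)

  write_results(result$records, result$codes, result$norm$cpm, fp("results.tsv"))

  fac <- data.frame(zone = names(result$norm$normalization_factors),
                    normalization_factor =
                      sprintf("%.12g", result$norm$normalization_factors),
                    effective_library_size =
                      sprintf("%.12g", result$norm$effective_library_sizes),
                    stringsAsFactors = FALSE)
  utils::write.table(fac, fp("factors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cat_df <- data.frame(code = names(result$summary$counts),
                       n_transcripts = as.integer(result$summary$counts),
                       stringsAsFactors = FALSE)
  utils::write.table(cat_df, fp("categories.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  qc <- result$qc$report
  qc$max_ks <- sprintf("%.12g", qc$max_ks)
  utils::write.table(qc, fp("qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
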