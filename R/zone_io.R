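#' Construct a zone count table
#'
#' Bundles a transcripts x zones matrix of raw RNA-seq counts with ordered
#' zone labels (anterior first) and per-zone library sizes. This is the
#' central input container of the package: all downstream steps (filtering,
#' TMM normalization, one-vs-rest exact tests, membership coding) consume it.
#'
#' @param counts Non-negative integer matrix, transcripts in rows and axial
#'   zones in columns. Dimnames, if present, seed `transcript_ids` and
#'   `zone_labels`.
#' @param transcript_ids Character vector of unique transcript identifiers.
#'   Defaults to the matrix rownames, or `t1..tn` when absent.
#' @param zone_labels Character vector of unique zone names in axial order,
#'   anterior first. Defaults to the matrix colnames, or `"1".."6"` style
#'   numbering.
#' @param library_sizes Positive per-zone sequencing depths. Defaults to the
#'   column sums of `counts`; override when library sizes come from the full
#'   alignment rather than the tabulated transcripts.
#' @return An object of class `zone_count_table`: a list with elements
#'   `counts` (integer matrix with dimnames), `zone_labels`,
#'   `transcript_ids`, and `library_sizes` (named numeric).
#' @examples
#' m <- matrix(rpois(12, 50), 2, 6)
#' zct <- zone_count_table(m)
#' zct$library_sizes
#' @export
zone_count_table <- function(counts, transcript_ids = rownames(counts),
                             zone_labels = colnames(counts),
                             library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(transcript_ids))
    transcript_ids <- paste0("t", seq_len(nrow(counts)))
  if (is.null(zone_labels))
    zone_labels <- as.character(seq_len(ncol(counts)))
  transcript_ids <- as.character(transcript_ids)
  zone_labels <- as.character(zone_labels)

  if (length(transcript_ids) != nrow(counts))
    stop("transcript_ids length (", length(transcript_ids),
         ") does not match number of rows (", nrow(counts), ")")
  if (length(zone_labels) != ncol(counts))
    stop("number of zone labels (", length(zone_labels),
         ") does not match number of count columns (", ncol(counts), ")")
  if (anyDuplicated(transcript_ids))
    stop("duplicate transcript ids: ",
         paste(unique(transcript_ids[duplicated(transcript_ids)]), collapse = ", "))
  if (anyDuplicated(zone_labels))
    stop("duplicate zone labels: ",
         paste(unique(zone_labels[duplicated(zone_labels)]), collapse = ", "))
  if (anyNA(counts))
    stop("counts contain missing values")
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("count for transcript '", transcript_ids[bad[1, 1]], "', zone '",
         zone_labels[bad[1, 2]], "' is not a non-negative integer: ",
         counts[bad[1, , drop = FALSE]])
  storage.mode(counts) <- "double"  # keeps exact integers, avoids overflow
  dimnames(counts) <- list(transcript_ids, zone_labels)

  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per zone")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stop("library_sizes must be positive for every zone (all-zero zones are rejected)")
  names(library_sizes) <- zone_labels

  structure(list(counts = counts, transcript_ids = transcript_ids,
                 zone_labels = zone_labels, library_sizes = library_sizes),
            class = "zone_count_table")
}

#' @export
print.zone_count_table <- function(x, ...) {
  cat("zone_count_table:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "zones\n")
  cat("zones (anterior -> posterior):", paste(x$zone_labels, collapse = ", "), "\n")
  cat("library sizes:", paste(format(x$library_sizes, big.mark = ","),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Subset a zone count table by transcript
#'
#' @param table A [zone_count_table()].
#' @param i Integer, logical or character index over transcripts.
#' @return A `zone_count_table` with the selected transcripts; library sizes
#'   are carried over unchanged (they describe sequencing depth, not the
#'   retained rows).
#' @export
subset_transcripts <- function(table, i) {
  stopifnot(inherits(table, "zone_count_table"))
  counts <- table$counts[i, , drop = FALSE]
  zone_count_table(counts, transcript_ids = rownames(counts),
                   zone_labels = table$zone_labels,
                   library_sizes = table$library_sizes)
}

#' Read a zone count matrix
#'
#' Reads raw counts either from a tab-separated table (header row of zone
#' labels, first column `transcript_id`, `#`-prefixed comment lines ignored)
#' or from a Matrix Market triplet file accompanied by sidecar name files
#' `<path>.rows` and `<path>.cols` (one transcript/zone name per line).
#' Column order is preserved as the axial (anterior to posterior) order.
#'
#' @param path Path to the counts file.
#' @param format `"tsv"` (default) or `"mtx"` for Matrix Market triplet.
#' @param library_sizes Optional per-zone library sizes overriding the
#'   column-sum default.
#' @return A validated [zone_count_table()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), library_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("malformed counts table '", path, "': ",
                               conditionMessage(e)))
    if (ncol(df) < 2)
      stop("malformed header in '", path,
           "': expected 'transcript_id' plus at least one zone column")
    if (names(df)[1] != "transcript_id")
      stop("malformed header in '", path, "' (line 1): first column must be ",
           "'transcript_id', found '", names(df)[1], "'")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m))
      stop("non-numeric count values in '", path, "'")
    rownames(m) <- ids
    zone_count_table(m, library_sizes = library_sizes)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rows_file <- paste0(path, ".rows")
    cols_file <- paste0(path, ".cols")
    if (!file.exists(rows_file) || !file.exists(cols_file))
      stop("MTX sidecar name files missing: expected ", rows_file,
           " and ", cols_file)
    ids <- readLines(rows_file)
    zones <- readLines(cols_file)
    zone_count_table(m, transcript_ids = ids, zone_labels = zones,
                     library_sizes = library_sizes)
  }
}

#' Write a zone count matrix
#'
#' Inverse of [read_counts()]: counts are written exactly (integers), so a
#' write/read round trip reproduces the matrix bit-exactly.
#'
#' @param table A [zone_count_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "zone_count_table"))
  if (format == "tsv") {
    df <- data.frame(transcript_id = table$transcript_ids,
                     table$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    Matrix::writeMM(Matrix::Matrix(table$counts, sparse = TRUE), path)
    writeLines(table$transcript_ids, paste0(path, ".rows"))
    writeLines(table$zone_labels, paste0(path, ".cols"))
  }
  invisible(path)
}

#' Write per-transcript results
#'
#' Emits the main results table: one row per transcript (input order) with
#' per-zone normalized CPM, per-zone BH-adjusted q-values from the
#' one-vs-rest exact test, and the composite zone-membership code. Numeric
#' values are written with 12 significant digits so a read-back reproduces
#' them to that precision.
#'
#' @param records Long-format test records from [one_vs_rest_tests()]
#'   (columns `transcript_id`, `zone`, `logFC`, `p_value`, `q_value`,
#'   `score`).
#' @param codes Data frame from [assign_membership_all()] with columns
#'   `transcript_id` and `code`.
#' @param cpm Normalized CPM matrix (transcripts x zones) on the same
#'   transcripts.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, codes, cpm, path) {
  if (is.null(records) || nrow(records) == 0)
    stop("no test records to write")
  if (is.null(codes) || nrow(codes) == 0)
    stop("no membership codes to write")
  ids <- codes$transcript_id
  zones <- colnames(cpm)
  qmat <- matrix(NA_real_, length(ids), length(zones),
                 dimnames = list(ids, zones))
  idx <- cbind(match(records$transcript_id, ids), match(records$zone, zones))
  qmat[idx] <- records$q_value
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (z in zones) out[[paste0("cpm_", z)]] <- sprintf("%.12g", cpm[ids, z])
  for (z in zones) out[[paste0("q_", z)]] <- sprintf("%.12g", qmat[ids, z])
  out$code <- codes$code
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# axiszone results: per-zone normalized CPM, per-zone ",
                    "BH q-value (one-vs-rest exact test), membership code"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the results TSV.
#' @return Data frame with `transcript_id`, numeric `cpm_*` and `q_*`
#'   columns, and the `code` column.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  num <- grepl("^(cpm|q)_", names(df))
  df[num] <- lapply(df[num], as.numeric)
  df
}

#' Run configuration for the zone-specificity pipeline
#'
#' Collects every tunable of the analysis. Defaults follow the published
#' procedure where it states a value (CPM cutoff 0.5) and field-standard
#' practice elsewhere (BH FDR at 0.05; TMM trims 0.3/0.05).
#'
#' @param cpm_cutoff Low-expression filter: a transcript is removed only if
#'   its CPM is below this in every zone. Default 0.5.
#' @param alpha FDR threshold applied to BH-adjusted q-values. Default 0.05.
#' @param dispersion Negative-binomial dispersion assumed by the exact test
#'   (variance \eqn{\mu + \phi \mu^2}). The zoned design pools replicate
#'   samples into one library per zone, so dispersion cannot be estimated
#'   from the data and is set here. Default 0.1.
#' @param dispersion_mode `"fixed"` uses `dispersion`; `"poisson"` forces
#'   \eqn{\phi = 0}.
#' @param prior_cpm Pseudo-CPM added to numerator and denominator of the
#'   log2 fold change so it stays finite. Default 0.5.
#' @param trim_m,trim_a TMM trim fractions for M-values (log ratios) and
#'   A-values (log abundances). Defaults 0.3 and 0.05.
#' @param seed Integer seed recorded in the run manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cpm_cutoff = 0.5, alpha = 0.05, dispersion = 0.1,
                       dispersion_mode = c("fixed", "poisson"),
                       prior_cpm = 0.5, trim_m = 0.3, trim_a = 0.05,
                       seed = 1L) {
  dispersion_mode <- match.arg(dispersion_mode)
  if (!is.numeric(cpm_cutoff) || cpm_cutoff < 0)
    stop("cpm_cutoff must be >= 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(dispersion) || dispersion < 0)
    stop("dispersion must be >= 0")
  if (!is.numeric(prior_cpm) || prior_cpm <= 0)
    stop("prior_cpm must be > 0")
  if (trim_m < 0 || trim_m >= 0.5) stop("trim_m must be in [0, 0.5)")
  if (trim_a < 0 || trim_a >= 0.5) stop("trim_a must be in [0, 0.5)")
  structure(list(cpm_cutoff = cpm_cutoff, alpha = alpha,
                 dispersion = dispersion, dispersion_mode = dispersion_mode,
                 prior_cpm = prior_cpm, trim_m = trim_m, trim_a = trim_a,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a validated [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
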