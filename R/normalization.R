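#' Counts per million
#'
#' CPM against *effective* library sizes: `1e6 * counts / effective library
#' size`, column-wise, where the effective size of a zone is its library
#' size times its TMM normalization factor. Pass raw library sizes (factors
#' of 1) to obtain unnormalized CPM, which is what the low-expression filter
#' operates on.
#'
#' @param table A [zone_count_table()], or a bare counts matrix.
#' @param effective_library_sizes Positive per-zone effective sizes.
#' @return Numeric matrix of the same shape as the counts.
#' @export
compute_cpm <- function(table, effective_library_sizes) {
  counts <- if (inherits(table, "zone_count_table")) table$counts else as.matrix(table)
  e <- as.numeric(effective_library_sizes)
  if (length(e) != ncol(counts))
    stop("need one effective library size per zone")
  if (any(!is.finite(e)) || any(e <= 0))
    stop("effective library sizes must be positive")
  sweep(counts, 2, e, "/") * 1e6
}

#' Low-expression filter
#'
#' A transcript is removed only when its CPM falls below `cutoff` in *every*
#' zone; it is kept as soon as one zone reaches the cutoff. Requiring the
#' cutoff in all zones instead would discard exactly the zone-restricted
#' transcripts the analysis is after.
#'
#' @param cpm CPM matrix (transcripts x zones), computed with raw library
#'   sizes.
#' @param cutoff Non-negative CPM threshold; default 0.5.
#' @return Integer indices of the kept transcripts, in input order.
#' @export
filter_low_expression <- function(cpm, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0)
    stop("cutoff must be a single non-negative number")
  cpm <- as.matrix(cpm)
  which(apply(cpm >= cutoff, 1, any))
}

# Pairwise TMM factor of one zone against the reference zone.
# M = log2 ratio of library-size-scaled proportions, A = average log2
# abundance; both trimmed, then M averaged with inverse delta-method
# variance weights (1-p1)/(n1 p1) + (1-p2)/(n2 p2).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a,
                            zone = "?", ref_zone = "?") {
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  shared <- obs > 0 & ref > 0
  if (!any(shared)) {
    warning("zone '", zone, "' shares no positive transcripts with reference '",
            ref_zone, "'; factor set to 1")
    return(1)
  }
  m <- log2(p_o[shared] / p_r[shared])
  a <- (log2(p_o[shared]) + log2(p_r[shared])) / 2
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
          rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  v <- (n_obs - obs[shared]) / (n_obs * obs[shared]) +
       (n_ref - ref[shared]) / (n_ref * ref[shared])
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization, computed from
#' scratch: (1) the reference zone is the one whose 75th-percentile CPM is
#' closest to the mean 75th percentile across zones; (2) each zone is
#' compared to the reference over transcripts positive in both, via
#' M-values (log2 ratio of library-size-scaled proportions) and A-values
#' (average log2 abundance); (3) the extreme `trim_m` fraction by M and
#' `trim_a` fraction by A are discarded on each side; (4) the factor is
#' 2 to the weighted mean of the remaining M-values, weighted by inverse
#' delta-method variances; (5) factors are rescaled to geometric mean 1.
#'
#' @param table A [zone_count_table()] (normally already filtered).
#' @param trim_m Two-sided trim fraction on M-values; default 0.3.
#' @param trim_a Two-sided trim fraction on A-values; default 0.05.
#' @return Named numeric vector of per-zone factors, geometric mean 1.
#' @export
tmm_factors <- function(table, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(table, "zone_count_table"))
  counts <- table$counts
  lib <- table$library_sizes
  if (ncol(counts) < 2) stop("TMM needs at least 2 zones")
  if (any(colSums(counts > 0) == 0))
    stop("every zone must have at least one positive count")
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5)
    stop("trim fractions must be in [0, 0.5)")
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    trim_m, trim_a,
                    zone = colnames(counts)[j],
                    ref_zone = colnames(counts)[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- table$zone_labels
  f
}

#' Normalize a zone count table
#'
#' Computes TMM factors, effective library sizes (`library size x factor`)
#' and the normalized CPM matrix (`1e6 * counts / effective library size`).
#'
#' @inheritParams tmm_factors
#' @return An object of class `zone_normalization`: list with
#'   `normalization_factors`, `effective_library_sizes` and `cpm`.
#' @examples
#' zct <- zone_count_table(matrix(rpois(60, 100), 10, 6))
#' norm <- normalize_zones(zct)
#' prod(norm$normalization_factors)  # geometric mean 1
#' @export
normalize_zones <- function(table, trim_m = 0.3, trim_a = 0.05) {
  f <- tmm_factors(table, trim_m = trim_m, trim_a = trim_a)
  eff <- table$library_sizes * f
  structure(list(normalization_factors = f,
                 effective_library_sizes = eff,
                 cpm = compute_cpm(table, eff)),
            class = "zone_normalization")
}

#' @export
print.zone_normalization <- function(x, ...) {
  cat("zone_normalization over", length(x$normalization_factors), "zones\n")
  print(round(rbind(factor = x$normalization_factors,
                    effective_size = x$effective_library_sizes), 4))
  invisible(x)
}

#' Quantile normalization (diagnostic)
#'
#' Forces every zone's CPM distribution to the across-zone mean of sorted
#' values (ties share their rank mean), so all columns end up with an
#' identical multiset of values. Used only as a diagnostic for choosing the
#' CPM cutoff, not as the normalization feeding the exact tests.
#'
#' @param cpm Numeric matrix with no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(cpm) {
  cpm <- as.matrix(cpm)
  if (anyNA(cpm)) stop("cpm must not contain missing values")
  out <- limma::normalizeQuantiles(cpm, ties = TRUE)
  dimnames(out) <- dimnames(cpm)
  out
}

# Two-sample Kolmogorov-Smirnov statistic (handles ties; statistic only).
ks_statistic <- function(x, y) {
  n_x <- length(x)
  n_y <- length(y)
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= n_x, 1 / n_x, -1 / n_y))
  z <- z[c(diff(sort(w)) != 0, TRUE)]
  max(abs(z))
}

#' Filter-cutoff diagnostic
#'
#' The CPM cutoff is meant to be chosen so that, after filtering, the
#' quantile-normalized per-zone CPM distributions are essentially identical.
#' For each candidate cutoff this applies the filter and reports the maximum
#' pairwise two-sample Kolmogorov-Smirnov statistic between zone log2-CPM
#' distributions, plus the summary statistics behind the usual QC plots:
#' per-zone quartiles of log2-CPM (box plot), a pairwise between-zone
#' distance matrix (hierarchical clustering) and 2-d classical MDS
#' coordinates.
#'
#' @param table A [zone_count_table()].
#' @param candidate_cutoffs Non-negative CPM cutoffs to evaluate; reported
#'   in ascending order.
#' @param prior_cpm Pseudo-CPM added before taking log2; default 0.5.
#' @return An object of class `cutoff_diagnostic`: list with `report` (data
#'   frame: `cutoff`, `n_kept`, `max_ks`) and `details` (per cutoff:
#'   `quartiles`, `dist`, `mds`).
#' @export
cutoff_diagnostic <- function(table, candidate_cutoffs = c(0, 0.5, 1),
                              prior_cpm = 0.5) {
  stopifnot(inherits(table, "zone_count_table"))
  if (any(candidate_cutoffs < 0)) stop("cutoffs must be >= 0")
  cutoffs <- sort(unique(as.numeric(candidate_cutoffs)))
  cpm <- compute_cpm(table, table$library_sizes)
  z <- ncol(cpm)
  details <- list()
  report <- data.frame(cutoff = cutoffs, n_kept = NA_integer_,
                       max_ks = NA_real_)
  for (i in seq_along(cutoffs)) {
    keep <- filter_low_expression(cpm, cutoffs[i])
    if (length(keep) == 0)
      stop("cutoff ", cutoffs[i], " removes every transcript")
    lc <- log2(cpm[keep, , drop = FALSE] + prior_cpm)
    ks_max <- 0
    for (a in seq_len(z - 1)) for (b in seq((a + 1), z))
      ks_max <- max(ks_max, ks_statistic(lc[, a], lc[, b]))
    quart <- apply(lc, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
    d <- stats::dist(t(lc))
    mds <- if (z > 2 && any(d > 0)) stats::cmdscale(d, k = 2) else NULL
    report$n_kept[i] <- length(keep)
    report$max_ks[i] <- ks_max
    details[[as.character(cutoffs[i])]] <-
      list(quartiles = quart, dist = d, mds = mds)
  }
  structure(list(report = report, details = details),
            class = "cutoff_diagnostic")
}

#' @export
print.cutoff_diagnostic <- function(x, ...) {
  cat("CPM cutoff diagnostic (max pairwise KS on log2 CPM):\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
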