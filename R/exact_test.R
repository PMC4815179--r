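#' Equalize library sizes
#'
#' The conditional exact test assumes every library has the same size.
#' Counts are rescaled to a common size (the geometric mean of the
#' effective library sizes) and rounded half-to-even back to integers.
#'
#' @param counts Counts matrix (transcripts x zones).
#' @param effective_library_sizes Positive per-zone effective sizes.
#' @return List with `counts` (adjusted integer matrix) and `common_size`.
#' @export
equalize_libraries <- function(counts, effective_library_sizes) {
  counts <- if (inherits(counts, "zone_count_table")) counts$counts else as.matrix(counts)
  e <- as.numeric(effective_library_sizes)
  if (any(!is.finite(e)) || any(e <= 0))
    stop("effective library sizes must be positive")
  common <- exp(mean(log(e)))
  adj <- round(sweep(counts, 2, common / e, "*"))  # round() is half-to-even
  list(counts = adj, common_size = common)
}

# Conditional distribution of the group-A sum given the total s, under H0
# of equal relative abundance, for groups of n_a and n_b equal-size
# libraries with NB dispersion phi per library. Returns probabilities for
# a = 0..s. Sums of n iid NB(m, phi) are NB(n*m, phi/n); phi = 0 reduces
# the conditional law to Binomial(s, n_a/(n_a+n_b)).
conditional_sum_dist <- function(s, n_a, n_b, phi) {
  a <- 0:s
  # below ~1e-8 the NB size parameter 1/phi exceeds double precision's
  # useful range in dnbinom; the Poisson-limit conditional law (binomial)
  # is then exact to machine precision and is used directly
  if (phi <= 1e-8) return(stats::dbinom(a, s, n_a / (n_a + n_b)))
  m <- s / (n_a + n_b)
  lp <- stats::dnbinom(a, size = n_a / phi, mu = n_a * m, log = TRUE) +
        stats::dnbinom(s - a, size = n_b / phi, mu = n_b * m, log = TRUE)
  p <- exp(lp - max(lp))
  p / sum(p)
}

# Two-sided "small-p" tail: sum of conditional probabilities no larger
# than the observed one (with a relative tolerance guarding float ties).
smallp_tail <- function(probs, observed) {
  min(1, sum(probs[probs <= probs[observed + 1] * (1 + 1e-10)]))
}

#' Negative-binomial conditional exact p-value
#'
#' Tests whether two groups of equal-size libraries share the same relative
#' abundance for a transcript. Under the null, the group sums are negative
#' binomial with means \eqn{n_a m} and \eqn{n_b m} and dispersions
#' \eqn{\phi/n_a}, \eqn{\phi/n_b} (Poisson when \eqn{\phi = 0}); \eqn{m} is
#' estimated as \eqn{(sum_a + sum_b)/(n_a + n_b)}. Conditional on the total
#' \eqn{s}, the p-value sums the probabilities of all outcomes no more
#' likely than the observed one (two-sided "small-p" rule). A total of zero
#' carries no information and returns p = 1.
#'
#' For totals above `max_enumeration` the conditional distribution is
#' replaced by a normal approximation (continuity-corrected, two-sided);
#' such p-values are flagged in the `"approximate"` attribute.
#'
#' @param sum_a,sum_b Group count sums (vectors recycle together).
#' @param n_a,n_b Number of libraries in each group.
#' @param dispersion Per-library NB dispersion \eqn{\phi \ge 0}.
#' @param max_enumeration Largest total enumerated exactly; default 10000.
#' @return Numeric vector of p-values in (0, 1], with a logical
#'   `"approximate"` attribute marking normal-approximation entries.
#' @examples
#' nb_exact_pvalue(12, 0, 1, 5, dispersion = 0)
#' @export
nb_exact_pvalue <- function(sum_a, sum_b, n_a, n_b, dispersion = 0.1,
                            max_enumeration = 10000) {
  if (n_a < 1 || n_b < 1) stop("n_a and n_b must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  k <- max(length(sum_a), length(sum_b))
  sum_a <- rep_len(sum_a, k)
  sum_b <- rep_len(sum_b, k)
  if (any(sum_a < 0 | sum_b < 0 | sum_a != round(sum_a) | sum_b != round(sum_b)))
    stop("group sums must be non-negative integers")
  s <- sum_a + sum_b
  p <- rep(1, k)
  approx <- s > max_enumeration
  for (i in which(s > 0 & !approx)) {
    probs <- conditional_sum_dist(s[i], n_a, n_b, dispersion)
    p[i] <- smallp_tail(probs, sum_a[i])
  }
  if (any(approx)) {
    m <- s[approx] / (n_a + n_b)
    mu_a <- n_a * m
    v_a <- mu_a + dispersion * mu_a^2 / n_a
    mu_b <- n_b * m
    v_b <- mu_b + dispersion * mu_b^2 / n_b
    sd_c <- sqrt(v_a * v_b / (v_a + v_b))
    z <- (abs(sum_a[approx] - mu_a) - 0.5) / sd_c
    p[approx] <- pmin(1, 2 * stats::pnorm(-z))
  }
  attr(p, "approximate") <- approx
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; thin wrapper over [stats::p.adjust()] kept as the
#' package's single multiple-testing entry point (applied within each
#' zone's family of tests).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order.
#' @export
adjust_pvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' One-vs-rest zone-specificity tests
#'
#' For every transcript and every zone, tests the zone (one library)
#' against the pooled remaining zones (Z - 1 libraries) on
#' library-equalized counts with [nb_exact_pvalue()]. The log2 fold change
#' compares the zone's normalized CPM to the mean CPM of the other zones,
#' with `prior_cpm` added to both sides so it is always finite; the score
#' is \eqn{-\log_{10} p}; q-values are BH-adjusted within each zone's
#' family of transcripts.
#'
#' @param table A filtered [zone_count_table()].
#' @param norm The matching [normalize_zones()] result.
#' @param config A [run_config()].
#' @return A data frame (class `zone_test_records`) with one row per
#'   (transcript, zone): `transcript_id`, `zone`, `logFC`, `p_value`,
#'   `q_value`, `score`, `approx`.
#' @export
one_vs_rest_tests <- function(table, norm, config = run_config()) {
  stopifnot(inherits(table, "zone_count_table"),
            inherits(norm, "zone_normalization"))
  z <- length(table$zone_labels)
  if (z < 2) stop("one-vs-rest testing needs at least 2 zones")
  if (!identical(rownames(norm$cpm), table$transcript_ids))
    stop("normalization result does not match the count table transcripts")
  phi <- if (config$dispersion_mode == "poisson") 0 else config$dispersion
  eq <- equalize_libraries(table$counts, norm$effective_library_sizes)
  adj <- eq$counts
  n_g <- nrow(adj)
  s <- rowSums(adj)
  max_enum <- 10000

  # For a given transcript the total s is shared by all Z one-vs-rest
  # tests (n_a = 1, n_b = Z - 1), so the conditional law is computed once.
  pmat <- matrix(1, n_g, z)
  for (g in which(s > 0 & s <= max_enum)) {
    probs <- conditional_sum_dist(s[g], 1, z - 1, phi)
    obs <- probs[adj[g, ] + 1]
    pmat[g, ] <- pmin(1, vapply(obs, function(po)
      sum(probs[probs <= po * (1 + 1e-10)]), numeric(1)))
  }
  big <- which(s > max_enum)
  for (g in big) {
    pmat[g, ] <- nb_exact_pvalue(adj[g, ], s[g] - adj[g, ], 1, z - 1,
                                 dispersion = phi,
                                 max_enumeration = max_enum)
  }

  cpm <- norm$cpm
  prior <- config$prior_cpm
  lfc <- matrix(NA_real_, n_g, z)
  for (j in seq_len(z)) {
    rest <- rowMeans(cpm[, -j, drop = FALSE])
    lfc[, j] <- log2((cpm[, j] + prior) / (rest + prior))
  }
  qmat <- apply(pmat, 2, adjust_pvalues)
  if (n_g == 1) qmat <- matrix(qmat, nrow = 1)

  out <- data.frame(
    transcript_id = rep(table$transcript_ids, each = z),
    zone = rep(table$zone_labels, times = n_g),
    logFC = as.vector(t(lfc)),
    p_value = as.vector(t(pmat)),
    q_value = as.vector(t(qmat)),
    score = -log10(as.vector(t(pmat))),
    approx = rep(s > max_enum, each = z),
    stringsAsFactors = FALSE
  )
  class(out) <- c("zone_test_records", "data.frame")
  out
}
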