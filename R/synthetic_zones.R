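#' Configuration for the zoned-count simulator
#'
#' Describes a synthetic experiment shaped like an axial-zone RNA-seq run:
#' a handful of ordered zones sequenced as one pooled library each, with
#' unequal depths, a log-normal baseline abundance distribution,
#' negative-binomial counting noise, and a planted mixture of expression
#' archetypes along the anterior-posterior axis.
#'
#' Archetypes: `flat` (no axial structure), `single_zone` (one zone
#' enriched `fold_change`-fold), `dual_adjacent` (two neighbouring zones
#' enriched, the stronger `dual_ratio` times the weaker), `gradient_posterior`
#' / `gradient_anterior` (geometric gradients with per-zone step
#' `gradient_step`), and `below_filter` (expressed below the CPM filter in
#' every zone).
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param n_zones Number of axial zones; default 6.
#' @param library_size_mean Mean per-zone library size; default 2e6.
#' @param library_size_jitter Uniform relative jitter on library sizes, in
#'   \[0, 1); default 0.2.
#' @param baseline_log_mean,baseline_log_sd Log-normal (natural log)
#'   parameters of the baseline relative abundance; defaults 1 and 1.5.
#' @param archetype_proportions Named fractions over the six archetypes,
#'   summing to 1.
#' @param fold_change Enrichment of the planted zone(s); default 8.
#' @param dual_ratio Ratio between the stronger and weaker enriched zone of
#'   `dual_adjacent` transcripts; default 2.
#' @param gradient_step Per-zone multiplicative step of gradients; default 2.
#' @param dispersion NB dispersion of the counting noise (variance
#'   \eqn{\mu + \phi\mu^2}); 0 gives Poisson. Default 0.05.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 6000, n_zones = 6,
                              library_size_mean = 2e6,
                              library_size_jitter = 0.2,
                              baseline_log_mean = 1, baseline_log_sd = 1.5,
                              archetype_proportions = c(
                                flat = 0.55, single_zone = 0.08,
                                dual_adjacent = 0.06,
                                gradient_posterior = 0.03,
                                gradient_anterior = 0.03,
                                below_filter = 0.25),
                              fold_change = 8, dual_ratio = 2,
                              gradient_step = 2, dispersion = 0.05,
                              seed = 1L) {
  kinds <- c("flat", "single_zone", "dual_adjacent", "gradient_posterior",
             "gradient_anterior", "below_filter")
  if (!setequal(names(archetype_proportions), kinds))
    stop("archetype_proportions must name exactly: ",
         paste(kinds, collapse = ", "))
  archetype_proportions <- archetype_proportions[kinds]
  if (any(archetype_proportions < 0) ||
      abs(sum(archetype_proportions) - 1) > 1e-9)
    stop("archetype proportions must be >= 0 and sum to 1")
  if (n_transcripts < 1 || n_zones < 2) stop("need >= 1 transcript and >= 2 zones")
  if (library_size_mean <= 0) stop("library_size_mean must be > 0")
  if (library_size_jitter < 0 || library_size_jitter >= 1)
    stop("library_size_jitter must be in [0, 1)")
  if (fold_change <= 1 || dual_ratio <= 1 || gradient_step <= 1)
    stop("fold_change, dual_ratio and gradient_step must be > 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 n_zones = as.integer(n_zones),
                 library_size_mean = library_size_mean,
                 library_size_jitter = library_size_jitter,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 archetype_proportions = archetype_proportions,
                 fold_change = fold_change, dual_ratio = dual_ratio,
                 gradient_step = gradient_step, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Expected membership code implied by a planted relative-abundance profile:
# the zones whose abundance exceeds the mean of the other zones, listed in
# decreasing abundance (ties anterior first).
expected_code_from_profile <- function(rel, zones) {
  z <- length(rel)
  excess <- vapply(seq_len(z), function(j) rel[j] > mean(rel[-j]), logical(1))
  sel <- which(excess)
  if (length(sel) == 0) return("none")
  sel <- sel[order(-rel[sel], sel)]
  paste(zones[sel], collapse = ".")
}

#' Simulate a zoned count matrix with known truth
#'
#' Draws library sizes, assigns each transcript an archetype and a planted
#' relative-abundance profile over the zones, then samples counts
#' \eqn{K_{gz} \sim NB(\mu_{gz}, \phi)} with \eqn{\mu_{gz} = p_{gz} L_z},
#' where \eqn{p_{gz}} is the planted abundance normalized within each zone
#' and \eqn{L_z} the zone's library size (variance
#' \eqn{\mu + \phi\mu^2}; Poisson when \eqn{\phi = 0}). `below_filter`
#' transcripts are planted at a CPM below `filter_cutoff` in every zone.
#' The same seed always reproduces the same matrix.
#'
#' @param config A [simulation_config()].
#' @param filter_cutoff CPM value the `below_filter` archetype must stay
#'   under; default 0.5.
#' @return List with `table` (a [zone_count_table()]) and `truth` (class
#'   `synthetic_truth`): data frame `info` (`transcript_id`, `archetype`,
#'   `expected_code`), matrices `relative_abundance` and `planted_cpm`, and
#'   the drawn `library_sizes`.
#' @export
simulate_zone_counts <- function(config, filter_cutoff = 0.5) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  z <- config$n_zones
  zones <- as.character(seq_len(z))
  ids <- sprintf("t%05d", seq_len(n))

  jit <- config$library_size_jitter
  lib <- round(config$library_size_mean * stats::runif(z, 1 - jit, 1 + jit))

  # archetype block sizes that sum exactly to n
  prop <- config$archetype_proportions
  sizes <- diff(round(cumsum(c(0, prop)) * n))
  archetype <- rep(names(prop), times = sizes)

  baseline <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  rel <- matrix(rep(baseline, z), n, z)
  fc <- config$fold_change
  for (g in seq_len(n)) {
    mult <- switch(archetype[g],
      flat = , below_filter = rep(1, z),
      single_zone = {
        m <- rep(1, z); m[sample.int(z, 1)] <- fc; m
      },
      dual_adjacent = {
        start <- sample.int(z - 1, 1)
        m <- rep(1, z)
        if (stats::runif(1) < 0.5) {
          m[start] <- fc; m[start + 1] <- fc / config$dual_ratio
        } else {
          m[start] <- fc / config$dual_ratio; m[start + 1] <- fc
        }
        m
      },
      gradient_posterior = config$gradient_step^(seq_len(z) - 1),
      gradient_anterior = config$gradient_step^(z - seq_len(z)))
    rel[g, ] <- rel[g, ] * mult
  }

  # plant below_filter rows at a tiny fixed CPM relative to the signal mass
  bf <- archetype == "below_filter"
  if (any(bf)) {
    signal_mass <- colSums(rel[!bf, , drop = FALSE])
    target <- stats::runif(sum(bf), 0.05, 0.30)
    rel[bf, ] <- outer(target, rep(mean(signal_mass) / 1e6, z))
    planted <- 1e6 * sweep(rel, 2, colSums(rel), "/")
    worst <- max(planted[bf, ])
    if (worst >= filter_cutoff)
      rel[bf, ] <- rel[bf, ] * (0.9 * filter_cutoff / worst)
  }

  p <- sweep(rel, 2, colSums(rel), "/")
  planted_cpm <- 1e6 * p
  mu <- sweep(p, 2, lib, "*")
  phi <- config$dispersion
  counts <- if (phi == 0) {
    matrix(stats::rpois(n * z, as.vector(mu)), n, z)
  } else {
    matrix(stats::rnbinom(n * z, mu = as.vector(mu), size = 1 / phi), n, z)
  }
  dimnames(counts) <- list(ids, zones)
  dimnames(rel) <- dimnames(planted_cpm) <- list(ids, zones)

  expected <- vapply(seq_len(n), function(g) {
    if (archetype[g] %in% c("flat", "below_filter")) "none"
    else expected_code_from_profile(rel[g, ], zones)
  }, character(1))

  table <- zone_count_table(counts, transcript_ids = ids, zone_labels = zones)
  truth <- structure(list(
    info = data.frame(transcript_id = ids, archetype = archetype,
                      expected_code = expected, stringsAsFactors = FALSE),
    relative_abundance = rel,
    planted_cpm = planted_cpm,
    library_sizes = stats::setNames(lib, zones)),
    class = "synthetic_truth")
  list(table = table, truth = truth)
}

#' Write / read the synthetic truth table
#'
#' @param truth A `synthetic_truth` object.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  df <- cbind(truth$info,
              stats::setNames(as.data.frame(truth$planted_cpm),
                              paste0("planted_cpm_",
                                     colnames(truth$planted_cpm))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score recovery of planted membership codes
#'
#' Compares assigned membership codes with the codes implied by the planted
#' design: per-archetype exact-code sensitivity, per-archetype agreement of
#' the primary (first-listed) zone, and the false-restriction rate (the
#' fraction of flat transcripts assigned any code other than `"none"`).
#'
#' @param assigned Named character vector of assigned codes (names are
#'   transcript ids). Transcripts removed by the expression filter should
#'   be entered as `"none"`.
#' @param truth The `synthetic_truth` from [simulate_zone_counts()].
#' @param strict When `TRUE` (default) the assigned ids must be exactly the
#'   truth's transcript universe; with `FALSE`, scoring is restricted to
#'   the supplied subset.
#' @return An object of class `recovery_summary`: data frame `by_archetype`
#'   (`archetype`, `n`, `sensitivity`, `primary_zone_agreement`) plus
#'   `false_restriction` and `n_scored`.
#' @export
score_recovery <- function(assigned, truth, strict = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ids <- names(assigned)
  if (is.null(ids)) stop("assigned must be a named vector of codes")
  universe <- truth$info$transcript_id
  if (strict) {
    if (!setequal(ids, universe))
      stop("assigned ids do not match the truth's transcript universe")
  } else if (!all(ids %in% universe)) {
    stop("assigned ids absent from the truth: ",
         paste(utils::head(setdiff(ids, universe)), collapse = ", "))
  }
  info <- truth$info[match(ids, universe), ]
  primary <- function(codes) vapply(codes, function(cd) {
    z <- membership_zones(cd)
    if (length(z) == 0) "none" else z[1]
  }, character(1), USE.NAMES = FALSE)
  by <- split(seq_along(ids), info$archetype)
  by_archetype <- do.call(rbind, lapply(names(by), function(k) {
    i <- by[[k]]
    data.frame(archetype = k, n = length(i),
               sensitivity = mean(assigned[i] == info$expected_code[i]),
               primary_zone_agreement =
                 mean(primary(assigned[i]) == primary(info$expected_code[i])),
               stringsAsFactors = FALSE)
  }))
  flat <- info$archetype == "flat"
  structure(list(by_archetype = by_archetype,
                 false_restriction = if (any(flat))
                   mean(assigned[flat] != "none") else NA_real_,
                 n_scored = length(ids)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("recovery over", x$n_scored, "transcripts\n")
  print(x$by_archetype, row.names = FALSE)
  cat("false-restriction rate (flat):", x$false_restriction, "\n")
  invisible(x)
}
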