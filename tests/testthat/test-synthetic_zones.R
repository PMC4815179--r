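flat_only <- c(flat = 1, single_zone = 0, dual_adjacent = 0,
               gradient_posterior = 0, gradient_anterior = 0,
               below_filter = 0)

test_that("simulator is deterministic in the seed", {
  cfg <- simulation_config(n_transcripts = 200, seed = 123)
  a <- simulate_zone_counts(cfg)
  b <- simulate_zone_counts(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$truth$info, b$truth$info)
  c2 <- simulate_zone_counts(simulation_config(n_transcripts = 200, seed = 124))
  expect_false(identical(a$table$counts, c2$table$counts))
})

test_that("config validation rejects bad archetype proportions", {
  bad <- flat_only; bad["flat"] <- 0.9
  expect_error(simulation_config(archetype_proportions = bad), "sum to 1")
  expect_error(simulation_config(archetype_proportions = c(flat = 1)),
               "must name exactly")
  expect_error(simulation_config(fold_change = 1), "must be > 1")
  expect_error(simulation_config(library_size_jitter = 1), "jitter")
})

test_that("Poisson mode hits its planted mean and unit variance/mean ratio", {
  # one flat transcript among many, equal libraries, planted mu = 100
  n <- 10000
  cfg <- simulation_config(n_transcripts = n, library_size_mean = n * 100,
                           library_size_jitter = 0, baseline_log_sd = 0,
                           archetype_proportions = flat_only,
                           dispersion = 0, seed = 77)
  sim <- simulate_zone_counts(cfg)
  expect_true(all(abs(sim$truth$planted_cpm - 1e6 / n) < 1e-9))
  g1 <- sim$table$counts[1, ]
  expect_lt(abs(mean(g1) - 100), 3 * sqrt(100 / length(g1)))
  # variance/mean ratio of Poisson draws concentrates at 1
  ratios <- apply(sim$table$counts[1:500, ], 1, function(x) var(x) / mean(x))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("single-zone archetype realizes its fold change in CPM", {
  cfg <- simulation_config(n_transcripts = 1000,
                           archetype_proportions = c(
                             flat = 0, single_zone = 1, dual_adjacent = 0,
                             gradient_posterior = 0, gradient_anterior = 0,
                             below_filter = 0),
                           fold_change = 8, seed = 21)
  sim <- simulate_zone_counts(cfg)
  cpm <- compute_cpm(sim$table, sim$table$library_sizes)
  planted <- vapply(seq_len(1000), function(g)
    which.max(sim$truth$relative_abundance[g, ]), integer(1))
  in_zone <- cpm[cbind(1:1000, planted)]
  out_zone <- (rowSums(cpm) - in_zone) / (ncol(cpm) - 1)
  expect_gt(mean(in_zone) / mean(out_zone), 7.5)
  expect_lt(mean(in_zone) / mean(out_zone), 8.5)
})

test_that("below-filter transcripts sit under the cutoff in every zone", {
  sim <- simulate_zone_counts(simulation_config(n_transcripts = 2000, seed = 3))
  bf <- sim$truth$info$archetype == "below_filter"
  expect_gt(sum(bf), 0)
  expect_true(all(sim$truth$planted_cpm[bf, ] < 0.5))
})

test_that("column sums scale with the drawn library sizes", {
  sim <- simulate_zone_counts(simulation_config(n_transcripts = 4000,
                                                library_size_jitter = 0.3,
                                                seed = 8))
  ratio <- colSums(sim$table$counts) / sim$truth$library_sizes
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("expected codes follow the planted-abundance rule", {
  sim <- simulate_zone_counts(simulation_config(n_transcripts = 600, seed = 13))
  info <- sim$truth$info
  rel <- sim$truth$relative_abundance
  for (g in seq_len(nrow(info))) {
    if (info$archetype[g] %in% c("flat", "below_filter")) {
      expect_identical(info$expected_code[g], "none")
      next
    }
    zones <- membership_zones(info$expected_code[g])
    over <- which(vapply(seq_len(6), function(j)
      rel[g, j] > mean(rel[g, -j]), logical(1)))
    expect_setequal(zones, as.character(over))
    # listed highest planted expression first
    expect_identical(zones,
                     zones[order(-rel[g, zones], match(zones, colnames(rel)))])
  }
  # archetype-shaped codes: single zone -> 1 label; dual adjacent -> 2
  single <- info$archetype == "single_zone"
  expect_true(all(nchar(gsub("[^.]", "", info$expected_code[single])) == 0))
  dual <- info$archetype == "dual_adjacent"
  expect_true(all(lengths(lapply(info$expected_code[dual],
                                 membership_zones)) == 2))
})

test_that("recovery scoring matches hand cases and random-guess analytics", {
  sim <- simulate_zone_counts(simulation_config(n_transcripts = 300, seed = 4))
  truth <- sim$truth
  perfect <- setNames(truth$info$expected_code, truth$info$transcript_id)
  r <- score_recovery(perfect, truth)
  expect_true(all(r$by_archetype$sensitivity == 1))
  expect_identical(r$false_restriction, 0)

  none <- setNames(rep("none", 300), truth$info$transcript_id)
  r2 <- score_recovery(none, truth)
  signal <- !r2$by_archetype$archetype %in% c("flat", "below_filter")
  expect_true(all(r2$by_archetype$sensitivity[signal] == 0))

  # random guessing over the 6 single-zone codes on single-zone-only truth
  cfg <- simulation_config(n_transcripts = 6000,
                           archetype_proportions = c(
                             flat = 0, single_zone = 1, dual_adjacent = 0,
                             gradient_posterior = 0, gradient_anterior = 0,
                             below_filter = 0), seed = 10)
  truth2 <- simulate_zone_counts(cfg)$truth
  set.seed(99)
  guess <- setNames(sample(as.character(1:6), 6000, replace = TRUE),
                    truth2$info$transcript_id)
  sens <- score_recovery(guess, truth2)$by_archetype$sensitivity
  expect_lt(abs(sens - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / 6000))

  expect_error(score_recovery(setNames("1", "nope"), truth), "ids")
})
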