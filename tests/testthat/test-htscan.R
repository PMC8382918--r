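mk_kh <- function(starts, ends, ids = 94.5) {
  data.frame(query_id = sprintf("p%03d", seq_along(starts)),
             target_id = "chr", pct_identity = ids, aln_len = ends - starts + 1L,
             t_start = as.integer(starts), t_end = as.integer(ends),
             score = 50, stringsAsFactors = FALSE)
}

test_that("dense-region merging follows the gap and length rules", {
  # two stretches separated by a 99-bp gap merge and pass the length bar
  kh <- mk_kh(c(seq(1000, 1250, by = 50), seq(1400, 1650, by = 50)),
              c(seq(1050, 1300, by = 50), seq(1450, 1700, by = 50)))
  r <- merge_dense_regions(kh, 500, 150)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(1000L, 1700L))
  expect_equal(r$mapped_bp, 602L)

  # a single short interval is below the length bar
  r2 <- merge_dense_regions(mk_kh(100, 200), 500, 150)
  expect_equal(nrow(r2), 0)

  # the > 500 length bar is strict: 500 mapped bases fail, 501 pass
  expect_equal(nrow(merge_dense_regions(mk_kh(100, 599), 500, 150)), 0)
  expect_equal(nrow(merge_dense_regions(mk_kh(100, 600), 500, 150)), 1)

  # gap of exactly 150 does not chain
  kh4 <- mk_kh(c(seq(1000, 1540, by = 60), 1741),
               c(seq(1050, 1590, by = 60), 1791))
  expect_equal(kh4$t_start[11] - kh4$t_end[10] - 1L, 150L)
  r4 <- merge_dense_regions(kh4, 500, 150)
  expect_equal(nrow(r4), 1)  # only the first chain survives
  expect_equal(r4$end, 1590L)
  # one bp closer and the chain absorbs the extra piece
  kh5 <- kh4; kh5$t_start[11] <- 1740L; kh5$t_end[11] <- 1790L
  r5 <- merge_dense_regions(kh5, 500, 150)
  expect_equal(r5$end, 1790L)
})

test_that("homolog search applies the strict half-length and identity bounds", {
  scen <- cached("amp_scenario", build_ht_scenario(
    small_config(seed = 202L, n_amplified_copies = 3L)))
  h <- homolog_search(scen$rt_seq, scen$recipient_genome)
  expect_equal(nrow(h), 4)  # one per planted copy
  expect_true(all(h$pct_identity > 85))

  # matched length of exactly half the query is excluded (strict >)
  rt <- scen$rt_seq
  qlen <- nchar(rt[[1]])
  half_target <- stats::setNames(substr(rt[[1]], 1, qlen / 2), "half")
  expect_equal(nrow(homolog_search(rt, half_target)), 0)
  over_half <- stats::setNames(substr(rt[[1]], 1, qlen / 2 + 1), "overhalf")
  expect_equal(nrow(homolog_search(rt, over_half)), 1)
})

test_that("targeted scan recovers the planted element and nothing else", {
  scen <- small_scenario()
  profs <- test_profiles()
  reps <- rt_cluster_representatives(scen$donor_reads, profs$RT)
  expect_gt(length(reps), 0)
  calls <- targeted_scan(reps, list(recipient = scen$recipient_genome),
                         scen$donor_reads, profiles = profs)
  expect_equal(nrow(calls), 1)
  expect_gte(calls$n_support_hits, 10)
  expect_gt(calls$mean_identity, 97)
  expect_false(calls$flank_elevated)
  # call interval matches the planted truth
  expect_lt(abs(calls$start - scen$truth$start[1]), 20)
  expect_lt(abs(calls$end - scen$truth$end[1]), 20)
})

test_that("support below ten hits or a vertical-only genome yields no call", {
  scen <- small_scenario()
  profs <- test_profiles()
  reps <- rt_cluster_representatives(scen$donor_reads, profs$RT)
  # throttle support: keep only 9 distinct reads among the supporters
  calls_full <- targeted_scan(reps, list(recipient = scen$recipient_genome),
                              scen$donor_reads, profiles = profs)
  sup <- calls_full$n_support_hits[1]
  calls9 <- targeted_scan(reps, list(recipient = scen$recipient_genome),
                          scen$donor_reads, profiles = profs,
                          min_hits = sup + 1L)
  expect_equal(nrow(calls9), 0)

  scen0 <- cached("neg_scenario",
                  build_ht_scenario(small_config(seed = 303L),
                                    plant_ht = FALSE))
  reps0 <- rt_cluster_representatives(scen0$donor_reads, profs$RT)
  calls0 <- targeted_scan(reps0, list(recipient = scen0$recipient_genome),
                          scen0$donor_reads, profiles = profs)
  expect_equal(nrow(calls0), 0)
})

test_that("nontargeted scan recovers the planted element; negative control clean", {
  scen <- small_scenario()
  calls <- suppressWarnings(
    nontargeted_scan(scen$donor_reads, scen$recipient_genome))
  expect_equal(nrow(calls), 1)
  expect_true(calls$start <= scen$truth$end[1] &&
                calls$end >= scen$truth$start[1])
  expect_false(calls$filtered[1])

  scen0 <- cached("neg_scenario",
                  build_ht_scenario(small_config(seed = 303L),
                                    plant_ht = FALSE))
  calls0 <- suppressWarnings(
    nontargeted_scan(scen0$donor_reads, scen0$recipient_genome))
  expect_equal(nrow(calls0), 0)
})

test_that("an old transfer registers at the 94% sweep point but not at 97%", {
  scen5 <- cached("old_ht_scenario", build_ht_scenario(
    small_config(seed = 404L, ht_divergence = 5)))
  calls94 <- suppressWarnings(
    nontargeted_scan(scen5$donor_reads, scen5$recipient_genome,
                     call_threshold = 94))
  expect_gte(nrow(calls94), 1)
  sw <- threshold_sweep(calls94, thresholds = c(94, 97, 100))
  expect_gte(sw$n_calls[sw$threshold == 94], 1)
  expect_identical(sw$n_calls[sw$threshold == 97], 0L)
})

test_that("exclusion filters remove organelle and simple-repeat regions", {
  chl <- htte:::random_dna(3000, 77)
  organelle_region <- substr(chl, 501, 1700)
  at_repeat <- strrep("AT", 600)
  te_region <- substr(small_scenario()$te$seq, 1001, 2200)
  regions <- data.frame(
    region_id = c("org", "sat", "te"),
    seq = c(organelle_region, at_repeat, te_region),
    stringsAsFactors = FALSE)
  kept <- apply_filters(regions, list(organelle = c(chl = chl)))
  expect_identical(kept$region_id, "te")
  report <- attr(kept, "report")
  expect_identical(report$removed_reason,
                   c("organelle", "simple_repeat", NA))
})

test_that("threshold sweep counts are correct and nonincreasing", {
  calls <- data.frame(mean_identity = c(94.5, 98, 100))
  sw <- threshold_sweep(calls)
  expect_equal(sw$n_calls, c(3L, 2L, 1L))
  sw0 <- threshold_sweep(calls[0, , drop = FALSE])
  expect_equal(sw0$n_calls, c(0L, 0L, 0L))
  for (seed in 1:25) {
    ids <- with_seed_local(seed, stats::runif(sample(0:30, 1), 90, 100))
    sw <- threshold_sweep(data.frame(mean_identity = ids),
                          thresholds = c(94, 95.5, 97, 99, 100))
    expect_true(all(diff(sw$n_calls) <= 0))
  }
})
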