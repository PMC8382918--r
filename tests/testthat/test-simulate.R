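test_that("make_te builds a structurally correct element, deterministically", {
  te <- make_te(5000, 300, seed = 1)
  expect_equal(nchar(te$seq), 5000)
  ltrs <- te$annotations[te$annotations$kind == "LTR", ]
  expect_equal(ltrs$start, c(1L, 4701L))
  expect_equal(ltrs$end, c(300L, 5000L))
  ltr1 <- substr(te$seq, 1, 300)
  ltr2 <- substr(te$seq, 4701, 5000)
  expect_identical(ltr1, ltr2)
  expect_identical(substr(ltr1, 1, 2), "TG")
  expect_identical(substr(ltr1, 299, 300), "CA")
  dom <- te$annotations[te$annotations$kind == "domain", ]
  expect_identical(dom$label, c("gag", "AP", "IN", "RT", "RH"))
  expect_true(all(diff(dom$start) > 0))
  # RT carries the YxDD catalytic motif
  rt_aa <- htte:::translate_frame(substr(te$seq, dom$start[4], dom$end[4]), 1)
  expect_match(rt_aa, "Y.DD")

  expect_identical(make_te(5000, 300, seed = 7)$seq,
                   make_te(5000, 300, seed = 7)$seq)
  expect_false(identical(make_te(5000, 300, seed = 7)$seq, te$seq))
  expect_error(make_te(900, 300, seed = 1), "too small")
})

test_that("insert_te duplicates the target site around the element", {
  ins <- insert_te("AAAATCGATCCCC", "TGACA", pos = 5, tsd_len = 5)
  expect_identical(ins$seq, "AAAATCGATTGACATCGATCCCC")
  expect_identical(ins$tsd, "TCGAT")
  expect_equal(unname(ins$element), c(10L, 14L))
  expect_equal(nchar(ins$seq), 13 + 5 + 5)

  blunt <- insert_te("AAAATCGATCCCC", "TGACA", pos = 5, tsd_len = 0)
  expect_equal(nchar(blunt$seq), 18)
  expect_identical(blunt$tsd, "")

  expect_error(insert_te("ACGTACGT", "TGACA", pos = 7, tsd_len = 5), "end")
})

test_that("junction detector recovers the planted TSD from an insertion", {
  g <- htte:::random_dna(4000, 42)
  te <- make_te(2600, 100, seed = 3)
  ins <- insert_te(g, te, pos = 2000, tsd_len = 5)
  expect_identical(detect_tsd(ins$seq, ins$element), ins$tsd)
})

test_that("mutate_seq realizes the exact substitution count", {
  m <- mutate_seq("ACGTACGTAC", 20, seed = 5)
  diffs <- sum(strsplit(m, "")[[1]] != strsplit("ACGTACGTAC", "")[[1]])
  expect_equal(diffs, 2)
  expect_identical(mutate_seq("ACGTACGTAC", 0, seed = 5), "ACGTACGTAC")
})

test_that("mutated global identity tracks the requested divergence", {
  s <- htte:::random_dna(12000, 8)
  m <- mutate_seq(s, 14, seed = 9)
  h <- local_align(stats::setNames(m, "m"), stats::setNames(s, "s"),
                   align_params(xdrop = 60))
  expect_gte(nrow(h), 1)
  expect_equal(h$pct_identity[1], 86, tolerance = 0.5 / 86)
})

test_that("shred draws the expected number of uniform reads from both strands", {
  g <- htte:::random_dna(10000, 11)
  reads <- shred(g, read_len = 100, coverage = 1, seed = 2)
  expect_length(reads, 100)
  expect_identical(reads, shred(g, read_len = 100, coverage = 1, seed = 2))
  expect_false(identical(reads, shred(g, read_len = 100, coverage = 1,
                                      seed = 3)))
  # both strands are sampled
  fwd <- vapply(reads, function(r) grepl(r, g, fixed = TRUE), logical(1))
  expect_gt(sum(fwd), 20)
  expect_gt(sum(!fwd), 20)
})

test_that("shred start positions are uniform across the genome", {
  g <- htte:::random_dna(100000, 12)
  reads <- shred(g, read_len = 100, coverage = 10, seed = 4)
  rc <- revcomp(reads)
  starts <- vapply(seq_along(reads), function(i) {
    p <- regexpr(reads[[i]], g, fixed = TRUE)
    if (p < 0) p <- regexpr(rc[[i]], g, fixed = TRUE)
    as.integer(p)
  }, integer(1))
  counts <- table(cut(starts, breaks = seq(0, 100000, by = 5000)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("scenario truth is exact and complete, and outputs deterministic", {
  scen <- small_scenario()
  expect_equal(nrow(scen$truth), 1 + scen$config$n_amplified_copies)
  el <- substr(scen$recipient_genome[[1]], scen$truth$start[1],
               scen$truth$end[1])
  # planted copy diverged from the donor element by ht_divergence
  d <- 100 * p_distance(el, scen$te$seq)
  expect_equal(d, scen$config$ht_divergence, tolerance = 0.25)
  # TSD flanks the element
  expect_identical(detect_tsd(scen$recipient_genome[[1]],
                              c(scen$truth$start[1], scen$truth$end[1])),
                   scen$truth$tsd[1])
  scen2 <- build_ht_scenario(small_config())
  expect_identical(scen2$recipient_genome, scen$recipient_genome)
  expect_identical(scen2$donor_reads, scen$donor_reads)
})

test_that("amplified copies share high mutual identity with the first copy", {
  scen <- cached("amp_scenario", build_ht_scenario(
    small_config(seed = 202L, n_amplified_copies = 3L)))
  expect_equal(nrow(scen$truth), 4)
  seqs <- substring(scen$recipient_genome[[1]], scen$truth$start,
                    scen$truth$end)
  for (i in 2:4) {
    d <- p_distance(seqs[1], seqs[i])
    expect_lt(100 * d, 2)  # > 98% mutual identity
  }
})

test_that("planted element maps at high identity, background well below", {
  scen <- small_scenario()
  te_reads <- shred(scen$te$seq, 150, 2, seed = 77, prefix = "te")
  h <- local_align(te_reads, scen$recipient_genome)
  inside <- h$t_start >= scen$truth$start[1] & h$t_end <= scen$truth$end[1]
  expect_gt(mean(h$pct_identity[inside]), 97)
  calib <- calibrate_divergence(scen$donor_reads, scen$cds)
  expect_lt(calib$peak_bin, 90)
})
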