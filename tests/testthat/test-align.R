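test_that("local_align finds exact and reverse-complement matches", {
  t <- htte:::random_dna(2000, 7)
  q <- stats::setNames(substr(t, 501, 700), "q1")
  h <- local_align(q, stats::setNames(t, "t1"))
  expect_equal(nrow(h), 1)
  expect_equal(h$pct_identity, 100)
  expect_equal(h$aln_len, 200L)
  expect_equal(c(h$t_start, h$t_end), c(501L, 700L))
  expect_identical(h$strand, "+")

  q2 <- revcomp(q)
  names(q2) <- "q2"
  h2 <- local_align(q2, stats::setNames(t, "t1"))
  expect_equal(c(h2$t_start, h2$t_end), c(501L, 700L))
  expect_identical(h2$strand, "-")
})

test_that("three substitutions in a 150-bp query give 98.0% identity", {
  t <- htte:::random_dna(2000, 9)
  q <- substr(t, 101, 250)
  for (pos in c(30, 75, 120)) {
    cur <- substr(q, pos, pos)
    substr(q, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  h <- local_align(stats::setNames(q, "q"), stats::setNames(t, "t1"))
  expect_equal(h$aln_len, 150L)
  expect_equal(h$pct_identity, 98.0)
})

test_that("self-alignment of any sequence is a full-length 100% hit", {
  for (seed in c(1, 2, 3)) {
    s <- stats::setNames(htte:::random_dna(500, seed), "s")
    h <- local_align(s, s)
    expect_equal(h$pct_identity[1], 100)
    expect_equal(h$aln_len[1], 500L)
  }
})

test_that("hit identity is consistent with the recomputed alignment columns", {
  t <- htte:::random_dna(3000, 21)
  q <- mutate_seq(substr(t, 1001, 1500), 5, seed = 3)
  h <- local_align(stats::setNames(q, "q"), stats::setNames(t, "t"))
  sub_t <- substr(t, h$t_start, h$t_end)
  sub_q <- substr(q, h$q_start, h$q_end)
  mm <- sum(strsplit(sub_q, "")[[1]] != strsplit(sub_t, "")[[1]])
  expect_equal(h$pct_identity, 100 * (h$aln_len - mm) / h$aln_len,
               tolerance = 1e-9)
})

test_that("empty inputs give an empty hit table with a warning", {
  expect_warning(h <- local_align(character(0),
                                  stats::setNames("ACGT", "t")), "empty")
  expect_equal(nrow(h), 0)
})

test_that("k-mismatch mapper places reads up to the mismatch allowance", {
  t <- htte:::random_dna(5000, 13)
  r <- substr(t, 2001, 2050)
  r3 <- r; r4 <- r
  for (pos in c(5, 20, 40)) substr(r3, pos, pos) <-
      setdiff(c("A", "C", "G", "T"), substr(r3, pos, pos))[1]
  for (pos in c(5, 20, 40, 45)) substr(r4, pos, pos) <-
      setdiff(c("A", "C", "G", "T"), substr(r4, pos, pos))[1]
  h3 <- map_kmismatch(stats::setNames(r3, "r3"), stats::setNames(t, "t"), 3)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$pct_identity, 94.0)
  expect_equal(h3$t_start, 2001L)
  h4 <- map_kmismatch(stats::setNames(r4, "r4"), stats::setNames(t, "t"), 3)
  expect_equal(nrow(h4), 0)
  expect_equal(kmismatch_identity_floor(50, 3), 94.0)
})

test_that("k = 0 mapping equals exact substring search", {
  t <- htte:::random_dna(3000, 17)
  reads <- shred(t, 30, 1.5, seed = 5)
  h <- map_kmismatch(reads, stats::setNames(t, "t"), 0)
  rc <- revcomp(reads)
  for (i in seq_along(reads)) {
    expected <- grepl(reads[[i]], t, fixed = TRUE) ||
      grepl(rc[[i]], t, fixed = TRUE)
    expect_identical(names(reads)[i] %in% h$query_id, expected)
  }
})

test_that("k-mismatch mapper agrees with a brute-force sliding window", {
  t <- htte:::random_dna(2000, 19)
  tc <- strsplit(t, "")[[1]]
  reads <- with_seed_local(31, {
    r <- shred(t, 40, 0.5, seed = 31)
    vapply(r, function(x) mutate_seq(x, 7.5, sample.int(1e6, 1)),
           character(1))
  })
  names(reads) <- sprintf("r%02d", seq_along(reads))
  h <- map_kmismatch(reads, stats::setNames(t, "t"), 3)
  # brute force: all offsets, both strands
  brute <- list()
  for (i in seq_along(reads)) {
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") reads[[i]] else revcomp(reads[[i]])
      rcvec <- strsplit(rs, "")[[1]]
      for (s in 1:(2000 - 40 + 1)) {
        mm <- sum(rcvec != tc[s:(s + 39)])
        if (mm <= 3) {
          brute[[length(brute) + 1]] <-
            data.frame(query_id = names(reads)[i], t_start = s,
                       strand = strand, mismatches = mm,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  brute <- do.call(rbind, brute)
  got <- h[order(h$query_id, h$t_start, h$strand),
           c("query_id", "t_start", "strand", "mismatches")]
  want <- brute[order(brute$query_id, brute$t_start, brute$strand), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("best-nonoverlapping selection follows the greedy contract", {
  mk <- function(q, s, e, score, len = e - s + 1) {
    data.frame(query_id = q, target_id = "t", pct_identity = 99,
               aln_len = len, t_start = s, t_end = e, score = score,
               stringsAsFactors = FALSE)
  }
  # 80 bp overlap: only the higher-scoring hit survives
  h <- rbind(mk("a", 1, 150, 140), mk("b", 71, 220, 120))
  out <- select_best_nonoverlapping(h, min_len = 100, max_overlap = 75)
  expect_identical(out$query_id, "a")
  # exactly 75 bp overlap: both pass (inclusive bound)
  h <- rbind(mk("a", 1, 150, 140), mk("b", 76, 225, 120))
  out <- select_best_nonoverlapping(h, min_len = 100, max_overlap = 75)
  expect_setequal(out$query_id, c("a", "b"))
  # short hits are dropped before selection
  h <- rbind(mk("a", 1, 90, 200), mk("b", 200, 320, 80))
  out <- select_best_nonoverlapping(h, min_len = 100, max_overlap = 75)
  expect_identical(out$query_id, "b")
})

test_that("selection matches an independent greedy implementation on random sets", {
  greedy_oracle <- function(h, min_len, max_overlap) {
    h <- h[h$aln_len >= min_len, , drop = FALSE]
    h <- h[order(-h$score, -h$aln_len, h$t_start, h$query_id), , drop = FALSE]
    kept <- h[0, ]
    for (i in seq_len(nrow(h))) {
      ok <- TRUE
      for (j in seq_len(nrow(kept))) {
        ov <- min(h$t_end[i], kept$t_end[j]) -
          max(h$t_start[i], kept$t_start[j]) + 1
        if (ov > max_overlap) { ok <- FALSE; break }
      }
      if (ok) kept <- rbind(kept, h[i, ])
    }
    sort(kept$query_id)
  }
  for (seed in 1:10) {
    h <- with_seed_local(seed, {
      n <- 50
      s <- sample.int(2000, n, replace = TRUE)
      data.frame(query_id = sprintf("q%02d", 1:n), target_id = "t",
                 pct_identity = 95, aln_len = sample(80:300, n, TRUE),
                 t_start = s, score = sample(60:300, n, TRUE),
                 stringsAsFactors = FALSE)
    })
    h$t_end <- h$t_start + h$aln_len - 1L
    got <- select_best_nonoverlapping(h, 100, 75)
    expect_identical(sort(got$query_id), greedy_oracle(h, 100, 75))
    # pairwise overlaps of the output respect the bound
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) {
        for (j in (i + 1):nrow(got)) {
          ov <- min(got$t_end[i], got$t_end[j]) -
            max(got$t_start[i], got$t_start[j]) + 1
          expect_lte(ov, 75)
        }
      }
    }
    expect_true(all(got$aln_len >= 100))
  }
})
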