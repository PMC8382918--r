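test_that("p-distance counts mismatches over retained columns", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)
  expect_equal(p_distance("ACNT", "ACGT"), 0)  # N columns excluded too
  expect_error(p_distance("----", "ACGT"), "no retained columns")
  expect_error(p_distance("ACG", "ACGT"), "aligned")
})

test_that("p-distance equals a brute-force column count on random pairs", {
  for (seed in 1:25) {
    pair <- with_seed_local(seed, {
      n <- sample(50:200, 1)
      a <- strsplit(htte:::random_dna(n), "")[[1]]
      b <- strsplit(htte:::random_dna(n), "")[[1]]
      gaps <- sample(n, round(n * 0.1))
      a[sample(gaps, length(gaps) %/% 2)] <- "-"
      b[sample(n, 5)] <- "N"
      list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
    })
    av <- strsplit(pair$a, "")[[1]]; bv <- strsplit(pair$b, "")[[1]]
    keep <- !(av %in% c("-", "N")) & !(bv %in% c("-", "N"))
    expect_equal(p_distance(pair$a, pair$b),
                 sum(av[keep] != bv[keep]) / sum(keep))
  }
})

test_that("neighbor joining is exact on additive matrices", {
  # tree ((a:1,b:2):1,c:3,d:4) gives an additive distance matrix
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- 3; dm["a", "c"] <- 5; dm["a", "d"] <- 6
  dm["b", "c"] <- 6; dm["b", "d"] <- 7; dm["c", "d"] <- 7
  dm <- dm + t(dm)
  tr <- nj_tree(dm)
  path <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(path, dm, tolerance = 1e-9)
  # the ab|cd split is recovered
  expect_identical(nesting_test(tr, c("a", "b"), c("c", "d")), "not_nested")

  # three taxa: closed-form star lengths
  dm3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(dm3)
  path3 <- ape::cophenetic.phylo(tr3)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(path3, dm3, tolerance = 1e-9)
  expect_error(nj_tree(dm3[1:2, 1:2]), "at least 3")
})

test_that("NJ topology is invariant to label permutations", {
  dm <- with_seed_local(5, {
    n <- 8
    pts <- matrix(stats::runif(2 * n), n)
    m <- as.matrix(stats::dist(pts))
    dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
    m
  })
  t1 <- nj_tree(dm)
  perm <- with_seed_local(6, sample(8))
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2)[1], 0)
})

test_that("nesting verdicts match the canonical topologies", {
  t1 <- ape::read.tree(text = "((D1,(D2,(R1,R2))),D3);")
  expect_identical(nesting_test(t1, c("D1", "D2", "D3"), c("R1", "R2")),
                   "recipient_nested_in_donor")
  t2 <- ape::read.tree(text = "((D1,D2),(R1,R2));")
  expect_identical(nesting_test(t2, c("D1", "D2"), c("R1", "R2")),
                   "not_nested")
  t3 <- ape::read.tree(text = "((R1,(R2,(D1,D2))),R3);")
  expect_identical(nesting_test(t3, c("D1", "D2"), c("R1", "R2", "R3")),
                   "donor_nested_in_recipient")
  expect_error(nesting_test(t1, c("D1", "D9"), c("R1", "R2")), "missing")
})

test_that("simulated transfers show recipient-nested-in-donor trees", {
  # donor family diversified before one lineage crossed into the
  # recipient and amplified there
  n_ok <- 0L
  n_sim <- 30L
  for (seed in seq_len(n_sim)) {
    fam <- with_seed_local(7000 + seed, {
      anc <- htte:::random_dna(800)
      donors <- lapply(1:4, function(i) {
        mutate_seq(anc, 6, sample.int(1e6, 1))
      })
      transferred <- mutate_seq(donors[[4]], 1, sample.int(1e6, 1))
      recips <- lapply(1:3, function(i) {
        mutate_seq(transferred, 1, sample.int(1e6, 1))
      })
      c(stats::setNames(donors, paste0("D", 1:4)),
        stats::setNames(recips, paste0("R", 1:3)))
    })
    aligned <- unlist(fam)  # substitution-only: already aligned
    dm <- p_distance_matrix(aligned)
    # tied distances occasionally produce tiny negative NJ branches,
    # which nj_tree clamps with a warning
    tr <- suppressWarnings(nj_tree(dm))
    v <- nesting_test(tr, paste0("D", 1:4), paste0("R", 1:3))
    if (v == "recipient_nested_in_donor") n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_sim, 0.95)
})

test_that("UPGMA reproduces the hand-computed merge heights", {
  dm <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- upgma_history(dm)
  expect_equal(h$node_heights, c(1, 4))
  expect_equal(h$merge_distances, c(2, 8))
  expect_equal(unname(h$histogram[c("1", "4")]), c(1L, 1L))
  # raw-distance convention on request
  h2 <- upgma_history(dm, halve = FALSE)
  expect_equal(h2$node_heights, c(2, 8))
  expect_error(upgma_history(dm[1, 1, drop = FALSE]), "at least 2")
})

test_that("identical sequences collapse at height zero", {
  seqs <- stats::setNames(rep(htte:::random_dna(300, 3), 5), paste0("s", 1:5))
  dm <- 100 * p_distance_matrix(seqs)
  h <- upgma_history(dm)
  expect_equal(h$node_heights, rep(0, 4))
  expect_equal(unname(h$histogram["0"]), 4L)
})

test_that("UPGMA heights are monotone and the histogram sums to n - 1", {
  for (seed in 1:10) {
    dm <- with_seed_local(seed, {
      n <- sample(4:12, 1)
      pts <- matrix(stats::runif(n * 3) * 20, n)
      m <- as.matrix(stats::dist(pts))
      dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
      m
    })
    h <- upgma_history(dm)
    expect_true(all(diff(h$node_heights) >= -1e-12))
    expect_equal(sum(h$histogram), nrow(dm) - 1L)
  }
})

test_that("an amplification burst gives a unimodal low-divergence profile", {
  fam <- with_seed_local(909, {
    anc <- htte:::random_dna(600)
    lapply(1:8, function(i) mutate_seq(anc, 2, sample.int(1e6, 1)))
  })
  seqs <- stats::setNames(unlist(fam), paste0("c", 1:8))
  dm <- identity_distance_matrix(seqs)
  h <- upgma_history(dm)
  # copies diverged ~2% from the ancestor: pairwise ~4%, heights ~2%
  n_low <- sum(h$histogram[as.character(1:2)])
  expect_gte(n_low, sum(h$histogram) / 2)
  expect_equal(sum(h$histogram), 7L)
})

test_that("alignment to the longest member projects sequences consistently", {
  base <- htte:::random_dna(400, 50)
  seqs <- c(long = base,
            sub1 = mutate_seq(substr(base, 51, 350), 2, 51),
            sub2 = substr(base, 101, 400))
  al <- align_to_reference(seqs)
  expect_true(all(nchar(al) == 400))
  expect_identical(al[["long"]], base)
  expect_lt(p_distance(al[["sub1"]], al[["long"]]), 0.04)
})
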