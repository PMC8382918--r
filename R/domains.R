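# The 20 standard amino acids, alphabetical.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.pkg_cache <- new.env(parent = emptyenv())

# One fixed codon per amino acid (first codon of the standard genetic code
# in alphabetical order), used by the simulator to encode domain peptides.
aa2codon <- function() {
  if (is.null(.pkg_cache$aa2codon)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[order(names(gc))]
    .pkg_cache$aa2codon <- vapply(AA_ALPHABET, function(a) {
      names(gc)[gc == a][1]
    }, character(1))
  }
  .pkg_cache$aa2codon
}

# Translate one frame of a DNA string; codons with ambiguous bases give "X".
translate_frame <- function(dna, frame) {
  n <- nchar(dna)
  if (n - frame + 1L < 3L) return("")
  starts <- seq.int(frame, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a DNA sequence in all six reading frames
#'
#' @param dna A DNA string.
#' @return Named character vector of amino-acid strings for frames
#'   `+1, +2, +3, -1, -2, -3` (stops as `*`, ambiguous codons as `X`).
#' @export
translate_six_frames <- function(dna) {
  dna <- toupper(as.character(dna)[1])
  rc <- .revcomp_cpp(dna)
  out <- c(vapply(1:3, function(f) translate_frame(dna, f), character(1)),
           vapply(1:3, function(f) translate_frame(rc, f), character(1)))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Build a position-specific score matrix from aligned domain sequences
#'
#' Columns with more than 50% gaps are dropped; remaining columns are
#' scored as log2 odds of the observed residue frequency (with an
#' additive pseudocount toward the uniform background) over the uniform
#' background. As the pseudocount grows, all scores shrink to 0.
#'
#' @param aligned_seqs Character vector (>= 2) of equal-length aligned
#'   amino-acid sequences; `-` marks gaps.
#' @param pseudocount Additive pseudocount (> 0).
#' @param name Profile name (e.g. `"RT"`).
#' @return A `pssm_profile` list with elements `name`, `matrix`
#'   (21 x L score matrix, rows = amino acids plus `X` scored 0),
#'   `length`, and `threshold` (bits; `NA` until calibrated with
#'   [calibrate_threshold()]).
#' @export
build_profile <- function(aligned_seqs, pseudocount = 1, name = "profile") {
  stopifnot(length(aligned_seqs) >= 2L, pseudocount > 0)
  lens <- nchar(aligned_seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length")
  }
  m <- do.call(rbind, strsplit(toupper(aligned_seqs), ""))
  gap_frac <- colMeans(m == "-")
  m <- m[, gap_frac <= 0.5, drop = FALSE]
  L <- ncol(m)
  q <- 1 / length(AA_ALPHABET)
  scores <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    n <- length(col)
    counts <- table(factor(col, levels = AA_ALPHABET))
    freq <- (as.numeric(counts) + pseudocount * q) / (n + pseudocount)
    log2(freq / q)
  }, numeric(length(AA_ALPHABET)))
  rownames(scores) <- AA_ALPHABET
  scores <- rbind(scores, X = 0)
  structure(list(name = name, matrix = scores, length = L, threshold = NA_real_),
            class = "pssm_profile")
}

# Score all placements of an amino-acid string against a profile.
# Returns best score, the shift achieving it (profile position aligned to
# residue 1 is `1 - shift`), and whether any placement was valid.
# With the default stop_penalty (-Inf) any placement whose overlap
# contains a stop codon is discarded (appropriate for reads); a finite
# penalty instead docks the score per stop, which tolerates the premature
# stops accumulating in decaying genomic elements.
score_placements <- function(aa, profile, min_overlap,
                             stop_penalty = -Inf) {
  M <- profile$matrix
  L <- profile$length
  ch <- strsplit(aa, "")[[1]]
  m <- length(ch)
  if (m < min_overlap) return(list(score = -Inf, shift = NA_integer_))
  idx <- match(ch, rownames(M))          # NA for stops
  stop_pos <- ch == "*"
  idx[is.na(idx)] <- match("X", rownames(M))
  # D[sh + m] accumulates the score of shift sh (profile pos = read pos + sh)
  D <- numeric(L + m - 1L)
  S <- numeric(L + m - 1L)               # stop counts per shift
  for (i in seq_len(m)) {
    at <- seq_len(L) - i + m
    D[at] <- D[at] + M[idx[i], ]
    if (stop_pos[i]) S[at] <- S[at] + 1
  }
  sh <- seq.int(1L - m, L - 1L)
  overlap <- pmin(L, m + sh) - pmax(1L, 1L + sh) + 1L
  if (is.infinite(stop_penalty)) {
    valid <- overlap >= min_overlap & S == 0
  } else {
    valid <- overlap >= min_overlap
    D <- D + stop_penalty * S
  }
  if (!any(valid)) return(list(score = -Inf, shift = NA_integer_))
  D[!valid] <- -Inf
  best <- which.max(D)
  list(score = D[best], shift = sh[best])
}

#' Calibrate a profile detection threshold on random sequence
#'
#' Sets the profile threshold to the `1 - fpr` quantile of best scan
#' scores over random DNA reads, so that scanning unrelated sequence
#' triggers at most at the requested false-positive rate.
#'
#' @param profile A [build_profile()] result.
#' @param read_len Read length (bp) of the calibration reads.
#' @param n Number of random reads.
#' @param fpr Target false-positive rate.
#' @param min_overlap Minimum profile/read overlap (amino acids).
#' @param seed Integer seed.
#' @return The profile with `threshold` set (bits).
#' @export
calibrate_threshold <- function(profile, read_len = 150L, n = 2000L,
                                fpr = 0.001, min_overlap = 25L, seed = 99L) {
  scores <- with_seed(seed, {
    reads <- vapply(seq_len(n), function(i) random_dna(read_len), character(1))
    vapply(reads, function(r) {
      best <- -Inf
      for (aa in translate_six_frames(r)) {
        s <- score_placements(aa, profile, min_overlap)$score
        if (s > best) best <- s
      }
      best
    }, numeric(1))
  })
  scores <- scores[is.finite(scores)]
  profile$threshold <- as.numeric(stats::quantile(scores, 1 - fpr, type = 8))
  profile
}

#' Default synthetic domain profiles
#'
#' PSSM profiles for the five canonical LTR-retrotransposon domains, built
#' from simulated variants of the synthetic domain consensus sequences
#' used by [make_te()], with thresholds calibrated on random reads. These
#' are synthetic stand-ins that match the simulator; profiles derived from
#' curated domain alignments should be supplied for real data.
#'
#' @param n_variants Training sequences per profile.
#' @param aa_divergence Percent amino-acid divergence of the variants.
#' @return Named list of calibrated `pssm_profile` objects.
#' @export
default_profiles <- function(n_variants = 10L, aa_divergence = 5) {
  key <- sprintf("profiles_%d_%g", n_variants, aa_divergence)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  cons <- domain_consensus()
  profs <- lapply(names(cons), function(d) {
    variants <- vapply(seq_len(n_variants), function(i) {
      mutate_aa(cons[[d]], aa_divergence, seed = 7000L + 13L * i)
    }, character(1))
    p <- build_profile(variants, pseudocount = 1, name = d)
    calibrate_threshold(p)
  })
  names(profs) <- names(cons)
  .pkg_cache[[key]] <- profs
  profs
}

# Substitution-only mutation of an amino-acid string.
mutate_aa <- function(aa, divergence_pct, seed = 1L) {
  ch <- strsplit(aa, "")[[1]]
  k <- round(divergence_pct / 100 * length(ch))
  if (k == 0L) return(aa)
  with_seed(seed, {
    pos <- sample.int(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(x) {
      sample(setdiff(AA_ALPHABET, x), 1L)
    }, character(1))
    paste(ch, collapse = "")
  })
}

#' Scan reads for a protein domain with a PSSM profile
#'
#' Each read is translated in all six frames and every
#' profile-vs-translation placement with at least `min_overlap` aligned
#' residues is scored; placements containing a stop codon are discarded.
#' A read is detected when its best score reaches the profile threshold.
#' Detection is invariant under reverse complementation of the read.
#'
#' @param reads Named character vector of DNA reads.
#' @param profile A calibrated `pssm_profile`.
#' @param min_overlap Minimum profile/read overlap (amino acids).
#' @return Data frame with `read_id`, `frame`, `bit_score`, `detected`.
#' @export
scan_reads <- function(reads, profile, min_overlap = 25L) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (is.na(profile$threshold)) {
    stop("profile threshold not calibrated; see calibrate_threshold()")
  }
  res <- lapply(seq_along(reads), function(i) {
    best <- -Inf; bframe <- NA_character_
    frames <- translate_six_frames(reads[[i]])
    for (fr in names(frames)) {
      s <- score_placements(frames[[fr]], profile, min_overlap)$score
      if (s > best) { best <- s; bframe <- fr }
    }
    data.frame(read_id = names(reads)[i], frame = bframe, bit_score = best,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$detected <- is.finite(out$bit_score) &
    out$bit_score >= profile$threshold
  out
}

# Locate up to `max_hits` nonoverlapping placements of a profile on a
# contig; returns genomic intervals of placements scoring >= threshold.
scan_contig <- function(contig, profile, min_overlap = NULL,
                        max_hits = 3L, stop_penalty = -8) {
  if (is.null(min_overlap)) min_overlap <- profile$length
  n <- nchar(contig)
  frames <- translate_six_frames(contig)
  hits <- NULL
  for (fi in seq_along(frames)) {
    aa <- frames[[fi]]
    m <- nchar(aa)
    if (m < min_overlap) next
    fname <- names(frames)[fi]
    masked <- aa
    for (h in seq_len(max_hits)) {
      pl <- score_placements(masked, profile, min_overlap, stop_penalty)
      if (!is.finite(pl$score) || pl$score < profile$threshold) break
      i1 <- max(1L, 1L - pl$shift)               # first aligned residue
      i2 <- min(m, profile$length - pl$shift)    # last aligned residue
      f <- as.integer(substr(fname, 2L, 2L))
      if (startsWith(fname, "+")) {
        g1 <- f + 3L * (i1 - 1L)
        g2 <- f + 3L * (i2 - 1L) + 2L
      } else {
        g1 <- n - (f + 3L * (i2 - 1L) + 2L) + 1L
        g2 <- n - (f + 3L * (i1 - 1L)) + 1L
      }
      hits <- rbind(hits, data.frame(start = g1, end = g2, frame = fname,
                                     bit_score = pl$score,
                                     stringsAsFactors = FALSE))
      # mask the found placement with stops and rescan
      substr(masked, i1, i2) <- strrep("*", i2 - i1 + 1L)
    }
  }
  hits
}

#' Annotate LTR-retrotransposon structure on a contig
#'
#' Domain placements come from PSSM scans of the six translated frames;
#' the LTR pair is found by ungapped self-comparison of the contig (a
#' direct repeat of at least `min_ltr_len` bp at `min_ltr_identity`
#' percent identity or better, flanking the domain block). Element
#' boundaries are the outer LTR edges. Missing domains are permitted; an
#' element with domains but no detectable LTR pair is reported with the
#' domain-block extent and flagged incomplete.
#'
#' @param contig A DNA string (>= 1 kb makes sense).
#' @param profiles Named list of calibrated profiles
#'   (default [default_profiles()]).
#' @param min_ltr_len Minimum LTR repeat length (bp).
#' @param min_ltr_identity Minimum LTR repeat identity (percent).
#' @param contig_id Id used in the output intervals.
#' @return Interval data frame with rows of kind `TE` (the element; label
#'   `"complete"` or `"incomplete"`), `LTR` and `domain`; empty (0 rows)
#'   if nothing is found.
#' @export
annotate_te <- function(contig, profiles = default_profiles(),
                        min_ltr_len = 100L, min_ltr_identity = 85,
                        contig_id = "contig") {
  contig <- toupper(as.character(contig)[1])
  dom <- NULL
  for (pname in names(profiles)) {
    h <- scan_contig(contig, profiles[[pname]])
    if (!is.null(h) && nrow(h) > 0L) {
      dom <- rbind(dom, cbind(intervals(contig_id, h$start, h$end,
                                        "domain", pname),
                              bit_score = h$bit_score))
    }
  }
  empty <- intervals(character(0), integer(0), integer(0), character(0))
  if (is.null(dom) || nrow(dom) == 0L) return(empty)
  dom <- dom[order(dom$start), , drop = FALSE]
  block_start <- min(dom$start); block_end <- max(dom$end)

  # direct-repeat search by self-comparison
  p <- align_params(single_hsp = FALSE, min_score = min_ltr_len / 2,
                    trim = TRUE)
  sh <- local_align(stats::setNames(contig, contig_id),
                    stats::setNames(contig, contig_id),
                    p, exclude_self = TRUE)
  sh <- sh[sh$strand == "+" & sh$aln_len >= min_ltr_len &
             sh$pct_identity >= min_ltr_identity &
             sh$q_end < sh$t_start, , drop = FALSE]
  # keep repeats flanking the domain block
  sh <- sh[sh$q_end <= block_start & sh$t_start >= block_end, , drop = FALSE]
  out <- NULL
  if (nrow(sh) > 0L) {
    best <- sh[order(-sh$score, sh$q_start), , drop = FALSE][1L, ]
    # refine edges to the canonical TG...CA termini within a few bp: the
    # repeat extension can over/undershoot by a base when flank bases
    # coincidentally match
    el_start <- best$q_start; el_end <- best$t_end
    for (d in order(abs(-3:3))) {
      p <- el_start + (-3:3)[d]
      if (p >= 1L && substr(contig, p, p + 1L) == "TG") {
        el_start <- p
        break
      }
    }
    for (d in order(abs(-3:3))) {
      p <- el_end + (-3:3)[d]
      if (p <= nchar(contig) && substr(contig, p - 1L, p) == "CA") {
        el_end <- p
        break
      }
    }
    el <- intervals(contig_id, el_start, el_end, "TE", "complete")
    ltrs <- rbind(intervals(contig_id, el_start,
                            el_start + (best$q_end - best$q_start), "LTR",
                            "LTR5"),
                  intervals(contig_id, el_end - (best$t_end - best$t_start),
                            el_end, "LTR", "LTR3"))
    out <- rbind(el, ltrs)
  } else {
    out <- intervals(contig_id, block_start, block_end, "TE", "incomplete")
  }
  out$bit_score <- NA_real_
  rbind(out, dom)
}
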