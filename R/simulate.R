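#' Simulation configuration for a horizontal-transfer scenario
#'
#' Describes a pair of genomes that diverged vertically from a common
#' ancestor, with one LTR-retrotransposon copied across the species barrier
#' at a much lower divergence, optional post-transfer amplification in the
#' recipient, and low-depth single-end read sampling of the donor genome.
#' Defaults emulate the study conditions of the panicoid/rice screens:
#' an 86% identity orthologous background (14% vertical divergence),
#' recent transfer (1.5% divergence), ~151 bp single-end reads at ~2.3x
#' coverage.
#'
#' @param seed Integer seed; all randomness in the scenario derives from it.
#' @param genome_len Genome length in bp.
#' @param vertical_divergence Percent divergence between the orthologous
#'   backgrounds of donor and recipient.
#' @param ht_divergence Percent divergence accumulated by the transferred
#'   element since the transfer.
#' @param te_len Total element length (bp), LTRs included.
#' @param ltr_len Length of each long terminal repeat (bp).
#' @param tsd_len Target-site duplication length (bp, 4-6 typical for
#'   LTR-retrotransposon integrases).
#' @param n_amplified_copies Number of additional post-transfer copies in
#'   the recipient genome.
#' @param read_len Read length for donor shotgun reads (bp).
#' @param coverage Fold coverage of the donor genome by reads.
#' @param indel_rate Reserved; the core mutation model is substitution-only
#'   and this must currently be 0.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_len = 100000L,
                       vertical_divergence = 14, ht_divergence = 1.5,
                       te_len = 5000L, ltr_len = 300L, tsd_len = 5L,
                       n_amplified_copies = 0L, read_len = 150L,
                       coverage = 2.3, indel_rate = 0) {
  stopifnot(vertical_divergence >= 0, vertical_divergence <= 100,
            ht_divergence >= 0, ht_divergence <= 100,
            2L * ltr_len < te_len, tsd_len >= 0L,
            n_amplified_copies >= 0L, read_len >= 20L, coverage > 0,
            indel_rate == 0)
  structure(list(seed = as.integer(seed), genome_len = as.integer(genome_len),
                 vertical_divergence = vertical_divergence,
                 ht_divergence = ht_divergence, te_len = as.integer(te_len),
                 ltr_len = as.integer(ltr_len), tsd_len = as.integer(tsd_len),
                 n_amplified_copies = as.integer(n_amplified_copies),
                 read_len = as.integer(read_len), coverage = coverage,
                 indel_rate = indel_rate),
            class = "sim_config")
}

# Uniform random DNA string (no N).
random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Length of the amino-acid consensus used for each synthetic pol/gag domain.
DOMAIN_AA_LEN <- 120L
DOMAIN_NAMES <- c("gag", "AP", "IN", "RT", "RH")

# Fixed synthetic amino-acid consensus for the five canonical
# LTR-retrotransposon domains (gag, aspartic protease, integrase, reverse
# transcriptase, RNase H). The RT consensus carries the conserved YxDD
# catalytic motif (as YVDD). These are synthetic stand-ins for curated
# domain profiles; real profiles can be supplied instead.
domain_consensus <- function() {
  cons <- with_seed(990137L, {
    out <- lapply(DOMAIN_NAMES, function(d) {
      paste(sample(AA_ALPHABET, DOMAIN_AA_LEN, replace = TRUE), collapse = "")
    })
    names(out) <- DOMAIN_NAMES
    out
  })
  cons <- unlist(cons)
  # plant the YxDD motif in the middle of the RT consensus
  substr(cons[["RT"]], 60L, 63L) <- "YVDD"
  cons
}

# Encode an amino-acid string as DNA using one fixed codon per residue.
encode_peptide <- function(aa) {
  paste(aa2codon()[strsplit(aa, "")[[1]]], collapse = "")
}

#' Build a synthetic LTR-retrotransposon
#'
#' The element is LTR + internal region + LTR with the two LTRs identical
#' at creation, each beginning `TG` and ending `CA`. The internal region
#' carries the five canonical coding domains (gag, AP, IN, RT, RH) in
#' standard order, encoded from fixed synthetic amino-acid consensus
#' sequences, the RT including the conserved YxDD motif.
#'
#' @param te_len Total element length in bp.
#' @param ltr_len LTR length in bp (>= 10).
#' @param seed Integer seed.
#' @return A list with `seq` (element sequence), `annotations` (interval
#'   table of LTRs and domains in element coordinates) and `domains`
#'   (named DNA sequences of the five domains).
#' @export
make_te <- function(te_len, ltr_len, seed = 1L) {
  te_len <- as.integer(te_len); ltr_len <- as.integer(ltr_len)
  if (ltr_len < 10L) stop("ltr_len must be >= 10")
  internal_len <- te_len - 2L * ltr_len
  dom_nt <- 3L * DOMAIN_AA_LEN
  need <- 5L * dom_nt + 6L * 10L
  if (internal_len < need) {
    stop("te_len too small: internal region must hold the five coding ",
         "domains (need >= ", need + 2L * ltr_len, " bp)")
  }
  cons <- domain_consensus()
  dom_dna <- vapply(cons, encode_peptide, character(1))
  with_seed(seed, {
    ltr <- random_dna(ltr_len)
    substr(ltr, 1L, 2L) <- "TG"
    substr(ltr, ltr_len - 1L, ltr_len) <- "CA"
    internal <- random_dna(internal_len)
    gap <- (internal_len - 5L * dom_nt) %/% 6L
    ann <- list()
    for (i in seq_along(DOMAIN_NAMES)) {
      off <- i * gap + (i - 1L) * dom_nt  # 0-based offset within internal
      substr(internal, off + 1L, off + dom_nt) <- dom_dna[[i]]
      ann[[i]] <- c(start = ltr_len + off + 1L, end = ltr_len + off + dom_nt)
    }
    seq <- paste0(ltr, internal, ltr)
    annotations <- rbind(
      intervals("te", 1L, ltr_len, "LTR", "LTR5"),
      intervals("te", te_len - ltr_len + 1L, te_len, "LTR", "LTR3"),
      do.call(rbind, lapply(seq_along(DOMAIN_NAMES), function(i) {
        intervals("te", ann[[i]]["start"], ann[[i]]["end"], "domain",
                  DOMAIN_NAMES[i])
      })))
    list(seq = seq, annotations = annotations,
         domains = stats::setNames(dom_dna, DOMAIN_NAMES))
  })
}

#' Insert a transposable element into a genome with a target-site duplication
#'
#' The `tsd_len` bases at `[pos, pos + tsd_len - 1]` are duplicated so that
#' identical copies flank the inserted element, as an integrase would leave
#' behind. Output length is input length + element length + `tsd_len`.
#'
#' @param genome A single DNA string (possibly named).
#' @param te Element sequence (string) or the result of [make_te()].
#' @param pos 1-based insertion position (start of the target site).
#' @param tsd_len Target-site duplication length (0 for a blunt insertion).
#' @return A list with `seq` (the new genome), `element` (1-based inclusive
#'   element interval in the new coordinates) and `tsd` (the duplicated
#'   sequence, `""` if `tsd_len == 0`).
#' @export
insert_te <- function(genome, te, pos, tsd_len = 5L) {
  if (is.list(te)) te <- te$seq
  g <- as.character(genome)[1]
  n <- nchar(g); pos <- as.integer(pos); tsd_len <- as.integer(tsd_len)
  if (pos < 1L || pos > n) stop("pos out of range")
  if (pos + tsd_len - 1L > n) stop("pos within tsd_len of the contig end")
  tsd <- if (tsd_len > 0L) substr(g, pos, pos + tsd_len - 1L) else ""
  left <- substr(g, 1L, pos + tsd_len - 1L)
  right <- substr(g, pos + tsd_len, n)
  el_start <- nchar(left) + 1L
  el_end <- el_start + nchar(te) - 1L
  list(seq = paste0(left, te, tsd, right),
       element = c(start = el_start, end = el_end),
       tsd = tsd)
}

#' Mutate a sequence to an exact percent divergence
#'
#' Substitution-only: exactly `round(divergence_pct / 100 * len)` positions,
#' drawn without replacement, are substituted with a different base, so the
#' realized divergence matches the requested one up to rounding.
#'
#' @param seq A DNA string.
#' @param divergence_pct Percent of positions to substitute, in \[0, 100\].
#' @param seed Integer seed.
#' @return The mutated DNA string.
#' @export
mutate_seq <- function(seq, divergence_pct, seed = 1L) {
  stopifnot(divergence_pct >= 0, divergence_pct <= 100)
  s <- as.character(seq)[1]
  n <- nchar(s)
  k <- round(divergence_pct / 100 * n)
  if (k == 0L) return(s)
  with_seed(seed, {
    b <- strsplit(s, "")[[1]]
    pos <- sample.int(n, k)
    # row = original base, columns = the three alternative bases
    alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    row <- match(b[pos], rownames(alt))
    pick <- sample.int(3L, k, replace = TRUE)
    new <- alt[cbind(row, pick)]
    # non-ACGT (N) positions get a uniform random base
    new[is.na(row)] <- sample(c("A", "C", "G", "T"), sum(is.na(row)),
                              replace = TRUE)
    b[pos] <- new
    paste(b, collapse = "")
  })
}

#' Shred a genome into uniform single-end reads
#'
#' `round(coverage * len / read_len)` reads are drawn with uniform start
#' positions; each read comes from either strand with probability 0.5
#' (minus-strand reads are reverse-complemented).
#'
#' @param genome A single DNA string.
#' @param read_len Read length in bp.
#' @param coverage Fold coverage.
#' @param seed Integer seed.
#' @param prefix Read-id prefix.
#' @return Named character vector of reads.
#' @export
shred <- function(genome, read_len = 150L, coverage = 2.3, seed = 1L,
                  prefix = "read") {
  g <- as.character(genome)[1]
  n <- nchar(g); read_len <- as.integer(read_len)
  if (read_len > n) stop("read_len exceeds genome length")
  n_reads <- round(coverage * n / read_len)
  with_seed(seed, {
    starts <- sample.int(n - read_len + 1L, n_reads, replace = TRUE)
    minus <- stats::runif(n_reads) < 0.5
    reads <- substring(g, starts, starts + read_len - 1L)
    reads[minus] <- .revcomp_cpp(reads[minus])
    names(reads) <- sprintf("%s%06d", prefix, seq_len(n_reads))
    reads
  })
}

#' Build a complete synthetic horizontal-transfer scenario
#'
#' Constructs a donor and a recipient genome that diverged vertically from
#' a shared ancestor, plants one LTR-retrotransposon in the donor and a
#' recently transferred copy (plus optional amplified copies) in the
#' recipient, extracts a panel of CDS-like calibration windows from the
#' recipient, and shreds the donor genome into sample reads. All truth
#' coordinates are exact.
#'
#' @param config A [sim_config()].
#' @param plant_ht If `FALSE`, no copy is transferred to the recipient
#'   (vertical-divergence-only negative control; the donor still carries
#'   its resident element).
#' @param n_cds Number of CDS-like calibration windows to cut from the
#'   recipient genome.
#' @param cds_len Length of each calibration window (bp).
#' @return A list with elements `config`, `donor_genome`,
#'   `recipient_genome` (named single-contig character vectors),
#'   `donor_reads`, `cds` (named character vector of recipient windows),
#'   `te` (the [make_te()] result), `rt_seq` (donor RT domain DNA),
#'   `donor_element` (interval in the donor contig) and `truth` (interval
#'   table of planted elements in the recipient, one row per copy, with the
#'   planted TSD recorded in the `tsd` column).
#' @export
build_ht_scenario <- function(config = sim_config(), plant_ht = TRUE,
                              n_cds = 40L, cds_len = 1500L) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$seed
  ancestor <- random_dna(config$genome_len, derive_seed(s, "ancestor"))
  donor <- mutate_seq(ancestor, config$vertical_divergence,
                      derive_seed(s, "donor_divergence"))
  te <- make_te(config$te_len, config$ltr_len, derive_seed(s, "te"))

  # insertion sites keep a margin from contig ends and existing copies
  pick_pos <- function(len, seed, avoid = NULL) {
    margin <- max(1000L, min(6000L, len %/% 12L))
    cand <- seq.int(margin, len - margin)
    if (!is.null(avoid) && nrow(avoid) > 0L) {
      ok <- rep(TRUE, length(cand))
      for (r in seq_len(nrow(avoid))) {
        ok <- ok & (cand < avoid$start[r] - margin |
                      cand > avoid$end[r] + margin)
      }
      cand <- cand[ok]
    }
    if (length(cand) == 0L) {
      stop("genome too small to place another element copy")
    }
    with_seed(seed, cand[sample.int(length(cand), 1L)])
  }

  dpos <- pick_pos(nchar(donor), derive_seed(s, "donor_pos"))
  dins <- insert_te(donor, te$seq, dpos, config$tsd_len)
  donor_genome <- stats::setNames(dins$seq, "donor_chr1")

  recipient <- ancestor
  truth <- NULL
  if (plant_ht) {
    te_ht <- mutate_seq(te$seq, config$ht_divergence,
                        derive_seed(s, "ht_divergence"))
    copies <- c(list(te_ht), lapply(seq_len(config$n_amplified_copies),
      function(i) mutate_seq(te_ht, 0.5, derive_seed(s, paste0("amp", i)))))
    for (i in seq_along(copies)) {
      pos <- pick_pos(nchar(recipient), derive_seed(s, paste0("rpos", i)),
                      avoid = truth)
      ins <- insert_te(recipient, copies[[i]], pos, config$tsd_len)
      recipient <- ins$seq
      shift <- nchar(copies[[i]]) + config$tsd_len
      if (!is.null(truth)) {
        # shift already-placed copies lying downstream of this insertion
        after <- truth$start > ins$element[["start"]]
        truth$start[after] <- truth$start[after] + shift
        truth$end[after] <- truth$end[after] + shift
      }
      tr <- intervals("recip_chr1", ins$element[["start"]],
                      ins$element[["end"]], "TE", sprintf("ht_copy%d", i))
      tr$tsd <- ins$tsd
      truth <- rbind(truth, tr)
    }
  }
  recipient_genome <- stats::setNames(recipient, "recip_chr1")

  # CDS-like calibration windows from the recipient, away from planted TEs
  starts <- seq(2000L, nchar(recipient) - cds_len - 2000L, by = cds_len + 500L)
  if (!is.null(truth)) {
    ok <- vapply(starts, function(p) {
      all(p + cds_len - 1L < truth$start - 1000L | p > truth$end + 1000L)
    }, logical(1))
    starts <- starts[ok]
  }
  starts <- utils::head(starts, n_cds)
  cds <- substring(recipient, starts, starts + cds_len - 1L)
  names(cds) <- sprintf("cds%03d", seq_along(starts))

  donor_reads <- shred(donor_genome, config$read_len, config$coverage,
                       derive_seed(s, "shred"), prefix = "donor_read")

  rt_iv <- te$annotations[te$annotations$label == "RT", ]
  rt_seq <- stats::setNames(substr(te$seq, rt_iv$start, rt_iv$end), "donor_RT")

  list(config = config, donor_genome = donor_genome,
       recipient_genome = recipient_genome, donor_reads = donor_reads,
       cds = cds, te = te, rt_seq = rt_seq,
       donor_element = dins$element, truth = truth)
}
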