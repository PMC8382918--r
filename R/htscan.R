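# Extract a window around an interval, truncating (with a warning) at
# contig edges. Returns the window string and its 1-based genomic offset.
extract_window <- function(contig, start, end, flank) {
  n <- nchar(contig)
  ws <- start - flank; we <- end + flank
  if (ws < 1L || we > n) {
    warning("window truncated at contig edge")
    ws <- max(1L, ws); we <- min(n, we)
  }
  list(seq = substr(contig, ws, we), offset = as.integer(ws))
}

empty_calls <- function() {
  data.frame(donor_taxon = character(0), recipient_taxon = character(0),
             target_id = character(0), start = integer(0), end = integer(0),
             n_support_hits = integer(0), mean_identity = numeric(0),
             mode = character(0), te_class = character(0),
             flank_elevated = logical(0), complete = logical(0),
             filtered = logical(0), stringsAsFactors = FALSE)
}

#' Representative RT sequences for the targeted screen
#'
#' Scans sample reads for the reverse-transcriptase domain, clusters the
#' detected RT reads by sequence similarity, and returns one
#' representative (the longest member, ties broken by id) per cluster
#' plus every singleton, mirroring the cluster-then-screen organisation
#' of the targeted search.
#'
#' @param reads Named character vector of sample reads.
#' @param rt_profile Calibrated RT `pssm_profile`
#'   (default `default_profiles()$RT`).
#' @param min_overlap Minimum profile/read overlap for detection (aa).
#' @param min_identity,min_cov Clustering thresholds, see
#'   [cluster_sequences()].
#' @return Named character vector of representative RT reads (may be
#'   empty when no read carries the domain).
#' @export
rt_cluster_representatives <- function(reads,
                                       rt_profile = default_profiles()$RT,
                                       min_overlap = 25L,
                                       min_identity = 90, min_cov = 0.55) {
  sc <- scan_reads(reads, rt_profile, min_overlap = min_overlap)
  rt_reads <- reads[sc$read_id[sc$detected]]
  if (length(rt_reads) == 0L) return(stats::setNames(character(0), character(0)))
  cl <- cluster_sequences(rt_reads, min_identity = min_identity,
                          min_cov = min_cov)
  reps <- character(0)
  if (nrow(cl$clusters) > 0L) {
    for (cid in unique(cl$clusters$cluster_id)) {
      members <- cl$clusters$member[cl$clusters$cluster_id == cid]
      lens <- nchar(rt_reads[members])
      reps <- c(reps, members[order(-lens, members)][1L])
    }
  }
  reps <- c(reps, cl$singletons)
  rt_reads[reps]
}

#' Targeted screen for horizontally transferred LTR-retrotransposons
#'
#' For each representative RT sequence: (1) align it to each target
#' genome and keep the top `top_n` hits with identity above
#' `min_rt_identity` and at least `min_rt_len` matched bp; (2) cut the hit
#' out with `flank` bp on each side (overlapping candidate windows are
#' merged); (3) align all sample reads to the window; (4) keep best
#' nonoverlapping read hits (at least `min_len` bp matched, at most
#' `max_overlap` bp overlap); (5) annotate the element boundaries
#' ([annotate_te()]); (6) call an HT when at least `min_hits` distinct
#' reads land fully inside the element and their unweighted mean identity
#' exceeds `min_mean_identity`. Read hits fully outside the element
#' should not show elevated identity; calls where they do are flagged
#' (`flank_elevated`).
#'
#' @param rt_seqs Named character vector of RT representatives
#'   (see [rt_cluster_representatives()]).
#' @param genomes Named list, one element per target taxon, each a named
#'   character vector of contigs.
#' @param reads Named character vector of sample reads.
#' @param params An [align_params()].
#' @param donor_taxon Label recorded as the donor lineage of the calls.
#' @param min_rt_identity,min_rt_len,top_n RT anchoring thresholds.
#' @param flank Window flank (bp) on each side of the RT hit.
#' @param min_len,max_overlap Best-nonoverlapping-hit selection.
#' @param min_hits,min_mean_identity Call thresholds: at least this many
#'   distinct supporting reads inside the element, with mean identity
#'   strictly above the threshold.
#' @param profiles Domain profiles for [annotate_te()].
#' @return A calls data frame (one row per called element).
#' @export
targeted_scan <- function(rt_seqs, genomes, reads, params = align_params(),
                          donor_taxon = "donor",
                          min_rt_identity = 85, min_rt_len = 140L, top_n = 3L,
                          flank = 10000L, min_len = 100L, max_overlap = 75L,
                          min_hits = 10L, min_mean_identity = 97.0,
                          profiles = default_profiles()) {
  calls <- empty_calls()
  if (length(rt_seqs) == 0L) return(calls)
  for (taxon in names(genomes)) {
    contigs <- genomes[[taxon]]
    anchors <- local_align(rt_seqs, contigs, params)
    anchors <- anchors[anchors$pct_identity > min_rt_identity &
                         anchors$aln_len >= min_rt_len, , drop = FALSE]
    if (nrow(anchors) == 0L) next
    # top hits per query within this genome
    anchors <- do.call(rbind, lapply(split(anchors, anchors$query_id),
      function(a) utils::head(a[order(-a$score), , drop = FALSE], top_n)))
    # merge overlapping candidate windows so each locus is scanned once
    loci <- NULL
    for (cid in unique(anchors$target_id)) {
      a <- anchors[anchors$target_id == cid, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(pmax(1L, a$t_start - flank),
                                             a$t_end + flank))
      loci <- rbind(loci, data.frame(target_id = cid,
                                     start = IRanges::start(ir),
                                     end = IRanges::end(ir),
                                     stringsAsFactors = FALSE))
    }
    for (li in seq_len(nrow(loci))) {
      contig <- contigs[[loci$target_id[li]]]
      we <- min(nchar(contig), loci$end[li])
      if (we < loci$end[li]) warning("window truncated at contig edge")
      win <- list(seq = substr(contig, loci$start[li], we),
                  offset = loci$start[li])
      wid <- sprintf("%s_window", loci$target_id[li])
      rh <- local_align(reads, stats::setNames(win$seq, wid), params)
      rh <- select_best_nonoverlapping(rh, min_len = min_len,
                                       max_overlap = max_overlap)
      ann <- annotate_te(win$seq, profiles = profiles, contig_id = wid)
      el <- ann[ann$kind == "TE", , drop = FALSE]
      if (nrow(el) == 0L) next
      el <- el[1L, ]
      inside <- rh$t_start >= el$start & rh$t_end <= el$end
      sup <- rh[inside, , drop = FALSE]
      n_sup <- length(unique(sup$query_id))
      mean_id <- if (nrow(sup) > 0L) mean(sup$pct_identity) else NA_real_
      flank_hits <- rh[rh$t_end < el$start | rh$t_start > el$end, ,
                       drop = FALSE]
      flank_elev <- nrow(flank_hits) > 0L &&
        mean(flank_hits$pct_identity) > min_mean_identity
      if (n_sup >= min_hits && isTRUE(mean_id > min_mean_identity)) {
        calls <- rbind(calls, data.frame(
          donor_taxon = donor_taxon, recipient_taxon = taxon,
          target_id = loci$target_id[li],
          start = win$offset + el$start - 1L,
          end = win$offset + el$end - 1L,
          n_support_hits = n_sup, mean_identity = mean_id,
          mode = "targeted", te_class = NA_character_,
          flank_elevated = flank_elev,
          complete = identical(el$label, "complete"),
          filtered = TRUE, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(calls) <- NULL
  calls
}

#' Find homologous copies of a transferred RT in a genome
#'
#' A hit counts as a homologous copy when its matched length is strictly
#' longer than half of the query RT and its identity is strictly above
#' `min_identity`. Distinct loci are obtained by best-nonoverlapping
#' selection; the identity list feeds the homolog identity histograms.
#'
#' @param rt_seq A single named RT sequence from a confirmed call.
#' @param genome Named character vector of contigs.
#' @param params An [align_params()].
#' @param min_identity Identity floor (percent, strict).
#' @return A hits data frame, one row per homologous copy.
#' @export
homolog_search <- function(rt_seq, genome, params = NULL,
                           min_identity = 85) {
  if (is.null(params)) params <- align_params(single_hsp = FALSE)
  params$single_hsp <- FALSE
  qlen <- nchar(rt_seq[[1]])
  h <- local_align(rt_seq, genome, params)
  h <- h[h$aln_len > qlen / 2 & h$pct_identity > min_identity, ,
         drop = FALSE]
  if (nrow(h) == 0L) return(h)
  select_best_nonoverlapping(h, min_len = floor(qlen / 2) + 1L,
                             max_overlap = 50L)
}

#' Merge k-mismatch read placements into densely mapped regions
#'
#' Mapped read intervals on a target are chained when the interval
#' between consecutive mapped stretches is strictly less than `max_gap`
#' bp; a chain is kept when the union of its mapped bases is strictly
#' greater than `min_region_len` bp. Both the covered-base count
#' (`mapped_bp`) and the chain span are reported.
#'
#' @param hits Hits from [map_kmismatch()].
#' @param min_region_len Minimum union of mapped bases in a region (bp).
#' @param max_gap Chaining gap bound (bp, strict).
#' @return Region data frame with `target_id, start, end, mapped_bp,
#'   span_bp, n_hits, mean_identity`.
#' @export
merge_dense_regions <- function(hits, min_region_len = 500L,
                                max_gap = 150L) {
  out <- data.frame(target_id = character(0), start = integer(0),
                    end = integer(0), mapped_bp = integer(0),
                    span_bp = integer(0), n_hits = integer(0),
                    mean_identity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)
  for (cid in unique(hits$target_id)) {
    h <- hits[hits$target_id == cid, , drop = FALSE]
    h <- h[order(h$t_start, h$t_end), , drop = FALSE]
    chain_end <- h$t_end[1L]; chain_idx <- 1L
    groups <- integer(nrow(h)); groups[1L] <- 1L
    for (i in seq_len(nrow(h))[-1L]) {
      gap <- h$t_start[i] - chain_end - 1L
      if (gap >= max_gap) chain_idx <- chain_idx + 1L
      groups[i] <- chain_idx
      chain_end <- max(chain_end, h$t_end[i])
    }
    for (g in unique(groups)) {
      hg <- h[groups == g, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(hg$t_start, hg$t_end))
      mapped <- sum(IRanges::width(ir))
      if (mapped > min_region_len) {
        out <- rbind(out, data.frame(
          target_id = cid, start = min(hg$t_start), end = max(hg$t_end),
          mapped_bp = mapped, span_bp = max(hg$t_end) - min(hg$t_start) + 1L,
          n_hits = nrow(hg), mean_identity = mean(hg$pct_identity),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Nontargeted screen for horizontally transferred fragments
#'
#' The whole-genome, element-type-agnostic screen: (1) sample reads are
#' chopped into `shred_len`-bp pieces; (2) pieces are mapped end to end
#' with at most `k` mismatches (for 50-bp pieces and `k = 3` this is a
#' 94% identity floor); (3) densely mapped regions are merged
#' ([merge_dense_regions()]); (4) each region is cut out with `flank` bp
#' on each side; (5) the full-length reads are aligned back to the
#' window; (6) a region becomes a call when reads above `call_threshold`
#' percent identity cover strictly more than `min_call_cover` bp; (7)
#' exclusion filters remove organelle/rRNA/conserved-gene/low-complexity
#' matches ([apply_filters()]). When no filter sets are supplied the scan
#' runs with a warning and calls are flagged unfiltered.
#'
#' @param reads Named character vector of full-length sample reads.
#' @param genome Named character vector of target contigs (one taxon).
#' @param filters Named list of exclusion FASTA sets (named character
#'   vectors), or `NULL`.
#' @param params An [align_params()].
#' @param donor_taxon,recipient_taxon Labels recorded in the calls.
#' @param shred_len,k Piece length and mismatch allowance of the first
#'   mapping pass.
#' @param min_region_len,max_gap Dense-region merging, see
#'   [merge_dense_regions()].
#' @param flank Window flank (bp).
#' @param call_threshold Identity threshold (percent, strict) for
#'   supporting reads.
#' @param min_call_cover Minimum coverage (bp, strict) of the window by
#'   supporting reads.
#' @return A calls data frame; per-call `mean_identity` is the unweighted
#'   mean over supporting read hits, so calls can be re-thresholded with
#'   [threshold_sweep()].
#' @export
nontargeted_scan <- function(reads, genome, filters = NULL,
                             params = align_params(),
                             donor_taxon = "donor",
                             recipient_taxon = "recipient",
                             shred_len = 50L, k = 3L,
                             min_region_len = 500L, max_gap = 150L,
                             flank = 20000L, call_threshold = 97,
                             min_call_cover = 500L) {
  calls <- empty_calls()
  pieces <- chop_reads(reads, shred_len)
  if (length(pieces) == 0L) return(calls)
  kh <- map_kmismatch(pieces, genome, k = k)
  regions <- merge_dense_regions(kh, min_region_len = min_region_len,
                                 max_gap = max_gap)
  if (nrow(regions) == 0L) return(calls)
  unfiltered <- is.null(filters)
  if (unfiltered) {
    warning("no exclusion filter sets supplied; calls are flagged unfiltered")
  }
  # merge regions whose windows overlap, so each locus is called once
  loci <- NULL
  for (cid in unique(regions$target_id)) {
    r <- regions[regions$target_id == cid, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(pmax(1L, r$start - flank),
                                           r$end + flank))
    loci <- rbind(loci, data.frame(target_id = cid,
                                   start = IRanges::start(ir) + flank,
                                   end = IRanges::end(ir) - flank,
                                   stringsAsFactors = FALSE))
  }
  for (ri in seq_len(nrow(loci))) {
    contig <- genome[[loci$target_id[ri]]]
    win <- extract_window(contig, loci$start[ri], loci$end[ri], flank)
    wid <- sprintf("%s_region%d", loci$target_id[ri], ri)
    rh <- local_align(reads, stats::setNames(win$seq, wid), params)
    sup <- rh[rh$pct_identity > call_threshold, , drop = FALSE]
    if (nrow(sup) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(sup$t_start, sup$t_end))
    cover <- sum(IRanges::width(ir))
    if (cover <= min_call_cover) next
    el_start <- win$offset + min(sup$t_start) - 1L
    el_end <- win$offset + max(sup$t_end) - 1L
    call <- data.frame(
      donor_taxon = donor_taxon, recipient_taxon = recipient_taxon,
      target_id = regions$target_id[ri],
      start = el_start, end = el_end,
      n_support_hits = length(unique(sup$query_id)),
      mean_identity = mean(sup$pct_identity),
      mode = "nontargeted", te_class = NA_character_,
      flank_elevated = FALSE, complete = NA,
      filtered = !unfiltered, stringsAsFactors = FALSE)
    if (!unfiltered) {
      region_seq <- stats::setNames(substr(contig, el_start, el_end), wid)
      keep <- apply_filters(data.frame(region_id = wid,
                                       seq = unname(region_seq),
                                       stringsAsFactors = FALSE),
                            filters)
      if (nrow(keep) == 0L) next
    }
    calls <- rbind(calls, call)
  }
  rownames(calls) <- NULL
  calls
}

# Chop reads into consecutive non-overlapping pieces of `piece_len` bp.
chop_reads <- function(reads, piece_len = 50L) {
  out <- character(0)
  nm <- character(0)
  for (i in seq_along(reads)) {
    n <- nchar(reads[[i]])
    if (n < piece_len) next
    starts <- seq.int(1L, n - piece_len + 1L, by = piece_len)
    out <- c(out, substring(reads[[i]], starts, starts + piece_len - 1L))
    nm <- c(nm, sprintf("%s/%d", names(reads)[i], seq_along(starts)))
  }
  stats::setNames(out, nm)
}

#' Filter candidate regions against exclusion sets
#'
#' A region is removed when at least `min_frac` of its bases are covered
#' by hits to any exclusion set (organelle genomes, ribosomal DNA,
#' conserved genes, ...) at more than `min_identity` percent identity, or
#' when at least `min_frac` of the region is low-complexity by a
#' sliding-window dinucleotide entropy rule (covers microsatellites and
#' other simple repeats without needing a reference set).
#'
#' @param regions Data frame with `region_id` and `seq` columns.
#' @param exclusion_sets Named list of named character vectors of
#'   reference sequences (e.g. `list(organelle = ..., rrna = ...)`).
#' @param min_identity Identity floor for exclusion matches (percent).
#' @param min_frac Fraction of region bases that must be implicated.
#' @param params An [align_params()].
#' @return The retained rows of `regions`, with a `removed_reason`
#'   column (`NA` for retained rows) attached to the full input in the
#'   `"report"` attribute.
#' @export
apply_filters <- function(regions, exclusion_sets, min_identity = 85,
                          min_frac = 0.5, params = align_params()) {
  reason <- rep(NA_character_, nrow(regions))
  for (ri in seq_len(nrow(regions))) {
    rs <- stats::setNames(regions$seq[ri], regions$region_id[ri])
    n <- nchar(rs)
    lc <- low_complexity_fraction(rs)
    if (lc >= min_frac) { reason[ri] <- "simple_repeat"; next }
    for (sname in names(exclusion_sets)) {
      h <- suppressWarnings(local_align(rs, exclusion_sets[[sname]], params))
      h <- h[h$pct_identity > min_identity, , drop = FALSE]
      if (nrow(h) == 0L) next
      ir <- IRanges::reduce(IRanges::IRanges(h$q_start, h$q_end))
      if (sum(IRanges::width(ir)) / n >= min_frac) {
        reason[ri] <- sname
        break
      }
    }
  }
  report <- regions
  report$removed_reason <- reason
  out <- regions[is.na(reason), , drop = FALSE]
  attr(out, "report") <- report
  out
}

# Fraction of a sequence lying in low-complexity windows (dinucleotide
# Shannon entropy below `min_entropy` bits; random DNA is close to 4).
low_complexity_fraction <- function(seq, win = 64L, step = 32L,
                                    min_entropy = 2.5) {
  s <- as.character(seq)[1]
  n <- nchar(s)
  if (n < win) return(0)
  starts <- seq.int(1L, n - win + 1L, by = step)
  low <- vapply(starts, function(p) {
    w <- substr(s, p, p + win - 1L)
    d1 <- substring(w, 1:(win - 1L), 1:(win - 1L))
    d2 <- substring(w, 2:win, 2:win)
    tab <- table(paste0(d1, d2))
    pr <- tab / sum(tab)
    -sum(pr * log2(pr)) < min_entropy
  }, logical(1))
  cov <- IRanges::reduce(IRanges::IRanges(starts[low],
                                          pmin(n, starts[low] + win - 1L)))
  sum(IRanges::width(cov)) / n
}

#' Count HT calls surviving a range of identity thresholds
#'
#' Calls are computed once at the loosest threshold with per-call mean
#' identities retained; the sweep counts how many calls have mean
#' identity at or above each threshold. Counts are nonincreasing in the
#' threshold.
#'
#' @param calls A calls data frame with a `mean_identity` column.
#' @param thresholds Identity thresholds (percent).
#' @return Data frame with `threshold` and `n_calls`.
#' @export
threshold_sweep <- function(calls, thresholds = c(94, 97, 100)) {
  thresholds <- sort(thresholds)
  n <- vapply(thresholds, function(t) {
    if (nrow(calls) == 0L) 0L else sum(calls$mean_identity >= t)
  }, integer(1))
  data.frame(threshold = thresholds, n_calls = n)
}
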