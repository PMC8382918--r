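#' Alignment parameters
#'
#' Score scheme and filtering thresholds for the built-in local aligner.
#' With the default `+1/-2` match/mismatch scheme, the `score > 60` floor
#' corresponds to roughly 60 bp of matched sequence, consistent with the
#' 100-140 bp match-length floors used elsewhere in the pipeline. Gap
#' penalties are part of the scheme for scoring imported gapped
#' alignments; the built-in extension engine itself is ungapped (see
#' [local_align()]).
#'
#' @param word_size Exact-match seed length (>= 4).
#' @param min_score Raw-score floor; hits must score strictly above it.
#' @param max_evalue E-value ceiling (Karlin-Altschul, ungapped).
#' @param match,mismatch,gap_open,gap_extend Score terms.
#' @param single_hsp Keep only the best-scoring HSP per query-target pair.
#' @param xdrop Extension stops when the running score falls this far
#'   below the running maximum.
#' @param trim Cut each HSP back to its score-maximal endpoints. The
#'   default keeps the full extended region, whose percent identity is an
#'   unbiased estimate of the underlying divergence; trimming gives
#'   boundary-precise endpoints for repeat discovery.
#' @return An `align_params` list, with the Karlin-Altschul `lambda` and
#'   `K` for the scheme attached.
#' @export
align_params <- function(word_size = 11L, min_score = 60, max_evalue = 1e-8,
                         match = 1, mismatch = -2, gap_open = -5,
                         gap_extend = -2, single_hsp = TRUE, xdrop = 20,
                         trim = FALSE) {
  stopifnot(word_size >= 4L, min_score > 0, match > 0, mismatch < 0)
  lambda <- stats::uniroot(function(l) {
    0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  }, c(1e-6, 10))$root
  # K for the default +1/-2 ungapped scheme; other schemes use a
  # conservative stand-in (the score floor dominates filtering anyway)
  K <- if (match == 1 && mismatch == -2) 0.621 else 0.3
  structure(list(word_size = as.integer(word_size), min_score = min_score,
                 max_evalue = max_evalue, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 single_hsp = isTRUE(single_hsp), xdrop = xdrop,
                 trim = isTRUE(trim), lambda = lambda, K = K),
            class = "align_params")
}

#' Seed-and-extend local alignment of queries against targets
#'
#' Exact-match seeds of `word_size` are extended in both directions with
#' ungapped x-drop extension on both strands; the HSP spans the full
#' extended region (terminal columns are retained up to the x-drop
#' boundary), so percent identity over the HSP is an unbiased estimate of
#' the underlying sequence divergence. Alignment columns containing N
#' count as mismatches. Hits scoring `<= min_score` or with e-value
#' `>= max_evalue` are dropped; with `single_hsp` only the best-scoring
#' HSP per query-target pair is kept (ties: longer alignment, then
#' smaller target start). The e-value search space is frozen to the
#' supplied target set.
#'
#' @param queries,targets Named character vectors of DNA sequences.
#' @param params An [align_params()].
#' @param exclude_self Skip the trivial main diagonal when a query is
#'   aligned against an identical target (used for direct-repeat
#'   discovery by self-comparison).
#' @return A hits data frame (see [read_hits()] for the columns), sorted
#'   by target, then target start.
#' @export
local_align <- function(queries, targets, params = align_params(),
                        exclude_self = FALSE) {
  if (length(queries) == 0L || length(targets) == 0L) {
    warning("empty query or target set")
    return(empty_hits())
  }
  stopifnot(!is.null(names(queries)), !is.null(names(targets)))
  n_space <- sum(nchar(targets))
  out <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    h <- .local_align_cpp(names(queries), unname(as.character(queries)),
                          as.character(targets[[ti]]),
                          params$word_size, as.integer(params$match),
                          as.integer(params$mismatch),
                          as.integer(params$xdrop), params$trim, exclude_self)
    if (nrow(h) == 0L) next
    h$target_id <- names(targets)[ti]
    out[[ti]] <- h
  }
  h <- do.call(rbind, out)
  if (is.null(h) || nrow(h) == 0L) return(empty_hits())
  qlen <- nchar(queries)[h$query_id]
  h$evalue <- params$K * as.numeric(qlen) * n_space *
    exp(-params$lambda * h$score)
  h$gap_open <- 0L
  h <- h[h$score > params$min_score & h$evalue < params$max_evalue, ,
         drop = FALSE]
  if (nrow(h) == 0L) return(empty_hits())
  if (params$single_hsp) {
    key <- paste(h$query_id, h$target_id, sep = "\r")
    o <- order(key, -h$score, -h$aln_len, h$t_start)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(key[o]), , drop = FALSE]
  }
  h <- h[order(h$target_id, h$t_start, h$t_end, h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  as_hits(h)
}

#' Map fixed-length reads end-to-end with at most k mismatches
#'
#' Ungapped, full-length placement of each read on both strands of each
#' target; all placements with at most `k` mismatches are reported (N
#' counts as a mismatch). Percent identity is
#' `100 * (read_len - mismatches) / read_len`, so for 50-bp reads and
#' `k = 3` the identity floor is exactly 94%.
#'
#' @param reads Named character vector of equal-length reads.
#' @param targets Named character vector of target sequences.
#' @param k Maximum number of mismatches.
#' @return A hits data frame (see [read_hits()]).
#' @export
map_kmismatch <- function(reads, targets, k = 3L) {
  stopifnot(k >= 0L)
  if (length(reads) == 0L || length(targets) == 0L) return(empty_hits())
  stopifnot(!is.null(names(reads)), !is.null(names(targets)))
  out <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    h <- .map_kmismatch_cpp(names(reads), unname(as.character(reads)),
                            as.character(targets[[ti]]), as.integer(k))
    if (nrow(h) == 0L) next
    h$target_id <- names(targets)[ti]
    out[[ti]] <- h
  }
  h <- do.call(rbind, out)
  if (is.null(h) || nrow(h) == 0L) return(empty_hits())
  h$q_start <- 1L
  h$q_end <- h$aln_len
  h$score <- (h$aln_len - h$mismatches) - 2 * h$mismatches
  h$gap_open <- 0L
  h$evalue <- NA_real_
  h <- h[order(h$target_id, h$t_start, h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  as_hits(h)
}

#' Identity floor of k-mismatch mapping
#'
#' The minimum percent identity a read can have and still be placed when
#' mapped end-to-end with at most `k` mismatches.
#'
#' @param read_len Read length in bp.
#' @param k Maximum number of mismatches.
#' @return Percent identity floor, `100 * (read_len - k) / read_len`.
#' @examples
#' kmismatch_identity_floor(50, 3)  # 94
#' @export
kmismatch_identity_floor <- function(read_len, k) {
  100 * (read_len - k) / read_len
}

#' Select the best nonoverlapping hits on a target
#'
#' Greedy selection by descending score (ties broken by longer alignment,
#' then smaller target start): a hit is accepted iff its alignment length
#' is at least `min_len` and its target-interval overlap with every
#' already-accepted hit is at most `max_overlap` bp (the bound is
#' inclusive: an overlap of exactly `max_overlap` passes). Applied per
#' target sequence.
#'
#' @param hits A hits data frame.
#' @param min_len Minimum alignment length (bp).
#' @param max_overlap Maximum allowed overlap with any accepted hit (bp).
#' @return The retained hits, sorted by target start.
#' @export
select_best_nonoverlapping <- function(hits, min_len = 100L,
                                       max_overlap = 75L) {
  hits <- as_hits(hits)
  hits <- hits[hits$aln_len >= min_len, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  pieces <- lapply(split(hits, hits$target_id), function(h) {
    o <- order(-h$score, -h$aln_len, h$t_start, h$query_id)
    h <- h[o, , drop = FALSE]
    acc_s <- integer(0); acc_e <- integer(0); keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      ov <- pmax(0L, pmin(h$t_end[i], acc_e) - pmax(h$t_start[i], acc_s) + 1L)
      if (all(ov <= max_overlap)) {
        keep[i] <- TRUE
        acc_s <- c(acc_s, h$t_start[i]); acc_e <- c(acc_e, h$t_end[i])
      }
    }
    h[keep, , drop = FALSE]
  })
  h <- do.call(rbind, pieces)
  h <- h[order(h$target_id, h$t_start, h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}
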