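#' Check the terminal TG...CA motif of an LTR-retrotransposon insertion
#'
#' An intact LTR-retrotransposon begins with `TG` and ends with `CA`
#' (the element boundaries being the outer LTR edges). Both orientations
#' are checked and the better one reported; note the motif is its own
#' reverse complement, so orientation rarely matters. With
#' `solo_ltr = TRUE` a single TG...CA unit (a solo LTR left by
#' intra-element recombination) passes.
#'
#' @param contig DNA string containing the element.
#' @param element Length-2 vector or 1-row interval with `start`, `end`.
#' @param solo_ltr Treat the interval as a solo LTR (single motif unit).
#' @return List with logical `ltr5_motif_ok`, `ltr3_motif_ok` and the
#'   reported `orientation` (`"+"` or `"-"`).
#' @export
check_terminal_motifs <- function(contig, element, solo_ltr = FALSE) {
  iv <- .element_interval(element)
  s <- toupper(substr(as.character(contig)[1], iv[1], iv[2]))
  fwd <- c(startsWith(s, "TG"), endsWith(s, "CA"))
  rev <- {
    rc <- .revcomp_cpp(s)
    c(startsWith(rc, "TG"), endsWith(rc, "CA"))
  }
  if (sum(fwd) >= sum(rev)) {
    out <- list(ltr5_motif_ok = fwd[1], ltr3_motif_ok = fwd[2],
                orientation = "+")
  } else {
    out <- list(ltr5_motif_ok = rev[1], ltr3_motif_ok = rev[2],
                orientation = "-")
  }
  if (solo_ltr) out$solo_ok <- out$ltr5_motif_ok && out$ltr3_motif_ok
  out
}

.element_interval <- function(element) {
  if (is.data.frame(element)) {
    c(as.integer(element$start[1]), as.integer(element$end[1]))
  } else {
    as.integer(element[1:2])
  }
}

#' Detect a target-site duplication at an insertion
#'
#' Looks for the longest exact match, anchored at the junctions, between
#' the `max_len` bases immediately 5' of the element and the bases
#' immediately 3' of it. Integration of an LTR-retrotransposon duplicates
#' 4-6 bp of host sequence, so a recovered duplication is strong evidence
#' of a genuine insertion; matches shorter than `min_len` return `""`.
#'
#' @param contig DNA string containing the element.
#' @param element Element interval (`start`, `end`); the TSD lies in the
#'   flanks, outside these bounds.
#' @param min_len,max_len TSD length search window (bp).
#' @return The duplicated sequence, or `""` if none qualifies.
#' @export
detect_tsd <- function(contig, element, min_len = 4L, max_len = 6L) {
  iv <- .element_interval(element)
  s <- toupper(as.character(contig)[1])
  if (iv[1] - max_len < 1L || iv[2] + max_len > nchar(s)) {
    stop("element needs at least max_len bp of flank on each side")
  }
  left <- substr(s, iv[1] - max_len, iv[1] - 1L)
  right <- substr(s, iv[2] + 1L, iv[2] + max_len)
  for (k in seq.int(max_len, min_len)) {
    a <- substr(left, max_len - k + 1L, max_len)  # suffix of left flank
    b <- substr(right, 1L, k)                     # prefix of right flank
    if (a == b) return(a)
  }
  ""
}

#' Count junction-spanning reads
#'
#' Reads confirming that a foreign element is integrated must align
#' across a junction between host and element sequence with at least
#' `min_anchor` aligned bp on each side. Counts are reported separately
#' for the left (element start) and right (element end) junctions.
#'
#' @param reads Named character vector of reads (>= `2 * min_anchor` bp).
#' @param contig DNA string containing the element.
#' @param element Element interval (`start`, `end`).
#' @param min_anchor Minimum aligned bp on each side of the junction.
#' @param params An [align_params()].
#' @return Integer vector `c(left, right)` of distinct spanning reads.
#' @export
junction_support <- function(reads, contig, element, min_anchor = 20L,
                             params = align_params()) {
  iv <- .element_interval(element)
  stopifnot(all(nchar(reads) >= 2L * min_anchor))
  h <- suppressWarnings(
    local_align(reads, stats::setNames(as.character(contig)[1], "contig"),
                params))
  left_b <- iv[1]   # junction between iv[1]-1 and iv[1]
  right_b <- iv[2]  # junction between iv[2] and iv[2]+1
  left <- h[h$t_start <= left_b - min_anchor &
              h$t_end >= left_b + min_anchor - 1L, , drop = FALSE]
  right <- h[h$t_start <= right_b - min_anchor + 1L &
               h$t_end >= right_b + min_anchor, , drop = FALSE]
  c(left = length(unique(left$query_id)),
    right = length(unique(right$query_id)))
}

#' Presence/absence of an insertion in orthologous regions
#'
#' For each genome the orthologous locus is anchored by aligning the
#' element's flanks (>= `anchor_len` bp at > `min_anchor_identity`
#' percent identity); the element is `present` when its sequence aligns
#' between the anchors at > `min_el_identity` percent identity over more
#' than half its length, `absent` when the anchors adjoin with less than
#' 10% of the element length between them, and `unresolved` otherwise
#' (including unalignable flanks).
#'
#' @param window DNA string: the element plus >= `anchor_len` flanks.
#' @param element Element interval within `window`.
#' @param other_genomes Named list of named character contig vectors.
#' @param anchor_len Flank anchor length (bp).
#' @param min_anchor_identity,min_el_identity Identity floors (percent).
#' @param params An [align_params()].
#' @return Named character vector over the genomes with values
#'   `"present"`, `"absent"` or `"unresolved"`.
#' @export
ortholog_presence <- function(window, element, other_genomes,
                              anchor_len = 1000L,
                              min_anchor_identity = 80,
                              min_el_identity = 85,
                              params = align_params()) {
  iv <- .element_interval(element)
  w <- toupper(as.character(window)[1])
  el_len <- iv[2] - iv[1] + 1L
  stopifnot(iv[1] > anchor_len, iv[2] + anchor_len <= nchar(w))
  left <- stats::setNames(substr(w, iv[1] - anchor_len, iv[1] - 1L), "left")
  right <- stats::setNames(substr(w, iv[2] + 1L, iv[2] + anchor_len), "right")
  el <- stats::setNames(substr(w, iv[1], iv[2]), "element")
  out <- stats::setNames(character(length(other_genomes)),
                         names(other_genomes))
  for (g in names(other_genomes)) {
    contigs <- other_genomes[[g]]
    lh <- suppressWarnings(local_align(left, contigs, params))
    rh <- suppressWarnings(local_align(right, contigs, params))
    ok <- function(h) {
      h <- h[h$pct_identity > min_anchor_identity &
               h$aln_len >= 0.8 * anchor_len, , drop = FALSE]
      if (nrow(h) == 0L) NULL else h[which.max(h$score), , drop = FALSE]
    }
    lb <- ok(lh); rb <- ok(rh)
    if (is.null(lb) || is.null(rb) || lb$target_id != rb$target_id ||
        lb$strand != rb$strand) {
      out[g] <- "unresolved"
      next
    }
    if (lb$strand == "+") {
      gap_start <- lb$t_end + 1L; gap_end <- rb$t_start - 1L
    } else {
      gap_start <- rb$t_end + 1L; gap_end <- lb$t_start - 1L
    }
    between <- gap_end - gap_start + 1L
    if (between < 0.1 * el_len) {
      out[g] <- "absent"
      next
    }
    locus <- substr(contigs[[lb$target_id]],
                    max(1L, gap_start), min(nchar(contigs[[lb$target_id]]),
                                            gap_end))
    eh <- if (nchar(locus) >= params$word_size) {
      suppressWarnings(local_align(el, stats::setNames(locus, "locus"),
                                   params))
    } else {
      empty_hits()
    }
    eh <- eh[eh$pct_identity > min_el_identity, , drop = FALSE]
    covered <- if (nrow(eh) > 0L) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(eh$q_start,
                                                          eh$q_end))))
    } else {
      0L
    }
    out[g] <- if (covered > 0.5 * el_len) "present" else "unresolved"
  }
  out
}

#' Full junction report for a called element
#'
#' Bundles the terminal-motif check, TSD detection and junction-spanning
#' read support for one element.
#'
#' @inheritParams junction_support
#' @param tsd_min,tsd_max TSD length search window (bp).
#' @return A `junction_report` list.
#' @export
junction_report <- function(contig, element, reads = NULL, min_anchor = 20L,
                            tsd_min = 4L, tsd_max = 6L) {
  iv <- .element_interval(element)
  motifs <- check_terminal_motifs(contig, iv)
  tsd <- detect_tsd(contig, iv, min_len = tsd_min, max_len = tsd_max)
  support <- if (is.null(reads)) c(left = NA_integer_, right = NA_integer_)
             else junction_support(reads, contig, iv, min_anchor)
  structure(list(element = iv, ltr5_motif_ok = motifs$ltr5_motif_ok,
                 ltr3_motif_ok = motifs$ltr3_motif_ok,
                 tsd_seq = tsd, tsd_len = nchar(tsd),
                 left_support = unname(support["left"]),
                 right_support = unname(support["right"])),
            class = "junction_report")
}
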