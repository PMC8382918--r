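#' Identity histogram of CDS-mapped sample reads
#'
#' Bins the percent identities of best nonoverlapping read-vs-CDS hits.
#' The histogram peak is read as the modal divergence between the two
#' lineages (the speciation point); the fraction of hits above a
#' candidate HT threshold measures how much of the vertical background
#' would leak through that threshold. Hits corresponding to paralogs are
#' not removed: they cannot be told apart from orthologs for short
#' unassembled reads.
#'
#' @param hits A hits data frame, already reduced per CDS with
#'   [select_best_nonoverlapping()].
#' @param bin_width Bin width in percent identity.
#' @return An `identity_histogram` with `counts` (named by bin lower
#'   edge), `n_total`, `peak_bin` (lowest-identity arg-max bin),
#'   `bin_width` and the raw `identities`.
#' @export
cds_identity_histogram <- function(hits, bin_width = 1) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) stop("no hits: cannot calibrate divergence")
  ids <- hits$pct_identity
  stopifnot(all(ids >= 0), all(ids <= 100))
  bins <- floor(ids / bin_width) * bin_width
  edges <- seq(0, 100, by = bin_width)
  counts <- table(factor(bins, levels = edges))
  counts <- stats::setNames(as.integer(counts), as.character(edges))
  peak <- edges[which(counts == max(counts))]
  structure(list(counts = counts, n_total = length(ids),
                 peak_bin = min(peak), bin_width = bin_width,
                 identities = ids),
            class = "identity_histogram")
}

#' Fraction of calibration hits above an identity threshold
#'
#' @param hist An `identity_histogram`.
#' @param threshold Percent identity threshold.
#' @return Fraction of hits with identity strictly above `threshold`;
#'   nonincreasing in the threshold.
#' @export
frac_above <- function(hist, threshold) {
  stopifnot(inherits(hist, "identity_histogram"))
  mean(hist$identities > threshold)
}

#' Validate an HT identity threshold against the divergence calibration
#'
#' A threshold is accepted when the histogram shows a genuine divergence
#' peak (the modal bin at least twice the median occupied-bin count — a
#' flat histogram locates no speciation point), the threshold clears that
#' peak by at least `margin` percentage points, and the fraction of
#' calibration hits above it stays below `max_frac`. With the canonical
#' values (peak 86%, threshold 97%, tail fraction around 2-3%) the check
#' passes.
#'
#' @param hist An `identity_histogram`.
#' @param threshold Candidate HT identity threshold (percent).
#' @param margin Required distance above the peak (percentage points).
#' @param max_frac Maximum tolerated fraction of hits above threshold.
#' @return A list with `peak`, `peak_prominent`, `threshold`,
#'   `frac_above` and `pass`.
#' @export
validate_threshold <- function(hist, threshold, margin = 5, max_frac = 0.05) {
  stopifnot(inherits(hist, "identity_histogram"))
  fa <- frac_above(hist, threshold)
  occupied <- hist$counts[hist$counts > 0]
  prominent <- max(occupied) >= 2 * stats::median(occupied)
  list(peak = hist$peak_bin, peak_prominent = prominent,
       threshold = threshold, frac_above = fa,
       pass = prominent && (threshold >= hist$peak_bin + margin) &&
         (fa < max_frac))
}

#' Run the CDS divergence calibration on reads and reference CDS
#'
#' Aligns sample reads to the CDS set, keeps best nonoverlapping hits per
#' CDS (minimum 100 bp matched length, at most 75 bp overlap), and builds
#' the identity histogram.
#'
#' @param reads Named character vector of sample reads.
#' @param cds Named character vector of reference coding sequences.
#' @param params An [align_params()].
#' @param bin_width Histogram bin width (percent).
#' @return An `identity_histogram`.
#' @export
calibrate_divergence <- function(reads, cds, params = align_params(),
                                 bin_width = 1) {
  hits <- local_align(reads, cds, params)
  hits <- select_best_nonoverlapping(hits, min_len = 100L, max_overlap = 75L)
  cds_identity_histogram(hits, bin_width = bin_width)
}
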