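#' Pairwise p-distance between aligned sequences
#'
#' Proportion of differing sites between two aligned sequences of equal
#' length. With pairwise deletion (the default), columns where either
#' sequence has a gap (`-`) or an ambiguous base (`N`/`X`) are excluded
#' from both numerator and denominator.
#'
#' @param seq_a,seq_b Aligned sequences (equal length; gaps as `-`).
#' @param pairwise_deletion Exclude gap/ambiguity columns per pair.
#' @return Distance in \[0, 1\]. Errors when no columns remain.
#' @export
p_distance <- function(seq_a, seq_b, pairwise_deletion = TRUE) {
  a <- strsplit(toupper(as.character(seq_a)[1]), "")[[1]]
  b <- strsplit(toupper(as.character(seq_b)[1]), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  bad <- a %in% c("-", "N", "X") | b %in% c("-", "N", "X")
  if (pairwise_deletion) {
    a <- a[!bad]; b <- b[!bad]
  }
  if (length(a) == 0L) stop("no retained columns for p-distance")
  sum(a != b) / length(a)
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aligned Named character vector of aligned equal-length
#'   sequences.
#' @param pairwise_deletion See [p_distance()].
#' @return Symmetric distance matrix with zero diagonal, labelled by the
#'   sequence names.
#' @export
p_distance_matrix <- function(aligned, pairwise_deletion = TRUE) {
  n <- length(aligned)
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d[i, j] <- d[j, i] <- p_distance(aligned[[i]], aligned[[j]],
                                         pairwise_deletion)
      }
    }
  }
  d
}

#' Align cluster members against their longest member
#'
#' Progressive pairwise alignment of each sequence to a reference (the
#' longest member by default) with a global pairwise aligner; insertions
#' relative to the reference are dropped so all sequences are projected
#' onto the reference coordinate system. A lightweight stand-in for a
#' full multiple aligner that is adequate for closely related repeat
#' copies; externally produced alignments can be used instead.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param reference Name of the reference sequence (default: longest).
#' @return Named character vector of aligned sequences, all of the
#'   reference's length, gaps as `-`.
#' @export
align_to_reference <- function(seqs, reference = NULL) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (is.null(reference)) {
    reference <- names(seqs)[order(-nchar(seqs), names(seqs))][1L]
  }
  ref <- as.character(seqs[[reference]])
  out <- stats::setNames(character(length(seqs)), names(seqs))
  out[reference] <- ref
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  for (nm in setdiff(names(seqs), reference)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(as.character(seqs[[nm]])),
      Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    ta <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    keep <- ta != "-"  # drop insertions relative to the reference
    out[nm] <- paste(qa[keep], collapse = "")
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on a p-distance (or any) matrix; labels are
#' sorted before tree building so ties resolve deterministically, and
#' negative branch lengths are clamped to zero with a warning.
#'
#' @param dm Symmetric distance matrix with labels (n >= 3).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  stopifnot(!is.null(rownames(dm)),
            max(abs(dm - t(dm))) < 1e-12)
  o <- order(rownames(dm))
  dm <- dm[o, o, drop = FALSE]
  tr <- ape::nj(stats::as.dist(dm))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Phylogenetic nesting test for transfer direction
#'
#' Root-agnostic test of whether one label set (e.g. the recipient
#' genome's element copies) nests inside the diversity of the other (the
#' donor lineage's copies). The recipients are nested in the donors iff
#' the recipient leaves form a clade under some rooting and, after
#' removing that clade, its attachment node still shows donor leaves on
#' at least two sides with at least one of those sides carrying two or
#' more donor leaves — i.e. the donor family's diversification predates
#' the transfer, and neither a single outgroup leaf nor a balanced
#' two-against-two split can fake nesting. The converse gives
#' donor-in-recipient nesting; otherwise the tree is uninformative.
#'
#' @param tree An [ape::phylo] tree containing all labels.
#' @param donor_labels,recipient_labels Disjoint tip label sets.
#' @return One of `"recipient_nested_in_donor"`,
#'   `"donor_nested_in_recipient"`, `"not_nested"`.
#' @export
nesting_test <- function(tree, donor_labels, recipient_labels) {
  stopifnot(length(intersect(donor_labels, recipient_labels)) == 0L)
  missing <- setdiff(c(donor_labels, recipient_labels), tree$tip.label)
  if (length(missing) > 0L) {
    stop("labels missing from tree: ", paste(missing, collapse = ", "))
  }
  nested <- function(inner, outer) {
    # inner labels must form a split side whose complement-side
    # attachment shows outer labels on >= 2 branches
    nt <- length(tree$tip.label)
    g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
    inner_tips <- match(inner, tree$tip.label)
    for (e in seq_len(nrow(tree$edge))) {
      v1 <- tree$edge[e, 1L]; v2 <- tree$edge[e, 2L]
      g2 <- igraph::delete_edges(g, e)
      comp <- igraph::components(g2)$membership
      side2 <- which(comp[seq_len(nt)] == comp[v2])
      for (side in list(side2, setdiff(seq_len(nt), side2))) {
        if (setequal(side, inner_tips)) {
          # attachment node is the edge endpoint on the complement side
          att <- if (all(inner_tips %in% side2)) v1 else v2
          nbr <- as.integer(igraph::neighbors(g, att))
          outer_per_side <- integer(0)
          for (u in nbr) {
            g3 <- igraph::delete_edges(
              g, igraph::get_edge_ids(g, c(att, u)))
            comp3 <- igraph::components(g3)$membership
            tips_u <- tree$tip.label[which(comp3[seq_len(nt)] == comp3[u])]
            if (any(inner %in% tips_u)) next
            outer_per_side <- c(outer_per_side, sum(outer %in% tips_u))
          }
          if (sum(outer_per_side >= 1L) >= 2L && max(outer_per_side) >= 2L) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }
  if (nested(recipient_labels, donor_labels)) {
    return("recipient_nested_in_donor")
  }
  if (nested(donor_labels, recipient_labels)) {
    return("donor_nested_in_recipient")
  }
  "not_nested"
}

#' UPGMA activity history of a repeat cluster
#'
#' Average-linkage agglomeration on an identity-distance matrix
#' (`d = 100 - percent identity`). Node heights are half the merge
#' distance (ultrametric convention, so heights read as per-lineage
#' divergence); raw merge distances are also kept. The histogram counts
#' node heights in 1% bins and always sums to `n - 1`: it is the relative
#' transposition-activity profile of the cluster.
#'
#' @param dm_identity Symmetric identity-distance matrix (percent units).
#' @param cluster_id Optional label carried in the result.
#' @param halve Use the height = distance/2 convention (default); with
#'   `FALSE` raw merge distances are binned instead.
#' @return An `activity_history` with `node_heights` (nondecreasing),
#'   `merge_distances`, `histogram` (named counts per 1% bin) and
#'   `cluster_id`.
#' @export
upgma_history <- function(dm_identity, cluster_id = NA_character_,
                          halve = TRUE) {
  dm <- as.matrix(dm_identity)
  if (nrow(dm) < 2L) stop("activity history needs at least 2 sequences")
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  merge_d <- hc$height
  heights <- if (halve) merge_d / 2 else merge_d
  bins <- floor(heights)
  edges <- seq(0, max(100, max(bins)), by = 1)
  histogram <- table(factor(bins, levels = edges))
  histogram <- stats::setNames(as.integer(histogram), as.character(edges))
  structure(list(cluster_id = cluster_id,
                 node_heights = sort(heights),
                 merge_distances = sort(merge_d),
                 histogram = histogram,
                 tree = ape::as.phylo(hc)),
            class = "activity_history")
}

#' Identity-distance matrix from all-vs-all alignment of cluster members
#'
#' Members are aligned to the cluster's longest sequence
#' ([align_to_reference()]) and pairwise identity distances
#' (`100 * p-distance`) are computed with pairwise deletion.
#'
#' @param seqs Named character vector of cluster member sequences.
#' @return Identity-distance matrix (percent units).
#' @export
identity_distance_matrix <- function(seqs) {
  aligned <- align_to_reference(seqs)
  100 * p_distance_matrix(aligned)
}
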