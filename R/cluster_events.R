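#' Cluster sequences by similarity into repeat families
#'
#' All-vs-all local alignment defines a graph with an edge between two
#' sequences when their best alignment reaches `min_identity` percent
#' identity over at least `min_cov` of the shorter sequence; clusters are
#' the connected components of size two or more (single-linkage
#' semantics), and the remaining sequences are singletons. Cluster ids
#' are assigned `CL001, CL002, ...` by descending size, ties broken by
#' the smallest member id, so naming is deterministic.
#'
#' @param seqs Named character vector of sequences (>= 1).
#' @param min_identity Edge identity threshold (percent).
#' @param min_cov Minimum alignment coverage of the shorter sequence.
#' @param params An [align_params()]; the score floor is lowered
#'   automatically for short inputs.
#' @return A list with `clusters` (data frame `cluster_id`, `member`) and
#'   `singletons` (character vector of ids).
#' @export
cluster_sequences <- function(seqs, min_identity = 90, min_cov = 0.55,
                              params = NULL) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (is.null(params)) {
    minlen <- min(nchar(seqs))
    params <- align_params(min_score = max(20, min(60, minlen / 3)),
                           single_hsp = TRUE)
  }
  ids <- names(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    h <- suppressWarnings(local_align(seqs, seqs, params, exclude_self = TRUE))
    h <- h[h$query_id != h$target_id, , drop = FALSE]
    if (nrow(h) > 0L) {
      shorter <- pmin(nchar(seqs)[h$query_id], nchar(seqs)[h$target_id])
      ok <- h$pct_identity >= min_identity & h$aln_len >= min_cov * shorter
      h <- h[ok, , drop = FALSE]
      for (r in seq_len(nrow(h))) {
        a <- find(match(h$query_id[r], ids))
        b <- find(match(h$target_id[r], ids))
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  cl_roots <- as.integer(names(sizes)[sizes >= 2L])
  singletons <- sort(ids[comp %in% as.integer(names(sizes)[sizes == 1L])])
  if (length(cl_roots) > 0L) {
    members <- lapply(cl_roots, function(r) sort(ids[comp == r]))
    o <- order(-lengths(members),
               vapply(members, `[[`, character(1), 1L))
    members <- members[o]
    clusters <- do.call(rbind, lapply(seq_along(members), function(i) {
      data.frame(cluster_id = sprintf("CL%03d", i), member = members[[i]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    clusters <- data.frame(cluster_id = character(0), member = character(0),
                           stringsAsFactors = FALSE)
  }
  list(clusters = clusters, singletons = singletons)
}

#' Construct HT call records for event accounting
#'
#' A light constructor for the donor/recipient/cluster records that feed
#' [merge_calls_to_events()]; element ids tie calls to tips of the
#' per-cluster phylogenetic trees when tree evidence is available.
#'
#' @param donor_taxon,recipient_taxon Taxon labels (disjoint per call).
#' @param cluster_id Repeat-cluster id (or a unique singleton id).
#' @param mean_identity Mean identity of the supporting hits (percent).
#' @param donor_element,recipient_element Optional sequence/element ids
#'   matching tree tip labels.
#' @return A calls data frame.
#' @export
ht_calls <- function(donor_taxon, recipient_taxon, cluster_id,
                     mean_identity = NA_real_,
                     donor_element = NA_character_,
                     recipient_element = NA_character_) {
  data.frame(call_id = sprintf("call%03d", seq_along(donor_taxon)),
             donor_taxon = donor_taxon, recipient_taxon = recipient_taxon,
             cluster_id = cluster_id, mean_identity = mean_identity,
             donor_element = donor_element,
             recipient_element = recipient_element,
             stringsAsFactors = FALSE)
}

# Do the tips `labels` form one clade (a split) of the unrooted tree?
tips_form_clade <- function(tree, labels) {
  labels <- unique(labels)
  stopifnot(all(labels %in% tree$tip.label))
  if (length(labels) <= 1L) return(TRUE)
  if (length(labels) >= length(tree$tip.label)) return(TRUE)
  out <- setdiff(tree$tip.label, labels)
  rooted <- ape::root(tree, outgroup = out[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, labels)
}

#' Merge HT calls into distinct HT events
#'
#' Two calls collapse into one event iff they share a repeat cluster and
#' either (a) the same donor taxon, with the recipient elements grouped
#' in one clade of the cluster tree, or (b) the same recipient taxon,
#' with the donor elements forming one clade. The transitive closure of
#' this relation defines the events. Tree evidence is optional: without a
#' tree for a cluster the clade conditions are taken as satisfied and the
#' event is flagged as unverified by phylogeny.
#'
#' @param calls A calls data frame (see [ht_calls()]).
#' @param trees Named list of [ape::phylo] trees, one per cluster id,
#'   with tip labels matching the calls' element ids; may be `NULL` or
#'   partial.
#' @return An events data frame with `event_id`, `cluster_id`,
#'   `donor_taxa`, `recipient_taxa` (`;`-joined), `n_calls`,
#'   `mean_identity` and `phylo_verified`. Invariant to the order of the
#'   input calls.
#' @export
merge_calls_to_events <- function(calls, trees = NULL) {
  n <- nrow(calls)
  stopifnot(n >= 1L)
  stopifnot(all(calls$donor_taxon != calls$recipient_taxon))
  calls <- calls[order(calls$cluster_id, calls$donor_taxon,
                       calls$recipient_taxon), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # Clade test for one side (donor or recipient elements): the other
  # side's elements are pruned first, since transferred copies are
  # expected to nest inside the donor lineage's diversity.
  clade_ok <- function(cluster, elements, drop) {
    tree <- trees[[cluster]]
    if (is.null(tree)) return(NA)  # no evidence: merge, but flag
    if (anyNA(elements)) return(NA)
    drop <- setdiff(intersect(drop, tree$tip.label), elements)
    if (length(drop) > 0L) tree <- ape::drop.tip(tree, drop)
    tips_form_clade(tree, elements)
  }
  verified <- rep(TRUE, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (calls$cluster_id[i] != calls$cluster_id[j]) next
        in_cl <- calls$cluster_id == calls$cluster_id[i]
        merge <- FALSE; ver <- TRUE
        if (calls$donor_taxon[i] == calls$donor_taxon[j]) {
          ok <- clade_ok(calls$cluster_id[i],
                         c(calls$recipient_element[i],
                           calls$recipient_element[j]),
                         drop = calls$donor_element[in_cl])
          if (is.na(ok)) { merge <- TRUE; ver <- FALSE }
          else if (ok) merge <- TRUE
        }
        if (!merge &&
            calls$recipient_taxon[i] == calls$recipient_taxon[j]) {
          ok <- clade_ok(calls$cluster_id[i],
                         c(calls$donor_element[i], calls$donor_element[j]),
                         drop = calls$recipient_element[in_cl])
          if (is.na(ok)) { merge <- TRUE; ver <- FALSE }
          else if (ok) merge <- TRUE
        }
        if (merge) {
          a <- find(i); b <- find(j)
          if (a != b) parent[max(a, b)] <- min(a, b)
          if (!ver) { verified[i] <- FALSE; verified[j] <- FALSE }
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  roots <- sort(unique(comp))
  events <- do.call(rbind, lapply(seq_along(roots), function(k) {
    m <- calls[comp == roots[k], , drop = FALSE]
    data.frame(event_id = k, cluster_id = m$cluster_id[1L],
               donor_taxa = paste(sort(unique(m$donor_taxon)),
                                  collapse = ";"),
               recipient_taxa = paste(sort(unique(m$recipient_taxon)),
                                      collapse = ";"),
               n_calls = nrow(m),
               mean_identity = mean(m$mean_identity),
               phylo_verified = all(verified[comp == roots[k]]),
               stringsAsFactors = FALSE)
  }))
  rownames(events) <- NULL
  events
}

#' Minimum number of independent HT events
#'
#' Each similarity cluster containing at least one horizontally
#' transferred element must derive from at least one transfer, and each
#' singleton transferred element from one of its own, so the minimum
#' event count is the number of HT clusters plus the number of HT
#' singletons.
#'
#' @param clusters_with_ht Number of HT clusters, or a vector of their
#'   ids.
#' @param ht_singletons Number of HT singletons, or a vector of their
#'   ids.
#' @return Integer minimum event count.
#' @examples
#' minimum_event_count(30, 18)  # 48
#' minimum_event_count(19, 8)   # 27
#' @export
minimum_event_count <- function(clusters_with_ht, ht_singletons) {
  nc <- if (is.numeric(clusters_with_ht) && length(clusters_with_ht) == 1L) {
    as.integer(clusters_with_ht)
  } else {
    length(unique(clusters_with_ht))
  }
  ns <- if (is.numeric(ht_singletons) && length(ht_singletons) == 1L) {
    as.integer(ht_singletons)
  } else {
    length(unique(ht_singletons))
  }
  stopifnot(nc >= 0L, ns >= 0L)
  nc + ns
}

#' Accounting of clustered vs singleton HT elements
#'
#' @param n_elements Total number of horizontally transferred elements.
#' @param n_singletons Number of those that did not cluster.
#' @return A list with `clustered` and `singleton` element counts.
#' @examples
#' ht_element_accounting(165, 18)$clustered  # 147
#' @export
ht_element_accounting <- function(n_elements, n_singletons) {
  n_elements <- as.integer(n_elements)
  n_singletons <- as.integer(n_singletons)
  stopifnot(n_singletons >= 0L, n_singletons <= n_elements)
  list(clustered = n_elements - n_singletons, singleton = n_singletons)
}

#' Tally HT events per recipient lineage
#'
#' Events whose recipients span several taxa are counted once per
#' recipient and flagged as shared.
#'
#' @param events An events data frame from [merge_calls_to_events()].
#' @return Data frame with `recipient`, `n_events`, `n_shared`.
#' @export
per_recipient_tally <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(recipient = character(0), n_events = integer(0),
                      n_shared = integer(0), stringsAsFactors = FALSE))
  }
  rec <- strsplit(events$recipient_taxa, ";", fixed = TRUE)
  shared <- lengths(rec) > 1L
  tab <- data.frame(recipient = unlist(rec),
                    shared = rep(shared, lengths(rec)),
                    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(tab, tab$recipient), function(x) {
    data.frame(recipient = x$recipient[1L], n_events = nrow(x),
               n_shared = sum(x$shared), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$n_events, out$recipient), , drop = FALSE]
}
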