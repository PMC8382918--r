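#' Read DNA sequences from a FASTA file
#'
#' Sequences are returned as an uppercase named character vector over the
#' alphabet A/C/G/T/N (other IUPAC codes are mapped to N). The name of each
#' element is the first whitespace-delimited token of the header; the
#' remainder of the header is kept in the `"descriptions"` attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences, in file order.
#'   Duplicated ids raise an error; an empty file returns an empty vector
#'   with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  .seqs_from_xstringset(x, path)
}

#' Read DNA sequences from a FASTQ file
#'
#' Base qualities are ignored; quality trimming is assumed to have happened
#' upstream.
#'
#' @inheritParams read_fasta
#' @return Named character vector of uppercase DNA reads.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTQ file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  .seqs_from_xstringset(x, path)
}

.seqs_from_xstringset <- function(x, path) {
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- desc
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write reads to a FASTQ file with uniform dummy qualities
#'
#' @inheritParams write_fasta
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  lines <- character(4L * length(seqs))
  lines[seq(1L, by = 4L, length.out = length(seqs))] <- paste0("@", names(seqs))
  lines[seq(2L, by = 4L, length.out = length(seqs))] <- as.character(seqs)
  lines[seq(3L, by = 4L, length.out = length(seqs))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(seqs))] <-
    vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(lines, path)
  invisible(path)
}

.hit_cols <- c("query_id", "target_id", "pct_identity", "aln_len",
               "mismatches", "gap_open", "q_start", "q_end",
               "t_start", "t_end", "evalue", "score", "strand")

#' Read local-alignment hits from 12-column tabular output
#'
#' Reads the standard 12-column tab-separated alignment format (the
#' "outfmt 6" dialect: query, target, percent identity, alignment length,
#' mismatches, gap opens, query start/end, target start/end, e-value,
#' score). Target coordinates are normalized so that `t_start <= t_end`;
#' records whose target coordinates were descending are flagged with
#' `strand == "-"`.
#'
#' @param path Path to a tab-separated hits file (no header).
#' @return A hits data frame with columns
#'   `query_id, target_id, pct_identity, aln_len, mismatches, gap_open,
#'   q_start, q_end, t_start, t_end, evalue, score, strand`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) return(empty_hits())
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop("malformed hits record (expected 12 tab-separated columns) at line ",
         bad[1L], " of ", path)
  }
  h <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                         col.names = c("query_id", "target_id", "pct_identity",
                                       "aln_len", "mismatches", "gap_open",
                                       "q_start", "q_end", "t_start", "t_end",
                                       "evalue", "score"),
                         colClasses = c("character", "character", "numeric",
                                        "integer", "integer", "integer",
                                        "integer", "integer", "integer",
                                        "integer", "numeric", "numeric"),
                         stringsAsFactors = FALSE)
  h$strand <- ifelse(h$t_start <= h$t_end, "+", "-")
  ts <- pmin(h$t_start, h$t_end)
  te <- pmax(h$t_start, h$t_end)
  h$t_start <- ts
  h$t_end <- te
  h[, .hit_cols]
}

#' Write hits in 12-column tabular format
#'
#' Inverse of [read_hits()]: minus-strand hits are written with descending
#' target coordinates, matching the usual tabular alignment convention.
#' Output is byte-stable for identical input.
#'
#' @param hits A hits data frame (see [read_hits()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  hits <- as_hits(hits)
  ts <- ifelse(hits$strand == "-", hits$t_end, hits$t_start)
  te <- ifelse(hits$strand == "-", hits$t_start, hits$t_end)
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   hits$query_id, hits$target_id, hits$pct_identity,
                   as.integer(hits$aln_len), as.integer(hits$mismatches),
                   as.integer(hits$gap_open),
                   as.integer(hits$q_start), as.integer(hits$q_end),
                   as.integer(ts), as.integer(te),
                   formatC(hits$evalue, format = "g", digits = 3),
                   formatC(hits$score, format = "g", digits = 6))
  writeLines(lines, path)
  invisible(path)
}

# Coerce/complete a data frame to the canonical hit column set.
as_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (is.null(hits$target_id)) hits$target_id <- NA_character_
  if (is.null(hits$gap_open)) hits$gap_open <- 0L
  if (is.null(hits$mismatches)) {
    hits$mismatches <- as.integer(round(hits$aln_len *
                                          (1 - hits$pct_identity / 100)))
  }
  if (is.null(hits$q_start)) hits$q_start <- 1L
  if (is.null(hits$q_end)) hits$q_end <- hits$aln_len
  if (is.null(hits$evalue)) hits$evalue <- NA_real_
  if (is.null(hits$score)) hits$score <- hits$aln_len - 3 * hits$mismatches
  if (is.null(hits$strand)) hits$strand <- "+"
  stopifnot(all(hits$t_start <= hits$t_end), all(hits$aln_len >= 1))
  hits[, .hit_cols]
}

empty_hits <- function() {
  data.frame(query_id = character(0), target_id = character(0),
             pct_identity = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gap_open = integer(0),
             q_start = integer(0), q_end = integer(0),
             t_start = integer(0), t_end = integer(0),
             evalue = numeric(0), score = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

.interval_kinds <- c("TE", "LTR", "domain", "gene", "exclusion", "region")

#' Construct an interval annotation table
#'
#' Intervals are 1-based inclusive, following the coordinate convention of
#' tabular alignment output used throughout the package.
#'
#' @param target_id Contig/sequence id.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param kind One of `"TE"`, `"LTR"`, `"domain"`, `"gene"`, `"exclusion"`,
#'   `"region"`.
#' @param label Free-text label.
#' @return A data frame with columns `target_id, start, end, kind, label`.
#' @export
intervals <- function(target_id, start, end, kind, label = "") {
  stopifnot(all(kind %in% .interval_kinds))
  target_id <- as.character(target_id)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(all(start <= end), all(start >= 1L))
  data.frame(target_id = target_id, start = start, end = end,
             kind = rep_len(as.character(kind), length(target_id)),
             label = rep_len(as.character(label), length(target_id)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param ivs Interval data frame (see [intervals()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(ivs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", ivs$target_id,
                   as.integer(ivs$start) - 1L, as.integer(ivs$end),
                   ifelse(nzchar(ivs$label), ivs$label, ivs$kind))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into a 1-based interval table
#'
#' @param path Path to a BED file (>= 3 columns).
#' @param kind Interval kind to assign (BED carries none).
#' @return Interval data frame (see [intervals()]).
#' @export
read_bed <- function(path, kind = "region") {
  x <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("BED file needs at least 3 columns: ", path)
  intervals(x[[1]], as.integer(x[[2]]) + 1L, as.integer(x[[3]]),
            kind = kind, label = if (ncol(x) >= 4L) x[[4]] else "")
}

#' Write intervals as GFF3
#'
#' @inheritParams write_bed
#' @param source Value for the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(ivs, path, source = "htte") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t+\t.\tName=%s",
                     ivs$target_id, source, ivs$kind,
                     as.integer(ivs$start), as.integer(ivs$end),
                     ifelse(nzchar(ivs$label), ivs$label, ivs$kind)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file into an interval table
#'
#' Only the columns used by the pipeline (seqid, type, start, end, Name)
#' are retained; types outside the internal kind vocabulary are mapped to
#' `"region"` with the original type kept as label.
#'
#' @param path Path to a GFF3 file.
#' @return Interval data frame (see [intervals()]).
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0L) return(intervals(character(0), integer(0), integer(0),
                                         character(0)))
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) < 8L)) stop("malformed GFF3 record in ", path)
  type <- vapply(f, `[[`, character(1), 3L)
  name <- sub("^.*Name=([^;]*).*$", "\\1",
              vapply(f, function(x) if (length(x) >= 9L) x[[9L]] else "",
                     character(1)))
  kind <- ifelse(type %in% .interval_kinds, type, "region")
  label <- ifelse(type %in% .interval_kinds, name, type)
  intervals(vapply(f, `[[`, character(1), 1L),
            as.integer(vapply(f, `[[`, character(1), 4L)),
            as.integer(vapply(f, `[[`, character(1), 5L)),
            kind, label)
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are rounded to six decimals so that write/read
#' round-trips are stable.
#'
#' @param tree An [ape::phylo] tree with unique, nonempty tip labels.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (any(!nzchar(tree$tip.label))) stop("tree has an unlabeled leaf")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
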