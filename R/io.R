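# Readers and writers for the external formats the pipeline touches.
# All internal coordinates are 0-based half-open; GFF3 is converted from
# 1-based inclusive on read, BED is taken as-is.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; IUPAC ambiguity codes are kept verbatim but
#' flagged in the log because alignment scoring treats any non-ACGT
#' character as a guaranteed mismatch.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences; names carry an
#'   attribute `descriptions` with the full header lines.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate sequence id in ", path, ": ", dup)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    ht_log("read_fasta: ", sum(bad), " record(s) contain IUPAC ambiguity codes",
           " (treated as mismatch-only in alignment): ",
           paste(head(ids[bad], 5), collapse = ", "))
  attr(seqs, "descriptions") <- setNames(full, ids)
  ht_log("read_fasta: ", length(seqs), " records from ", path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Convert between GFF 1-based inclusive and internal 0-based half-open
#'
#' `gff_to_internal` and `internal_to_gff` are mutually inverse.
#'
#' @param start,end coordinates.
#' @return list with `start` and `end`.
#' @export
gff_to_internal <- function(start, end) list(start = start - 1L, end = end)

#' @rdname gff_to_internal
#' @export
internal_to_gff <- function(start, end) list(start = start + 1L, end = end)

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS/UTR features into a gene model table. When a
#' transcript has CDS but no explicit UTR features, 5' and 3' UTRs are
#' derived by subtracting the CDS span from the exon set (strand-aware).
#' Orphan child features (whose Parent is not in the file) are skipped
#' with a warning.
#'
#' @param path GFF3 file.
#' @return data.frame with columns contig, start, end (0-based half-open),
#'   strand, type (gene, mRNA, exon, CDS, five_prime_UTR,
#'   three_prime_UTR), id, parent, gene_id.
#' @export
read_gff_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (length(ln) == 0) return(empty_gene_models())
  f <- strsplit(ln, "\t", fixed = TRUE)
  keep <- vapply(f, length, 1L) >= 9
  f <- f[keep]
  df <- data.frame(
    contig = vapply(f, `[`, "", 1),
    type = vapply(f, `[`, "", 3),
    start = as.integer(vapply(f, `[`, "", 4)) - 1L,
    end = as.integer(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7),
    attr = vapply(f, `[`, "", 9),
    stringsAsFactors = FALSE)
  gettag <- function(a, tag) {
    m <- regexpr(paste0("(^|;)", tag, "=[^;]*"), a)
    out <- rep(NA_character_, length(a))
    vals <- regmatches(a, m)
    out[m > 0] <- sub(paste0("^;?", tag, "="), "", vals)
    out
  }
  df$id <- gettag(df$attr, "ID")
  df$parent <- gettag(df$attr, "Parent")
  df$attr <- NULL
  df$type[df$type %in% c("transcript")] <- "mRNA"
  df <- df[df$type %in% c("gene", "mRNA", "exon", "CDS",
                          "five_prime_UTR", "three_prime_UTR"), , drop = FALSE]
  # resolve gene_id: genes map to self, mRNA to Parent, children via mRNA
  gene_ids <- df$id[df$type == "gene"]
  mrna <- df[df$type == "mRNA", ]
  orphan_mrna <- !is.na(mrna$parent) & !(mrna$parent %in% gene_ids)
  if (any(orphan_mrna)) {
    warning("skipping ", sum(orphan_mrna), " orphan mRNA feature(s)")
    df <- df[!(df$id %in% mrna$id[orphan_mrna]), , drop = FALSE]
    mrna <- mrna[!orphan_mrna, , drop = FALSE]
  }
  mrna_gene <- setNames(mrna$parent, mrna$id)
  is_child <- df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  orphan_child <- is_child & (is.na(df$parent) | !(df$parent %in% mrna$id))
  if (any(orphan_child)) {
    warning("skipping ", sum(orphan_child), " orphan child feature(s)")
    df <- df[!orphan_child, , drop = FALSE]
  }
  df$gene_id <- NA_character_
  df$gene_id[df$type == "gene"] <- df$id[df$type == "gene"]
  df$gene_id[df$type == "mRNA"] <- mrna_gene[df$id[df$type == "mRNA"]]
  ci <- df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  df$gene_id[ci] <- mrna_gene[df$parent[ci]]
  df <- derive_utrs(df)
  ht_log("read_gff_genes: ", sum(df$type == "gene"), " genes, ",
         sum(df$type == "mRNA"), " transcripts from ", path)
  rownames(df) <- NULL
  df
}

empty_gene_models <- function() {
  data.frame(contig = character(0), type = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             id = character(0), parent = character(0),
             gene_id = character(0), stringsAsFactors = FALSE)
}

# Derive UTR rows from exon minus CDS for transcripts lacking explicit UTRs.
derive_utrs <- function(df) {
  for (tx in df$id[df$type == "mRNA"]) {
    has_utr <- any(df$type %in% c("five_prime_UTR", "three_prime_UTR") &
                     df$parent == tx, na.rm = TRUE)
    ex <- df[df$type == "exon" & !is.na(df$parent) & df$parent == tx, ]
    cds <- df[df$type == "CDS" & !is.na(df$parent) & df$parent == tx, ]
    if (has_utr || nrow(ex) == 0 || nrow(cds) == 0) next
    cds_lo <- min(cds$start); cds_hi <- max(cds$end)
    utr <- list()
    for (i in seq_len(nrow(ex))) {
      e <- ex[i, ]
      if (e$start < cds_lo) {
        piece <- e; piece$end <- min(e$end, cds_lo)
        piece$type <- if (e$strand == "-") "three_prime_UTR" else "five_prime_UTR"
        piece$id <- NA_character_
        utr[[length(utr) + 1L]] <- piece
      }
      if (e$end > cds_hi) {
        piece <- e; piece$start <- max(e$start, cds_hi)
        piece$type <- if (e$strand == "-") "five_prime_UTR" else "three_prime_UTR"
        piece$id <- NA_character_
        utr[[length(utr) + 1L]] <- piece
      }
    }
    if (length(utr)) df <- rbind(df, do.call(rbind, utr))
  }
  df
}

#' Read a BED file of intervals (already 0-based half-open)
#'
#' @param path BED3+ file.
#' @return data.frame contig/start/end plus name, score, strand if present.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  cols <- c("contig", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6))]
  df
}

#' Read a rooted, dated Newick tree
#'
#' Branch lengths are interpreted as Ma. For insertion dating the tree
#' must be rooted and ultrametric within `tol`; `require_ultrametric`
#' enforces this.
#'
#' @param path Newick file (or a Newick string via `text`).
#' @param text optional Newick string instead of a file.
#' @param require_ultrametric check root-to-tip equality within `tol`.
#' @param tol absolute tolerance in Ma.
#' @return an [ape::phylo] with a `node_ages` attribute (ages in Ma for
#'   all nodes, tips first).
#' @export
read_newick_dated <- function(path = NULL, text = NULL,
                              require_ultrametric = TRUE, tol = 1e-6) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(tr)) stop("tree must be rooted for dating")
  depths <- ape::node.depth.edgelength(tr)
  tipd <- depths[seq_len(ape::Ntip(tr))]
  if (require_ultrametric && diff(range(tipd)) > tol)
    stop("tree is not ultrametric (tip depth range ",
         signif(diff(range(tipd)), 4), " Ma); cannot be used for dating")
  ages <- max(depths) - depths
  attr(tr, "node_ages") <- ages
  tr
}

#' Ages (Ma) of all nodes of a dated tree
#'
#' @param tree a rooted tree with branch lengths in Ma.
#' @return numeric vector over nodes 1..(Ntip+Nnode), tips first.
#' @export
node_ages <- function(tree) {
  a <- attr(tree, "node_ages")
  if (!is.null(a)) return(a)
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

hit_columns <- c("query_id", "subject_id", "percent_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "score")

#' Write / read pairwise hits in the 12-column tabular dialect
#'
#' Columns: query, subject, \% identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, e-value, score. On disk coordinates
#' are 1-based inclusive and a minus-strand hit has sstart > send; in
#' memory coordinates are 0-based half-open on the plus strand with an
#' explicit `strand` column. The round trip is lossless.
#'
#' @param hits data.frame of hits as returned by [search_hits()].
#' @param path file path.
#' @return `read_hits`: the hits data.frame; `write_hits`: `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    query_id = hits$query_id, subject_id = hits$subject_id,
    percent_identity = sprintf("%.3f", hits$percent_identity),
    aln_length = hits$aln_length, mismatches = hits$mismatches,
    gap_opens = hits$gap_opens,
    q_start = hits$q_start + 1L, q_end = hits$q_end,
    s_start = ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end),
    s_end = ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L),
    evalue = format(hits$evalue, digits = 6),
    score = hits$score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @param path file path.
#' @export
read_hits <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = hit_columns)
  minus <- raw$s_start > raw$s_end
  df <- data.frame(
    query_id = raw$query_id, subject_id = raw$subject_id,
    strand = ifelse(minus, "-", "+"),
    q_start = raw$q_start - 1L, q_end = raw$q_end,
    s_start = ifelse(minus, raw$s_end, raw$s_start) - 1L,
    s_end = ifelse(minus, raw$s_start, raw$s_end),
    score = raw$score,
    percent_identity = as.numeric(raw$percent_identity),
    aln_length = raw$aln_length, mismatches = raw$mismatches,
    gap_opens = raw$gap_opens, evalue = as.numeric(raw$evalue),
    stringsAsFactors = FALSE)
  df
}
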