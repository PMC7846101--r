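# Gene-context annotation of TE insertions and flank-contiguity
# validation against comparison assemblies.

category_levels <- c("coding_exon", "utr5", "utr3", "in_transcript",
                     "upstream_le_5000", "intergenic")

#' Intersect insertions with gene models
#'
#' Each insertion receives exactly one category by the fixed priority
#' coding_exon > utr5 > utr3 > in_transcript > upstream_le_5000 >
#' intergenic (the most functionally specific overlap wins). "Upstream"
#' is strand-aware: the gap from the insertion's nearest edge to the
#' start of the transcript's 5' UTR, measured on the gene's 5' side,
#' with an inclusive 5,000-bp cutoff. For genes without an annotated 5'
#' UTR the transcript start is used instead (logged).
#'
#' @param insertions data.frame with contig, start, end (0-based
#'   half-open) and family columns (e.g. from simulation truth or a hit
#'   table).
#' @param gene_models data.frame from [read_gff_genes()].
#' @param upstream_max inclusive upstream cutoff in bp (default 5000).
#' @return data.frame of insertion records: the input columns plus
#'   category, gene_id, distance_to_5utr (NA unless upstream),
#'   insertion_size.
#' @export
intersect_insertions <- function(insertions, gene_models,
                                 upstream_max = 5000L) {
  stopifnot(all(c("contig", "start", "end") %in% names(insertions)))
  ins_gr <- GenomicRanges::GRanges(
    insertions$contig,
    IRanges::IRanges(insertions$start + 1L, insertions$end))
  feat <- function(types) {
    g <- gene_models[gene_models$type %in% types, , drop = FALSE]
    GenomicRanges::GRanges(g$contig,
                           IRanges::IRanges(g$start + 1L, g$end),
                           strand = g$strand, gene_id = g$gene_id)
  }
  cds <- feat("CDS"); utr5 <- feat("five_prime_UTR")
  utr3 <- feat("three_prime_UTR"); tx <- feat("mRNA")
  n <- nrow(insertions)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  dist5 <- rep(NA_integer_, n)
  assign_overlap <- function(gr, label) {
    ov <- GenomicRanges::findOverlaps(ins_gr, gr)
    for (k in seq_along(ov)) {
      i <- S4Vectors::queryHits(ov)[k]
      if (category[i] != "intergenic") next
      category[i] <<- label
      gene_id[i] <<- gr$gene_id[S4Vectors::subjectHits(ov)[k]]
    }
  }
  assign_overlap(cds, "coding_exon")
  assign_overlap(utr5, "utr5")
  assign_overlap(utr3, "utr3")
  assign_overlap(tx, "in_transcript")
  # upstream: strand-aware distance to the 5' UTR start (or transcript
  # start when no UTR is annotated)
  txs <- gene_models[gene_models$type == "mRNA", , drop = FALSE]
  no_utr_logged <- character(0)
  for (i in which(category == "intergenic")) {
    best <- NULL
    for (j in seq_len(nrow(txs))) {
      if (txs$contig[j] != insertions$contig[i]) next
      u5 <- gene_models[gene_models$type == "five_prime_UTR" &
                          gene_models$gene_id == txs$gene_id[j], , drop = FALSE]
      if (nrow(u5) == 0) no_utr_logged <- c(no_utr_logged, txs$gene_id[j])
      if (txs$strand[j] == "-") {
        anchor <- if (nrow(u5)) max(u5$end) else txs$end[j]
        gap <- insertions$start[i] - anchor
      } else {
        anchor <- if (nrow(u5)) min(u5$start) else txs$start[j]
        gap <- anchor - insertions$end[i]
      }
      if (gap > 0 && gap <= upstream_max &&
          (is.null(best) || gap < best$gap))
        best <- list(gap = gap, gene = txs$gene_id[j])
    }
    if (!is.null(best)) {
      category[i] <- "upstream_le_5000"
      gene_id[i] <- best$gene
      dist5[i] <- best$gap
    }
  }
  if (length(no_utr_logged))
    ht_log("intersect_insertions: no 5' UTR annotated for ",
           length(unique(no_utr_logged)),
           " gene(s); transcript start used as upstream anchor")
  out <- insertions
  out$category <- factor(category, levels = category_levels)
  out$gene_id <- gene_id
  out$distance_to_5utr <- dist5
  out$insertion_size <- insertions$end - insertions$start
  out
}

#' Validate an insertion's assembly context by flank contiguity
#'
#' The 2-kb flanks on either side of the insertion are searched in each
#' comparison assembly. For one comparison the flank pair is contiguous
#' when both flanks' best hits land on one contig within twice the
#' expected span (insertion + both flanks); it is broken when they land
#' on different contigs. The overall status is `"split"` when the pair
#' is broken in EVERY comparison assembly (the insertion is disregarded
#' as a likely assembly artifact), `"contiguous"` when at least one
#' comparison places both flanks correctly on one contig, and
#' `"unresolved"` otherwise (e.g. a flank missing from all comparisons).
#' Flanks running over a contig end are truncated and logged.
#'
#' @param insertion one row (contig, start, end).
#' @param self_assembly named character vector of the focal assembly's
#'   contigs.
#' @param comparison_assemblies list of named character vectors (or
#'   prebuilt indexes), one per comparison assembly.
#' @param flank flank length in bp (default 2000).
#' @param params search parameters.
#' @return character status; attributes `per_comparison` with the vote
#'   of each assembly.
#' @export
validate_flanks <- function(insertion, self_assembly, comparison_assemblies,
                            flank = 2000L, params = search_params("default")) {
  stopifnot(length(comparison_assemblies) >= 1)
  ctg <- self_assembly[[insertion$contig]]
  clen <- nchar(ctg)
  lf_lo <- max(0L, insertion$start - flank)
  rf_hi <- min(clen, insertion$end + flank)
  if (lf_lo == 0 && insertion$start < flank ||
      rf_hi == clen && insertion$end + flank > clen)
    ht_log("validate_flanks: flank truncated at contig end for ",
           insertion$contig)
  left <- substr(ctg, lf_lo + 1L, insertion$start)
  right <- substr(ctg, insertion$end + 1L, rf_hi)
  span_limit <- 2 * ((insertion$end - insertion$start) + 2 * flank)
  votes <- character(length(comparison_assemblies))
  for (k in seq_along(comparison_assemblies)) {
    cmp <- comparison_assemblies[[k]]
    idx <- if (inherits(cmp, "seed_index")) cmp
           else build_index(cmp, params$word_size)
    lh <- search_hits(c(left = left), idx, params)
    rh <- search_hits(c(right = right), idx, params)
    if (nrow(lh) == 0 || nrow(rh) == 0) { votes[k] <- "unresolved"; next }
    lbest <- lh[1, ]; rbest <- rh[1, ]
    if (lbest$subject_id != rbest$subject_id) { votes[k] <- "broken"; next }
    span <- max(lbest$s_end, rbest$s_end) - min(lbest$s_start, rbest$s_start)
    votes[k] <- if (span <= span_limit) "contiguous" else "unresolved"
  }
  status <- if (any(votes == "contiguous")) "contiguous"
            else if (all(votes == "broken")) "split"
            else "unresolved"
  attr(status, "per_comparison") <- votes
  status
}

#' Flank-validate a whole insertion table
#'
#' @param insertions data.frame (contig, start, end, ...).
#' @param self_assembly focal assembly.
#' @param comparison_assemblies list of comparison assemblies.
#' @param ... passed to [validate_flanks()].
#' @return insertions with a `flank_status` column.
#' @export
validate_all_flanks <- function(insertions, self_assembly,
                                comparison_assemblies, ...) {
  idxs <- lapply(comparison_assemblies, function(cmp)
    if (inherits(cmp, "seed_index")) cmp else build_index(cmp, 28L))
  insertions$flank_status <- vapply(seq_len(nrow(insertions)), function(i)
    as.character(validate_flanks(insertions[i, ], self_assembly, idxs, ...)),
    "")
  n <- table(insertions$flank_status)
  ht_log("validate_all_flanks: ",
         paste(names(n), as.integer(n), sep = "=", collapse = ", "))
  insertions
}

#' Gene-context report table
#'
#' One row per retained (non-split) insertion: gene, family, distance or
#' in-feature label, insertion size; sorted by family then gene.
#' Split-status insertions are excluded and counted in the log.
#'
#' @param records output of [intersect_insertions()] (optionally with
#'   `flank_status`).
#' @param path optional TSV output path.
#' @return report data.frame.
#' @export
gene_context_report <- function(records, path = NULL) {
  if (!is.null(records$flank_status)) {
    nsplit <- sum(records$flank_status == "split")
    if (nsplit) ht_log("gene_context_report: ", nsplit,
                       " split insertion(s) disregarded")
    records <- records[records$flank_status != "split", , drop = FALSE]
  }
  records <- records[records$category != "intergenic", , drop = FALSE]
  lab <- as.character(records$category)
  lab[lab == "coding_exon"] <- "In coding exon"
  lab[lab == "utr5"] <- "In 5' UTR"
  lab[lab == "utr3"] <- "In 3' UTR"
  lab[lab == "in_transcript"] <- "In transcript"
  lab[records$category == "upstream_le_5000"] <-
    as.character(records$distance_to_5utr[records$category == "upstream_le_5000"])
  rep <- data.frame(gene = records$gene_id, family = records$family,
                    distance_or_feature = lab,
                    insertion_size = records$insertion_size,
                    stringsAsFactors = FALSE)
  rep <- rep[order(rep$family, rep$gene), , drop = FALSE]
  rownames(rep) <- NULL
  if (!is.null(path))
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep
}
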