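# Presence/absence calling of curated families across genome and
# transcriptome panels.
#
# The three-state call mirrors the screening convention used for
# HTT surveys: a species is "present_similar" when it carries at least
# one hit of >= 1,000 bp at >= 75 percent identity to the family
# consensus, "present_divergent" when it carries more than one hit of
# >= 1,000 bp but all below 75 percent identity, and "absent" otherwise
# (in particular, a single sub-75-percent hit is not counted, which
# guards against false positives from isolated fragments).

#' Screen one genome for one family
#'
#' Runs the similarity search (relaxed preset for divergent panel
#' screens; use the default preset for close relatives), merges
#' overlapping hits per locus, and collects the evidence needed by
#' [call_presence()].
#'
#' @param family named character vector of length 1 (the consensus).
#' @param genome named character vector of contigs or a [build_index()].
#' @param params search parameters.
#' @param min_hit_len minimum hit length retained as evidence (bp).
#' @return list: `hits` (data.frame of merged hits >= min_hit_len),
#'   `best_identity`, `best_length`, `n_long_hits`, `family`.
#' @export
screen_genome <- function(family, genome, params = search_params("relaxed"),
                          min_hit_len = 1000L) {
  stopifnot(length(family) == 1)
  if (is.null(names(family))) names(family) <- "family"
  hits <- search_hits(family, genome, params)
  hits <- hits[(hits$s_end - hits$s_start) >= min_hit_len, , drop = FALSE]
  list(family = names(family),
       hits = hits,
       best_identity = if (nrow(hits)) max(hits$percent_identity) else NA_real_,
       best_length = if (nrow(hits)) max(hits$s_end - hits$s_start) else 0L,
       n_long_hits = nrow(hits))
}

#' Three-state presence call from screening evidence
#'
#' `present_similar` iff at least one hit of >= 1,000 bp reaches
#' `similar_identity` percent identity; `present_divergent` iff more
#' than one such hit exists and all are below the threshold; `absent`
#' otherwise. Raising any hit identity can never turn a present call
#' into absent (the call is monotone in the evidence).
#'
#' @param evidence result of [screen_genome()].
#' @param similar_identity identity threshold (default 75).
#' @return one of "present_similar", "present_divergent", "absent".
#' @export
call_presence <- function(evidence, similar_identity = 75) {
  h <- evidence$hits
  if (is.null(h) || nrow(h) == 0) return("absent")
  if (any(h$percent_identity >= similar_identity)) return("present_similar")
  if (nrow(h) > 1) return("present_divergent")
  "absent"
}

#' Presence/absence matrix of families across a genome panel
#'
#' @param families named character vector of family consensi.
#' @param genomes named list of genomes (named character vectors of
#'   contigs).
#' @param params search parameters (relaxed preset by default).
#' @param verify reciprocal-verification library: when supplied (named
#'   character vector including the probed families), each candidate
#'   region is re-searched against it and hits whose best match is a
#'   different family are dropped (see [verify_reciprocal()]).
#' @return list: `calls` (character matrix families x species),
#'   `evidence` (nested list).
#' @export
screen_panel <- function(families, genomes, params = search_params("relaxed"),
                         verify = NULL) {
  calls <- matrix("absent", length(families), length(genomes),
                  dimnames = list(names(families), names(genomes)))
  evidence <- list()
  for (sp in names(genomes)) {
    idx <- build_index(genomes[[sp]], params$word_size)
    for (fam in names(families)) {
      ev <- screen_genome(families[fam], idx, params)
      if (!is.null(verify))
        ev <- verify_reciprocal(ev, verify, idx)
      calls[fam, sp] <- call_presence(ev)
      evidence[[sp]][[fam]] <- ev
    }
  }
  ht_log("screen_panel: ", length(families), " families x ",
         length(genomes), " species")
  list(calls = calls, evidence = evidence)
}

#' Reciprocal verification of screening evidence
#'
#' Each evidence region is extracted from the screened genome and
#' re-searched against the whole family library; the region is kept only
#' when its best library match is the probing family. Dropped regions
#' are logged.
#'
#' @param evidence result of [screen_genome()].
#' @param family_library named character vector of all family consensi.
#' @param genome the screened genome (named contig vector or index) the
#'   evidence refers to.
#' @param params search parameters for the reciprocal search.
#' @return evidence list with non-reciprocal hits removed.
#' @export
verify_reciprocal <- function(evidence, family_library, genome,
                              params = search_params("relaxed")) {
  h <- evidence$hits
  if (is.null(h) || nrow(h) == 0) return(evidence)
  idx <- if (inherits(genome, "seed_index")) genome
         else build_index(genome, params$word_size)
  lib_idx <- build_index(family_library, params$word_size)
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    region <- extract_hit(idx, h[i, ], 0L)
    rh <- search_hits(c(region = region), lib_idx, params)
    keep[i] <- nrow(rh) > 0 && rh$subject_id[1] == evidence$family
  }
  if (any(!keep))
    ht_log("verify_reciprocal[", evidence$family, "]: dropped ",
           sum(!keep), " non-reciprocal region(s)")
  h <- h[keep, , drop = FALSE]
  list(family = evidence$family, hits = h,
       best_identity = if (nrow(h)) max(h$percent_identity) else NA_real_,
       best_length = if (nrow(h)) max(h$s_end - h$s_start) else 0L,
       n_long_hits = nrow(h))
}

#' Transcript support call for a family in a transcriptome assembly
#'
#' `supported` iff some transcript hit reaches `min_identity` percent
#' identity over at least `min_len` bp; `fragment_only` iff such
#' identity is reached only on shorter hits; `none` otherwise.
#'
#' @param family named character vector of length 1.
#' @param transcriptome named character vector of transcripts (or index).
#' @param params search parameters.
#' @param min_identity identity threshold in percent (default 95).
#' @param min_len minimum supported-transcript hit length (default 500).
#' @return list: `call` in supported/fragment_only/none, `best_identity`,
#'   `best_len_at_identity`, `hits`.
#' @export
transcript_support <- function(family, transcriptome,
                               params = search_params("default"),
                               min_identity = 95, min_len = 500L) {
  stopifnot(length(family) == 1)
  if (is.null(names(family))) names(family) <- "family"
  hits <- search_hits(family, transcriptome, params)
  hi <- hits[hits$percent_identity >= min_identity, , drop = FALSE]
  lens <- if (nrow(hi)) hi$s_end - hi$s_start else integer(0)
  call <- if (nrow(hi) == 0) "none"
          else if (any(lens >= min_len)) "supported"
          else "fragment_only"
  list(call = call,
       best_identity = if (nrow(hits)) max(hits$percent_identity) else NA_real_,
       best_len_at_identity = if (nrow(hi)) max(lens) else 0L,
       hits = hits)
}

#' Serialize a presence matrix to TSV and back
#' @param calls character matrix (families x species).
#' @param path TSV file.
#' @return `read_presence_matrix`: the matrix.
#' @export
write_presence_matrix <- function(calls, path) {
  df <- data.frame(family = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$family
  m
}
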