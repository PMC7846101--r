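# Built-in seed-and-extend local DNA similarity search.
#
# The engine finds exact word seeds, clusters them by diagonal, and runs a
# banded affine-gap local alignment around each cluster; below a size
# threshold it simply runs the exact full-matrix local DP, so short pairs
# are scored identically to exhaustive Smith-Waterman. Any non-ACGT
# character scores as a mismatch, never as a match.

#' Search parameter presets
#'
#' Two presets mirror the two search regimes used throughout the pipeline:
#' `"default"` (megablast-like: word 28, reward 1, penalty -2) for
#' within-species and close-relative searches, and `"relaxed"` (word 10,
#' reward 3, penalty -4, gap open 30 / extend 6, e-value 2e-5, dust on)
#' for divergent cross-species panel screens. The `default` preset
#' documents its own values; it does not claim bit-compatibility with any
#' external tool's defaults.
#'
#' @param preset `"default"` or `"relaxed"`.
#' @param ... overrides for individual fields (word_size, reward, penalty,
#'   gap_open, gap_extend, max_evalue, min_score, dust, dust_threshold,
#'   band_margin, cluster_diag_gap, cluster_pos_gap, full_dp_limit, K).
#' @return list of parameters.
#' @export
search_params <- function(preset = c("default", "relaxed"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "default") {
    list(word_size = 28L, reward = 1L, penalty = -2L,
         gap_open = 2L, gap_extend = 2L,
         max_evalue = 1e-5, min_score = NULL, dust = TRUE)
  } else {
    list(word_size = 10L, reward = 3L, penalty = -4L,
         gap_open = 30L, gap_extend = 6L,
         xdrop_ungapped = 80, xdrop_gapped = 130, xdrop_gapped_final = 150,
         max_evalue = 2e-5, min_score = NULL, dust = TRUE)
  }
  p <- utils::modifyList(p, list(dust_threshold = 1.5, band_margin = 120L,
                                 cluster_diag_gap = 100L, cluster_pos_gap = 1500L,
                                 full_dp_limit = 250000, K = 0.1,
                                 preset = preset))
  p <- utils::modifyList(p, list(...))
  stopifnot(p$word_size >= 7, p$reward > 0, p$penalty < 0,
            p$gap_open >= 0, p$gap_extend >= 0)
  p
}

#' Reverse complement
#' @param seq DNA string.
#' @return reverse complement string.
#' @export
revcomp <- function(seq) dna_decode_cpp(revcomp_codes_cpp(dna_encode_cpp(seq)))

#' Build an exact-word seed index over subject sequences
#'
#' Both strands are searched by reverse-complementing the query at search
#' time; the index itself stores plus-strand words only.
#'
#' @param subject_seqs named character vector of subject sequences.
#' @param word_size exact word length (7-31).
#' @return a seed index object.
#' @export
build_index <- function(subject_seqs, word_size) {
  stopifnot(length(subject_seqs) >= 1, !is.null(names(subject_seqs)))
  codes <- lapply(subject_seqs, dna_encode_cpp)
  lens <- vapply(codes, length, 1L)
  if (word_size > max(lens))
    warning("word_size ", word_size, " exceeds longest subject (", max(lens),
            "): index is empty")
  structure(list(ptr = build_seed_index_cpp(unname(codes), word_size),
                 contigs = names(subject_seqs), lens = lens,
                 codes = codes, k = as.integer(word_size),
                 total_len = sum(as.numeric(lens))),
            class = "seed_index")
}

#' Look up the occurrences of one exact word in a seed index
#' @param index a [build_index()] object.
#' @param kmer word of length `index$k`.
#' @return data.frame contig / pos (0-based).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  m <- query_seed_index_cpp(index$ptr, dna_encode_cpp(kmer), FALSE, 0)
  data.frame(contig = index$contigs[m[, 2] + 1L], pos = m[, 3],
             stringsAsFactors = FALSE)
}

#' Karlin-Altschul lambda for match/mismatch scoring
#'
#' Solves sum over base pairs of p_i p_j exp(lambda s_ij) = 1 under
#' uniform base frequencies, i.e. (1/4) e^(lambda R) + (3/4) e^(lambda P) = 1,
#' for the unique positive root.
#'
#' @param reward match reward (> 0).
#' @param penalty mismatch penalty (< 0).
#' @return lambda.
#' @export
karlin_lambda <- function(reward, penalty) {
  if (reward / 4 + 3 * penalty / 4 >= 0)
    stop("lambda solver: expected score per aligned pair must be negative")
  f <- function(l) 0.25 * exp(l * reward) + 0.75 * exp(l * penalty) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(1e-9, hi), tol = 1e-12)$root
}

#' Karlin-Altschul e-value of a hit
#'
#' E = K * m * n * exp(-lambda * score). Monotone decreasing in score and
#' linear in the search space m * n.
#'
#' @param score alignment score (> 0).
#' @param m query length; @param n total subject length.
#' @param params a [search_params()] list (scoring and K).
#' @return expected number of chance hits at or above `score`.
#' @export
evalue_ka <- function(score, m, n, params = search_params()) {
  stopifnot(all(score > 0))
  lam <- karlin_lambda(params$reward, params$penalty)
  params$K * m * n * exp(-lam * score)
}

score_cutoff <- function(params, m, n) {
  if (!is.null(params$min_score)) return(params$min_score)
  lam <- karlin_lambda(params$reward, params$penalty)
  max(1, ceiling(log(params$K * m * n / params$max_evalue) / lam))
}

# Cluster seed matches (single contig) into candidate loci.
cluster_seeds <- function(qpos, spos, diag_gap, pos_gap) {
  d <- spos - qpos
  o <- order(d, spos)
  d <- d[o]; qp <- qpos[o]; sp <- spos[o]
  grp <- cumsum(c(1L, as.integer(diff(d) > diag_gap)))
  out <- list()
  for (g in split(seq_along(d), grp)) {
    oo <- g[order(sp[g])]
    sub <- cumsum(c(1L, as.integer(diff(sp[oo]) > pos_gap)))
    for (h in split(oo, sub))
      out[[length(out) + 1L]] <- list(qpos = qp[h], spos = sp[h], diag = d[h])
  }
  out
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             strand = character(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0), score = integer(0),
             percent_identity = numeric(0), aln_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

hit_from_alignment <- function(res, query_id, subject_id, strand, qlen,
                               s_offset, lam, K, m, n) {
  aln_len <- res$aln_length
  if (aln_len == 0) return(NULL)
  ops <- res$ops
  gap_opens <- sum(diff(c(0L, as.integer(ops != 0))) == 1L)
  qs <- res$q_start; qe <- res$q_end
  if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
  data.frame(query_id = query_id, subject_id = subject_id, strand = strand,
             q_start = qs, q_end = qe,
             s_start = res$s_start + s_offset, s_end = res$s_end + s_offset,
             score = res$score,
             percent_identity = 100 * res$matches / aln_len,
             aln_length = aln_len,
             mismatches = aln_len - res$matches - res$gaps,
             gap_opens = gap_opens,
             evalue = K * m * n * exp(-lam * res$score),
             stringsAsFactors = FALSE)
}

# Drop hits whose subject interval is mostly covered by a better hit on
# the same contig (greedy, by descending score).
dedupe_hits <- function(hits, max_frac = 0.5) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      prior <- hits[keep & hits$subject_id == hits$subject_id[i], , drop = FALSE]
      if (nrow(prior)) {
        ov <- pmax(0, pmin(prior$s_end, hits$s_end[i]) -
                     pmax(prior$s_start, hits$s_start[i]))
        short <- pmin(prior$s_end - prior$s_start,
                      hits$s_end[i] - hits$s_start[i])
        if (any(ov > max_frac * short)) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Local similarity search of queries against subjects
#'
#' Seed words are clustered by diagonal; each cluster seeds a banded
#' affine-gap local alignment. When the whole problem is small (single
#' contig, m*n below `full_dp_limit`) the exact unbanded local DP is run
#' instead, so scores on short pairs equal the full Smith-Waterman
#' optimum. Hits are reported on the plus strand of both sequences with a
#' strand flag, deduplicated by subject overlap (best score wins) and
#' sorted by descending score. Percent identity counts gap columns in the
#' denominator.
#'
#' @param query named character vector of query sequences (or one string).
#' @param subject named character vector of subjects, or a [build_index()]
#'   object (reused across calls for speed).
#' @param params a [search_params()] list.
#' @return data.frame of hits (possibly empty): query_id, subject_id,
#'   strand, q_start, q_end, s_start, s_end (0-based half-open, plus
#'   strand), score, percent_identity, aln_length, mismatches, gap_opens,
#'   evalue.
#' @export
search_hits <- function(query, subject, params = search_params()) {
  if (length(query) == 0) return(empty_hits())
  if (is.null(names(query))) {
    if (length(query) == 1) names(query) <- "query" else
      stop("multiple queries must be named")
  }
  idx <- if (inherits(subject, "seed_index")) subject
         else build_index(subject, params$word_size)
  lam <- karlin_lambda(params$reward, params$penalty)
  n_total <- idx$total_len
  out <- list()
  for (qid in names(query)) {
    qseq <- query[[qid]]
    qlen <- nchar(qseq)
    if (qlen == 0) next
    qcodes_p <- dna_encode_cpp(qseq)
    cutoff <- score_cutoff(params, qlen, n_total)
    small <- length(idx$codes) == 1 &&
      as.numeric(qlen) * as.numeric(idx$lens[1]) <= params$full_dp_limit
    for (strand in c("+", "-")) {
      qcodes <- if (strand == "+") qcodes_p else revcomp_codes_cpp(qcodes_p)
      if (small) {
        scod <- idx$codes[[1]]
        res <- align_band_cpp(qcodes, scod, params$reward, params$penalty,
                              params$gap_open, params$gap_extend,
                              -qlen, length(scod), 0L)
        if (res$score >= cutoff) {
          h <- hit_from_alignment(res, qid, idx$contigs[1], strand, qlen,
                                  0L, lam, params$K, qlen, n_total)
          if (!is.null(h)) out[[length(out) + 1L]] <- h
        }
        next
      }
      seeds <- query_seed_index_cpp(idx$ptr, qcodes,
                                    isTRUE(params$dust), params$dust_threshold)
      if (nrow(seeds) == 0) next
      for (ci in unique(seeds[, 2])) {
        sel <- seeds[, 2] == ci
        scod <- idx$codes[[ci + 1L]]
        slen <- length(scod)
        clusters <- cluster_seeds(seeds[sel, 1], seeds[sel, 3],
                                  params$cluster_diag_gap,
                                  params$cluster_pos_gap)
        # cheap ungapped X-drop prefilter: a cluster must contain a seed
        # whose ungapped extension reaches a fraction of the score cutoff
        # before the banded gapped DP is spent on it
        xd <- if (!is.null(params$xdrop_ungapped)) params$xdrop_ungapped else 40
        pre_min <- ceiling(0.6 * cutoff)
        for (cl in clusters) {
          take <- if (length(cl$qpos) > 8)
            unique(round(seq(1, length(cl$qpos), length.out = 8))) else
              seq_along(cl$qpos)
          ug <- max(vapply(take, function(t)
            ungapped_extend_cpp(qcodes, scod, cl$qpos[t], cl$spos[t],
                                idx$k, params$reward, params$penalty, xd),
            1L))
          if (ug < pre_min) next
          margin <- params$band_margin
          s_lo <- max(0L, min(cl$diag) - margin)
          s_hi <- min(slen, max(cl$diag) + qlen + margin)
          sub <- scod[(s_lo + 1L):s_hi]
          band_lo <- min(cl$diag) - margin - s_lo
          band_hi <- max(cl$diag) + margin - s_lo
          res <- align_band_cpp(qcodes, sub, params$reward, params$penalty,
                                params$gap_open, params$gap_extend,
                                band_lo, band_hi, 0L)
          if (res$score < cutoff) next
          h <- hit_from_alignment(res, qid, idx$contigs[ci + 1L], strand,
                                  qlen, s_lo, lam, params$K, qlen, n_total)
          if (!is.null(h)) out[[length(out) + 1L]] <- h
        }
      }
    }
  }
  if (length(out) == 0) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- dedupe_hits(hits)
  hits <- hits[order(-hits$score, hits$subject_id, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Reciprocal best hits between two hit sets
#'
#' A pair (a, b) is reported when a's best subject is b and b's best
#' subject is a. Ties on score are broken by higher percent identity,
#' then by lexicographically smaller subject id.
#'
#' @param hits_ab hits of set A queried against set B.
#' @param hits_ba hits of set B queried against set A.
#' @return data.frame with columns a, b.
#' @export
reciprocal_best_hit <- function(hits_ab, hits_ba) {
  best_of <- function(hits) {
    if (nrow(hits) == 0) return(character(0))
    o <- order(hits$query_id, -hits$score, -hits$percent_identity,
               hits$subject_id)
    h <- hits[o, ]
    h <- h[!duplicated(h$query_id), ]
    setNames(h$subject_id, h$query_id)
  }
  ab <- best_of(hits_ab)
  ba <- best_of(hits_ba)
  pairs <- list()
  for (a in names(ab)) {
    b <- ab[[a]]
    if (!is.na(ba[b]) && !is.null(ba[b]) && identical(unname(ba[b]), a))
      pairs[[length(pairs) + 1L]] <- data.frame(a = a, b = b,
                                                stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0)
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, pairs))
}
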