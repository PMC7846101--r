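# Iterative "search, extend, align, trim" (SEAT) consensus refinement.
#
# One round: search the genome with the current consensus, keep the best
# hits above a length floor, extend their coordinates into the flanks,
# extract (reverse-complementing minus-strand hits), align, trim
# non-homologous flanks by column occupancy, and call a majority-rule
# consensus. Rounds repeat until successive consensi converge.

#' SEAT curation parameters
#'
#' @param top_n hits used per round (default 25).
#' @param min_hit_len minimum hit length in bp (default 1000).
#' @param extension bp added each side of a hit (default 1000; cross-species
#'   mode uses 3000).
#' @param max_iter maximum refinement rounds.
#' @param convergence_identity percent identity between successive consensi
#'   at which iteration stops.
#' @param consensus_min_occupancy minimum non-gap column occupancy for a
#'   column to contribute a consensus base.
#' @param edge_trim_window consecutive qualifying columns required at each
#'   alignment edge.
#' @param full_length_frac fraction of the consensus a hit must cover to
#'   count as a full-length copy.
#' @param split_identity percent-identity cut for subfamily splitting.
#' @param search a [search_params()] list used for the genome searches.
#' @return parameter list.
#' @export
seat_params <- function(top_n = 25L, min_hit_len = 1000L, extension = 1000L,
                        max_iter = 10L, convergence_identity = 99,
                        consensus_min_occupancy = 0.5, edge_trim_window = 10L,
                        full_length_frac = 0.95, split_identity = 94,
                        search = search_params("default")) {
  stopifnot(top_n >= 2, extension >= 0)
  list(top_n = top_n, min_hit_len = min_hit_len, extension = extension,
       max_iter = max_iter, convergence_identity = convergence_identity,
       consensus_min_occupancy = consensus_min_occupancy,
       edge_trim_window = edge_trim_window,
       full_length_frac = full_length_frac,
       split_identity = split_identity, search = search)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

aln_occupancy <- function(aln) {
  m <- aln_matrix(aln)
  colMeans(m != "-")
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence with the largest summed pairwise similarity
#' (best local hit score against every other input); every sequence is
#' aligned to the center with a free-end-gap affine global alignment and
#' the pairwise alignments are merged by gap projection. The center
#' choice is canonical (ties broken by input order after sorting names),
#' so permuting the input order does not change the result.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @return named character vector of equal-length gapped rows, in the
#'   input order.
#' @export
msa <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  ord <- order(names(seqs))
  canon <- seqs[ord]
  # relaxed-regime scoring (reward 3 / penalty -4) keeps the expected
  # per-column score positive down to ~60 percent identity, so divergent
  # homologs (cross-species repeat sets) still align
  k <- max(7L, min(12L, min(nchar(canon))))
  p <- search_params("relaxed", word_size = k, min_score = 1,
                     full_dp_limit = 40000)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    idx <- build_index(canon[i], k)
    for (j in (i + 1):n) {
      h <- search_hits(canon[j], idx, p)
      S[i, j] <- S[j, i] <- if (nrow(h)) h$score[1] else 0
    }
  }
  center <- which.max(rowSums(S))
  cseq <- canon[[center]]
  Lc <- nchar(cseq)
  ccod <- dna_encode_cpp(cseq)
  ins_before <- matrix(0L, n, Lc + 1L) # per row, insertions before center pos
  aligned <- vector("list", n) # per row: list(ins = list of char vectors, col = chars)
  for (i in seq_len(n)) {
    if (i == center) next
    x <- canon[[i]]
    xc <- dna_encode_cpp(x)
    res <- align_band_cpp(xc, ccod, p$reward, p$penalty, p$gap_open,
                          p$gap_extend, -length(xc), Lc, 0L)
    ops <- res$ops
    qs <- res$q_start; ss <- res$s_start
    qe <- res$q_end; se <- res$s_end
    xv <- strsplit(x, "", fixed = TRUE)[[1]]
    ins <- vector("list", Lc + 1L)
    colchar <- rep("-", Lc)
    cur_q <- qs; cur_s <- ss
    if (qs > 0) ins[[ss + 1L]] <- xv[seq_len(qs)]
    for (op in ops) {
      if (op == 0L) {
        colchar[cur_s + 1L] <- xv[cur_q + 1L]
        cur_q <- cur_q + 1L; cur_s <- cur_s + 1L
      } else if (op == 1L) { # consume x only: insertion before center pos cur_s
        ins[[cur_s + 1L]] <- c(ins[[cur_s + 1L]], xv[cur_q + 1L])
        cur_q <- cur_q + 1L
      } else {
        cur_s <- cur_s + 1L
      }
    }
    if (qe < length(xv))
      ins[[se + 1L]] <- c(ins[[se + 1L]], xv[(qe + 1L):length(xv)])
    ins_before[i, ] <- vapply(ins, length, 1L)
    aligned[[i]] <- list(ins = ins, col = colchar)
  }
  # Segments of a row that did not align to the center are not homologous
  # to anything, so every row gets its own private insertion columns
  # (blocks from different rows are never stacked into shared columns);
  # occupancy-based trimming then removes them.
  M <- colSums(ins_before)
  before <- apply(ins_before, 2, function(x) c(0L, cumsum(x))[seq_len(n)])
  if (is.null(dim(before))) before <- matrix(before, nrow = n)
  cvec <- strsplit(cseq, "", fixed = TRUE)[[1]]
  rows <- character(n)
  for (i in seq_len(n)) {
    parts <- vector("list", 2L * (Lc + 1L))
    for (pos in seq_len(Lc + 1L)) {
      if (i == center) {
        parts[[2L * pos - 1L]] <- strrep("-", M[pos])
        if (pos <= Lc) parts[[2L * pos]] <- cvec[pos]
      } else {
        a <- aligned[[i]]
        k_ins <- length(a$ins[[pos]])
        parts[[2L * pos - 1L]] <- paste0(
          strrep("-", before[i, pos]),
          paste(a$ins[[pos]], collapse = ""),
          strrep("-", M[pos] - before[i, pos] - k_ins))
        if (pos <= Lc) parts[[2L * pos]] <- a$col[pos]
      }
    }
    rows[i] <- paste(unlist(parts), collapse = "")
  }
  names(rows) <- names(canon)
  rows[names(seqs)]
}

#' Majority-rule consensus of an alignment
#'
#' Majority base among non-gap characters per column; ties broken in the
#' fixed order A < C < G < T; a column contributes a base only if its
#' non-gap occupancy is at least `min_occupancy`.
#'
#' @param aln gapped rows (equal length).
#' @param min_occupancy occupancy threshold (inclusive).
#' @return consensus DNA string.
#' @export
consensus_call <- function(aln, min_occupancy = 0.5) {
  m <- aln_matrix(aln)
  bases <- c("A", "C", "G", "T")
  out <- apply(m, 2, function(col) {
    occ <- mean(col != "-")
    if (occ < min_occupancy) return("")
    cnt <- table(factor(col[col %in% bases], levels = bases))
    if (sum(cnt) == 0) return("")
    bases[which.max(cnt)]
  })
  paste(out, collapse = "")
}

#' Percent identity between two sequences (free-end-gap alignment)
#'
#' @param a,b DNA strings.
#' @return percent identity over the aligned block (gap columns counted
#'   in the denominator).
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) return(0)
  ca <- dna_encode_cpp(a); cb <- dna_encode_cpp(b)
  res <- align_band_cpp(ca, cb, 1L, -2L, 4L, 1L, -length(ca), length(cb), 2L)
  if (res$aln_length == 0) return(0)
  100 * res$matches / res$aln_length
}

#' Trim non-homologous alignment flanks by column occupancy
#'
#' From each end, columns are dropped until a window of
#' `edge_trim_window` consecutive columns all reach non-gap occupancy
#' >= `min_occupancy` (inclusive); internal columns with occupancy below
#' `internal_min` are also dropped. Errors rather than returning an empty
#' alignment.
#'
#' @param aln gapped rows.
#' @param params a [seat_params()] list (window and occupancy settings).
#' @param internal_min occupancy below which internal columns are dropped.
#' @return trimmed alignment with attribute `kept` (logical over input
#'   columns).
#' @export
trim_flanks <- function(aln, params = seat_params(), internal_min = 0.2) {
  m <- aln_matrix(aln)
  occ <- colMeans(m != "-")
  w <- params$edge_trim_window
  nc <- length(occ)
  if (nc < w) stop("no homologous core: alignment shorter than trim window")
  good <- occ >= params$consensus_min_occupancy
  runfun <- function(g) {
    # first index i such that g[i..i+w-1] all TRUE
    cs <- cumsum(as.integer(g))
    win <- cs[w:length(g)] - c(0, cs)[seq_len(length(g) - w + 1L)]
    which(win == w)[1]
  }
  lo <- runfun(good)
  hi_rev <- runfun(rev(good))
  if (is.na(lo) || is.na(hi_rev)) stop("no homologous core in alignment")
  hi <- nc - hi_rev + 1L
  keep <- rep(FALSE, nc)
  keep[lo:hi] <- TRUE
  keep[occ < internal_min] <- FALSE
  if (!any(keep)) stop("no homologous core in alignment")
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(aln)
  attr(out, "kept") <- keep
  out
}

# Pairwise identity between aligned rows over columns where both are
# non-gap.
row_identity_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  I <- matrix(100, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(both)) { I[i, j] <- I[j, i] <- 0; next }
    I[i, j] <- I[j, i] <- 100 * mean(m[i, both] == m[j, both])
  }
  I
}

#' Split an alignment into subfamilies by pairwise identity clustering
#'
#' Average-linkage clustering of the aligned rows on (100 - identity),
#' cut at `split_identity` percent. Clusters with at least two rows
#' become subfamilies; singleton rows attach to the cluster they are most
#' similar to. Subfamilies are named by the suffixes H1, H2, ... in
#' decreasing cluster size.
#'
#' @param aln gapped rows (>= 2).
#' @param split_identity identity cut (percent).
#' @return named list of alignments (all-gap columns removed); names are
#'   the H-suffixes.
#' @export
split_subfamilies <- function(aln, split_identity = 94) {
  stopifnot(length(aln) >= 2)
  I <- row_identity_matrix(aln)
  d <- as.dist(100 - I)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = 100 - split_identity)
  sizes <- table(cl)
  cores <- as.integer(names(sizes)[sizes >= 2])
  if (length(cores) == 0) cores <- as.integer(names(sizes))
  for (i in which(!(cl %in% cores))) {
    best <- cores[which.max(vapply(cores, function(g)
      mean(I[i, cl == g & seq_along(cl) != i]), 1))]
    cl[i] <- best
  }
  sizes <- sort(table(cl), decreasing = TRUE)
  out <- list()
  for (r in seq_along(sizes)) {
    rows <- aln[cl == as.integer(names(sizes)[r])]
    m <- aln_matrix(rows)
    keep <- colSums(m != "-") > 0
    rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
    names(rows) <- names(aln)[cl == as.integer(names(sizes)[r])]
    out[[paste0("H", r)]] <- rows
  }
  out
}

#' One SEAT curation run for a seed consensus on a genome
#'
#' @param seed_consensus starting consensus (>= 100 bp).
#' @param genome named character vector of contigs, or a [build_index()]
#'   object built with `params$search$word_size`.
#' @param params a [seat_params()] list.
#' @param name family name used in the result.
#' @return a `curated_consensus` list: name, seq, iterations,
#'   n_copies_used, identity_trace (percent identity of each consensus to
#'   its predecessor), converged, single_copy, alignment (final trimmed
#'   MSA or NULL).
#' @export
seat_iterate <- function(seed_consensus, genome, params = seat_params(),
                         name = "family") {
  stopifnot(nchar(seed_consensus) >= 100)
  idx <- if (inherits(genome, "seed_index")) genome
         else build_index(genome, params$search$word_size)
  consensus <- seed_consensus
  trace <- numeric(0)
  aln <- NULL
  n_used <- 0L
  converged <- FALSE
  for (iter in seq_len(params$max_iter)) {
    hits <- search_hits(setNames(consensus, name), idx, params$search)
    qual <- hits[(hits$s_end - hits$s_start) >= params$min_hit_len, ,
                 drop = FALSE]
    if (nrow(qual) == 0) {
      if (iter == 1) stop("family not present at curation thresholds")
      break
    }
    if (nrow(qual) == 1) {
      copy <- extract_hit(idx, qual[1, ], 0L)
      ht_log("seat_iterate[", name, "]: single qualifying copy, ",
             "returned verbatim")
      return(structure(list(name = name, seq = copy, iterations = iter,
                            n_copies_used = 1L, identity_trace = trace,
                            converged = TRUE, single_copy = TRUE,
                            alignment = NULL),
                       class = "curated_consensus"))
    }
    top <- head(qual, params$top_n)
    seqs <- vapply(seq_len(nrow(top)), function(i)
      extract_hit(idx, top[i, ], params$extension), "")
    names(seqs) <- sprintf("copy%02d", seq_along(seqs))
    aln <- msa(seqs)
    aln <- trim_flanks(aln, params)
    cons_new <- consensus_call(aln, params$consensus_min_occupancy)
    if (!nchar(cons_new)) stop("empty consensus after trimming")
    idty <- pairwise_identity(cons_new, consensus)
    trace <- c(trace, idty)
    n_used <- nrow(top)
    consensus <- cons_new
    if (idty >= params$convergence_identity) { converged <- TRUE; break }
  }
  ht_log("seat_iterate[", name, "]: ", length(trace), " iterations, ",
         n_used, " copies, final length ", nchar(consensus),
         if (converged) ", converged" else ", max_iter reached")
  structure(list(name = name, seq = consensus, iterations = length(trace),
                 n_copies_used = n_used, identity_trace = trace,
                 converged = converged, single_copy = FALSE,
                 alignment = aln),
            class = "curated_consensus")
}

# Extract a hit region (optionally extended, clipped at contig ends) from
# an index, reverse-complementing minus-strand hits.
extract_hit <- function(idx, hit, extension) {
  ci <- match(hit$subject_id, idx$contigs)
  len <- idx$lens[ci]
  lo <- max(0L, hit$s_start - extension)
  hi <- min(len, hit$s_end + extension)
  piece <- dna_decode_cpp(idx$codes[[ci]][(lo + 1L):hi])
  if (hit$strand == "-") piece <- revcomp(piece)
  piece
}
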