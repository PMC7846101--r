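# Repeat-versus-species phylogeny discordance: intactness filtering,
# alignment block trimming, distance/NJ tree building, and
# Robinson-Foulds comparison against the host tree. Extreme discordance
# of TE and host topologies (e.g. a snake TE clustering inside teleost
# fish TEs) is the third diagnostic of horizontal transfer.

#' Filter sequences to structurally intact elements
#'
#' Keeps sequences whose domain evidence covers at least `min_coverage`
#' of BOTH the endonuclease and reverse transcriptase domains.
#'
#' @param seqs named character vector.
#' @param domain_hits data.frame (consensus_id, domain, coverage).
#' @param min_coverage coverage threshold (default 0.8).
#' @param domains required domain names.
#' @return subset of `seqs`; removals logged. Errors when nothing
#'   survives.
#' @export
filter_intact <- function(seqs, domain_hits, min_coverage = 0.8,
                          domains = c("EN", "RT")) {
  keep <- vapply(names(seqs), function(id) {
    h <- domain_hits[domain_hits$consensus_id == id, , drop = FALSE]
    all(vapply(domains, function(d)
      any(h$domain == d & h$coverage >= min_coverage), TRUE))
  }, TRUE)
  if (!any(keep)) stop("no intact sequences after domain filtering")
  if (any(!keep))
    ht_log("filter_intact: removed ", sum(!keep), " sequence(s): ",
           paste(names(seqs)[!keep], collapse = ", "))
  seqs[keep]
}

#' Block-trim an alignment (relaxed mode)
#'
#' Keeps columns with non-gap occupancy >= `min_occupancy`, then keeps
#' only runs of at least `min_run` consecutive kept columns, removing
#' poorly aligned regions while allowing small final blocks and gaps
#' inside blocks.
#'
#' @param aln gapped rows (>= 4).
#' @param min_occupancy column occupancy threshold (default 0.5).
#' @param min_run minimum kept-column run (default 5).
#' @return trimmed alignment with attribute `kept`.
#' @export
block_trim <- function(aln, min_occupancy = 0.5, min_run = 5L) {
  stopifnot(length(aln) >= 4)
  m <- aln_matrix(aln)
  occ <- colMeans(m != "-")
  keep <- occ >= min_occupancy
  r <- rle(keep)
  r$values[r$values & r$lengths < min_run] <- FALSE
  keep <- inverse.rle(r)
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(aln)
  attr(out, "kept") <- keep
  out
}

#' Pairwise distances between aligned rows
#'
#' p-distance (or its Jukes-Cantor transform) over columns where both
#' rows are non-gap.
#'
#' @param aln gapped rows.
#' @param distance "p" or "jc".
#' @return dist object.
#' @export
aln_distances <- function(aln, distance = c("p", "jc")) {
  distance <- match.arg(distance)
  I <- row_identity_matrix(aln)
  p <- (100 - I) / 100
  d <- if (distance == "jc") {
    dd <- jc_correct(p); diag(dd) <- 0; dd
  } else p
  as.dist(d)
}

#' Neighbor-joining tree from an alignment
#'
#' Distances on shared non-gap columns; negative branch lengths clamped
#' to zero. The result is the usual unrooted binary NJ topology.
#'
#' @param aln gapped rows (>= 4 sequences).
#' @param distance "p" or "jc".
#' @return an [ape::phylo].
#' @export
nj_tree <- function(aln, distance = c("p", "jc")) {
  stopifnot(length(aln) >= 4)
  tr <- ape::nj(aln_distances(aln, distance))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Discordance statistics between a TE tree and the host species tree
#'
#' Duplicate-host TE tips are first collapsed (keeping, per host, the
#' tip with the smallest mean patristic distance to the other tips of
#' the same host, i.e. the one closest to that host clade's centroid);
#' the collapsed TE tree is relabelled by host and compared with the
#' species tree pruned to the shared hosts via the normalized
#' Robinson-Foulds distance. For every TE tip the host of its
#' cladistically closest (smallest patristic distance) non-self tip is
#' also reported: under horizontal transfer a recipient's nearest
#' neighbor is the donor lineage's TE, not its own host's vertical TEs.
#'
#' @param te_tree phylo of TE sequences.
#' @param species_tree host phylo.
#' @param tip_to_host named character vector mapping every TE tip to a
#'   host species.
#' @return list: rf_normalized, nearest_neighbor (data.frame tip, host,
#'   nn_tip, nn_host), n_shared_hosts.
#' @export
discordance_stat <- function(te_tree, species_tree, tip_to_host) {
  missing <- setdiff(te_tree$tip.label, names(tip_to_host))
  if (length(missing))
    stop("no host mapping for: ", paste(missing, collapse = ", "))
  D <- ape::cophenetic.phylo(te_tree)
  # nearest neighbors before any collapsing
  nn <- do.call(rbind, lapply(te_tree$tip.label, function(tp) {
    d <- D[tp, setdiff(colnames(D), tp)]
    nn_tip <- names(d)[which.min(d)]
    data.frame(tip = tp, host = unname(tip_to_host[tp]), nn_tip = nn_tip,
               nn_host = unname(tip_to_host[nn_tip]),
               stringsAsFactors = FALSE)
  }))
  # collapse duplicate-host tips
  keep <- vapply(unique(tip_to_host[te_tree$tip.label]), function(h) {
    tips <- te_tree$tip.label[tip_to_host[te_tree$tip.label] == h]
    if (length(tips) == 1) return(tips)
    cent <- vapply(tips, function(tp) mean(D[tp, setdiff(tips, tp)]), 1)
    tips[which.min(cent)]
  }, "")
  te2 <- ape::keep.tip(te_tree, unname(keep))
  te2$tip.label <- unname(tip_to_host[te2$tip.label])
  shared <- intersect(te2$tip.label, species_tree$tip.label)
  if (length(shared) < 4)
    stop("fewer than 4 shared hosts; RF distance is not informative")
  te2 <- ape::keep.tip(te2, shared)
  sp2 <- ape::keep.tip(species_tree, shared)
  rf <- phangorn::RF.dist(ape::unroot(te2), ape::unroot(sp2),
                          normalize = TRUE, check.labels = TRUE)
  list(rf_normalized = rf, nearest_neighbor = nn,
       n_shared_hosts = length(shared))
}

#' Identity comparison of two consensus sequence sets
#'
#' Convenience wrapper reproducing the "most similar curated repeat"
#' comparisons: each query is searched against the subject set with the
#' default preset and the best hit's identity and length are tabulated.
#'
#' @param queries named character vector.
#' @param subjects named character vector.
#' @param params search parameters.
#' @return data.frame query, best_subject, percent_identity, hit_length.
#' @export
compare_consensi <- function(queries, subjects,
                             params = search_params("default")) {
  idx <- build_index(subjects, params$word_size)
  rows <- lapply(names(queries), function(q) {
    h <- search_hits(queries[q], idx, params)
    if (nrow(h) == 0)
      return(data.frame(query = q, best_subject = NA_character_,
                        percent_identity = NA_real_, hit_length = 0L,
                        stringsAsFactors = FALSE))
    data.frame(query = q, best_subject = h$subject_id[1],
               percent_identity = h$percent_identity[1],
               hit_length = h$aln_length[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
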