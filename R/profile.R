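# Coverage/divergence profiling of a family's genomic fragments against
# its consensus, with the LINE-typical 5'-truncation statistic.

#' Build a coverage/divergence profile of a family in a genome
#'
#' All fragments of the family are located by similarity search
#' (overlapping hits from one locus are merged by the search's
#' deduplication, so tandem fragments are not double-counted). Depth at
#' consensus position i is the number of fragments whose consensus
#' interval covers i; each fragment's divergence is
#' (100 - percent identity)/100. The truncation ratio is the mean depth
#' over the 3' quartile of consensus positions divided by the mean depth
#' over the 5' quartile; values well above 1 are the coverage signature
#' of 5'-truncated LINE replication.
#'
#' @param family named character vector of length 1 (the consensus).
#' @param genome named character vector of contigs or index.
#' @param params search parameters.
#' @param min_len minimum fragment length profiled (bp).
#' @param full_length_frac consensus coverage above which a fragment
#'   counts as full-length (default 0.95).
#' @param jc cap divergences with the Jukes-Cantor transform.
#' @return `family_profile` list: consensus_length, depth (vector),
#'   fragments (data.frame start, end, divergence, full_length),
#'   n_fragments, n_full_length, truncation_ratio.
#' @export
build_profile <- function(family, genome, params = search_params("default"),
                          min_len = 100L, full_length_frac = 0.95,
                          jc = FALSE) {
  stopifnot(length(family) == 1)
  if (is.null(names(family))) names(family) <- "family"
  L <- nchar(family[[1]])
  hits <- search_hits(family, genome, params)
  hits <- hits[(hits$q_end - hits$q_start) >= min_len, , drop = FALSE]
  if (nrow(hits) == 0) {
    warning("no fragments of ", names(family), " found; empty profile")
    return(structure(list(consensus_length = L, depth = rep(0L, L),
                          fragments = data.frame(start = integer(0),
                                                 end = integer(0),
                                                 divergence = numeric(0),
                                                 full_length = logical(0)),
                          n_fragments = 0L, n_full_length = 0L,
                          truncation_ratio = NA_real_),
                     class = "family_profile"))
  }
  depth <- integer(L)
  for (i in seq_len(nrow(hits)))
    depth[(hits$q_start[i] + 1L):hits$q_end[i]] <-
      depth[(hits$q_start[i] + 1L):hits$q_end[i]] + 1L
  p <- 1 - hits$percent_identity / 100
  frag <- data.frame(start = hits$q_start, end = hits$q_end,
                     divergence = if (jc) jc_correct(p) else p,
                     full_length = (hits$q_end - hits$q_start) >=
                       full_length_frac * L)
  q1 <- seq_len(floor(L / 4))                 # 5' quartile
  q4 <- (L - floor(L / 4) + 1L):L             # 3' quartile
  tr <- mean(depth[q4]) / mean(depth[q1])
  structure(list(consensus_length = L, depth = depth, fragments = frag,
                 n_fragments = nrow(frag), n_full_length = sum(frag$full_length),
                 truncation_ratio = tr),
            class = "family_profile")
}

#' Call the LINE-typical 5'-truncation pattern
#'
#' TRUE iff the profile's 3'/5' depth ratio is at least `threshold`
#' (inclusive).
#'
#' @param profile a [build_profile()] result.
#' @param threshold ratio threshold (default 2.0).
#' @return logical.
#' @export
truncation_call <- function(profile, threshold = 2.0) {
  stopifnot(inherits(profile, "family_profile"))
  if (profile$n_fragments == 0) return(FALSE)
  !is.na(profile$truncation_ratio) && profile$truncation_ratio >= threshold
}

#' Export a profile as TSV (and optionally a plot)
#'
#' The TSV holds two record types: one `depth` row per consensus
#' position and one `fragment` row per fragment (start, end,
#' divergence), so the file has consensus_length + n_fragments data
#' rows. When ggplot2 is available and `plot_path` is given, a
#' depth-line + divergence-segment rendering is written as well.
#'
#' @param profile a [build_profile()] result.
#' @param path TSV output path.
#' @param plot_path optional image path (png/pdf by extension).
#' @return invisibly, the TSV path.
#' @export
export_profile_plot <- function(profile, path, plot_path = NULL) {
  dep <- if (profile$consensus_length > 0 && profile$n_fragments > 0)
    data.frame(record = "depth", position = seq_len(profile$consensus_length),
               end = NA, value = profile$depth)
  else if (profile$n_fragments == 0)
    data.frame(record = character(0), position = integer(0), end = integer(0),
               value = numeric(0))
  else NULL
  frg <- if (profile$n_fragments > 0)
    data.frame(record = "fragment", position = profile$fragments$start,
               end = profile$fragments$end,
               value = profile$fragments$divergence)
  else NULL
  out <- rbind(dep, frg)
  if (is.null(out))
    out <- data.frame(record = character(0), position = integer(0),
                      end = integer(0), value = numeric(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_path) && requireNamespace("ggplot2", quietly = TRUE) &&
      profile$n_fragments > 0) {
    dd <- data.frame(pos = seq_len(profile$consensus_length),
                     depth = profile$depth)
    ff <- profile$fragments
    ff$y <- ff$divergence
    sc <- max(dd$depth) / max(max(ff$divergence), 0.01)
    gp <- ggplot2::ggplot() +
      ggplot2::geom_segment(data = ff,
        ggplot2::aes(x = start, xend = end, y = y, yend = y),
        colour = ifelse(ff$full_length, "darkorange", "black"),
        linewidth = 0.3) +
      ggplot2::geom_line(data = dd,
        ggplot2::aes(x = pos, y = depth / sc), colour = "steelblue") +
      ggplot2::scale_y_continuous(
        name = "divergence from consensus",
        sec.axis = ggplot2::sec_axis(~ . * sc, name = "depth")) +
      ggplot2::labs(x = "consensus position") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_path, gp, width = 7, height = 4)
  }
  invisible(path)
}
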