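# Synthetic genomes with vertical and horizontally transferred LINE
# families, with per-copy 5' truncation and post-insertion divergence,
# plus exact ground-truth logs. This is the package's stand-in for real
# assemblies: every detection stage is validated against the truth
# records it emits.

#' Random host background DNA
#' @param n length in bp.
#' @param gc GC fraction (default 0.41).
#' @return DNA string.
#' @export
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Specification of one simulated TE family
#'
#' @param name family name.
#' @param length consensus length in bp (>= 800, the classifier's
#'   admission rule).
#' @param mode `"vertical"` (shared ancestrally, present in every tip) or
#'   `"htt"` (gained on one branch at one time).
#' @param origin_branch child-node label/id of the branch carrying the
#'   gain (htt only).
#' @param origin_time age of the transfer in Ma (htt only; must lie
#'   within the branch's age span).
#' @param copy_number_per_genome copies inserted per carrier genome.
#' @param divergence_d expected substitutions/site since insertion for
#'   vertical families (htt families derive it from origin_time and the
#'   host clock); must be in [0, 0.75].
#' @param truncation_p per-copy probability of 5' truncation.
#' @param indel_rate per-site indel event rate (0 disables; default 0).
#' @return a `te_family_spec` list, with an EN+RT domain layout.
#' @export
te_family_spec <- function(name, length = 3000L, mode = c("vertical", "htt"),
                           origin_branch = NULL, origin_time = NULL,
                           copy_number_per_genome = 20L,
                           divergence_d = 0.1, truncation_p = 0.5,
                           indel_rate = 0) {
  mode <- match.arg(mode)
  if (length < 800) stop("family length must be >= 800 bp (classifier admission rule)")
  if (divergence_d < 0 || divergence_d > 0.75)
    stop("divergence_d must be in [0, 0.75]")
  if (mode == "htt" && (is.null(origin_branch) || is.null(origin_time)))
    stop("htt families need origin_branch and origin_time")
  structure(list(name = name, length = as.integer(length), mode = mode,
                 origin_branch = origin_branch, origin_time = origin_time,
                 copy_number_per_genome = as.integer(copy_number_per_genome),
                 divergence_d = divergence_d, truncation_p = truncation_p,
                 indel_rate = indel_rate,
                 domain_layout = default_domain_layout(length)),
            class = "te_family_spec")
}

# EN in the 5' third, RT in the 3' two-thirds, mirroring the canonical
# LINE ORF2 layout.
default_domain_layout <- function(len) {
  data.frame(domain = c("EN", "RT"),
             start = as.integer(c(round(0.05 * len), round(0.40 * len))),
             end = as.integer(c(round(0.30 * len), round(0.90 * len))),
             stringsAsFactors = FALSE)
}

#' Generate a library of mutually dissimilar TE consensus sequences
#'
#' Families are rejection-sampled until all pairs lack any local hit of
#' >= 100 bp at >= 60 percent identity, so that subfamily splitting and
#' reciprocal assignment are testable without cross-talk. Each consensus
#' carries EN and RT marker intervals.
#'
#' @param n_families number of families (>= 1).
#' @param seed RNG seed; the library is reproducible.
#' @param length consensus length (single value or vector).
#' @param max_tries rejection-sampling budget.
#' @return list of `te_consensus` objects: name, seq, domain data.frame.
#' @export
make_te_library <- function(n_families, seed = 1L, length = 3000L,
                            max_tries = 1000L) {
  stopifnot(n_families >= 1)
  if (any(length < 800)) stop("family length must be >= 800 bp (classifier admission rule)")
  set.seed(seed)
  lens <- rep_len(length, n_families)
  lib <- list()
  p <- search_params("relaxed", max_evalue = 1)
  for (i in seq_len(n_families)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      cand <- random_dna(lens[i], gc = 0.5)
      ok <- TRUE
      for (prev in lib) {
        h <- search_hits(c(cand = cand), c(prev = prev$seq), p)
        h <- h[h$aln_length >= 100 & h$percent_identity >= 60, , drop = FALSE]
        if (nrow(h) > 0) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("could not generate a dissimilar family in ", max_tries, " draws")
    lib[[i]] <- structure(list(name = sprintf("TEfam%02d", i), seq = cand,
                               domains = default_domain_layout(lens[i])),
                          class = "te_consensus")
  }
  names(lib) <- vapply(lib, `[[`, "", "name")
  ht_log("make_te_library: ", n_families, " families, seed ", seed)
  lib
}

#' Truth domain-hit table for a simulated library
#'
#' Emits the tabular domain evidence (consensus_id, domain, coverage,
#' start, end) that the classifier consumes, with full coverage.
#'
#' @param library a [make_te_library()] list.
#' @return data.frame of domain hits.
#' @export
te_domain_hits <- function(library) {
  do.call(rbind, lapply(library, function(fam) {
    data.frame(consensus_id = fam$name, domain = fam$domains$domain,
               coverage = 1.0, start = fam$domains$start,
               end = fam$domains$end, stringsAsFactors = FALSE)
  }))
}

#' Mutate a sequence under the Jukes-Cantor model
#'
#' Each site is substituted with probability
#' p = (3/4)(1 - exp(-4 d / 3)); substituted sites receive one of the
#' three other bases uniformly. d = 0 returns the input unchanged; as
#' d grows the observed difference fraction saturates at 3/4.
#'
#' @param seq DNA string.
#' @param d expected substitutions per site (>= 0).
#' @param seed optional RNG seed.
#' @return mutated sequence.
#' @export
mutate_sequence <- function(seq, d, seed = NULL) {
  stopifnot(d >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (d == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    repl <- vapply(v[hit], function(b) {
      a <- alt[[b]]
      if (is.null(a)) "N" else a[sample.int(3, 1)]
    }, "")
    v[hit] <- repl
  }
  paste(v, collapse = "")
}

#' Insert TE copies into a genome with truncation, strand and divergence
#'
#' Each copy optionally loses its 5' end (with probability
#' `truncation_p`, keeping a fraction f ~ Uniform(0.05, 1) of the 3'
#' end - the hallmark coverage shape of LINE replication), lands on a
#' random strand, and is diverged from the consensus by `d` substitutions
#' per site under Jukes-Cantor. Insertion sites are non-overlapping and
#' kept >= 300 bp apart.
#'
#' @param genome single genome string.
#' @param family a `te_consensus` or `te_family_spec` carrying `name` and
#'   `seq` (for specs, the consensus must be supplied via `consensus`).
#' @param n number of copies.
#' @param d substitutions/site applied per copy.
#' @param truncation_p per-copy 5' truncation probability.
#' @param seed optional RNG seed.
#' @param consensus consensus sequence (overrides `family$seq`).
#' @param min_gap minimum spacing between insertion points.
#' @param avoid optional data.frame of start/end intervals (current genome
#'   coordinates) that insertion points must not fall into; used to keep
#'   copies of different families from nesting.
#' @return list with `genome` (modified string) and `truth` (data.frame:
#'   family, contig, start, end, strand, retained_fraction,
#'   true_divergence, cons_start, cons_end).
#' @export
insert_copies <- function(genome, family, n, d = 0, truncation_p = 0,
                          seed = NULL, consensus = NULL, min_gap = 300L,
                          avoid = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cons <- if (!is.null(consensus)) consensus else family$seq
  fam_name <- family$name
  L <- nchar(cons)
  truth <- data.frame(family = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), retained_fraction = numeric(0),
                      true_divergence = numeric(0),
                      cons_start = integer(0), cons_end = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(list(genome = genome, truth = truth))
  glen <- nchar(genome)
  if (glen < n * (L + min_gap)) stop("genome too short for ", n, " copies")
  # draw insertion points in the original coordinate system, spaced out
  # and outside avoided intervals
  cand <- sort(sample.int(glen - 1L, min(glen - 1L, n * 8L)))
  if (!is.null(avoid) && nrow(avoid)) {
    bad <- vapply(cand, function(p)
      any(p > avoid$start - min_gap & p < avoid$end + min_gap), TRUE)
    cand <- cand[!bad]
  }
  cand <- cand[c(TRUE, diff(cand) >= min_gap)]
  if (length(cand) < n) stop("could not place ", n, " spaced insertion points")
  pts <- cand[sort(sample.int(length(cand), n))]
  pieces <- character(2 * n + 1)
  prev <- 0L
  rows <- vector("list", n)
  offset <- 0L
  for (i in seq_len(n)) {
    truncated <- runif(1) < truncation_p
    f <- if (truncated) runif(1, 0.05, 1) else 1
    keep_from <- L - as.integer(round(f * L)) + 1L
    piece <- substr(cons, keep_from, L)
    piece <- mutate_sequence(piece, d)
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") piece <- revcomp(piece)
    pieces[2 * i - 1] <- substr(genome, prev + 1L, pts[i])
    pieces[2 * i] <- piece
    start <- pts[i] + offset
    rows[[i]] <- data.frame(family = fam_name, contig = NA_character_,
                            start = start, end = start + nchar(piece),
                            strand = strand, retained_fraction = f,
                            true_divergence = d,
                            cons_start = keep_from - 1L, cons_end = L,
                            stringsAsFactors = FALSE)
    offset <- offset + nchar(piece)
    prev <- pts[i]
  }
  pieces[2 * n + 1] <- substr(genome, prev + 1L, glen)
  list(genome = paste(pieces, collapse = ""), truth = do.call(rbind, rows))
}

#' Simulate a genome panel along a dated tree with vertical and HTT families
#'
#' Host backgrounds evolve along the tree by Jukes-Cantor at
#' `rate_per_site_per_year`. Vertical families are carried by every tip
#' with per-copy divergence `divergence_d`; an HTT family is carried only
#' by tips descending from its origin branch, with per-copy divergence
#' rate x origin_time (the no-loss model: a gain on a branch forces
#' presence in all tips below it).
#'
#' @param tree a rooted ultrametric [ape::phylo] with branch lengths in Ma
#'   (tips and, optionally, node labels name the branches).
#' @param family_specs list of [te_family_spec()] objects.
#' @param consensi optional named list/vector of consensus sequences per
#'   family (defaults to a fresh [make_te_library()] draw).
#' @param genome_length background length per species.
#' @param rate_per_site_per_year host substitution rate (default 1.25e-9,
#'   i.e. 1.25e-8 per site per generation at a 10-year generation time).
#' @param gc background GC content.
#' @param seed RNG seed; output is byte-identical across runs with the
#'   same seed.
#' @return list with `genomes` (named list of single-contig named
#'   character vectors), `truth` (data.frame of copies), `presence`
#'   (logical matrix families x tips), `events` (data.frame family,
#'   branch, time_ma), `consensi` (named character vector), `tree`.
#' @export
simulate_panel <- function(tree, family_specs, consensi = NULL,
                           genome_length = 100000L,
                           rate_per_site_per_year = 1.25e-9,
                           gc = 0.41, seed = 1L) {
  stopifnot(rate_per_site_per_year > 0)
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  labels <- node_labels(tree)
  if (is.null(names(family_specs)))
    names(family_specs) <- vapply(family_specs, `[[`, "", "name")
  if (is.null(consensi)) {
    lib <- make_te_library(length(family_specs),
                           seed = sample.int(.Machine$integer.max, 1),
                           length = vapply(family_specs, `[[`, 1L, "length"))
    consensi <- setNames(vapply(lib, `[[`, "", "seq"), names(family_specs))
  }
  consensi <- unlist(consensi)[names(family_specs)]
  # validate htt events against the tree
  events <- list()
  carriers <- list()
  for (fs in family_specs) {
    if (fs$mode == "htt") {
      node <- match_branch(tree, fs$origin_branch, labels)
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      stem_age <- ages[parent]
      crown_age <- ages[node]
      if (fs$origin_time > stem_age || fs$origin_time < crown_age)
        stop("origin_time ", fs$origin_time, " outside branch age span [",
             crown_age, ", ", stem_age, "] for family ", fs$name)
      tips <- tips_below(tree, node)
      events[[length(events) + 1L]] <-
        data.frame(family = fs$name, branch = labels[node],
                   time_ma = fs$origin_time, stringsAsFactors = FALSE)
      carriers[[fs$name]] <- tree$tip.label[tips]
    } else {
      carriers[[fs$name]] <- tree$tip.label
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(family = character(0), branch = character(0),
               time_ma = numeric(0), stringsAsFactors = FALSE)
  presence <- matrix(FALSE, length(family_specs), ntip,
                     dimnames = list(names(family_specs), tree$tip.label))
  for (fam in names(carriers)) presence[fam, carriers[[fam]]] <- TRUE

  # evolve backgrounds along the tree
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- random_dna(genome_length, gc)
  for (e in seq_len(nrow(tree$edge))[order(tree$edge[, 1])]) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    d <- rate_per_site_per_year * tree$edge.length[e] * 1e6
    seqs[[child]] <- mutate_sequence(seqs[[par]], d)
  }

  genomes <- list()
  truth <- list()
  for (t in seq_len(ntip)) {
    sp <- tree$tip.label[t]
    g <- seqs[[t]]
    rows <- list()
    for (fs in family_specs) {
      if (!presence[fs$name, sp]) next
      d <- if (fs$mode == "htt")
        rate_per_site_per_year * fs$origin_time * 1e6 else fs$divergence_d
      prev_iv <- if (length(rows)) do.call(rbind, rows)[, c("start", "end")] else NULL
      ins <- insert_copies(g, fs, fs$copy_number_per_genome, d = d,
                           truncation_p = fs$truncation_p,
                           consensus = consensi[[fs$name]], avoid = prev_iv)
      # shift earlier copies' coordinates past the new insertions
      if (length(rows)) {
        prevs <- do.call(rbind, rows)
        for (j in seq_len(nrow(ins$truth))) {
          st <- ins$truth$start[j]; w <- ins$truth$end[j] - st
          bump <- prevs$start >= st
          prevs$start[bump] <- prevs$start[bump] + w
          prevs$end[bump] <- prevs$end[bump] + w
        }
        rows <- list(prevs)
      }
      g <- ins$genome
      rows[[length(rows) + 1L]] <- ins$truth
    }
    contig <- paste0(sp, "_c1")
    genomes[[sp]] <- setNames(g, contig)
    if (length(rows)) {
      tr <- do.call(rbind, rows)
      tr$contig <- contig
      tr$species <- sp
      truth[[length(truth) + 1L]] <- tr
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth)) rownames(truth) <- NULL
  ht_log("simulate_panel: ", ntip, " species, ", length(family_specs),
         " families, seed ", seed)
  list(genomes = genomes, truth = truth, presence = presence,
       events = events, consensi = consensi, tree = tree)
}

node_labels <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab <- c(tree$tip.label,
           if (!is.null(tree$node.label) && length(tree$node.label))
             tree$node.label else paste0("node", seq_len(tree$Nnode) + ntip))
  lab[!nzchar(lab)] <- paste0("node", which(!nzchar(lab)))
  lab
}

match_branch <- function(tree, branch, labels = node_labels(tree)) {
  node <- match(branch, labels)
  if (is.na(node) && is.numeric(branch)) node <- as.integer(branch)
  if (is.na(node) || node == ape::Ntip(tree) + 1L)
    stop("unknown (or root) branch: ", branch)
  node
}

tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_below, tree = tree))
}

#' Propagate a gain-event list to a truth presence matrix (no-loss model)
#'
#' @param tree dated tree.
#' @param events data.frame with columns family, branch.
#' @param families all family names (rows of the output).
#' @return logical matrix families x tips.
#' @export
propagate_events <- function(tree, events, families = unique(events$family)) {
  labels <- node_labels(tree)
  m <- matrix(FALSE, length(families), ape::Ntip(tree),
              dimnames = list(families, tree$tip.label))
  for (i in seq_len(nrow(events))) {
    node <- match_branch(tree, events$branch[i], labels)
    m[events$family[i], tips_below(tree, node)] <- TRUE
  }
  m
}

#' Synthetic flank-contiguity fixture
#'
#' Builds one focal assembly carrying `n_insertions` gene-proximal TE
#' insertions (each on its own contig between 2-kb flanks) and
#' `n_comparisons` comparison assemblies in which `n_split` of the
#' insertions have their two flanks engineered onto different contigs in
#' EVERY comparison (emulating assembly breaks); the remaining
#' insertions' flank pairs are contiguous (empty-site contigs). Flanks in
#' comparisons are diverged from the focal assembly by `d`.
#'
#' @param n_insertions total insertions.
#' @param n_split insertions placed on contig breaks in all comparisons.
#' @param te_seq TE sequence inserted (its length is the insertion span).
#' @param flank flank length.
#' @param d comparison-assembly divergence (substitutions/site).
#' @param n_comparisons number of comparison assemblies.
#' @param seed RNG seed.
#' @return list: `self` (named contigs), `comparisons` (list of named
#'   contig vectors), `insertions` (data.frame contig/start/end/family),
#'   `truth_split` (logical vector, TRUE = engineered break).
#' @export
make_flank_fixture <- function(n_insertions = 23L, n_split = 8L,
                               te_seq = NULL, flank = 2000L, d = 0.02,
                               n_comparisons = 2L, seed = 1L) {
  stopifnot(n_split <= n_insertions, n_comparisons >= 1)
  set.seed(seed)
  if (is.null(te_seq)) te_seq <- random_dna(300, gc = 0.5)
  split_idx <- sort(sample.int(n_insertions, n_split))
  self <- character(n_insertions)
  comps <- replicate(n_comparisons, character(0), simplify = FALSE)
  ins <- vector("list", n_insertions)
  truth <- rep(FALSE, n_insertions)
  for (i in seq_len(n_insertions)) {
    L <- random_dna(flank); R <- random_dna(flank)
    contig <- paste0("self_ctg", i)
    self[i] <- paste0(L, te_seq, R)
    names(self)[i] <- contig
    ins[[i]] <- data.frame(contig = contig, start = flank,
                           end = flank + nchar(te_seq),
                           family = "TEfix", stringsAsFactors = FALSE)
    truth[i] <- i %in% split_idx
    for (k in seq_len(n_comparisons)) {
      Lc <- mutate_sequence(L, d); Rc <- mutate_sequence(R, d)
      if (truth[i]) {
        a <- setNames(paste0(random_dna(500), Lc), paste0("cmp", k, "_ctg", i, "a"))
        b <- setNames(paste0(Rc, random_dna(500)), paste0("cmp", k, "_ctg", i, "b"))
        comps[[k]] <- c(comps[[k]], a, b)
      } else {
        a <- setNames(paste0(Lc, Rc), paste0("cmp", k, "_ctg", i))
        comps[[k]] <- c(comps[[k]], a)
      }
    }
  }
  list(self = self, comparisons = comps,
       insertions = do.call(rbind, ins), truth_split = truth)
}
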