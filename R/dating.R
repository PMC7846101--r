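# Two clocks for horizontal-transfer events and their reconciliation:
# (a) divergence-based insertion ages from copy substitutions against the
#     family consensus, scaled by a host substitution rate;
# (b) gain-parsimony event inference on the dated host tree under a
#     no-loss model, which brackets each event between the crown and stem
#     ages of the smallest clade containing all carrier tips.

#' Substitution-rate clock parameters
#'
#' Defaults encode an elapid whole-genome estimate of 1.25e-8
#' substitutions per site per generation and a 10-year generation time.
#' The clock divides the observed per-copy divergence by the
#' per-generation rate directly (no ploidy factor).
#'
#' @param rate_per_site_per_generation substitution rate (> 0).
#' @param generation_years generation time in years (> 0).
#' @return clock parameter list.
#' @export
clock_params <- function(rate_per_site_per_generation = 1.25e-8,
                         generation_years = 10) {
  stopifnot(rate_per_site_per_generation > 0, generation_years > 0)
  list(rate_per_site_per_generation = rate_per_site_per_generation,
       generation_years = generation_years)
}

#' Mean per-copy divergence of a family's genomic copies
#'
#' Finds all copies of the family in a genome, computes each copy's
#' divergence from the consensus as substitutions per site read from its
#' best alignment (raw p-distance by default; Jukes-Cantor correction
#' optional, which can only increase the estimate), and returns the mean,
#' SD and copy count. Per-copy divergence is 1 - identity where identity
#' is counted over aligned columns.
#'
#' @param family named character vector of length 1 (the consensus).
#' @param genome named character vector of contigs or index.
#' @param params search parameters.
#' @param min_len minimum copy (hit) length used (bp).
#' @param jc apply Jukes-Cantor correction.
#' @return list: mean_d, sd_d, se_d, n, per_copy (numeric vector).
#' @export
copy_divergence <- function(family, genome, params = search_params("default"),
                            min_len = 300L, jc = FALSE) {
  stopifnot(length(family) == 1)
  if (is.null(names(family))) names(family) <- "family"
  hits <- search_hits(family, genome, params)
  hits <- hits[(hits$s_end - hits$s_start) >= min_len, , drop = FALSE]
  if (nrow(hits) == 0) stop("no copies of ", names(family), " found")
  p <- 1 - hits$percent_identity / 100
  d <- if (jc) jc_correct(p) else p
  list(mean_d = mean(d), sd_d = sd(d), se_d = sd(d) / sqrt(length(d)),
       n = length(d), per_copy = d)
}

#' Jukes-Cantor distance correction
#'
#' d = -(3/4) log(1 - 4p/3); p-distances at or beyond the 0.75
#' saturation limit are capped just below it. The corrected distance is
#' never smaller than the input.
#'
#' @param p observed proportion of differing sites.
#' @return corrected substitutions per site.
#' @export
jc_correct <- function(p) {
  p <- pmin(p, 0.75 - 1e-9)
  -0.75 * log(1 - 4 * p / 3)
}

#' Insertion age from mean divergence under the substitution-rate clock
#'
#' T (Ma) = mean_d / rate_per_generation * generation_years / 1e6.
#' Linear in the divergence; the SD is scaled identically.
#'
#' @param mean_d mean substitutions per site.
#' @param sd_d SD of the per-copy divergences (scaled like the mean).
#' @param clock a [clock_params()] list.
#' @return list: T_mean, T_sd (Ma).
#' @export
insertion_time <- function(mean_d, sd_d = 0, clock = clock_params()) {
  f <- clock$generation_years / clock$rate_per_site_per_generation / 1e6
  list(T_mean = mean_d * f, T_sd = sd_d * f)
}

#' Gain-parsimony HTT event inference on a dated tree (no-loss model)
#'
#' Under a no-loss model a gain on a branch forces presence in every tip
#' below it, so the minimal explanation of a presence pattern is one gain
#' on the stem of each maximal clade whose tips are all present. Each
#' event is dated to the interval [crown age of the clade, stem age]
#' (a single-tip event has crown age 0).
#'
#' @param presence named logical (or call character) vector over the
#'   tree's tips. Character input counts `"present_similar"` as present
#'   and, by default, `"present_divergent"` as absent (the events of
#'   interest concern high-identity families); set
#'   `divergent_is_present = TRUE` to change that.
#' @param tree dated rooted tree ([read_newick_dated()]).
#' @param family family name stored in the result.
#' @param divergent_is_present count divergent calls as present.
#' @return data.frame of events: family, branch (label of the clade's
#'   crown node), crown_age, stem_age, n_tips. Zero rows when the family
#'   is present in no tip.
#' @export
infer_gain_events <- function(presence, tree, family = "family",
                              divergent_is_present = FALSE) {
  if (is.character(presence)) {
    keep <- c("present_similar", if (divergent_is_present) "present_divergent")
    presence <- setNames(presence %in% keep, names(presence))
  }
  if (is.null(names(presence))) stop("presence vector must be named by tip")
  missing_tips <- setdiff(tree$tip.label, names(presence))
  if (length(missing_tips))
    stop("presence missing for tips: ", paste(missing_tips, collapse = ", "))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ages <- node_ages(tree)
  labels <- node_labels(tree)
  pres <- presence[tree$tip.label]
  # postorder AND: a node is all-present iff every tip below it is present;
  # events sit on the stems of maximal all-present clades
  allp <- compute_allpresent(tree, pres)
  parent_of <- integer(ntip + nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  event_nodes <- Filter(function(v) v == root || !allp[parent_of[v]],
                        which(allp))
  if (length(event_nodes) == 0)
    return(data.frame(family = character(0), branch = character(0),
                      crown_age = numeric(0), stem_age = numeric(0),
                      n_tips = integer(0), stringsAsFactors = FALSE))
  rows <- lapply(event_nodes, function(v) {
    stem <- if (v == root) ages[root] else ages[parent_of[v]]
    data.frame(family = family, branch = labels[v],
               crown_age = unname(ages[v]), stem_age = unname(stem),
               n_tips = length(tips_below(tree, v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_tips, out$branch), , drop = FALSE]
}

compute_allpresent <- function(tree, pres) {
  ntip <- ape::Ntip(tree)
  allp <- c(unname(pres), rep(NA, tree$Nnode))
  rec <- function(node) {
    if (node <= ntip) return(allp[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    vals <- vapply(kids, rec, TRUE)
    allp[node] <<- all(vals)
    allp[node]
  }
  rec(ntip + 1L)
  allp
}

#' Events for every family of a presence matrix
#'
#' @param calls character or logical matrix (families x species).
#' @param tree dated tree covering the species.
#' @param divergent_is_present see [infer_gain_events()].
#' @return data.frame of events over all families.
#' @export
infer_all_events <- function(calls, tree, divergent_is_present = FALSE) {
  rows <- lapply(rownames(calls), function(fam)
    infer_gain_events(setNames(calls[fam, ], colnames(calls)), tree,
                      family = fam,
                      divergent_is_present = divergent_is_present))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consistency of branch intervals with divergence-clock ages
#'
#' An event is consistent when the clock interval mean +/- sd overlaps
#' the branch age interval [crown_age, stem_age].
#'
#' @param events data.frame from [infer_gain_events()].
#' @param clock_ages data.frame with family, clock_mean, clock_sd (Ma);
#'   matched to events by family.
#' @return events with clock_mean, clock_sd and `consistent` columns.
#' @export
consistency <- function(events, clock_ages) {
  i <- match(events$family, clock_ages$family)
  events$clock_mean <- clock_ages$clock_mean[i]
  events$clock_sd <- clock_ages$clock_sd[i]
  lo <- events$clock_mean - events$clock_sd
  hi <- events$clock_mean + events$clock_sd
  events$consistent <- !(hi < events$crown_age | lo > events$stem_age)
  events
}

# ---- study system ----------------------------------------------------

#' Dated elapid snake phylogeny used by the sea-snake application
#'
#' Seven-taxon ultrametric tree of the king cobra (outgroup), the
#' yellow-lipped sea krait (an independently marine lineage, split
#' 25 Ma), two terrestrial Australian elapids, and three sea snakes (a
#' Hydrophis-lineage species and the Emydocephalus-Aipysurus clade).
#' Node ages follow published divergence-time estimates for the group
#' (sea-snake radiation within the last ~10 Ma; marine transition at
#' most 18 Ma).
#'
#' @return dated tree ([read_newick_dated()]).
#' @export
elapid_timetree <- function() {
  txt <- paste0(
    "(Ophiophagus_hannah:30,(Laticauda_colubrina:25,",
    "((Pseudonaja_textilis:12,Notechis_scutatus:12):3,",
    "(Hydrophis_melanocephalus:10,",
    "(Emydocephalus_ijimae:5,Aipysurus_laevis:5):5):5):10):5);")
  read_newick_dated(text = txt)
}

#' Presence/absence of the seven sea-snake HTT LINE subfamilies
#'
#' Reciprocal-search presence calls of the seven LINE subfamilies
#' discovered in the olive sea snake across the seven-taxon elapid panel:
#' RTE-Snek_1 restricted to Aipysurus laevis; Proto2-Snek also in
#' Emydocephalus ijimae; Rex1-Snek_1H1, Rex1-Snek_2 and RTE-Snek_2 in
#' all three sea snakes; Rex1-Snek_1H2 and Rex1-Snek_1H3 in Aipysurus
#' and Hydrophis but not Emydocephalus. All seven are absent from the
#' terrestrial and amphibious outgroups.
#'
#' @return logical matrix (7 families x 7 species) whose columns match
#'   [elapid_timetree()] tips.
#' @export
sea_snake_presence <- function() {
  species <- c("Ophiophagus_hannah", "Laticauda_colubrina",
               "Pseudonaja_textilis", "Notechis_scutatus",
               "Hydrophis_melanocephalus", "Emydocephalus_ijimae",
               "Aipysurus_laevis")
  fams <- c("Rex1-Snek_1H1", "Rex1-Snek_1H2", "Rex1-Snek_1H3",
            "Rex1-Snek_2", "RTE-Snek_1", "RTE-Snek_2", "Proto2-Snek")
  m <- matrix(FALSE, length(fams), length(species),
              dimnames = list(fams, species))
  m["Rex1-Snek_1H1", c("Aipysurus_laevis", "Emydocephalus_ijimae",
                       "Hydrophis_melanocephalus")] <- TRUE
  m["Rex1-Snek_1H2", c("Aipysurus_laevis", "Hydrophis_melanocephalus")] <- TRUE
  m["Rex1-Snek_1H3", c("Aipysurus_laevis", "Hydrophis_melanocephalus")] <- TRUE
  m["Rex1-Snek_2", c("Aipysurus_laevis", "Emydocephalus_ijimae",
                     "Hydrophis_melanocephalus")] <- TRUE
  m["RTE-Snek_1", "Aipysurus_laevis"] <- TRUE
  m["RTE-Snek_2", c("Aipysurus_laevis", "Emydocephalus_ijimae",
                    "Hydrophis_melanocephalus")] <- TRUE
  m["Proto2-Snek", c("Aipysurus_laevis", "Emydocephalus_ijimae")] <- TRUE
  m
}
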