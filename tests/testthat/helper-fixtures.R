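# Shared fixtures: all test data is generated in code, seeded.

rnd_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substitute exactly k sites (guaranteed differences, unlike the JC
# simulator which draws the count)
mutate_exact <- function(seq, k) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), k)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  v[pos] <- vapply(v[pos], function(b) sample(alt[[b]], 1), "")
  paste(v, collapse = "")
}

# a pair of homologous sequences derived from one ancestor
related_pair <- function(len = 200, d1 = 0.08, d2 = 0.08) {
  anc <- rnd_dna(len)
  list(a = mutate_sequence(anc, d1), b = mutate_sequence(anc, d2))
}

# Smith-Waterman oracle: Biostrings full local DP, same scoring
sw_oracle_score <- function(a, b, reward, penalty, gap_open, gap_extend) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = reward, mismatch = penalty, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend))
}

# brute-force minimal number of no-loss gains explaining a presence set
brute_min_gains <- function(tree, present_tips) {
  ntip <- ape::Ntip(tree)
  nodes <- seq_len(ntip + tree$Nnode)
  clades <- lapply(nodes, function(v) sort(httrace:::tips_below(tree, v)))
  pres <- sort(match(present_tips, tree$tip.label))
  if (length(pres) == 0) return(0L)
  eligible <- which(vapply(clades, function(cl) all(cl %in% pres), TRUE))
  for (k in seq_along(eligible)) {
    combs <- utils::combn(eligible, k, simplify = FALSE)
    for (cb in combs) {
      u <- sort(unique(unlist(clades[cb])))
      if (identical(u, pres)) return(k)
    }
  }
  stop("unreachable")
}

# unrooted 4-taxon RF by direct split comparison
rf4_oracle <- function(t1, t2) {
  split_of <- function(tr) {
    tr <- ape::unroot(tr)
    internal <- tr$edge[tr$edge[, 2] > ape::Ntip(tr), 2]
    sp <- lapply(internal, function(v)
      sort(tr$tip.label[httrace:::tips_below(tr, v)]))
    sp <- Filter(function(s) length(s) == 2, sp)
    sp
  }
  s1 <- split_of(t1); s2 <- split_of(t2)
  matches <- sum(vapply(s1, function(s)
    any(vapply(s2, identical, TRUE, x = s) |
          vapply(s2, function(z) identical(sort(setdiff(t1$tip.label, z)), s), TRUE)),
    TRUE))
  (length(s1) - matches) / length(s1)
}

# small dated 4-5 taxon trees
tree4 <- function() read_newick_dated(text = "((A:5,B:5):5,(C:5,D:5):5);")
tree5 <- function() read_newick_dated(
  text = "(E:20,((A:5,B:5):5,(C:5,D:5):5):10);")
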