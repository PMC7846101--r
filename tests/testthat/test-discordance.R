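# TE-versus-host tree discordance: intactness filter, block trimming,
# NJ trees and Robinson-Foulds statistics.

test_that("intactness filtering requires 80 percent of both EN and RT", {
  dh <- data.frame(
    consensus_id = c("a", "a", "b", "b", "c"),
    domain = c("EN", "RT", "EN", "RT", "EN"),
    coverage = c(0.85, 0.90, 0.85, 0.70, 1.0),
    stringsAsFactors = FALSE)
  seqs <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  expect_message(kept <- filter_intact(seqs, dh), "removed")
  expect_setequal(names(kept), "a")
  expect_error(filter_intact(seqs["b"], dh), "no intact")
})

test_that("block trimming keeps occupied runs of at least five columns", {
  set.seed(91)
  gapless <- setNames(vapply(1:4, function(i) rnd_dna(60), ""), letters[1:4])
  expect_identical(as.character(block_trim(gapless)), unname(gapless))
  # an isolated kept column between gap deserts is dropped
  mk <- function(blocks) paste(blocks, collapse = "")
  rows <- c(a = mk(c(rnd_dna(10), strrep("-", 6), "A", strrep("-", 6), rnd_dna(10))),
            b = mk(c(rnd_dna(10), strrep("-", 6), "C", strrep("-", 6), rnd_dna(10))),
            c = mk(c(rnd_dna(10), strrep("-", 6), "G", strrep("-", 6), rnd_dna(10))),
            d = mk(c(rnd_dna(10), strrep("-", 6), "T", strrep("-", 6), rnd_dna(10))))
  tr <- block_trim(rows)
  expect_equal(nchar(tr[[1]]), 20)
  # a half-deleted center block is removed, conserved flanks kept
  ctr <- c(a = mk(c(rnd_dna(20), rnd_dna(30), rnd_dna(20))),
           b = mk(c(rnd_dna(20), strrep("-", 30), rnd_dna(20))),
           c = mk(c(rnd_dna(20), strrep("-", 30), rnd_dna(20))),
           d = mk(c(rnd_dna(20), strrep("-", 30), rnd_dna(20))))
  tc <- block_trim(ctr)
  expect_equal(nchar(tc[[1]]), 40)
})

test_that("NJ recovers the generating topology from clean sequence data", {
  set.seed(92)
  anc <- rnd_dna(2000)
  ab <- mutate_sequence(anc, 0.06); cd <- mutate_sequence(anc, 0.06)
  seqs <- c(A = mutate_sequence(ab, 0.02), B = mutate_sequence(ab, 0.02),
            C = mutate_sequence(cd, 0.02), D = mutate_sequence(cd, 0.02))
  al <- msa(seqs)
  tr <- nj_tree(al)
  expect_equal(ape::Ntip(tr), 4)
  truth <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(truth)), 0)
  # permuting the input rows leaves the topology unchanged
  tr2 <- nj_tree(al[c(3, 1, 4, 2)])
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr2)), 0)
  # identical sequences form a zero-length cherry
  seqs2 <- c(seqs[1:3], D2 = seqs[["C"]])
  tr3 <- nj_tree(msa(seqs2))
  d3 <- ape::cophenetic.phylo(tr3)
  expect_equal(d3["C", "D2"], 0)
  # distances: JC-corrected never smaller than p
  expect_true(all(aln_distances(al, "jc") >= aln_distances(al, "p") - 1e-12))
})

test_that("RF discordance is 0 for congruent trees and 1 for a 4-taxon NNI", {
  sp <- read_newick_dated(text = "((h1:5,h2:5):5,(h3:5,h4:5):5);")
  te_cong <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  map <- c(t1 = "h1", t2 = "h2", t3 = "h3", t4 = "h4")
  ds <- discordance_stat(te_cong, sp, map)
  expect_equal(ds$rf_normalized, 0)
  # nearest-neighbor interchange: maximal discordance on 4 taxa
  te_nni <- ape::read.tree(text = "((t1:1,t3:1):1,(t2:1,t4:1):1);")
  ds2 <- discordance_stat(te_nni, sp, map)
  expect_equal(ds2$rf_normalized, 1)
  # brute-force split-comparison oracle agrees
  host_te <- te_nni; host_te$tip.label <- unname(map[host_te$tip.label])
  expect_equal(ds2$rf_normalized, rf4_oracle(host_te, sp))
  expect_equal(rf4_oracle(te_cong_host <- {
    t <- te_cong; t$tip.label <- unname(map[t$tip.label]); t
  }, sp), 0)
})

test_that("RF reduction is symmetric and duplicate hosts collapse to one tip", {
  sp <- read_newick_dated(text = "((h1:5,h2:5):5,(h3:5,h4:5):5);")
  te <- ape::read.tree(text = "(((t1a:1,t1b:1):1,t2:2):1,(t3:1,t4:1):2);")
  map <- c(t1a = "h1", t1b = "h1", t2 = "h2", t3 = "h3", t4 = "h4")
  ds <- discordance_stat(te, sp, map)
  expect_equal(ds$n_shared_hosts, 4)
  expect_equal(ds$rf_normalized, 0)
  expect_error(discordance_stat(te, sp, map[-1]), "no host mapping")
})

test_that("an HTT recipient's TE clusters with the donor lineage, not its host kin", {
  # hosts: snake and fish diverged deeply; the snake carries vertical TEs
  # plus one recently transferred TE nearly identical to the fish TE
  set.seed(93)
  anc <- rnd_dna(1500)
  vert_anc <- mutate_sequence(anc, 0.25)
  fish_te <- mutate_sequence(anc, 0.25)
  seqs <- c(
    snake_vert1 = mutate_sequence(vert_anc, 0.02),
    snake_vert2 = mutate_sequence(vert_anc, 0.02),
    fish_te = fish_te,
    snake_htt = mutate_sequence(fish_te, 0.01),
    outgroup = rnd_dna(1500))
  al <- msa(seqs)
  tr <- nj_tree(al)
  map <- c(snake_vert1 = "snake", snake_vert2 = "snake", fish_te = "fish",
           snake_htt = "snake", outgroup = "worm")
  sp <- read_newick_dated(text = "((snake:50,fish:50):50,worm:100);")
  D <- ape::cophenetic.phylo(tr)
  nn <- names(which.min(D["snake_htt", setdiff(colnames(D), "snake_htt")]))
  expect_equal(nn, "fish_te")
})
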