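# The synthetic-genome generator: substitution model, truncation model,
# panel simulation and its ground truth.

test_that("Jukes-Cantor mutation matches its binomial oracle", {
  set.seed(21)
  s <- rnd_dna(100000)
  expect_identical(mutate_sequence(s, 0), s)
  m <- mutate_sequence(s, 0.05)
  pdiff <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  p <- 0.75 * (1 - exp(-4 * 0.05 / 3)) # 0.04836
  expect_lt(abs(pdiff - p), 3 * sqrt(p * (1 - p) / 100000))
  # saturation limit
  msat <- mutate_sequence(s, 50)
  psat <- mean(strsplit(s, "")[[1]] != strsplit(msat, "")[[1]])
  expect_lt(abs(psat - 0.75), 0.01)
})

test_that("copy insertion honors truncation, strand, spacing and truth records", {
  set.seed(22)
  fam <- list(name = "f", seq = rnd_dna(1000))
  g <- rnd_dna(50000)
  r0 <- insert_copies(g, fam, 0)
  expect_identical(r0$genome, g)
  expect_equal(nrow(r0$truth), 0)
  # truncation_p = 0: all copies full length
  r <- insert_copies(g, fam, 10, truncation_p = 0, seed = 1)
  expect_true(all(r$truth$retained_fraction == 1))
  expect_true(all(r$truth$end - r$truth$start == 1000))
  expect_equal(nchar(r$genome), 50000 + 10000)
  # truth coordinates are exact: the genome slice equals the copy
  for (i in seq_len(nrow(r$truth))) {
    piece <- substr(r$genome, r$truth$start[i] + 1, r$truth$end[i])
    if (r$truth$strand[i] == "-") piece <- revcomp(piece)
    expect_identical(piece, fam$seq)
  }
  # truncation_p = 1, 200 copies: mean retained fraction near 0.525
  r2 <- insert_copies(rnd_dna(400000), fam, 200, truncation_p = 1, seed = 2)
  expect_lt(abs(mean(r2$truth$retained_fraction) - 0.525),
            3 * sqrt(0.95^2 / 12 / 200))
  # insufficient space errors
  expect_error(insert_copies(rnd_dna(3000), fam, 10), "too short|could not place")
})

test_that("TE library families are reproducible, dissimilar, and length-checked", {
  lib1 <- make_te_library(2, seed = 7, length = 1000)
  lib2 <- make_te_library(2, seed = 7, length = 1000)
  expect_identical(lib1[[1]]$seq, lib2[[1]]$seq)
  expect_identical(lib1[[2]]$seq, lib2[[2]]$seq)
  # pairwise dissimilarity: no long high-identity local hit
  h <- search_hits(c(a = lib1[[1]]$seq), c(b = lib1[[2]]$seq),
                   search_params("relaxed", max_evalue = 1))
  h <- h[h$aln_length >= 100 & h$percent_identity >= 60, ]
  expect_equal(nrow(h), 0)
  expect_error(make_te_library(1, length = 500), "800")
  expect_error(te_family_spec("x", length = 500), "800")
  expect_error(te_family_spec("x", divergence_d = 0.9), "0.75")
})

test_that("panel simulation propagates events exactly and reproduces per seed", {
  tr <- tree5()
  specs <- list(
    te_family_spec("vert", length = 900, mode = "vertical",
                   copy_number_per_genome = 3, divergence_d = 0.1,
                   truncation_p = 0.2),
    te_family_spec("htt", length = 900, mode = "htt",
                   origin_branch = "node8", origin_time = 8,
                   copy_number_per_genome = 3, truncation_p = 0.2))
  # node8 is the stem of the (A,B) cherry in tree5 (tips 1..5 = E,A,B,C,D)
  lab <- httrace:::node_labels(tr)
  cherry_ab <- ape::getMRCA(tr, c("A", "B"))
  specs[[2]]$origin_branch <- lab[cherry_ab]
  sim1 <- simulate_panel(tr, specs, genome_length = 20000, seed = 5)
  sim2 <- simulate_panel(tr, specs, genome_length = 20000, seed = 5)
  expect_identical(sim1$genomes, sim2$genomes)
  # truth matrix equals no-loss propagation of the event list
  expect_true(all(sim1$presence["vert", ]))
  prop <- propagate_events(tr, sim1$events, families = "htt")
  expect_identical(sim1$presence["htt", ], prop["htt", ])
  expect_setequal(colnames(sim1$presence)[sim1$presence["htt", ]], c("A", "B"))
  # htt copies carry the clock-implied divergence
  d_exp <- 1.25e-9 * 8e6
  htt_rows <- sim1$truth[sim1$truth$family == "htt", ]
  expect_true(all(abs(htt_rows$true_divergence - d_exp) < 1e-12))
  # an origin_time outside the branch errors
  bad <- te_family_spec("bad", mode = "htt", origin_branch = lab[cherry_ab],
                        origin_time = 25, copy_number_per_genome = 1)
  expect_error(simulate_panel(tr, list(bad), genome_length = 20000, seed = 1),
               "origin_time")
})

test_that("two independent gains on sibling branches give two truth events", {
  tr <- tree4()
  specs <- list(
    te_family_spec("f2", mode = "htt", origin_branch = "A", origin_time = 2,
                   length = 900, copy_number_per_genome = 2),
    te_family_spec("f2b", mode = "htt", origin_branch = "C", origin_time = 2,
                   length = 900, copy_number_per_genome = 2))
  sim <- simulate_panel(tr, specs, genome_length = 15000, seed = 9)
  expect_equal(nrow(sim$events), 2)
  expect_setequal(sim$events$branch, c("A", "C"))
})
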