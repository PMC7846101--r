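# Presence/absence calling and transcript support.

test_that("the three-state presence call follows the 1 kb / 75 percent rule", {
  ev <- function(ids, lens = rep(1200, length(ids))) {
    h <- data.frame(percent_identity = ids, s_start = rep(0L, length(ids)),
                    s_end = lens)
    list(family = "f", hits = h, n_long_hits = nrow(h))
  }
  expect_equal(call_presence(ev(80)), "present_similar")
  expect_equal(call_presence(ev(c(70, 68))), "present_divergent")
  expect_equal(call_presence(ev(70)), "absent")       # one sub-75 hit only
  expect_equal(call_presence(list(hits = NULL)), "absent")
  expect_equal(call_presence(ev(numeric(0))), "absent")
  # monotonicity: raising the best identity never turns present into absent
  for (ids in list(c(60, 65), c(74, 74.9), 75, c(80, 40))) {
    base <- call_presence(ev(ids))
    up <- call_presence(ev(ids + 5))
    if (base != "absent") expect_true(up != "absent")
  }
})

test_that("genome screening collects only >= 1 kb evidence", {
  set.seed(51)
  fam <- rnd_dna(1500)
  # one 1.2 kb copy at ~80 percent identity
  copy <- mutate_sequence(substr(fam, 200, 1399), 0.22)
  g1 <- c(chr = paste0(rnd_dna(8000), copy, rnd_dna(8000)))
  ev1 <- screen_genome(c(f = fam), g1, search_params("relaxed"))
  expect_equal(ev1$n_long_hits, 1)
  expect_true(ev1$best_identity > 75 && ev1$best_identity < 90)
  expect_equal(call_presence(ev1), "present_similar")
  # fragments of <= 999 bp only: empty evidence
  frag <- substr(fam, 1, 900)
  g2 <- c(chr = paste0(rnd_dna(8000), frag, rnd_dna(8000)))
  ev2 <- screen_genome(c(f = fam), g2, search_params("relaxed"))
  expect_equal(ev2$n_long_hits, 0)
  expect_equal(call_presence(ev2), "absent")
})

test_that("transcript support distinguishes supported, fragment-only and none", {
  set.seed(52)
  fam <- rnd_dna(2500)
  tx_sup <- c(t1 = mutate_sequence(substr(fam, 1, 2000), 0.02))   # 98% over 2 kb
  tx_frag <- c(t2 = paste0(rnd_dna(300),
                           mutate_sequence(substr(fam, 1000, 1179), 0.02),
                           rnd_dna(300)))                          # ~98% over 180 bp
  tx_none <- c(t3 = mutate_sequence(substr(fam, 1, 2000), 0.11))  # ~90%
  expect_equal(transcript_support(c(f = fam), tx_sup)$call, "supported")
  expect_equal(transcript_support(c(f = fam), tx_frag)$call, "fragment_only")
  expect_equal(transcript_support(c(f = fam), tx_none)$call, "none")
})

test_that("reciprocal verification drops regions matching a different family better", {
  set.seed(53)
  famA <- rnd_dna(1500)
  famB <- mutate_sequence(famA, 0.09)  # ~85 percent identity relatives
  lib <- c(famA = famA, famB = famB)
  # genome carries only copies of A
  g <- c(chr = paste0(rnd_dna(6000), famA, rnd_dna(4000),
                      mutate_sequence(famA, 0.02), rnd_dna(6000)))
  # screening with B finds the A copies (they are within relaxed reach)...
  evB <- screen_genome(c(famB = famB), g, search_params("relaxed"))
  expect_gt(evB$n_long_hits, 0)
  # ...but reciprocity assigns them to A and drops them
  evB2 <- verify_reciprocal(evB, lib, g)
  expect_equal(evB2$n_long_hits, 0)
  # whereas A evidence survives
  evA <- verify_reciprocal(screen_genome(c(famA = famA), g,
                                         search_params("relaxed")), lib, g)
  expect_gt(evA$n_long_hits, 0)
})

test_that("panel screening recovers the simulated truth matrix exactly", {
  for (seed in 1:3) {
    tr <- tree5()
    lab <- httrace:::node_labels(tr)
    cherry <- ape::getMRCA(tr, c("C", "D"))
    specs <- list(
      te_family_spec("vert", length = 1400, mode = "vertical",
                     copy_number_per_genome = 6, divergence_d = 0.1,
                     truncation_p = 0.3),
      te_family_spec("htt", length = 1400, mode = "htt",
                     origin_branch = lab[cherry], origin_time = 7,
                     copy_number_per_genome = 6, truncation_p = 0.3))
    sim <- simulate_panel(tr, specs, genome_length = 25000, seed = seed)
    fams <- sim$consensi
    scr <- screen_panel(fams, sim$genomes, search_params("relaxed"))
    called <- scr$calls == "present_similar"
    expect_identical(called, sim$presence[rownames(called), ],
                     label = paste("seed", seed))
  }
})

test_that("presence matrices serialize to TSV losslessly", {
  m <- matrix(c("present_similar", "absent", "present_divergent", "absent"),
              2, 2, dimnames = list(c("f1", "f2"), c("sp1", "sp2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence_matrix(m, f)
  expect_identical(read_presence_matrix(f), m)
})
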