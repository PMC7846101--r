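# The seed-and-extend search engine against exhaustive-DP oracles and
# its own contracts.

test_that("seed index retrieves every k-mer occurrence and keeps contigs apart", {
  idx <- build_index(c(s = "ACGTACGT"), 4)
  hit <- index_lookup(idx, "ACGT")
  expect_equal(sort(hit$pos), c(0L, 4L))
  expect_warning(build_index(c(s = "ACGT"), 8), "word_size")
  idx2 <- build_index(c(c1 = "AAAACGTACGTTTT", c2 = "GGACGTACGTGG"), 7)
  h <- index_lookup(idx2, "CGTACGT")
  expect_setequal(h$contig, c("c1", "c2"))
})

test_that("top hit score equals exhaustive Smith-Waterman on random related pairs", {
  set.seed(11)
  for (i in 1:30) {
    pr <- related_pair(len = sample(80:300, 1), d1 = 0.1, d2 = 0.1)
    p <- search_params("relaxed", min_score = 5)
    h <- search_hits(c(q = pr$a), c(s = pr$b), p)
    expect_gt(nrow(h), 0)
    expect_equal(h$score[1],
                 sw_oracle_score(pr$a, pr$b, 3, -4, 30, 6))
  }
  # and with the default-preset scoring
  for (i in 1:10) {
    pr <- related_pair(len = 250, d1 = 0.05, d2 = 0.05)
    p <- search_params("default", min_score = 5)
    h <- search_hits(c(q = pr$a), c(s = pr$b), p)
    expect_equal(h$score[1], sw_oracle_score(pr$a, pr$b, 1, -2, 2, 2))
  }
})

test_that("an exact substring yields a perfect full-length hit", {
  set.seed(12)
  g <- rnd_dna(3000)
  q <- substr(g, 1001, 1100)
  h <- search_hits(c(q = q), c(s = g), search_params("relaxed"))
  expect_equal(h$score[1], 300) # 100 bp x reward 3
  expect_equal(h$percent_identity[1], 100)
  expect_equal(h$aln_length[1], 100)
  expect_equal(c(h$s_start[1], h$s_end[1]), c(1000L, 1100L))
})

test_that("strand symmetry: a reverse-complement query mirrors the hit", {
  set.seed(13)
  g <- setNames(rnd_dna(20000), "chr")
  q <- substr(g, 5001, 6200)
  h1 <- search_hits(c(q = q), g, search_params("default"))
  h2 <- search_hits(c(q = revcomp(q)), g, search_params("default"))
  expect_equal(h1$score[1], h2$score[1])
  expect_equal(h1$s_start[1], h2$s_start[1])
  expect_equal(h1$s_end[1], h2$s_end[1])
  expect_setequal(c(h1$strand[1], h2$strand[1]), c("+", "-"))
})

test_that("self-search returns a full-length 100 percent top hit", {
  set.seed(14)
  for (len in c(500, 2500)) {
    s <- setNames(rnd_dna(len), "self")
    h <- search_hits(s, s, search_params("default"))
    expect_equal(h$percent_identity[1], 100)
    expect_equal(h$q_start[1], 0L)
    expect_equal(h$q_end[1], len)
  }
})

test_that("empty queries and seedless subjects return empty hit tables", {
  expect_equal(nrow(search_hits(character(0), c(s = "ACGTACGTACGT"))), 0)
  set.seed(15)
  h <- search_hits(c(q = rnd_dna(500)), c(s = rnd_dna(500)),
                   search_params("default", full_dp_limit = 1))
  expect_equal(nrow(h), 0)
})

test_that("Karlin-Altschul lambda matches a bisection oracle and e-values behave", {
  for (sc in list(c(1, -1), c(1, -2), c(3, -4))) {
    lam <- karlin_lambda(sc[1], sc[2])
    f <- function(l) 0.25 * exp(l * sc[1]) + 0.75 * exp(l * sc[2]) - 1
    lo <- 1e-9; hi <- 10
    for (i in 1:200) { mid <- (lo + hi) / 2; if (f(mid) < 0) lo <- mid else hi <- mid }
    expect_equal(lam, (lo + hi) / 2, tolerance = 1e-6)
  }
  p <- search_params("relaxed")
  expect_equal(evalue_ka(100, 1000, 2e6, p) / evalue_ka(100, 1000, 1e6, p), 2)
  expect_gt(evalue_ka(80, 1000, 1e6, p), evalue_ka(120, 1000, 1e6, p))
  expect_error(karlin_lambda(3, -1), "negative")
})

test_that("reciprocal best hits require mutual best and break ties by identity", {
  mk <- function(q, s, score, id) data.frame(
    query_id = q, subject_id = s, strand = "+", q_start = 0L, q_end = 100L,
    s_start = 0L, s_end = 100L, score = score, percent_identity = id,
    aln_length = 100L, mismatches = 0L, gap_opens = 0L, evalue = 1e-10,
    stringsAsFactors = FALSE)
  ab <- rbind(mk("A1", "B1", 500, 99), mk("A2", "B1", 400, 95))
  ba <- rbind(mk("B1", "A1", 500, 99))
  rb <- reciprocal_best_hit(ab, ba)
  expect_equal(nrow(rb), 1)
  expect_equal(unlist(rb[1, ]), c(a = "A1", b = "B1"))
  # A1 best is B1, but B1 best is A2: no pair for A1 (the A2-B1 pair is
  # mutual and stands)
  ba2 <- rbind(mk("B1", "A2", 600, 99))
  rb2 <- reciprocal_best_hit(ab, ba2)
  expect_false("A1" %in% rb2$a)
  expect_equal(rb2$a, "A2")
  # score tie resolved by identity
  ab3 <- rbind(mk("A1", "B1", 500, 90), mk("A1", "B2", 500, 99))
  ba3 <- rbind(mk("B2", "A1", 500, 99), mk("B1", "A1", 500, 90))
  rb3 <- reciprocal_best_hit(ab3, ba3)
  expect_equal(unname(unlist(rb3[1, ])), c("A1", "B2"))
})

test_that("a multi-copy genome yields one hit per locus", {
  set.seed(16)
  fam <- rnd_dna(1200)
  g <- paste0(rnd_dna(4000), fam, rnd_dna(3000),
              revcomp(fam), rnd_dna(2000), mutate_sequence(fam, 0.05),
              rnd_dna(2000))
  h <- search_hits(c(f = fam), c(chr = g), search_params("default"))
  expect_equal(nrow(h), 3)
  expect_setequal(h$strand, c("+", "-", "+"))
  # conservation of subject intervals: the three loci do not overlap
  o <- order(h$s_start)
  expect_true(all(h$s_end[o][-3] <= h$s_start[o][-1]))
})
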