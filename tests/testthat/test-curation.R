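# SEAT consensus refinement: MSA, trimming, subfamily splitting and the
# full iteration.

test_that("center-star MSA is gapless on identical inputs and order-invariant", {
  set.seed(41)
  s <- rnd_dna(300)
  a <- msa(c(x = s, y = s, z = s))
  expect_false(any(grepl("-", a, fixed = TRUE)))
  expect_true(all(nchar(a) == 300))
  # removing gap columns recovers each input
  seqs <- setNames(vapply(1:4, function(i) mutate_sequence(s, 0.05), ""),
                   c("p", "q", "r", "t"))
  al <- msa(seqs)
  expect_equal(length(unique(nchar(al))), 1)
  for (nm in names(seqs))
    expect_identical(gsub("-", "", al[[nm]], fixed = TRUE), seqs[[nm]])
  # permuting the input order changes nothing downstream
  al2 <- msa(seqs[c(3, 1, 4, 2)])
  expect_identical(consensus_call(al2[names(al)]), consensus_call(al))
})

test_that("each row-to-center projection of the MSA is an optimal pairwise alignment", {
  # the star merge must preserve every row's pairwise alignment to the
  # center exactly, so the projected pair scores equal the exhaustive
  # local-DP optimum under the MSA's scoring (reward 3 / penalty -4 /
  # gap 30+6L)
  proj_score <- function(al, i, j) {
    m <- do.call(rbind, strsplit(unname(al), ""))
    a <- m[i, ]; b <- m[j, ]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    # per-column scores with affine gaps (open charged per direction run),
    # then the best positive stretch = best local alignment in the
    # projection (Kadane)
    state <- 0L # 0 diag, 1 gap in a, 2 gap in b
    best <- 0; cur <- 0
    for (k in seq_along(a)) {
      if (a[k] != "-" && b[k] != "-") {
        v <- if (a[k] == b[k]) 3 else -4
        state <- 0L
      } else {
        s <- if (a[k] == "-") 1L else 2L
        v <- if (state == s) -6 else -36
        state <- s
      }
      cur <- cur + v
      if (cur < 0) { cur <- 0; state <- 0L }
      if (cur > best) best <- cur
    }
    best
  }
  set.seed(42)
  for (rep in 1:5) {
    anc <- rnd_dna(150)
    toys <- setNames(vapply(1:3, function(i) mutate_sequence(anc, 0.08), ""),
                     c("a", "b", "c"))
    al <- msa(toys)
    # identify the center as the row whose projections achieve the optima
    opt <- outer(1:3, 1:3, Vectorize(function(i, j)
      if (i == j) NA else sw_oracle_score(toys[i], toys[j], 3, -4, 30, 6)))
    hits <- vapply(1:3, function(ctr)
      sum(vapply(setdiff(1:3, ctr), function(i)
        proj_score(al, ctr, i) == opt[ctr, i], TRUE)), 0L)
    expect_true(any(hits == 2))
  }
})

test_that("flank trimming keeps the occupied core and errors on hopeless input", {
  set.seed(43)
  core <- rnd_dna(200)
  # 10 rows sharing a 200-col core; each row has a private 50-col flank
  rows <- vapply(1:10, function(i)
    paste0(strrep("-", (i - 1) * 50), rnd_dna(50), strrep("-", (10 - i) * 50),
           core,
           strrep("-", (i - 1) * 50), rnd_dna(50), strrep("-", (10 - i) * 50)),
    "")
  names(rows) <- paste0("r", 1:10)
  tr <- trim_flanks(rows, seat_params())
  expect_equal(nchar(tr[[1]]), 200)
  # fully occupied alignment is unchanged
  full <- setNames(c(rnd_dna(100), rnd_dna(100)), c("a", "b"))
  expect_identical(as.character(trim_flanks(full, seat_params())),
                   unname(full))
  # occupancy exactly at threshold is retained (inclusive rule)
  half <- c(a = rnd_dna(50), b = rnd_dna(50), c = strrep("-", 50),
            d = strrep("-", 50))
  expect_equal(nchar(trim_flanks(half, seat_params())[[1]]), 50)
  # all-gap-dominated alignment has no core
  bad <- c(a = paste0(rnd_dna(5), strrep("-", 50)),
           b = paste0(strrep("-", 50), rnd_dna(5)),
           c = strrep("-", 55), d = strrep("-", 55))
  expect_error(trim_flanks(bad, seat_params()), "no homologous core")
})

test_that("subfamily splitting recovers simulated clusters at the 94 percent cut", {
  set.seed(44)
  anc <- rnd_dna(600)
  sub1 <- mutate_sequence(anc, 0.08)  # inter-subfamily identity ~86-90%
  sub2 <- mutate_sequence(anc, 0.08)
  mk <- function(s, n, d = 0.01) vapply(1:n, function(i) mutate_sequence(s, d), "")
  seqs <- c(setNames(mk(sub1, 3), paste0("a", 1:3)),
            setNames(mk(sub2, 2), paste0("b", 1:2)))
  al <- msa(seqs)
  subs <- split_subfamilies(al, split_identity = 94)
  expect_equal(length(subs), 2)
  expect_equal(names(subs), c("H1", "H2"))
  expect_setequal(names(subs$H1), paste0("a", 1:3)) # larger cluster first
  expect_setequal(names(subs$H2), paste0("b", 1:2))
  # near-identical rows collapse to one subfamily
  one <- msa(setNames(mk(anc, 4, 0.003), paste0("x", 1:4)))
  expect_equal(length(split_subfamilies(one)), 1)
  # 5 rows, 3 clusters (2/2/1); the singleton joins its nearest cluster
  sub3 <- mutate_sequence(anc, 0.08)
  seqs5 <- c(setNames(mk(sub1, 2), paste0("a", 1:2)),
             setNames(mk(sub2, 2), paste0("b", 1:2)),
             setNames(mk(sub3, 1), "c1"))
  subs5 <- split_subfamilies(msa(seqs5), split_identity = 94)
  expect_equal(length(subs5), 2)
  expect_equal(sum(vapply(subs5, length, 1L)), 5)
})

test_that("SEAT iteration uses the 25 best hits and recovers the true consensus", {
  set.seed(45)
  cons <- rnd_dna(1500)
  g <- rnd_dna(120000)
  # 30 qualifying copies available: exactly top_n = 25 used
  ins <- insert_copies(g, list(name = "f", seq = cons), 30, d = 0.05,
                       truncation_p = 0, seed = 46)
  idx <- build_index(c(chr = ins$genome), 28)
  p <- seat_params(extension = 400, min_hit_len = 1000)
  cc <- seat_iterate(mutate_sequence(cons, 0.03), idx, p, name = "f")
  expect_equal(cc$n_copies_used, 25L)
  expect_gte(pairwise_identity(cc$seq, cons), 99)
  expect_lt(abs(nchar(cc$seq) - 1500) / 1500, 0.02)
  # identity trace is non-decreasing on the road to convergence
  expect_true(all(diff(cc$identity_trace) >= -1e-9) || length(cc$identity_trace) < 2)
})

test_that("a single qualifying copy is returned verbatim as the consensus", {
  set.seed(47)
  cons <- rnd_dna(1200)
  g <- paste0(rnd_dna(20000), cons, rnd_dna(20000))
  cc <- seat_iterate(mutate_sequence(cons, 0.02), c(chr = g),
                     seat_params(), name = "solo")
  expect_true(cc$single_copy)
  expect_identical(cc$seq, cons)
  # and zero qualifying hits error out
  expect_error(
    seat_iterate(rnd_dna(1200), c(chr = rnd_dna(30000)), seat_params(),
                 name = "ghost"),
    "not present")
})

test_that("SEAT convergence holds across seeded scenarios", {
  for (seed in 1:5) {
    set.seed(seed * 100)
    cons <- rnd_dna(1200)
    g <- rnd_dna(60000)
    ins <- insert_copies(g, list(name = "f", seq = cons), 12, d = 0.06,
                         truncation_p = 0.5, seed = seed)
    p <- seat_params(extension = 300, min_hit_len = 600, top_n = 12)
    cc <- seat_iterate(mutate_sequence(cons, 0.04), c(chr = ins$genome), p)
    expect_true(cc$converged || cc$iterations == p$max_iter)
    expect_true(length(cc$identity_trace) < 2 ||
                  all(diff(cc$identity_trace) >= -1e-9))
    expect_gte(pairwise_identity(cc$seq, cons), 98)
  }
})
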