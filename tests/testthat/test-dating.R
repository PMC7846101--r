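# Insertion-age clock and gain-parsimony event inference.

test_that("gain parsimony equals the brute-force minimal-gain oracle on all 2^7 patterns", {
  tr <- elapid_timetree()
  tips <- tr$tip.label
  for (code in 0:(2^7 - 1)) {
    present <- tips[bitwAnd(code, 2^(0:6)) > 0]
    pres <- setNames(tips %in% present, tips)
    ev <- infer_gain_events(pres, tr)
    expect_equal(nrow(ev), brute_min_gains(tr, present),
                 info = paste("pattern", code))
  }
})

test_that("single-tip presence dates to [0, stem age] on the tip branch", {
  tr <- elapid_timetree()
  pres <- setNames(tr$tip.label == "Aipysurus_laevis", tr$tip.label)
  ev <- infer_gain_events(pres, tr, family = "solo")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$branch, "Aipysurus_laevis")
  expect_equal(ev$crown_age, 0)
  expect_equal(ev$stem_age, 5)
  # no presence, no events
  none <- infer_gain_events(setNames(rep(FALSE, 7), tr$tip.label), tr)
  expect_equal(nrow(none), 0)
})

test_that("the sea-snake presence matrix implies nine transfer events", {
  tr <- elapid_timetree()
  m <- sea_snake_presence()
  ev <- infer_all_events(m, tr)
  expect_equal(nrow(ev), 9)
  # Rex1-Snek_1H2/H3 absent from Emydocephalus: two independent events each,
  # one into Aipysurus and one into Hydrophis
  for (fam in c("Rex1-Snek_1H2", "Rex1-Snek_1H3")) {
    e <- ev[ev$family == fam, ]
    expect_equal(nrow(e), 2)
    expect_setequal(e$branch, c("Aipysurus_laevis", "Hydrophis_melanocephalus"))
  }
  # all events postdate the marine transition window upper bound
  expect_true(all(ev$stem_age <= 18))
})

test_that("character presence calls map through divergent_is_present", {
  tr <- tree4() # ((A,B),(C,D))
  calls <- setNames(c("present_similar", "absent", "present_divergent",
                      "absent"), tr$tip.label)
  # divergent counts as absent by default: one single-tip event on A
  expect_equal(nrow(infer_gain_events(calls, tr)), 1)
  # counted as present: A and C are not a clade, so two events
  expect_equal(nrow(infer_gain_events(calls, tr, divergent_is_present = TRUE)), 2)
})

test_that("the substitution-rate clock is linear and unit-consistent", {
  expect_equal(insertion_time(0)$T_mean, 0)
  # one generation of divergence = 10 years = 1e-5 Ma
  expect_equal(insertion_time(1.25e-8)$T_mean, 1e-5)
  expect_equal(insertion_time(0.0125)$T_mean, 10)
  # doubling the rate halves the age
  ck2 <- clock_params(rate_per_site_per_generation = 2.5e-8)
  expect_equal(insertion_time(0.0125, clock = ck2)$T_mean, 5)
  # SD scales identically
  it <- insertion_time(0.0125, sd_d = 0.0025)
  expect_equal(it$T_sd / it$T_mean, 0.2)
  expect_error(clock_params(rate_per_site_per_generation = 0))
})

test_that("copy divergence recovers the simulated value and JC never shrinks it", {
  set.seed(61)
  fam <- rnd_dna(2000)
  g <- rnd_dna(120000)
  ins <- insert_copies(g, list(name = "f", seq = fam), 50, d = 0.05,
                       truncation_p = 0, seed = 62)
  cd <- copy_divergence(c(f = fam), c(chr = ins$genome))
  expect_equal(cd$n, 50)
  p_exp <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  expect_lt(abs(cd$mean_d - p_exp), 3 * cd$se_d + 1e-4)
  cdj <- copy_divergence(c(f = fam), c(chr = ins$genome), jc = TRUE)
  expect_true(all(cdj$per_copy >= cd$per_copy - 1e-12))
  # JC correction recovers d itself
  expect_lt(abs(cdj$mean_d - 0.05), 3 * cdj$se_d + 2e-4)
  # identical copies: zero divergence; empty genome errors
  ins0 <- insert_copies(g, list(name = "f", seq = fam), 5, d = 0,
                        truncation_p = 0, seed = 63)
  expect_equal(copy_divergence(c(f = fam), c(chr = ins0$genome))$mean_d, 0)
  expect_error(copy_divergence(c(f = fam), c(chr = rnd_dna(20000))),
               "no copies")
})

test_that("clock and branch intervals are reconciled by interval overlap", {
  ev <- data.frame(family = c("a", "b"), branch = c("x", "y"),
                   crown_age = c(4, 4), stem_age = c(9, 9),
                   n_tips = c(2L, 2L), stringsAsFactors = FALSE)
  ca <- data.frame(family = c("a", "b"), clock_mean = c(5, 1),
                   clock_sd = c(2, 0.5))
  out <- consistency(ev, ca)
  expect_equal(out$consistent, c(TRUE, FALSE))
})

test_that("simulated transfer ages are recovered by the clock within tolerance", {
  # an event at 10 Ma under the default clock (rate 1.25e-9 per site per
  # year): copies diverge by 0.0125 and the inferred age lands near 10 Ma
  set.seed(64)
  fam <- rnd_dna(3000)
  d_true <- 1.25e-9 * 10e6
  g <- rnd_dna(200000)
  ins <- insert_copies(g, list(name = "f", seq = fam), 50, d = d_true,
                       truncation_p = 0.3, seed = 65)
  cd <- copy_divergence(c(f = fam), c(chr = ins$genome), jc = TRUE)
  t_hat <- insertion_time(cd$mean_d, cd$sd_d)$T_mean
  expect_lt(abs(t_hat - 10) / 10, 0.2)
})
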