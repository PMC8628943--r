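# Peak matching, the four-score family, the decision rule, FDR, heat map.

make_spec <- function(mz, intensity, scan = "s1", pmz = 651.31, z = 2L) {
  spectrum(scan, pmz, z, mz, intensity)
}

# fabricate a match object with chosen statistical scores
fake_match <- function(pp, pp2, pp_tag) {
  structure(list(pp = pp, pp2 = pp2, pp_tag = pp_tag,
                 score = 50, scan_id = paste0("s", stats::runif(1))),
            class = "xl_match")
}

test_that("match_peaks applies the window and intensity tie rules", {
  f <- data.frame(chain = "alpha", series = "b", index = 1,
                  carries_partner = FALSE, charge = 1,
                  neutral_mass = 174.11, mz = 175.12)
  s <- make_spec(c(175.8, 176.2), c(5, 500))
  m <- match_peaks(s, f, 0.8)
  expect_identical(nrow(m), 1L)
  expect_equal(s$peaks$mz[m$peak], 175.8)
  # most intense within window wins over closer peak
  s2 <- make_spec(c(175.0, 175.3), c(100, 10))
  m2 <- match_peaks(s2, f, 0.8)
  expect_equal(s2$peaks$mz[m2$peak], 175.0)
  expect_identical(nrow(match_peaks(make_spec(numeric(), numeric()), f, 0.8)),
                   0L)
})

test_that("a full-coverage synthetic spectrum matches all 22 fragments", {
  p <- txlp_pair()
  s <- simulate_spectrum(p, 2, sim_params(fragment_coverage = 1,
                                          noise_peaks = 0, mz_jitter_sd = 0,
                                          seed = 3))
  f <- predict_fragments(p, 1)
  m <- match_peaks(s, f, 0.8)
  expect_identical(nrow(m), 22L)
  expect_true(all(abs(m$error) < 1e-9))
})

test_that("descriptive score is the matched-abundance percentage", {
  s <- make_spec(c(100, 200, 300, 400, 500), c(10, 20, 30, 40, 100))
  matched <- data.frame(frag = 1:3, peak = c(2L, 4L, 5L), error = 0,
                        shared = FALSE)
  expect_equal(descriptive_score(s, matched), 80)
  all_m <- data.frame(frag = 1:5, peak = 1:5, error = 0, shared = FALSE)
  expect_equal(descriptive_score(s, all_m), 100)
  none <- data.frame(frag = integer(), peak = integer(), error = numeric(),
                     shared = logical())
  expect_equal(descriptive_score(s, none), 0)
  zero <- make_spec(c(100, 200), c(0, 0))
  expect_error(descriptive_score(zero, none), "zero total intensity")
})

test_that("pp equals exact binomial enumeration for n <= 12", {
  s <- make_spec(seq(200, 1200, length.out = 22), rep(10, 22))
  p_rand <- min(1, 22 * 2 * 0.8 / 1850)
  # independent oracle: explicit pmf summation
  exact_tail <- function(n, k, p) {
    sum(vapply(k:n, function(i)
      choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
  }
  for (n in c(3, 7, 12)) for (k in seq(0, n, by = 2)) {
    got <- pp_score(n, k, s, 0.8, c(150, 2000))
    want <- if (k == 0) 0 else -log10(exact_tail(n, k, p_rand))
    expect_equal(got, want, tolerance = 1e-8)
  }
  # the spec-anchored case: 18 of 22 matched among 22 peaks
  got <- pp_score(22, 18, s, 0.8, c(150, 2000))
  expect_equal(got, -log10(exact_tail(22, 18, p_rand)), tolerance = 1e-8)
  expect_gt(got, 20)
})

test_that("pp decreases when the spectrum gets noisier", {
  s1 <- make_spec(seq(200, 1200, length.out = 22), rep(10, 22))
  s2 <- make_spec(seq(200, 1200, length.out = 44), rep(10, 44))
  expect_gt(pp_score(22, 18, s1, 0.8), pp_score(22, 18, s2, 0.8))
  expect_equal(pp_score(22, 0, s1, 0.8), 0)
  expect_equal(pp_score(0, 0, s1, 0.8), 0)
})

test_that("pp2 is seeded, monotone in matched abundance, and extrapolates", {
  set.seed(1)
  s <- make_spec(seq(200, 1900, length.out = 60),
                 stats::rlnorm(60, 10, 1))
  o <- order(-s$peaks$intensity)
  top <- data.frame(frag = 1:10, peak = o[1:10], error = 0, shared = FALSE)
  bottom <- data.frame(frag = 1:10, peak = o[51:60], error = 0, shared = FALSE)
  a1 <- pp2_score(s, top, seed = 7, n_theoretical = 40)
  a2 <- pp2_score(s, top, seed = 7, n_theoretical = 40)
  expect_identical(a1, a2)  # determinism
  b <- pp2_score(s, bottom, seed = 7, n_theoretical = 40)
  expect_gte(a1, b)  # the k most intense maximize pp2 for that k
  expect_equal(pp2_score(s, top[0, ], seed = 7, n_theoretical = 40), 0)
  # matching everything heavily must escape the Monte-Carlo ceiling
  all_m <- data.frame(frag = 1:60, peak = 1:60, error = 0, shared = FALSE)
  expect_gt(pp2_score(s, all_m, seed = 7, n_theoretical = 60), 5)
})

test_that("pp_tag rewards consecutive ion-series runs", {
  p <- txlp_pair()
  f <- predict_fragments(p, 1)
  s <- make_spec(seq(200, 1200, length.out = 22), rep(10, 22))
  none <- data.frame(frag = integer(), peak = integer(), error = numeric(),
                     shared = logical())
  expect_equal(pp_tag_score(f, none, s, 0.8), 0)
  # full alpha y-series: L = 6; plug-in arithmetic oracle
  ys <- which(f$chain == "alpha" & f$series == "y")
  my <- data.frame(frag = ys, peak = seq_along(ys), error = 0, shared = FALSE)
  p_rand <- min(1, 22 * 2 * 0.8 / 1850)
  want <- -log10(min(1, 22 * p_rand^6))
  expect_equal(pp_tag_score(f, my, s, 0.8), want, tolerance = 1e-8)
  # scattered matches of the same count never beat the consecutive run
  scattered <- which(f$chain == "alpha" & f$series == "y" &
                       f$index %in% c(1, 3, 5)) # L = 1
  ms <- data.frame(frag = scattered, peak = 1:3, error = 0, shared = FALSE)
  consec <- which(f$chain == "alpha" & f$series == "y" & f$index %in% 1:3)
  mc <- data.frame(frag = consec, peak = 1:3, error = 0, shared = FALSE)
  expect_lte(pp_tag_score(f, ms, s, 0.8), pp_tag_score(f, mc, s, 0.8))
  expect_equal(pp_tag_score(f, ms, s, 0.8), 0)  # L <= 1
})

test_that("overall score and decision rule follow the reported pattern", {
  sp <- search_params()
  mk_site <- function(matches) site_result("p", 10, "p", 20, matches)
  # no spectrum passes the minima
  s0 <- mk_site(list(fake_match(4, 9, 2)))
  expect_equal(overall_score(s0, sp), 0)
  expect_false(decide(s0, sp))
  # one spectrum with pp = pp2 = pp_tag = 6 scores 6
  s1 <- mk_site(list(fake_match(6, 6, 6)))
  expect_equal(overall_score(s1, sp), 6)
  # additivity over passing spectra
  s2 <- mk_site(list(fake_match(6, 6, 6), fake_match(9, 9, 9)))
  expect_equal(overall_score(s2, sp), 15)
  expect_gt(overall_score(s2, sp), overall_score(s1, sp))
  # overall 22 with 5 spectra: accepted
  five <- mk_site(replicate(5, fake_match(5.5, 5.5, 2.2), simplify = FALSE))
  expect_equal(overall_score(five, sp), 22)
  expect_true(decide(five, sp))
  # overall 10 with 1 spectrum: rejected
  one10 <- mk_site(list(fake_match(10, 10, 10)))
  expect_equal(overall_score(one10, sp), 10)
  expect_false(decide(one10, sp))
  # overall 22 with 1 spectrum: rejected by the spectral-count rule
  one22 <- mk_site(list(fake_match(22, 22, 22)))
  expect_equal(overall_score(one22, sp), 22)
  expect_false(decide(one22, sp))
})

test_that("target-decoy FDR behaves at the boundaries", {
  ov <- c(30, 25, 20, 18, 16, 15, 12, 11, 10, 9)
  cls <- c(rep("TT", 5), "TD", rep("TT", 4))
  q <- compute_fdr(ov, cls)
  # at the most permissive threshold: TT = 9, TD = 1, DD = 0 -> FDR 1/9
  expect_equal(q[length(q)], 1 / 9)
  # sites above the decoy carry q = 0
  expect_equal(q[1:5], rep(0, 5))
  # no decoys anywhere: all q-values 0
  expect_equal(compute_fdr(ov, rep("TT", 10)), rep(0, 10))
  # all hits decoy: clamped to [0, 1]
  qd <- compute_fdr(c(10, 9), c("TD", "TD"))
  expect_true(all(qd >= 0 & qd <= 1))
  expect_equal(qd, c(1, 1))
  # decoy q-values never undercut a higher-scoring target's q-value
  expect_true(all(q[cls == "TD"] >= q[1]))
  expect_length(compute_fdr(numeric(), character()), 0)
})

test_that("heat map indexes overall scores by protein coordinates", {
  qpos <- c(100, 200); kpos <- c(50, 150, 250)
  empty <- build_heatmap(qpos, kpos, data.frame())
  expect_identical(dim(empty), c(2L, 3L))
  expect_true(all(empty == 0))
  sites <- data.frame(q_pos = c(200, 100), k_pos = c(150, 50),
                      overall = c(22, 3))
  m <- build_heatmap(qpos, kpos, sites)
  expect_equal(m["Q200", "K150"], 22)
  expect_equal(m["Q100", "K50"], 3)
  expect_identical(which(m == max(m)), which(m == 22))
})
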