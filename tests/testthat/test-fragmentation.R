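# Branched b/y fragment prediction against a brute-force prefix/suffix
# oracle, plus the complementarity conservation identity.

# independent oracle: enumerate all prefix/suffix sums directly
oracle_fragments <- function(a_seq, b_seq, k, q) {
  branch <- function(seq_own, seq_other, xl) {
    v <- MONO[strsplit(seq_own, "")[[1]]]
    partner <- sum(MONO[strsplit(seq_other, "")[[1]]]) + WATER - NH3
    n <- length(v)
    out <- NULL
    for (i in seq_len(n - 1)) {
      b <- sum(v[1:i]) + if (xl <= i) partner else 0
      y <- sum(v[(n - i + 1):n]) + WATER + if (xl > n - i) partner else 0
      out <- rbind(out, data.frame(series = c("b", "y"), index = i,
                                   neutral = c(b, y)))
    }
    out
  }
  list(alpha = branch(a_seq, b_seq, k), beta = branch(b_seq, a_seq, q))
}

test_that("TXLP fragments match counts and the printed anchor values", {
  p <- txlp_pair()
  f <- predict_fragments(p, 1)
  expect_identical(nrow(f), 22L)  # (7-1)*2 + (6-1)*2
  y1 <- f[f$chain == "alpha" & f$series == "y" & f$index == 1, ]
  expect_equal(y1$mz, 175.119, tolerance = 1e-3)
  expect_false(y1$carries_partner)
  b4 <- f[f$chain == "alpha" & f$series == "b" & f$index == 4, ]
  expect_equal(b4$mz, 973.433, tolerance = 1e-3)
  expect_true(b4$carries_partner)
  expect_true(all(f$mz > 0))
  expect_error(predict_fragments(p, 0), "invalid charge")
})

test_that("fragments agree with the brute-force oracle on short pairs", {
  set.seed(11)
  cases <- list(c("EGGKGPR", "SQDGGR", 4, 2),
                c("AKGR", "GQR", 2, 2),
                c("GGKAAR", "AQGGAR", 3, 2),
                c("WKHACR", "MQYFNR", 2, 2))
  for (cs in cases) {
    pr <- crosslinked_pair(cs[1], cs[2], as.integer(cs[3]), as.integer(cs[4]))
    f <- predict_fragments(pr, 1)
    orc <- oracle_fragments(cs[1], cs[2], as.integer(cs[3]), as.integer(cs[4]))
    for (ch in c("alpha", "beta")) {
      got <- f[f$chain == ch, ]
      exp <- orc[[ch]]
      got <- got[order(got$series, got$index), ]
      exp <- exp[order(exp$series, exp$index), ]
      expect_equal(got$neutral_mass, exp$neutral, tolerance = 1e-6)
    }
  }
})

test_that("complementary b/y fragments conserve the pair mass", {
  p <- txlp_pair()
  f <- predict_fragments(p, 2)
  expect_true(fragment_conservation_check(p, f))
  # i = 4 on alpha: b4 + y3 = pair mass (one of them carries the partner)
  b4 <- f$neutral_mass[f$chain == "alpha" & f$series == "b" &
                         f$index == 4 & f$charge == 1]
  y3 <- f$neutral_mass[f$chain == "alpha" & f$series == "y" &
                         f$index == 3 & f$charge == 1]
  expect_equal(b4 + y3, pair_mass(p), tolerance = 1e-4)
  # perturbation is detected
  f2 <- f
  f2$neutral_mass[5] <- f2$neutral_mass[5] + 0.01
  expect_false(fragment_conservation_check(p, f2))
  # linear textbook identity: b_i + y_{n-i} = M for an uncross-linked chain
  v <- MONO[strsplit("SAMPLER", "")[[1]]]
  for (i in 1:6)
    expect_equal(sum(v[1:i]) + (sum(v[(i + 1):7]) + WATER),
                 oracle_mass("SAMPLER"))
})

test_that("exactly one complementary fragment carries the partner", {
  for (sd in 1:5) {
    seqs <- random_sequences(2, c(4, 8), sd)
    a <- gsub("K", "L", seqs[1]); b <- gsub("Q", "N", seqs[2])
    a <- paste0(substring(a, 1, 2), "K", substring(a, 3))
    b <- paste0(substring(b, 1, 1), "Q", substring(b, 2))
    pr <- crosslinked_pair(a, b, 3, 2)
    f <- predict_fragments(pr, 1)
    for (ch in c("alpha", "beta")) {
      d <- f[f$chain == ch, ]
      n <- max(d$index) + 1
      for (i in unique(d$index)) {
        cb <- d$carries_partner[d$series == "b" & d$index == i]
        cy <- d$carries_partner[d$series == "y" & d$index == n - i]
        expect_identical(cb + cy, 1L)
      }
    }
    expect_true(fragment_conservation_check(pr, f))
  }
})

test_that("modifications shift fragment masses but not counts", {
  plain <- crosslinked_pair("EGGKGPR", "SQDGGR", 4, 2)
  ox <- crosslinked_pair(
    peptide("MGGKGPR", mods = data.frame(pos = 1L, name = "oxidation",
                                         delta = 15.994915)),
    peptide("SQDGGR"), 4, 2)
  f1 <- predict_fragments(plain, 2)
  f2 <- predict_fragments(ox, 2)
  expect_identical(nrow(f1), nrow(f2))
  expect_identical(f1[, c("chain", "series", "index", "charge")],
                   f2[, c("chain", "series", "index", "charge")])
})
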