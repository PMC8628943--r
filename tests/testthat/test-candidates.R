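# Cross-linkable sites, modification expansion, pair enumeration.

test_that("cross-linkable sites follow the boundary and deamidation rules", {
  s <- crosslinkable_sites(peptide("EGGKGPR"))
  expect_identical(s$k, 4L)
  expect_length(s$q, 0)
  s <- crosslinkable_sites(peptide("SQDGGR"))
  expect_length(s$k, 0)
  expect_identical(s$q, 2L)
  expect_length(crosslinkable_sites(peptide("AAAK"))$k, 0)
  expect_identical(crosslinkable_sites(peptide("AAAK"),
                                       allow_cterm_k = TRUE)$k, 4L)
  deam <- peptide("SQDGGR", mods = data.frame(pos = 2L, name = "deamidation",
                                              delta = 0.984016))
  expect_length(crosslinkable_sites(deam)$q, 0)
})

test_that("modification expansion enumerates the right variants", {
  mods <- standard_modifications()
  sp <- search_params(fixed_modifications = list(mods$carbamidomethyl),
                      variable_modifications = list(mods$oxidation),
                      max_variable_mods = 2L)
  v <- expand_modifications(peptide("AMGGGR"), sp)
  expect_length(v, 2)  # one M: present/absent
  v <- expand_modifications(peptide("ACGGGR"), sp)
  expect_length(v, 1)  # fixed only
  expect_equal(peptide_mass(v[[1]]), oracle_mass("ACGGGR", 57.02146),
               tolerance = 1e-4)
  v <- expand_modifications(peptide("AMGMGR"), sp)
  expect_length(v, 4)  # 2^2 combinations of two M sites
})

test_that("enumerate_pairs finds exactly the model pair at its precursor", {
  peps <- list(peptide("EGGKGPR", missed_cleavages = 1),
               peptide("SQDGGR"), peptide("AAAAAR"))
  sp <- search_params()
  pairs <- enumerate_pairs(peps, 1300.612, sp)
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$alpha$sequence, "EGGKGPR")
  expect_identical(pairs[[1]]$k_pos, 4L)
  expect_identical(pairs[[1]]$q_pos, 2L)
  # 1 Da off is far outside 20 ppm of 1300
  expect_length(enumerate_pairs(peps, 1301.612, sp), 0)
  expect_length(enumerate_pairs(list(), 1300.612, sp), 0)
})

test_that("decoy chains label pairs TD", {
  alpha <- peptide("EGGKGPR", missed_cleavages = 1)
  beta_decoy <- peptide("SQDGGR", is_decoy = TRUE)
  pairs <- enumerate_pairs(list(alpha, beta_decoy), 1300.612, search_params())
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$decoy_class, "TD")
})

test_that("enumeration matches an exhaustive brute-force oracle", {
  prot <- synthetic_protein(300, seed = 5)
  peps <- digest(prot$sequence, prot$protein_id,
                 params = digest_params(3, 6, 40))
  peps <- peps[seq_len(min(50, length(peps)))]
  sp <- search_params()
  rule <- protease_rule()
  # oracle: exhaustive triple loop over all (K-peptide, Q-peptide, sites)
  oracle <- function(precursor) {
    keys <- character()
    for (a in peps) for (b in peps) {
      sa <- crosslinkable_sites(a); sb <- crosslinkable_sites(b)
      for (k in sa$k) for (q in sb$q) {
        if (isoxlink:::effective_missed_cleavages(a, k, rule) > 2) next
        if (b$missed_cleavages > 2) next
        m <- peptide_mass(a) + peptide_mass(b) - NH3
        if (abs(m - precursor) / precursor <= 20e-6)
          keys <- c(keys, paste(a$start, a$end, k, b$start, b$end, q))
      }
    }
    sort(unique(keys))
  }
  masses <- vapply(peps, peptide_mass, numeric(1))
  precursors <- c(masses[1] + masses[2] - NH3, masses[3] + masses[7] - NH3,
                  2000.123)
  for (pm in precursors) {
    got <- enumerate_pairs(peps, pm, sp)
    got_keys <- sort(vapply(got, function(p)
      paste(p$alpha$start, p$alpha$end, p$k_pos,
            p$beta$start, p$beta$end, p$q_pos), character(1)))
    expect_identical(got_keys, oracle(pm))
  }
})

test_that("widening the precursor tolerance never removes a candidate", {
  prot <- synthetic_protein(300, seed = 5)
  peps <- digest(prot$sequence, prot$protein_id,
                 params = digest_params(3, 6, 40))
  pm <- peptide_mass(peps[[1]]) + peptide_mass(peps[[4]]) - NH3 + 0.01
  keyset <- function(tol) {
    prs <- enumerate_pairs(peps, pm, search_params(precursor_tol_ppm = tol))
    vapply(prs, function(p) paste(p$alpha$start, p$k_pos,
                                  p$beta$start, p$q_pos), character(1))
  }
  k10 <- keyset(10); k20 <- keyset(20); k100 <- keyset(100)
  expect_true(all(k10 %in% k20))
  expect_true(all(k20 %in% k100))
})

test_that("no enumerated pair carries a modification on its linked site", {
  prot <- synthetic_protein(300, seed = 8)
  mods <- standard_modifications()
  sp <- search_params(variable_modifications = list(mods$oxidation,
                                                    mods$deamidation))
  peps <- digest(prot$sequence, prot$protein_id,
                 params = digest_params(3, 6, 40))
  expanded <- unlist(lapply(peps, expand_modifications, sp),
                     recursive = FALSE)
  kp <- Filter(function(p) length(crosslinkable_sites(p)$k) > 0, peps)[[1]]
  qp <- Filter(function(p) length(crosslinkable_sites(p)$q) > 0, peps)[[1]]
  pm <- peptide_mass(kp) + peptide_mass(qp) - NH3
  prs <- enumerate_pairs(expanded, pm, sp)
  expect_gte(length(prs), 1)
  for (p in prs) {
    if (nrow(p$alpha$mods)) expect_false(p$k_pos %in% p$alpha$mods$pos)
    if (nrow(p$beta$mods)) expect_false(p$q_pos %in% p$beta$mods$pos)
  }
})
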