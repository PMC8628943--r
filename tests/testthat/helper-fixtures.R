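# Shared fixtures: the model cross-linked pair (EGGKGPR x SQDGGR, mimicking
# collagen alpha-1(I) tryptic peptides) and small helpers. All fixtures are
# built in code; no binary data.

txlp_alpha <- function() peptide("EGGKGPR", "collagen_a1", start = 893,
                                 missed_cleavages = 1)
txlp_beta <- function() peptide("SQDGGR", "collagen_a1", start = 1198)
txlp_pair <- function() crosslinked_pair(txlp_alpha(), txlp_beta(), 4, 2)

MONO <- residue_mass_table()$residue_masses
WATER <- residue_mass_table()$water_mass
PROTON <- residue_mass_table()$proton_mass
NH3 <- residue_mass_table()$ammonia_mass

# independent hand-sum mass oracle (no shared code path with peptide_mass)
oracle_mass <- function(seq, mod_delta = 0) {
  sum(MONO[strsplit(seq, "")[[1]]]) + WATER + mod_delta
}

proteins_df <- function(...) {
  ps <- list(...)
  data.frame(protein_id = vapply(ps, `[[`, "", "protein_id"),
             sequence = vapply(ps, `[[`, "", "sequence"),
             stringsAsFactors = FALSE)
}

# display rounding used by the literature (half away from zero)
round_half_up_test <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# random valid peptide sequences for property tests
random_sequences <- function(n, len_range = c(4, 12), seed = 1) {
  set.seed(seed)
  letters20 <- names(MONO)
  replicate(n, paste(sample(letters20, sample(len_range[1]:len_range[2], 1),
                            replace = TRUE), collapse = ""))
}
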