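# Monoisotopic mass model: residues, modifications, peptides, and the
# Lys-Gln isopeptide cross-link (condensation with loss of NH3).

#' Standard monoisotopic residue masses (Da)
#'
#' Residue (not free amino acid) masses for the 20 standard amino acids.
#' @keywords internal
AMINO_ACID_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

MASS_WATER   <- 18.010565
MASS_PROTON  <- 1.007276
MASS_AMMONIA <- 17.026549  # lost on isopeptide bond formation

#' Monoisotopic residue mass table
#'
#' The mass model used throughout the package: residue masses for the 20
#' standard amino acids, water (peptide termini), the proton (charging), and
#' ammonia (the neutral lost when a glutamine side-chain amide condenses
#' with a lysine epsilon-amine to form the isopeptide cross-link).
#'
#' @return A list with elements `residue_masses` (named numeric vector),
#'   `water_mass`, `proton_mass` and `ammonia_mass` (Da).
#' @export
#' @examples
#' residue_mass_table()$ammonia_mass
residue_mass_table <- function() {
  list(
    residue_masses = AMINO_ACID_MONO,
    water_mass     = MASS_WATER,
    proton_mass    = MASS_PROTON,
    ammonia_mass   = MASS_AMMONIA
  )
}

valid_sequence <- function(sequence) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
}

assert_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("invalid sequence: empty or not a single string", call. = FALSE)
  if (!valid_sequence(sequence))
    stop("invalid sequence: unknown residue letter in '", sequence, "'",
         call. = FALSE)
  invisible(sequence)
}

#' Define a peptide modification
#'
#' @param name Short name, e.g. `"oxidation"`.
#' @param target Residue letter the modification applies to, or `"N-term"` /
#'   `"C-term"`.
#' @param delta_mass Monoisotopic mass shift in Da.
#' @param type `"fixed"` (always applied) or `"variable"` (combinatorially
#'   expanded during the search).
#' @return An object of class `xl_mod`.
#' @export
modification <- function(name, target, delta_mass,
                         type = c("variable", "fixed")) {
  type <- match.arg(type)
  if (!is.finite(delta_mass)) stop("delta_mass must be finite", call. = FALSE)
  ok <- target %in% c(names(AMINO_ACID_MONO), "N-term", "C-term")
  if (!ok) stop("modification target must be a residue letter or terminus",
                call. = FALSE)
  structure(list(name = name, target = target,
                 delta_mass = delta_mass, type = type),
            class = "xl_mod")
}

#' The search's standard modification set
#'
#' Carbamidomethylation of cysteine (fixed, from iodoacetamide alkylation),
#' methionine oxidation and glutamine deamidation (variable). These are the
#' modifications relevant to in-gel digests of cross-linked proteins.
#'
#' @return Named list of [modification()] objects.
#' @export
standard_modifications <- function() {
  list(
    carbamidomethyl = modification("carbamidomethyl", "C", 57.021464, "fixed"),
    oxidation       = modification("oxidation",       "M", 15.994915, "variable"),
    deamidation     = modification("deamidation",     "Q",  0.984016, "variable")
  )
}

empty_mods <- function() {
  data.frame(pos = integer(), name = character(), delta = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a peptide
#'
#' A digested sequence with provenance coordinates (1-based inclusive
#' positions in the parent protein), a missed-cleavage count, attached
#' modifications and a decoy flag.
#'
#' @param sequence Residue string (uppercased).
#' @param protein_id Parent protein identifier.
#' @param start 1-based start coordinate in the parent protein.
#' @param missed_cleavages Number of internal uncleaved protease sites.
#' @param mods `data.frame` with columns `pos` (1-based position within the
#'   peptide), `name`, `delta` (Da); or `NULL` for none.
#' @param is_decoy Whether the peptide derives from a reversed sequence.
#' @return An object of class `xl_peptide`.
#' @export
#' @examples
#' peptide("EGGKGPR", "collagen_a1", start = 893, missed_cleavages = 1)
peptide <- function(sequence, protein_id = "", start = 1L,
                    missed_cleavages = 0L, mods = NULL, is_decoy = FALSE) {
  sequence <- toupper(sequence)
  assert_sequence(sequence)
  n <- nchar(sequence)
  if (is.null(mods)) mods <- empty_mods()
  if (nrow(mods) && (any(mods$pos < 1L) || any(mods$pos > n)))
    stop("modification position outside peptide", call. = FALSE)
  structure(list(
    sequence = sequence,
    protein_id = protein_id,
    start = as.integer(start),
    end = as.integer(start) + n - 1L,
    missed_cleavages = as.integer(missed_cleavages),
    mods = mods,
    is_decoy = isTRUE(is_decoy)
  ), class = "xl_peptide")
}

#' @export
print.xl_peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s  [%s %d-%d]  missed=%d  mods=%d%s\n",
              x$sequence, x$protein_id, x$start, x$end,
              x$missed_cleavages, nrow(x$mods),
              if (x$is_decoy) "  DECOY" else ""))
  invisible(x)
}

as_peptide <- function(p) {
  if (inherits(p, "xl_peptide")) p else peptide(p)
}

# Per-residue masses including modification deltas; used by both the
# peptide mass and the fragment predictor so the two cannot disagree.
residue_masses_with_mods <- function(p) {
  v <- unname(AMINO_ACID_MONO[strsplit(p$sequence, "")[[1]]])
  if (nrow(p$mods)) {
    for (i in seq_len(nrow(p$mods)))
      v[p$mods$pos[i]] <- v[p$mods$pos[i]] + p$mods$delta[i]
  }
  v
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water plus all modification deltas.
#'
#' @param p An [peptide()] object or a bare sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("EGGKGPR")  # 699.3664
peptide_mass <- function(p) {
  p <- as_peptide(p)
  sum(residue_masses_with_mods(p)) + MASS_WATER
}

#' Construct a Lys-Gln cross-linked peptide pair
#'
#' Joins a lysine-donor chain (`alpha`) and a glutamine-donor chain (`beta`)
#' through an isopeptide bond. The pair's neutral mass is
#' `mass(alpha) + mass(beta) - NH3`: the condensation releases ammonia.
#'
#' @param alpha Lys-donor [peptide()] (or sequence string).
#' @param beta Gln-donor [peptide()] (or sequence string).
#' @param k_pos 1-based position of the cross-linked K within `alpha`.
#' @param q_pos 1-based position of the cross-linked Q within `beta`.
#' @return An object of class `xl_pair`.
#' @export
#' @examples
#' crosslinked_pair("EGGKGPR", "SQDGGR", k_pos = 4, q_pos = 2)
crosslinked_pair <- function(alpha, beta, k_pos, q_pos) {
  alpha <- as_peptide(alpha); beta <- as_peptide(beta)
  k_pos <- as.integer(k_pos); q_pos <- as.integer(q_pos)
  if (substring(alpha$sequence, k_pos, k_pos) != "K")
    stop("alpha position ", k_pos, " is not K", call. = FALSE)
  if (substring(beta$sequence, q_pos, q_pos) != "Q")
    stop("beta position ", q_pos, " is not Q", call. = FALSE)
  if (nrow(alpha$mods) && k_pos %in% alpha$mods$pos)
    stop("cross-linked K carries another modification", call. = FALSE)
  if (nrow(beta$mods) && q_pos %in% beta$mods$pos)
    stop("cross-linked Q carries another modification", call. = FALSE)
  dc <- c("TT", "TD", "DD")[1L + alpha$is_decoy + beta$is_decoy]
  structure(list(
    alpha = alpha, beta = beta, k_pos = k_pos, q_pos = q_pos,
    neutral_mass = peptide_mass(alpha) + peptide_mass(beta) - MASS_AMMONIA,
    decoy_class = dc
  ), class = "xl_pair")
}

#' @export
print.xl_pair <- function(x, ...) {
  cat(sprintf("<cross-linked pair> %s(K%d) x %s(Q%d)  M = %.4f Da  [%s]\n",
              x$alpha$sequence, x$k_pos, x$beta$sequence, x$q_pos,
              x$neutral_mass, x$decoy_class))
  invisible(x)
}

#' Neutral mass of a cross-linked pair
#'
#' @param pair An [crosslinked_pair()] object.
#' @return `mass(alpha) + mass(beta) - 17.026549` Da.
#' @export
pair_mass <- function(pair) {
  stopifnot(inherits(pair, "xl_pair"))
  pair$neutral_mass
}

#' Mass-to-charge ratio of a protonated ion
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return `(neutral_mass + charge * proton) / charge`.
#' @export
#' @examples
#' mz(1300.612, 2)  # 651.31
mz <- function(neutral_mass, charge) {
  charge <- as.integer(charge)
  if (any(is.na(charge)) || any(charge < 1L))
    stop("invalid charge: must be a positive integer", call. = FALSE)
  (neutral_mass + charge * MASS_PROTON) / charge
}

# Round half away from zero, for display at the precision the literature
# prints (sprintf/round use banker's rounding in edge cases).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
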