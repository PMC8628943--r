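# In silico protease digestion with missed cleavages, reversed-sequence
# decoys, and model cross-link pair design.

#' Define a protease cleavage rule
#'
#' @param name Protease name.
#' @param cleave_after Residues after which the backbone is cleaved.
#' @param suppress_before Residues that suppress cleavage when they follow
#'   the site (classically proline for trypsin). Use `character(0)` to
#'   disable suppression.
#' @return An object of class `xl_protease`.
#' @export
protease_rule <- function(name = "trypsin", cleave_after = c("K", "R"),
                          suppress_before = "P") {
  if (length(cleave_after) == 0L)
    stop("cleave_after must be non-empty", call. = FALSE)
  structure(list(name = name, cleave_after = cleave_after,
                 suppress_before = suppress_before),
            class = "xl_protease")
}

#' Digestion parameters
#'
#' Defaults follow standard cross-link search settings: at most 2 missed
#' cleavages, peptide length 6-40 residues.
#'
#' @param max_missed_cleavages Maximum internal uncleaved sites per peptide.
#' @param min_length,max_length Peptide length bounds (residues).
#' @return An object of class `xl_digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 2L, min_length = 6L,
                          max_length = 40L) {
  if (max_missed_cleavages < 0L || min_length < 1L || min_length > max_length)
    stop("invalid digestion parameters", call. = FALSE)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "xl_digest_params")
}

# Positions i such that the bond after residue i is cleaved.
cleavage_positions <- function(sequence, rule) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) return(integer())
  i <- which(res[-n] %in% rule$cleave_after)
  if (length(rule$suppress_before))
    i <- i[!(res[i + 1L] %in% rule$suppress_before)]
  i
}

#' Digest a protein sequence in silico
#'
#' Fully specific digestion: every returned peptide runs between two
#' cleavage boundaries (or a protein terminus) and contains at most
#' `max_missed_cleavages` internal uncleaved sites. Trypsin cleaves after
#' K/R but not before P.
#'
#' @param sequence Protein sequence string.
#' @param protein_id Identifier carried into peptide provenance.
#' @param rule A [protease_rule()].
#' @param params A [digest_params()].
#' @param is_decoy Flag propagated to every peptide.
#' @return List of [peptide()] objects, ordered by start then length.
#' @export
#' @examples
#' digest("AKRPGK", "p1", params = digest_params(0, 1, 40))
digest <- function(sequence, protein_id = "", rule = protease_rule(),
                   params = digest_params(), is_decoy = FALSE) {
  sequence <- toupper(sequence)
  assert_sequence(sequence)
  n <- nchar(sequence)
  bounds <- c(0L, cleavage_positions(sequence, rule), n)
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    for (m in 0:params$max_missed_cleavages) {
      j <- i + 1L + m
      if (j > nb) break
      s <- bounds[i] + 1L
      e <- bounds[j]
      len <- e - s + 1L
      if (len < params$min_length || len > params$max_length) next
      out[[length(out) + 1L]] <- peptide(
        substring(sequence, s, e), protein_id, start = s,
        missed_cleavages = m, is_decoy = is_decoy)
    }
  }
  out
}

#' Reverse a protein sequence to build a decoy record
#'
#' @param sequence Protein sequence.
#' @param protein_id Original identifier; the decoy id is prefixed.
#' @param decoy_prefix Marker prepended to the id.
#' @return List with `protein_id`, `sequence`, `is_decoy = TRUE`.
#' @export
reverse_protein <- function(sequence, protein_id, decoy_prefix = "rev_") {
  sequence <- toupper(sequence)
  assert_sequence(sequence)
  list(protein_id = paste0(decoy_prefix, protein_id),
       sequence = paste(rev(strsplit(sequence, "")[[1]]), collapse = ""),
       is_decoy = TRUE)
}

#' Kyte-Doolittle hydropathy values
#' @keywords internal
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Mean Kyte-Doolittle hydropathy of a sequence
#'
#' Negative values are hydrophilic; used as the solubility screen when
#' selecting model peptides for enzymatic cross-link synthesis.
#'
#' @param sequence Residue string.
#' @return Mean hydropathy (GRAVY score).
#' @export
#' @examples
#' hydropathy("EGGKGPR")  # -2.1
hydropathy <- function(sequence) {
  assert_sequence(toupper(sequence))
  mean(KYTE_DOOLITTLE[strsplit(toupper(sequence), "")[[1]]])
}

#' Design candidate model peptide pairs for cross-link synthesis
#'
#' Screens the tryptic peptides of a protein for pairs suitable as a
#' synthetic cross-link standard: (i) C-terminal arginine on both chains (a
#' C-terminal lysine would side-react during enzymatic cross-linking),
#' (ii) short sequences for clean chromatographic behaviour, and (iii)
#' hydrophilicity sufficient for aqueous solubility. One chain must carry a
#' non-C-terminal lysine (the amine donor), the other a glutamine (the
#' amide donor).
#'
#' @param sequence Protein sequence to screen.
#' @param protein_id Identifier for provenance.
#' @param rule,params Digestion settings; missed cleavages must allow the
#'   internal-K peptide (its K is an uncleaved site).
#' @param max_len Maximum chain length (default 10).
#' @param hydropathy_threshold Maximum mean Kyte-Doolittle hydropathy
#'   (default 0, i.e. net hydrophilic).
#' @return `data.frame` with one row per candidate (K-peptide, Q-peptide)
#'   pair: sequences, protein coordinates of the K and Q sites, and the two
#'   hydropathy values. Zero rows when nothing qualifies.
#' @export
design_model_pairs <- function(sequence, protein_id = "",
                               rule = protease_rule(),
                               params = digest_params(),
                               max_len = 10L, hydropathy_threshold = 0) {
  peps <- digest(sequence, protein_id, rule, params)
  ok <- vapply(peps, function(p) {
    nchar(p$sequence) <= max_len &&
      substring(p$sequence, nchar(p$sequence)) == "R" &&
      hydropathy(p$sequence) <= hydropathy_threshold
  }, logical(1))
  peps <- peps[ok]
  k_peps <- Filter(function(p) {
    ks <- gregexpr("K", p$sequence)[[1]]
    any(ks > 0 & ks < nchar(p$sequence))
  }, peps)
  q_peps <- Filter(function(p) grepl("Q", p$sequence), peps)
  rows <- list()
  for (kp in k_peps) for (qp in q_peps) {
    if (kp$start == qp$start && kp$end == qp$end) next
    rows[[length(rows) + 1L]] <- data.frame(
      k_peptide = kp$sequence, k_start = kp$start, k_end = kp$end,
      q_peptide = qp$sequence, q_start = qp$start, q_end = qp$end,
      k_hydropathy = hydropathy(kp$sequence),
      q_hydropathy = hydropathy(qp$sequence),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(k_peptide = character(), k_start = integer(),
                      k_end = integer(), q_peptide = character(),
                      q_start = integer(), q_end = integer(),
                      k_hydropathy = numeric(), q_hydropathy = numeric(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}
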