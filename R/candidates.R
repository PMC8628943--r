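# Candidate generation: cross-linkable sites, variable-modification
# expansion, and precursor-mass-filtered pair enumeration.

#' Search parameters
#'
#' Defaults mirror standard cross-link search settings on an ion-trap CID
#' instrument: precursor tolerance +/-20 ppm, fragment tolerance +/-0.8 Da,
#' trypsin with at most 2 missed cleavages, peptide length 6-40, one
#' cross-link per peptide, per-spectrum score minima pp >= 5, pp2 >= 5,
#' pp_tag >= 1.3, site acceptance at overall >= 15 with >= 2 spectra.
#'
#' @param precursor_tol_ppm Precursor mass tolerance (+/- ppm).
#' @param fragment_tol_da Fragment m/z tolerance (+/- Da).
#' @param max_crosslinks_per_peptide Only 1 is supported.
#' @param fixed_modifications,variable_modifications Lists of
#'   [modification()] objects.
#' @param max_variable_mods Cap on simultaneous variable modifications per
#'   peptide.
#' @param max_missed_cleavages,min_length,max_length Digestion bounds.
#' @param allow_cterm_k Permit a C-terminal lysine as cross-link site
#'   (off by default: a cross-linked K blocks cleavage, so it is expected
#'   internal in an observed peptide).
#' @param suppress_proline Apply the no-cleavage-before-proline rule.
#' @param min_pp,min_pp2,min_pp_tag Per-spectrum score minima.
#' @param overall_threshold,min_spectra Site acceptance thresholds.
#' @param pp2_draws Monte-Carlo draws for the pp2 null.
#' @param mz_range Acquisition m/z window (Da), used by the random-match
#'   probability model.
#' @return An object of class `xl_search_params`.
#' @export
search_params <- function(precursor_tol_ppm = 20, fragment_tol_da = 0.8,
                          max_crosslinks_per_peptide = 1L,
                          fixed_modifications = list(),
                          variable_modifications = list(),
                          max_variable_mods = 2L,
                          max_missed_cleavages = 2L,
                          min_length = 6L, max_length = 40L,
                          allow_cterm_k = FALSE,
                          suppress_proline = TRUE,
                          min_pp = 5, min_pp2 = 5, min_pp_tag = 1.3,
                          overall_threshold = 15, min_spectra = 2L,
                          pp2_draws = 10000L,
                          mz_range = c(150, 2000)) {
  if (precursor_tol_ppm <= 0 || fragment_tol_da <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (max_crosslinks_per_peptide != 1L)
    stop("only max_crosslinks_per_peptide = 1 is supported", call. = FALSE)
  structure(list(
    precursor_tol_ppm = precursor_tol_ppm,
    fragment_tol_da = fragment_tol_da,
    max_crosslinks_per_peptide = 1L,
    fixed_modifications = fixed_modifications,
    variable_modifications = variable_modifications,
    max_variable_mods = as.integer(max_variable_mods),
    max_missed_cleavages = as.integer(max_missed_cleavages),
    min_length = as.integer(min_length),
    max_length = as.integer(max_length),
    allow_cterm_k = isTRUE(allow_cterm_k),
    suppress_proline = isTRUE(suppress_proline),
    min_pp = min_pp, min_pp2 = min_pp2, min_pp_tag = min_pp_tag,
    overall_threshold = overall_threshold,
    min_spectra = as.integer(min_spectra),
    pp2_draws = as.integer(pp2_draws),
    mz_range = mz_range
  ), class = "xl_search_params")
}

#' Cross-linkable K and Q positions of a peptide
#'
#' K sites exclude the C-terminal residue by default (a cross-linked lysine
#' cannot be cleaved, so an observed cross-linked peptide carries it
#' internally). Q sites exclude deamidated glutamines: deamidation and
#' cross-linking both consume the same side-chain amide.
#'
#' @param p An [peptide()].
#' @param allow_cterm_k Permit the C-terminal K as a site.
#' @return List with integer vectors `k` and `q` (1-based positions).
#' @export
#' @examples
#' crosslinkable_sites(peptide("EGGKGPR"))
crosslinkable_sites <- function(p, allow_cterm_k = FALSE) {
  p <- as_peptide(p)
  res <- strsplit(p$sequence, "")[[1]]
  n <- length(res)
  k <- which(res == "K")
  if (!allow_cterm_k) k <- k[k < n]
  q <- which(res == "Q")
  if (nrow(p$mods)) {
    deam <- p$mods$pos[p$mods$name == "deamidation"]
    q <- setdiff(q, deam)
  }
  list(k = k, q = q)
}

#' Expand a peptide into its modification variants
#'
#' Fixed modifications are applied at every eligible residue in all
#' variants. Variable modifications are expanded combinatorially over their
#' eligible sites, up to `max_variable_mods` simultaneous modifications; the
#' fully unmodified (fixed-only) variant is always included.
#'
#' @param p An [peptide()].
#' @param params An [search_params()] carrying the modification lists.
#' @return List of `xl_peptide` variants (the input is variant 1).
#' @export
expand_modifications <- function(p, params) {
  p <- as_peptide(p)
  res <- strsplit(p$sequence, "")[[1]]
  fixed <- empty_mods()
  for (m in params$fixed_modifications) {
    at <- which(res == m$target)
    if (length(at))
      fixed <- rbind(fixed, data.frame(pos = at, name = m$name,
                                       delta = m$delta_mass,
                                       stringsAsFactors = FALSE))
  }
  var_sites <- list()
  for (m in params$variable_modifications) {
    at <- which(res == m$target)
    for (a in at)
      var_sites[[length(var_sites) + 1L]] <-
        list(pos = a, name = m$name, delta = m$delta_mass)
  }
  make_variant <- function(var_subset) {
    mods <- fixed
    for (v in var_subset)
      mods <- rbind(mods, data.frame(pos = v$pos, name = v$name,
                                     delta = v$delta, stringsAsFactors = FALSE))
    if (nrow(mods)) mods <- mods[order(mods$pos), , drop = FALSE]
    peptide(p$sequence, p$protein_id, p$start, p$missed_cleavages,
            mods = mods, is_decoy = p$is_decoy)
  }
  out <- list(make_variant(list()))
  nmax <- min(params$max_variable_mods, length(var_sites))
  if (nmax >= 1L && length(var_sites)) {
    for (k in seq_len(nmax)) {
      combos <- utils::combn(length(var_sites), k, simplify = FALSE)
      for (cmb in combos) {
        sel <- var_sites[cmb]
        if (anyDuplicated(vapply(sel, `[[`, 0L, "pos"))) next
        out[[length(out) + 1L]] <- make_variant(sel)
      }
    }
  }
  out
}

# Raw missed-cleavage count minus the cross-linked-K site, when that K is
# itself a cleavable position: the cross-link blocks cleavage there, so it
# must not consume the missed-cleavage budget.
effective_missed_cleavages <- function(p, k_pos, rule = protease_rule()) {
  n <- nchar(p$sequence)
  m <- p$missed_cleavages
  if (k_pos < n && "K" %in% rule$cleave_after) {
    nxt <- substring(p$sequence, k_pos + 1L, k_pos + 1L)
    if (!(nxt %in% rule$suppress_before)) m <- m - 1L
  }
  max(m, 0L)
}

mod_signature <- function(p) {
  if (!nrow(p$mods)) return("")
  paste(sprintf("%d:%s", p$mods$pos, p$mods$name), collapse = ",")
}

pair_key <- function(alpha, k_pos, beta, q_pos) {
  paste(alpha$protein_id, alpha$start, alpha$end, mod_signature(alpha), k_pos,
        beta$protein_id, beta$start, beta$end, mod_signature(beta), q_pos,
        sep = "|")
}

# Precompute per-peptide masses and site lists so pair enumeration over
# many spectra does not redo O(n) work each time.
pair_index <- function(peptides, params, rule = protease_rule()) {
  masses <- vapply(peptides, peptide_mass, numeric(1))
  k_pep <- integer(); k_pos <- integer()
  q_pep <- integer(); q_pos <- integer()
  for (i in seq_along(peptides)) {
    s <- crosslinkable_sites(peptides[[i]], params$allow_cterm_k)
    for (k in s$k) {
      if (effective_missed_cleavages(peptides[[i]], k, rule) >
          params$max_missed_cleavages) next
      k_pep <- c(k_pep, i); k_pos <- c(k_pos, k)
    }
    if (peptides[[i]]$missed_cleavages <= params$max_missed_cleavages) {
      for (q in s$q) { q_pep <- c(q_pep, i); q_pos <- c(q_pos, q) }
    }
  }
  list(peptides = peptides, masses = masses,
       k_pep = k_pep, k_pos = k_pos, q_pep = q_pep, q_pos = q_pos)
}

#' Enumerate cross-linked candidate pairs for a precursor mass
#'
#' All (K-donor peptide, Q-donor peptide, site) combinations whose
#' cross-linked neutral mass lies within the precursor tolerance. Pairs are
#' deduplicated and labelled `TT`, `TD` or `DD` by the decoy flags of their
#' chains. The missed cleavage at the cross-linked K does not count toward
#' the missed-cleavage budget (the cross-link blocks cleavage there), so
#' feed this function peptides digested with one extra allowed missed
#' cleavage.
#'
#' @param peptides List of (modification-expanded) [peptide()] objects.
#' @param precursor_neutral_mass Observed precursor neutral mass (Da).
#' @param params An [search_params()].
#' @param rule Protease rule used for the missed-cleavage accounting.
#' @param index Optional precomputed index (internal; for repeated calls).
#' @return List of [crosslinked_pair()] objects.
#' @export
enumerate_pairs <- function(peptides, precursor_neutral_mass, params,
                            rule = protease_rule(), index = NULL) {
  if (!length(peptides)) return(list())
  if (is.null(index)) index <- pair_index(peptides, params, rule)
  tol <- params$precursor_tol_ppm * 1e-6 * precursor_neutral_mass
  out <- list()
  seen <- character()
  if (!length(index$k_pep) || !length(index$q_pep)) return(out)
  q_masses <- index$masses[index$q_pep]
  for (ii in seq_along(index$k_pep)) {
    i <- index$k_pep[ii]
    target <- precursor_neutral_mass - index$masses[i] + MASS_AMMONIA
    hits <- which(abs(q_masses - target) <= tol)
    for (jj in hits) {
      j <- index$q_pep[jj]
      a <- index$peptides[[i]]; b <- index$peptides[[j]]
      key <- pair_key(a, index$k_pos[ii], b, index$q_pos[jj])
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <-
        crosslinked_pair(a, b, index$k_pos[ii], index$q_pos[jj])
    }
  }
  out
}

#' Neutral precursor mass from an MGF-style precursor record
#'
#' @param pepmass Precursor m/z as recorded (PEPMASS).
#' @param charge Precursor charge.
#' @return `pepmass * charge - charge * proton` (Da).
#' @export
precursor_neutral_mass <- function(pepmass, charge) {
  charge <- as.integer(charge)
  if (any(charge < 1L)) stop("invalid charge", call. = FALSE)
  pepmass * charge - charge * MASS_PROTON
}
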