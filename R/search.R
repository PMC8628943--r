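# End-to-end search pipeline: digest (target + reversed decoy), expand
# modifications, enumerate candidates per spectrum, fragment, match,
# score, aggregate per site, decide, estimate FDR, build the heat map.

derive_seed <- function(seed, i) {
  (as.integer(seed) + 7919L * as.integer(i)) %% 2147483647L
}

best_of_matches <- function(matches) {
  key <- vapply(matches, function(m) mean(c(m$pp, m$pp2, m$pp_tag)),
                numeric(1))
  matches[[order(-key, -vapply(matches, `[[`, 0, "pp"))[1]]]
}

#' Run a cross-link search
#'
#' The full pipeline over a protein database and a set of MS2 spectra.
#' Proteins are digested (together with their reversed-sequence decoys when
#' `decoy = TRUE`) with one extra allowed missed cleavage, since the
#' cross-linked lysine blocks cleavage at its own position and must not
#' consume the missed-cleavage budget. For each spectrum, candidate pairs
#' within the precursor tolerance are scored and the spectrum is assigned
#' to its single best-scoring candidate (rank-1 assignment; targets and
#' decoys compete for each spectrum); matches are aggregated per
#' (Q position, K position) site, keeping the best match per scan; sites
#' are accepted by the overall-score and spectral-count rule and q-values
#' estimated by target-decoy competition. Sites involving a decoy chain
#' (TD/DD) are retained for the FDR estimate but never flagged accepted:
#' in a target-decoy search, decoy hits are error calibration, not
#' identifications.
#'
#' @param proteins `data.frame` with `protein_id`/`sequence`, or a FASTA
#'   path.
#' @param spectra List of [spectrum()] objects, or an MGF path.
#' @param params An [search_params()].
#' @param seed Integer seed (drives the pp2 Monte-Carlo null per spectrum).
#' @param decoy Search the reversed sequences alongside the targets.
#' @param target_protein Protein id used for the heat map (default: first
#'   target protein).
#' @return An object of class `xl_results`: `sites` (data.frame, sorted by
#'   overall score), `site_objects`, `heatmap`, `params`, `seed`,
#'   `n_spectra`.
#' @export
run_search <- function(proteins, spectra, params = search_params(),
                       seed = 1L, decoy = TRUE, target_protein = NULL) {
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  if (is.character(spectra)) spectra <- read_mgf(spectra)
  rule <- protease_rule(suppress_before =
                          if (params$suppress_proline) "P" else character(0))
  records <- lapply(seq_len(nrow(proteins)), function(i) {
    list(protein_id = proteins$protein_id[i],
         sequence = toupper(proteins$sequence[i]), is_decoy = FALSE)
  })
  if (decoy) {
    records <- c(records, lapply(records, function(r)
      reverse_protein(r$sequence, r$protein_id)))
  }
  dp <- digest_params(params$max_missed_cleavages + 1L,
                      params$min_length, params$max_length)
  peps <- list()
  for (r in records) {
    peps <- c(peps, digest(r$sequence, r$protein_id, rule, dp,
                           is_decoy = r$is_decoy))
  }
  expanded <- list()
  for (p in peps)
    expanded <- c(expanded, expand_modifications(p, params))
  index <- pair_index(expanded, params, rule)

  # rank-1 assignment: each spectrum supports only its best-scoring
  # candidate pair (standard PSM practice; targets and decoys compete)
  matches <- list()
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    pm <- precursor_neutral_mass(s$precursor_mz, s$precursor_charge)
    pairs <- enumerate_pairs(expanded, pm, params, rule, index = index)
    if (!length(pairs)) next
    scored <- lapply(pairs, function(pr)
      score_match(s, pr, params, seed = derive_seed(seed, i)))
    matches[[length(matches) + 1L]] <- best_of_matches(scored)
  }

  # aggregate per site, best match per scan
  site_key <- vapply(matches, function(m)
    paste(m$pair$beta$protein_id, m$pair$beta$start + m$pair$q_pos - 1L,
          m$pair$alpha$protein_id, m$pair$alpha$start + m$pair$k_pos - 1L,
          sep = "|"), character(1))
  site_objects <- list()
  rows <- list()
  for (key in unique(site_key)) {
    ms <- matches[site_key == key]
    by_scan <- split(ms, vapply(ms, `[[`, "", "scan_id"))
    best <- lapply(by_scan, best_of_matches)
    m1 <- best[[1]]
    site <- site_result(
      q_protein = m1$pair$beta$protein_id,
      q_pos = m1$pair$beta$start + m1$pair$q_pos - 1L,
      k_protein = m1$pair$alpha$protein_id,
      k_pos = m1$pair$alpha$start + m1$pair$k_pos - 1L,
      spectra = best, decoy_class = m1$decoy_class)
    ov <- overall_score(site, params)
    n_pass <- length(passing_spectra(site, params))
    site_objects[[length(site_objects) + 1L]] <- site
    rows[[length(rows) + 1L]] <- data.frame(
      q_protein = site$q_protein, q_pos = site$q_pos,
      k_protein = site$k_protein, k_pos = site$k_pos,
      alpha_peptide = render_peptide(m1$pair$alpha, m1$pair$k_pos),
      beta_peptide = render_peptide(m1$pair$beta, m1$pair$q_pos),
      n_spectra = n_pass, n_spectra_total = length(best),
      overall = ov, decoy_class = site$decoy_class,
      # decoy-containing sites inform the FDR estimate but are never
      # reportable identifications
      accepted = decide(site, params) && site$decoy_class == "TT",
      stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else data.frame(
    q_protein = character(), q_pos = integer(), k_protein = character(),
    k_pos = integer(), alpha_peptide = character(),
    beta_peptide = character(), n_spectra = integer(),
    n_spectra_total = integer(), overall = numeric(),
    decoy_class = character(), accepted = logical(),
    stringsAsFactors = FALSE)
  sites$q_value <- compute_fdr(sites$overall, sites$decoy_class)
  if (nrow(sites)) {
    o <- order(-sites$overall, sites$q_pos, sites$k_pos)
    sites <- sites[o, , drop = FALSE]
    site_objects <- site_objects[o]
    rownames(sites) <- NULL
  }

  if (is.null(target_protein)) target_protein <- proteins$protein_id[1]
  tseq <- proteins$sequence[match(target_protein, proteins$protein_id)]
  hm <- NULL
  if (!is.na(tseq)) {
    res <- strsplit(toupper(tseq), "")[[1]]
    tsites <- sites[sites$q_protein == target_protein &
                      sites$k_protein == target_protein, , drop = FALSE]
    hm <- build_heatmap(which(res == "Q"), which(res == "K"), tsites)
  }
  structure(list(sites = sites, site_objects = site_objects, heatmap = hm,
                 params = params, seed = seed,
                 n_spectra = length(spectra)),
            class = "xl_results")
}

#' @export
print.xl_results <- function(x, ...) {
  cat(sprintf("<cross-link search results>  %d spectra, %d candidate sites, %d accepted\n",
              x$n_spectra, nrow(x$sites), sum(x$sites$accepted)))
  if (nrow(x$sites)) {
    show <- utils::head(x$sites[, c("q_protein", "q_pos", "k_pos",
                                    "alpha_peptide", "beta_peptide",
                                    "n_spectra", "overall", "q_value",
                                    "accepted")], 10)
    show$overall <- round(show$overall, 2)
    print(show)
  }
  invisible(x)
}
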