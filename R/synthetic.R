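# Seeded synthetic CID spectrum generator: stands in for deposited raw
# data so the whole pipeline is testable offline. Collision energy is
# abstracted as fragment coverage; no physical CID model is attempted.

#' Simulator parameters
#'
#' The stated world of the generator: `fragment_coverage` is the "collision
#' energy" knob (the fraction of theoretical fragments that appear as
#' peaks; over- or under-fragmentation shows up as low coverage),
#' `mz_jitter_sd` emulates ion-trap mass error (default 0.1 Da, well inside
#' the 0.8 Da matching tolerance), noise peaks are uniform over the
#' acquisition window with intensities drawn from the lower quartile of the
#' log-normal signal intensity model.
#'
#' @param fragment_coverage Fraction of theoretical fragments emitted.
#' @param noise_peaks Number of uniform random noise peaks.
#' @param mz_jitter_sd Gaussian m/z jitter SD (Da), clipped at `max_jitter`.
#' @param intensity_meanlog,intensity_sdlog Log-normal signal intensity
#'   parameters.
#' @param mz_range Acquisition window (Da).
#' @param seed RNG seed.
#' @param max_jitter Hard clip on jitter so peaks stay inside the matching
#'   tolerance used downstream.
#' @return An object of class `xl_sim_params`.
#' @export
sim_params <- function(fragment_coverage = 0.8, noise_peaks = 30L,
                       mz_jitter_sd = 0.1, intensity_meanlog = 10,
                       intensity_sdlog = 1, mz_range = c(150, 2000),
                       seed = 1L, max_jitter = 0.75) {
  if (fragment_coverage < 0 || fragment_coverage > 1)
    stop("fragment_coverage must be in [0, 1]", call. = FALSE)
  if (noise_peaks < 0 || mz_jitter_sd < 0)
    stop("invalid simulator parameters", call. = FALSE)
  structure(list(fragment_coverage = fragment_coverage,
                 noise_peaks = as.integer(noise_peaks),
                 mz_jitter_sd = mz_jitter_sd,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 mz_range = mz_range, seed = as.integer(seed),
                 max_jitter = max_jitter),
            class = "xl_sim_params")
}

#' Simulate one CID spectrum of a cross-linked pair
#'
#' Emits a seeded random subset of the predicted b/y fragments (fraction
#' `fragment_coverage`, charges `1..min(precursor_charge - 1, 3)`), each
#' with Gaussian m/z jitter and log-normal intensity, plus uniform noise
#' peaks over the acquisition window. Signal peaks are kept even when they
#' fall just outside the window, so the coverage-1/no-noise spectrum is
#' exactly the theoretical fragment list.
#'
#' @param pair An [crosslinked_pair()].
#' @param precursor_charge Precursor charge state.
#' @param params An [sim_params()].
#' @param scan_id Scan identifier for the spectrum.
#' @return An [spectrum()].
#' @export
simulate_spectrum <- function(pair, precursor_charge = 3L,
                              params = sim_params(),
                              scan_id = "synthetic_scan") {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  zmax <- max(1L, min(precursor_charge - 1L, 3L))
  frags <- predict_fragments(pair, zmax)
  keep <- stats::runif(nrow(frags)) < params$fragment_coverage
  fmz <- frags$mz[keep]
  if (length(fmz)) {
    jit <- stats::rnorm(length(fmz), 0, params$mz_jitter_sd)
    jit <- pmin(pmax(jit, -params$max_jitter), params$max_jitter)
    fmz <- fmz + jit
    fint <- stats::rlnorm(length(fmz), params$intensity_meanlog,
                          params$intensity_sdlog)
  } else fint <- numeric()
  if (params$noise_peaks > 0L) {
    nmz <- stats::runif(params$noise_peaks, params$mz_range[1],
                        params$mz_range[2])
    nint <- stats::qlnorm(stats::runif(params$noise_peaks, 0, 0.25),
                          params$intensity_meanlog, params$intensity_sdlog)
    fmz <- c(fmz, nmz); fint <- c(fint, nint)
  }
  spectrum(scan_id, mz(pair$neutral_mass, precursor_charge),
           precursor_charge, fmz, fint)
}

#' Generate a benchmark dataset with planted cross-links
#'
#' Digests the proteins, enumerates all distinct cross-linkable
#' (K position, Q position) site pairs, plants `n_sites` of them (seeded
#' sample) and emits `spectra_per_site` simulated spectra for each. Writes
#' the MGF peak list and a ground-truth TSV (one row per planted site).
#'
#' @param proteins `data.frame` with `protein_id`, `sequence`.
#' @param n_sites Number of distinct sites to plant.
#' @param spectra_per_site Spectra per planted site.
#' @param params An [sim_params()].
#' @param dparams An [digest_params()].
#' @param mgf_path,truth_path Optional output paths.
#' @param charge Precursor charge of the simulated spectra.
#' @return Invisibly, a list with `spectra` (list of [spectrum()]),
#'   `truth` (`data.frame`: protein/position bookkeeping plus scan ids) and
#'   `pairs` (the planted [crosslinked_pair()] objects).
#' @export
generate_benchmark <- function(proteins, n_sites, spectra_per_site,
                               params = sim_params(),
                               dparams = digest_params(),
                               mgf_path = NULL, truth_path = NULL,
                               charge = 3L) {
  sp <- search_params(max_missed_cleavages = dparams$max_missed_cleavages,
                      min_length = dparams$min_length,
                      max_length = dparams$max_length)
  cand <- list(); seen <- character()
  for (r in seq_len(nrow(proteins))) {
    peps <- digest(proteins$sequence[r], proteins$protein_id[r],
                   params = dparams)
    for (a in peps) {
      sa <- crosslinkable_sites(a)
      if (!length(sa$k)) next
      for (b in peps) {
        sb <- crosslinkable_sites(b)
        if (!length(sb$q)) next
        for (k in sa$k) for (q in sb$q) {
          key <- paste(proteins$protein_id[r], a$start + k - 1L,
                       b$start + q - 1L)
          if (key %in% seen) next
          seen <- c(seen, key)
          cand[[length(cand) + 1L]] <- list(alpha = a, beta = b,
                                            k = k, q = q)
        }
      }
    }
  }
  if (length(cand) < n_sites)
    stop("insufficient cross-linkable sites: need ", n_sites,
         ", found ", length(cand), call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  chosen <- if (n_sites > 0L) sample(length(cand), n_sites) else integer()
  spectra <- list(); rows <- list(); pairs <- list()
  for (si in seq_along(chosen)) {
    cc <- cand[[chosen[si]]]
    pair <- crosslinked_pair(cc$alpha, cc$beta, cc$k, cc$q)
    pairs[[si]] <- pair
    scan_ids <- character()
    for (s in seq_len(spectra_per_site)) {
      sid <- sprintf("site%d_scan%d", si, s)
      p_s <- params
      p_s$seed <- (params$seed + 104729L * si + s) %% 2147483647L
      spectra[[length(spectra) + 1L]] <-
        simulate_spectrum(pair, charge, p_s, scan_id = sid)
      scan_ids <- c(scan_ids, sid)
    }
    rows[[si]] <- data.frame(
      protein = cc$alpha$protein_id,
      q_pos = cc$beta$start + cc$q - 1L,
      k_pos = cc$alpha$start + cc$k - 1L,
      alpha_peptide = cc$alpha$sequence,
      beta_peptide = cc$beta$sequence,
      scan_ids = paste(scan_ids, collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), q_pos = integer(), k_pos = integer(),
               alpha_peptide = character(), beta_peptide = character(),
               scan_ids = character(), stringsAsFactors = FALSE)
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(spectra = spectra, truth = truth, pairs = pairs))
}

#' Synthetic collagen-alpha-1(I)-like sequence (stand-in, built in code)
#'
#' A glycine/proline-rich repeat sequence carrying the model tryptic
#' peptides EGGKGPR at residues 893-899 (K896) and SQDGGR at 1198-1203
#' (Q1199), so site coordinates match the collagen bookkeeping convention.
#' This is NOT the real Uniprot P11087 sequence; it is a synthetic stand-in
#' with the same two model peptides at the same coordinates, plus a few
#' additional K/Q residues in the filler so the heat map has competing
#' cells.
#'
#' @return List with `protein_id` and `sequence`.
#' @export
synthetic_collagen <- function() {
  block <- "GAPGAPGR"
  blocks <- rep(block, 111)
  blocks[50] <- "GAKGAPGR"   # extra (non-cross-linked) lysine
  blocks[70] <- "GAQGAPGR"   # extra glutamine
  prefix <- paste0(paste(blocks, collapse = ""), "GAGR")   # 892 residues
  mid <- paste0(paste(rep(block, 37), collapse = ""), "GR") # 298 residues
  seqn <- paste0(prefix, "EGGKGPR", mid, "SQDGGR",
                 paste(rep(block, 2), collapse = ""))
  list(protein_id = "synthetic_collagen_a1", sequence = seqn)
}

#' Deterministic synthetic protein with guaranteed cross-linkable sites
#'
#' Builds a protein from a pool of unique tryptic-peptide blocks. Every few
#' blocks an internal-lysine block or a glutamine block is included, so a
#' digest always yields multiple distinct cross-linkable (K, Q) site pairs
#' with unique peptide sequences (no ambiguous coordinates).
#'
#' @param length Target length in residues (default 400).
#' @param seed Seed controlling block shuffling.
#' @return List with `protein_id` and `sequence`.
#' @export
synthetic_protein <- function(length = 400L, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  aa_pool <- c("A", "G", "S", "L", "V", "T", "P", "D", "E", "F", "N", "I")
  blocks <- character(); total <- 0L; i <- 0L
  while (total < length) {
    i <- i + 1L
    body <- paste(sample(aa_pool, 5, replace = TRUE), collapse = "")
    blk <- if (i %% 3L == 1L) {
      paste0(body, "K", paste(sample(aa_pool, 1), collapse = ""), "R")
    } else if (i %% 3L == 2L) {
      paste0(substring(body, 1, 3), "Q", substring(body, 4, 5), "R")
    } else {
      paste0(body, sample(c("R", "K"), 1))
    }
    blocks <- c(blocks, blk)
    total <- total + nchar(blk)
  }
  seqn <- substring(paste(blocks, collapse = ""), 1, length)
  list(protein_id = sprintf("synthetic_protein_%d", seed), sequence = seqn)
}
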