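# Readers/writers: FASTA (via Biostrings), MGF peak lists, results and
# heat-map TSV, JSON config and run manifests.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return `data.frame` with columns `protein_id` (first whitespace token of
#'   the description), `description`, `sequence` (uppercased, `*` stripped
#'   with a warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(protein_id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  if (any(grepl("\\*", seqs))) {
    warning("stop character '*' stripped from sequence(s)")
    seqs <- gsub("\\*", "", seqs)
  }
  data.frame(
    protein_id = sub("\\s.*$", "", names(aa)),
    description = unname(names(aa)),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' Write protein sequences to FASTA
#'
#' @param proteins `data.frame` with `protein_id` and `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  lines <- character()
  for (i in seq_len(nrow(proteins))) {
    lines <- c(lines, paste0(">", proteins$protein_id[i]),
               gsub("(.{60})", "\\1\n", proteins$sequence[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_mgf_charge <- function(x) {
  # accepted dialects: "2+", "+2", "2"
  x <- trimws(x)
  if (grepl("^\\+?[0-9]+\\+?$", x)) as.integer(gsub("\\+", "", x)) else NA_integer_
}

#' Read MS2 spectra from an MGF peak list
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS` and `CHARGE`
#' headers. Records without a parseable charge are skipped with a warning
#' (a cross-link search needs the precursor charge to derive the neutral
#' mass). Peaks are sorted by m/z.
#'
#' @param path MGF file.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  i <- 1L; n <- length(lines); block <- 0L
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    block <- block + 1L
    title <- paste0("scan_", block); pepmass <- NA_real_
    charge <- NA_integer_; pmz <- numeric(); pint <- numeric()
    i <- i + 1L
    while (i <= n && trimws(lines[i]) != "END IONS") {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^PEPMASS=", ln)) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
      } else if (grepl("^CHARGE=", ln)) {
        charge <- parse_mgf_charge(sub("^CHARGE=", "", ln))
      } else if (grepl("^[A-Z_]+=", ln)) {
        # other headers ignored
      } else {
        tok <- strsplit(ln, "[\t ]+")[[1]]
        v <- suppressWarnings(as.numeric(tok))
        if (length(v) < 2L || anyNA(v[1:2]))
          stop("malformed peak line in ", path, ": '", ln, "'", call. = FALSE)
        pmz <- c(pmz, v[1]); pint <- c(pint, v[2])
      }
      i <- i + 1L
    }
    i <- i + 1L
    if (is.na(charge)) {
      warning("spectrum '", title, "' skipped: missing/unparseable CHARGE")
      next
    }
    out[[length(out) + 1L]] <- spectrum(title, pepmass, charge, pmz, pint)
  }
  out
}

#' Write spectra to MGF
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$scan_id),
                 sprintf("PEPMASS=%.5f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$precursor_charge),
                 sprintf("%.5f %.4f", s$peaks$mz, s$peaks$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Render a peptide sequence with cross-link and modification markers
#'
#' The cross-linked residue is followed by `$1`; oxidized methionine is
#' rendered `oxM` and deamidated glutamine `deQ`. Fixed carbamidomethyl
#' cysteine is left unmarked.
#'
#' @param p An [peptide()].
#' @param xl_pos 1-based position of the cross-linked residue, or `NA`.
#' @return Annotated sequence string, e.g. `"EGGK$1GPR"`.
#' @export
render_peptide <- function(p, xl_pos = NA) {
  res <- strsplit(p$sequence, "")[[1]]
  if (nrow(p$mods)) {
    for (i in seq_len(nrow(p$mods))) {
      pre <- switch(p$mods$name[i], oxidation = "ox", deamidation = "de", "")
      res[p$mods$pos[i]] <- paste0(pre, res[p$mods$pos[i]])
    }
  }
  if (!is.na(xl_pos)) res[xl_pos] <- paste0(res[xl_pos], "$1")
  paste(res, collapse = "")
}

#' Write site results to TSV
#'
#' One row per site with protein coordinates, annotated chain sequences,
#' spectral counts, overall score, q-value and the acceptance flag.
#'
#' @param sites Site `data.frame` (as in `xl_results$sites`).
#' @param path Output path.
#' @export
write_results <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a site results TSV back
#' @param path Results file written by [write_results()].
#' @return `data.frame`.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the Q x K heat-map matrix as dense TSV
#'
#' @param heatmap Matrix from [build_heatmap()].
#' @param path Output path.
#' @export
write_heatmap <- function(heatmap, path) {
  d <- data.frame(q = rownames(heatmap), heatmap, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records inputs, configuration and seed so any result file can be traced
#' to the run that produced it and reproduced exactly.
#'
#' @param inputs Named list/character of input file paths.
#' @param config Configuration list (serializable fields only).
#' @param seed Integer seed of the run.
#' @param timestamp Stored for audit; excluded from determinism claims.
#' @return Manifest list.
#' @export
run_manifest <- function(inputs, config, seed,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  list(tool = "isoxlink",
       version = as.character(utils::packageVersion("isoxlink")),
       inputs = inputs, config = config, seed = seed,
       timestamp = timestamp)
}

#' Write a manifest as JSON
#' @param manifest From [run_manifest()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$config <- manifest$config[!vapply(manifest$config, is.function,
                                             logical(1))]
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Read a JSON configuration file
#'
#' Known keys override [search_params()] / simulator defaults; flags given
#' on the command line override the file.
#'
#' @param path JSON file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
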