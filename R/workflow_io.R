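## Run configuration, annotated table I/O, and the stage drivers that bind
## the pipeline together (simulate | digest | search | quant | report).
## A thin command-line wrapper over these drivers ships in inst/cli/.

.pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("hgmod")),
           error = function(e) "dev")
}

#' Hash a configuration object
#'
#' @param x Any JSON-serializable object.
#' @return MD5 hex digest of its canonical JSON form.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Write a result table with a provenance header
#'
#' The first line is a comment naming the producing package version and the
#' configuration hash; [read_result_table()] skips it.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config Configuration object hashed into the header (optional).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, config = NULL) {
  hash <- if (is.null(config)) "none" else config_hash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hgmod %s config=%s", .pkg_version(), hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read an abundance matrix as a pair of TSV files
#'
#' `<prefix>_areas.tsv` holds the peptide-by-sample areas (first column
#' `peptide`), `<prefix>_samples.tsv` the sample metadata sidecar.
#'
#' @param am An [abundance_matrix()].
#' @param prefix Path prefix.
#' @param config Optional configuration for the provenance header.
#' @return The prefix, invisibly (writer); an `abundance_matrix` (reader).
#' @export
write_abundance <- function(am, prefix, config = NULL) {
  areas <- data.frame(peptide = rownames(am$areas), am$areas,
                      check.names = FALSE)
  write_result_table(areas, paste0(prefix, "_areas.tsv"), config)
  write_result_table(am$samples, paste0(prefix, "_samples.tsv"), config)
  invisible(prefix)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(prefix) {
  areas <- read_result_table(paste0(prefix, "_areas.tsv"))
  smp <- read_result_table(paste0(prefix, "_samples.tsv"))
  m <- as.matrix(areas[, -1, drop = FALSE])
  rownames(m) <- areas$peptide
  colnames(m) <- smp$sample
  abundance_matrix(m, smp)
}

#' Write a peptide digest table
#'
#' @param peptides Digest data frame from [cleave()]/[sequential_digest()].
#' @param path Output path.
#' @param config Optional configuration for the header.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path, config = NULL) {
  write_result_table(peptides, path, config)
}

#' Flatten PSMs into a table
#'
#' @param psms List of `psm` objects (localization and neutral-loss flags
#'   included when present).
#' @return One row per PSM.
#' @export
psm_table <- function(psms) {
  do.call(rbind, lapply(psms, function(p) {
    loc <- p$localization
    nlA <- p$nl_flags$A
    nlB <- p$nl_flags$B
    data.frame(
      spectrum_id = p$spectrum_id,
      sequence = p$peptide$sequence,
      mod_site = if (length(p$peptide$mods) > 0) p$peptide$mods[[1]]$site
                 else NA_integer_,
      match_score = p$match_score,
      matched_ion_count = p$matched_ion_count,
      rt = p$rt,
      precursor_neutral = p$precursor_neutral,
      best_site = if (!is.null(loc)) loc$best_site else NA_integer_,
      delta_score = if (!is.null(loc)) loc$delta_score else NA_real_,
      nl_A_observed = if (!is.null(nlA))
        nlA$precursor_observed || nlA$fragment_observed else NA,
      nl_A_rel = if (!is.null(nlA)) nlA$relative_abundance else NA_real_,
      nl_B_observed = if (!is.null(nlB))
        nlB$precursor_observed || nlB$fragment_observed else NA,
      nl_B_rel = if (!is.null(nlB)) nlB$relative_abundance else NA_real_)
  }))
}

#' Simulate a dataset bundle to disk
#'
#' Writes FASTA proteome, digest table, ground-truth ledger, abundance
#' tables, light and heavy MGF files, and the serialized configuration.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param n_planted Optional planted-peptide count.
#' @return Named list of file paths, invisibly.
#' @export
run_simulate <- function(config, outdir, n_planted = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config, n_planted = n_planted)
  paths <- list(
    fasta = file.path(outdir, "proteome.fasta"),
    peptides = file.path(outdir, "peptides.tsv"),
    ledger = file.path(outdir, "ground_truth_ledger.tsv"),
    abundance = file.path(outdir, "abundance"),
    mgf_light = file.path(outdir, "spectra_light.mgf"),
    mgf_heavy = file.path(outdir, "spectra_heavy.mgf"),
    config = file.path(outdir, "sim_config.json")
  )
  write_fasta(study$proteome, paths$fasta)
  write_peptide_table(study$peptides, paths$peptides, config)
  write_result_table(study$ledger, paths$ledger, config)
  write_abundance(study$abundances, paths$abundance, config)
  write_mgf(simulate_spectra(study$ledger, config, heavy = FALSE),
            paths$mgf_light)
  write_mgf(simulate_spectra(study$ledger, config, heavy = TRUE),
            paths$mgf_heavy)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Digest a FASTA file to a peptide table
#'
#' @param fasta Input FASTA path.
#' @param out Output TSV path.
#' @param rules,max_missed As in [sequential_digest()].
#' @return The digest data frame, invisibly.
#' @export
run_digest <- function(fasta, out, rules = list(trypsin(), gluc()),
                       max_missed = c(2L, 2L)) {
  proteome <- read_fasta(fasta)
  peptides <- digest_proteome(proteome, rules, max_missed)
  write_peptide_table(peptides, out,
                      config = list(rules = vapply(rules, `[[`, "", "name"),
                                    max_missed = max_missed))
  invisible(peptides)
}

#' Search an MGF file against candidate modified peptides
#'
#' Builds candidates by placing one 2HG modification on every S/T/Y of
#' every digest peptide (plus the unmodified form), then matches,
#' localizes, and runs neutral-loss detection per spectrum.
#'
#' @param mgf MGF path.
#' @param peptides Digest data frame or path to a peptide table.
#' @param out Output PSM table path.
#' @param tol_ppm,precursor_tol_ppm Tolerances (ppm).
#' @param heavy Search with d4 adduct masses.
#' @return List of `psm` objects, invisibly.
#' @export
run_search <- function(mgf, peptides, out = NULL, tol_ppm = 10,
                       precursor_tol_ppm = 20, heavy = FALSE) {
  if (is.character(peptides)) peptides <- read_result_table(peptides)
  spectra <- read_mgf(mgf)
  specmod <- mod_2hg()
  seqs <- unique(peptides$sequence)
  cand <- list()
  for (s in seqs) {
    cand[[length(cand) + 1L]] <- peptide(s)
    for (site in which(strsplit(s, "")[[1]] %in% specmod$targets)) {
      cand[[length(cand) + 1L]] <-
        peptide(s, mods = list(list(site = site, spec = specmod)))
    }
  }
  masses <- vapply(cand, peptide_neutral_mass, numeric(1), heavy = heavy)
  ord <- order(masses)
  cand <- cand[ord]
  masses <- masses[ord]
  psms <- list()
  for (sp in spectra) {
    obs <- neutral_mass(sp$precursor_mz, sp$precursor_charge)
    tol <- obs * precursor_tol_ppm * 1e-6
    lo <- findInterval(obs - tol, masses) + 1L
    hi <- findInterval(obs + tol, masses)
    if (hi < lo) next
    res <- match_spectrum(sp, cand[lo:hi], tol_ppm = tol_ppm,
                          precursor_tol_ppm = precursor_tol_ppm,
                          heavy = heavy)
    if (is.null(res$best)) next
    p <- res$best
    if (length(p$peptide$mods) > 0) {
      p <- localize_site(p, sp, tol_ppm = tol_ppm)
      p <- detect_neutral_loss(p, sp, tol_ppm = tol_ppm, heavy = heavy)
    }
    psms[[length(psms) + 1L]] <- p
  }
  if (!is.null(out) && length(psms) > 0) {
    write_result_table(psm_table(psms), out,
                       config = list(tol_ppm = tol_ppm,
                                     precursor_tol_ppm = precursor_tol_ppm,
                                     heavy = heavy))
  }
  invisible(psms)
}

#' Quantify and call chirality from abundance tables
#'
#' TIC-normalizes, runs the dose-response classifier for both enantiomer
#' series, and writes call and evidence tables.
#'
#' @param prefix Abundance table prefix (see [write_abundance()]).
#' @param outdir Output directory.
#' @param ... Passed to [chirality_call()].
#' @return The [chirality_call()] result, invisibly.
#' @export
run_quant <- function(prefix, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  am <- tic_normalize(read_abundance(prefix))
  res <- chirality_call(am, ...)
  cfg <- list(stage = "quant", args = list(...))
  write_result_table(res$calls, file.path(outdir, "chirality_calls.tsv"), cfg)
  write_result_table(res$evidence, file.path(outdir, "chirality_evidence.tsv"),
                     cfg)
  invisible(res)
}

#' Summary report across pipeline outputs
#'
#' Aggregates neutral-loss frequency bins, the paired RT shift test, and
#' (when a ground-truth ledger is supplied, e.g. in validation runs)
#' recovery of planted enantiomer assignments.
#'
#' @param psms List of `psm` objects with NL flags (or NULL).
#' @param calls `calls` data frame from [chirality_call()] (or NULL).
#' @param rt_pairs Data frame with columns `rt_modified`, `rt_unmodified`
#'   (or NULL).
#' @param ledger Ground-truth ledger (or NULL).
#' @return A list summary; also printed.
#' @export
run_report <- function(psms = NULL, calls = NULL, rt_pairs = NULL,
                       ledger = NULL) {
  out <- list()
  if (!is.null(psms) && length(psms) > 0) {
    modded <- Filter(function(p) !is.null(p$nl_flags), psms)
    if (length(modded) > 0) out$nl_frequency <- nl_frequency_summary(modded)
  }
  if (!is.null(rt_pairs) && nrow(rt_pairs) >= 3) {
    out$rt_shift <- paired_rt_test(rt_pairs$rt_modified,
                                   rt_pairs$rt_unmodified)
  }
  if (!is.null(calls) && !is.null(ledger)) {
    merged <- merge(ledger, calls, by.x = "peptide_id", by.y = "peptide")
    tab <- table(truth = merged$enantiomer, call = merged$call)
    recov <- function(e) {
      n <- sum(merged$enantiomer == e)
      if (n == 0) NA_real_ else sum(merged$enantiomer == e &
                                      merged$call == e) / n
    }
    out$recovery <- list(table = tab, d_recovery = recov("D"),
                         l_recovery = recov("L"))
  }
  out
}
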