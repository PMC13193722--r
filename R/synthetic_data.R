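## Seeded generator of synthetic proteomes, planted 2HG modifications,
## dose-response abundance matrices, and MS/MS spectra (light/heavy), with
## the statistical structure the analysis assumes. Ground truth lives in a
## separate ledger that analysis stages never see.

# Approximate vertebrate proteome residue frequencies (renormalized).
.AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, E = 0.071,
  Q = 0.048, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057,
  M = 0.021, F = 0.036, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
  Y = 0.027, V = 0.060
)

# Kyte-Doolittle hydropathy index, used by the surrogate RT model.
.KD_INDEX <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Run code under a stage-specific seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.stage_seed <- function(seed, stage) (as.integer(seed) %% 20000000L) * 100L + stage

#' Simulation configuration
#'
#' Defaults define the emulated study conditions: three biological
#' replicates per group, dose gradients 0/5/10/20 (arbitrary units
#' mirroring mM) for each enantiomer against a shared vehicle, an
#' S>T>Y site distribution (0.6/0.3/0.1), lognormal replicate noise at
#' CV 0.15, 20% spurious MS/MS peaks with intensity jitter CV 0.2, and a
#' positive retention-time shift for modified peptides. Planted top-dose
#' fold changes are drawn from Uniform(2, 4), the magnitude range shown by
#' responsive peptides in dose-gradient treatments.
#'
#' @param seed Integer seed; the same config + seed is byte-reproducible.
#' @param n_proteins,protein_length Proteome size and length range.
#' @param site_weights Sampling weights for S/T/Y modification sites.
#' @param fraction_modified Fraction of eligible peptides planted.
#' @param enantiomer_probs Probabilities of D / L / shared assignment.
#' @param dose_levels Dose series (first must be 0 = vehicle).
#' @param n_replicates Replicates per condition.
#' @param fc_range Range of true top-dose fold changes.
#' @param abundance_cv Lognormal replicate CV.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline areas.
#' @param baseline_occupancy Modified-row baseline as a fraction of the
#'   modified + unmodified total.
#' @param n_background Unmodified, unresponsive background peptide rows
#'   included in the abundance matrix; keeps the total ion current
#'   dominated by bulk signal, as in real label-free runs.
#' @param spurious_peak_fraction Spurious MS/MS peaks per real peak.
#' @param intensity_jitter_cv Fragment intensity jitter CV.
#' @param nl_probability Per-channel neutral-loss emission probability.
#' @param nl_abundance_range Relative abundance range of emitted losses
#'   (fraction of base peak).
#' @param rt_range Gradient window in minutes.
#' @param rt_mod_shift Positive RT shift for modified peptides (minutes).
#' @param rt_noise_sd RT noise SD (minutes).
#' @param precursor_charge,fragment_charges Charges used for spectra.
#' @param max_missed Missed cleavages per protease in the digest.
#' @param peptide_length_range Eligible peptide lengths for planting.
#' @return A `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 40L,
                       protein_length = c(200L, 400L),
                       site_weights = c(S = 0.6, T = 0.3, Y = 0.1),
                       fraction_modified = 0.2,
                       enantiomer_probs = c(D = 0.45, L = 0.45, shared = 0.10),
                       dose_levels = c(0, 5, 10, 20),
                       n_replicates = 3L,
                       fc_range = c(2, 4),
                       abundance_cv = 0.15,
                       baseline_meanlog = log(1e6),
                       baseline_sdlog = 0.6,
                       baseline_occupancy = 0.12,
                       n_background = 800L,
                       spurious_peak_fraction = 0.2,
                       intensity_jitter_cv = 0.2,
                       nl_probability = c(A = 0.95, B = 0.85),
                       nl_abundance_range = c(0.005, 0.15),
                       rt_range = c(10, 90),
                       rt_mod_shift = 1.5,
                       rt_noise_sd = 0.2,
                       precursor_charge = 2L,
                       fragment_charges = 1L,
                       max_missed = c(1L, 1L),
                       peptide_length_range = c(7L, 25L)) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              protein_length = as.integer(protein_length),
              site_weights = site_weights,
              fraction_modified = fraction_modified,
              enantiomer_probs = enantiomer_probs,
              dose_levels = dose_levels, n_replicates = as.integer(n_replicates),
              fc_range = fc_range, abundance_cv = abundance_cv,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              baseline_occupancy = baseline_occupancy,
              n_background = as.integer(n_background),
              spurious_peak_fraction = spurious_peak_fraction,
              intensity_jitter_cv = intensity_jitter_cv,
              nl_probability = nl_probability,
              nl_abundance_range = nl_abundance_range,
              rt_range = rt_range, rt_mod_shift = rt_mod_shift,
              rt_noise_sd = rt_noise_sd,
              precursor_charge = as.integer(precursor_charge),
              fragment_charges = as.integer(fragment_charges),
              max_missed = as.integer(max_missed),
              peptide_length_range = as.integer(peptide_length_range))
  probs <- c(cfg$site_weights, cfg$enantiomer_probs, cfg$nl_probability,
             cfg$fraction_modified, cfg$baseline_occupancy)
  if (any(probs < 0 | probs > 1.000001)) {
    stop("all probabilities/weights must lie in [0, 1]")
  }
  if (any(diff(cfg$dose_levels) <= 0)) {
    stop("dose levels must be strictly increasing")
  }
  if (cfg$n_proteins < 0 || any(cfg$protein_length <= 0)) {
    stop("infeasible proteome constraints")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a random proteome
#'
#' Sequences are drawn from proteome-like residue frequencies with a
#' guaranteed minimum content of K/R (tryptic sites), E/D (GluC sites)
#' and S/T/Y (modifiable residues); deterministic per seed.
#'
#' @param config A [sim_config()].
#' @return Named character vector of protein sequences.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_proteins == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  .with_seed(.stage_seed(config$seed, 1L), {
    lens <- sample(seq(config$protein_length[1], config$protein_length[2]),
                   config$n_proteins, replace = TRUE)
    out <- vapply(lens, function(len) {
      repeat {
        s <- paste(sample(names(.AA_FREQ), len, replace = TRUE,
                          prob = .AA_FREQ), collapse = "")
        ok <- function(cls) sum(strsplit(s, "")[[1]] %in% cls) >= 2
        if (ok(c("K", "R")) && ok(c("E", "D")) && ok(c("S", "T", "Y"))) {
          return(s)
        }
      }
    }, character(1))
    names(out) <- sprintf("SYN%04d", seq_along(out))
    out
  })
}

#' Plant 2HG modifications on digested peptides
#'
#' Selects eligible peptides (length within range, carrying at least one
#' S/T/Y), samples one modification site per peptide by the configured
#' residue weights, assigns each an enantiomer (D/L/shared) and a true
#' top-dose fold change, and returns the ground-truth ledger. The ledger
#' is for generators and test harnesses only; analysis functions never
#' take it as input.
#'
#' @param peptides Digest data frame (needs a `sequence` column) or a
#'   character vector of peptide sequences.
#' @param config A [sim_config()].
#' @param n Number of peptides to plant; default
#'   `round(fraction_modified * n_eligible)`.
#' @return Ledger data frame: peptide_id, sequence, site, residue,
#'   enantiomer, true_fc.
#' @export
plant_modifications <- function(peptides, config, n = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  seqs <- unique(seqs)
  len <- nchar(seqs)
  eligible <- seqs[len >= config$peptide_length_range[1] &
                     len <= config$peptide_length_range[2] &
                     grepl("[STY]", seqs)]
  if (length(eligible) == 0) {
    return(data.frame(peptide_id = character(0), sequence = character(0),
                      site = integer(0), residue = character(0),
                      enantiomer = character(0), true_fc = numeric(0)))
  }
  if (is.null(n)) n <- round(config$fraction_modified * length(eligible))
  n <- min(n, length(eligible))
  .with_seed(.stage_seed(config$seed, 2L), {
    chosen <- sample(sort(eligible), n)
    site <- integer(n)
    residue <- character(n)
    for (i in seq_len(n)) {
      chars <- strsplit(chosen[i], "")[[1]]
      cand <- which(chars %in% names(config$site_weights))
      w <- config$site_weights[chars[cand]]
      s <- if (length(cand) == 1) cand else sample(cand, 1, prob = w)
      site[i] <- s
      residue[i] <- chars[s]
    }
    enantiomer <- sample(names(config$enantiomer_probs), n, replace = TRUE,
                         prob = config$enantiomer_probs)
    true_fc <- stats::runif(n, config$fc_range[1], config$fc_range[2])
    data.frame(
      peptide_id = sprintf("%s_%s%d", chosen, residue, site),
      sequence = chosen, site = site, residue = residue,
      enantiomer = enantiomer, true_fc = true_fc)
  })
}

# Dose-response factor: log-linear interpolation on log1p(dose) between 1
# at dose 0 and the true fold change at the top dose.
.dose_factor <- function(fc, dose, top_dose) {
  fc ^ (log1p(dose) / log1p(top_dose))
}

.sample_table <- function(config) {
  doses <- config$dose_levels[config$dose_levels > 0]
  reps <- seq_len(config$n_replicates)
  veh <- data.frame(series = "vehicle", dose = 0, replicate = reps)
  trt <- expand.grid(replicate = reps, dose = doses,
                     series = c("D2HG", "L2HG"), stringsAsFactors = FALSE)
  smp <- rbind(veh, trt[, c("series", "dose", "replicate")])
  smp$condition <- sprintf("%s_%g", smp$series, smp$dose)
  smp$sample <- sprintf("%s_r%d", smp$condition, smp$replicate)
  smp[, c("sample", "condition", "series", "dose", "replicate")]
}

#' Simulate a dose-response abundance matrix
#'
#' Baseline areas are lognormal; modified peptides respond in their
#' assigned enantiomer series (shared responds in both) with a factor
#' interpolated in log-dose up to the peptide's true top-dose fold change;
#' replicate noise is lognormal with the configured CV (mean 1, so fold
#' changes are unbiased). Unmodified counterpart rows (the plain sequence)
#' are included for occupancy and RT pairing.
#'
#' @param ledger Output of [plant_modifications()].
#' @param config A [sim_config()].
#' @return An [abundance_matrix()].
#' @export
simulate_abundances <- function(ledger, config) {
  stopifnot(inherits(config, "sim_config"))
  smp <- .sample_table(config)
  top_dose <- max(config$dose_levels)
  n_mod <- nrow(ledger)
  unmod_seq <- unique(ledger$sequence)
  bg_id <- if (config$n_background > 0) {
    sprintf("BG%04d", seq_len(config$n_background))
  } else character(0)
  rows <- c(ledger$peptide_id, unmod_seq, bg_id)
  .with_seed(.stage_seed(config$seed, 3L), {
    unmod_base <- stats::rlnorm(length(unmod_seq), config$baseline_meanlog,
                                config$baseline_sdlog)
    names(unmod_base) <- unmod_seq
    bg_base <- stats::rlnorm(length(bg_id), config$baseline_meanlog,
                             config$baseline_sdlog)
    occ <- config$baseline_occupancy
    mod_base <- unmod_base[ledger$sequence] * occ / (1 - occ)
    expected <- matrix(0, length(rows), nrow(smp),
                       dimnames = list(rows, smp$sample))
    for (j in seq_len(nrow(smp))) {
      fac <- rep(1, n_mod)
      if (smp$dose[j] > 0) {
        series_enant <- sub("2HG$", "", smp$series[j])  # "D2HG" -> "D"
        match_series <- ledger$enantiomer == series_enant |
          ledger$enantiomer == "shared"
        fac[match_series] <- .dose_factor(ledger$true_fc[match_series],
                                          smp$dose[j], top_dose)
      }
      expected[, j] <- c(mod_base * fac, unmod_base, bg_base)
    }
    cv <- config$abundance_cv
    areas <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      noise <- matrix(stats::rlnorm(length(expected), -sdlog^2 / 2, sdlog),
                      nrow(expected), ncol(expected))
      expected * noise
    } else expected
    abundance_matrix(areas, smp)
  })
}

#' Simulate a null abundance matrix (no planted effect)
#'
#' Two conditions, lognormal noise, no true differences; used to calibrate
#' the t-test machinery.
#'
#' @param n_peptides Number of rows.
#' @param n_replicates Replicates per condition.
#' @param cv Lognormal CV.
#' @param seed Seed.
#' @return An [abundance_matrix()] with conditions `"treated"`/`"control"`.
#' @export
simulate_null_abundances <- function(n_peptides = 1000, n_replicates = 3,
                                     cv = 0.15, seed = 1L) {
  smp <- data.frame(
    sample = c(sprintf("control_r%d", seq_len(n_replicates)),
               sprintf("treated_r%d", seq_len(n_replicates))),
    condition = rep(c("control", "treated"), each = n_replicates),
    series = rep(c("control", "treated"), each = n_replicates),
    dose = rep(c(0, 1), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2))
  .with_seed(.stage_seed(seed, 7L), {
    base <- stats::rlnorm(n_peptides, log(1e6), 0.6)
    sdlog <- sqrt(log(1 + cv^2))
    areas <- base * matrix(stats::rlnorm(n_peptides * nrow(smp),
                                         -sdlog^2 / 2, sdlog),
                           n_peptides, nrow(smp))
    rownames(areas) <- sprintf("null%04d", seq_len(n_peptides))
    colnames(areas) <- smp$sample
    abundance_matrix(areas, smp)
  })
}

# Deterministic part of the surrogate RT model: mean hydropathy mapped
# linearly into the gradient window, plus a fixed shift when modified.
.predict_rt <- function(sequence, modified, config) {
  kd <- mean(.KD_INDEX[strsplit(sequence, "")[[1]]])
  x <- (kd + 4.5) / 9
  config$rt_range[1] + x * diff(config$rt_range) +
    if (modified) config$rt_mod_shift else 0
}

#' Simulate MS/MS spectra for planted peptides
#'
#' Each spectrum contains all b/y ions (unit base intensity with lognormal
#' jitter), per-channel neutral-loss peaks (fragment loss variants plus
#' charge-reduced precursor losses) emitted with the configured probability
#' and relative abundance, and spurious peaks uniform over the m/z range.
#' `heavy = TRUE` applies the d4 adduct; `modified = FALSE` generates the
#' unmodified counterpart spectra (for RT pairing).
#'
#' @param ledger Output of [plant_modifications()].
#' @param config A [sim_config()].
#' @param heavy Simulate the d4 isotopologue.
#' @param modified Simulate with (default) or without the modification.
#' @return List of [spectrum()] objects.
#' @export
simulate_spectra <- function(ledger, config, heavy = FALSE, modified = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  stage <- 4L + heavy + 2L * (!modified)
  .with_seed(.stage_seed(config$seed, stage), {
    lapply(seq_len(nrow(ledger)), function(i) {
      seqi <- ledger$sequence[i]
      pep <- if (modified) {
        peptide(seqi, mods = list(list(site = ledger$site[i],
                                       spec = mod_2hg())))
      } else peptide(seqi)
      frag <- theoretical_fragments(pep, charges = config$fragment_charges,
                                    include_losses = FALSE, heavy = heavy)
      jit <- function(n) stats::rlnorm(n, 0, sqrt(log(1 + config$intensity_jitter_cv^2)))
      pmz <- 100 * jit(nrow(frag))
      peaks_mz <- frag$mz
      peaks_int <- pmz
      base <- max(peaks_int)
      prec <- precursor_descriptor(pep, config$precursor_charge, heavy = heavy)
      if (modified) {
        loss_frag <- theoretical_fragments(pep, charges = config$fragment_charges,
                                           include_losses = TRUE, heavy = heavy)
        for (ch in names(config$nl_probability)) {
          if (stats::runif(1) <= config$nl_probability[[ch]]) {
            rel <- stats::runif(1, config$nl_abundance_range[1],
                                config$nl_abundance_range[2])
            sel <- loss_frag$loss == ch
            lm <- mod_2hg()$neutral_loss_masses[[ch]] +
              if (heavy) d4_shift() else 0
            prec_loss_mz <- mz(prec$neutral_mass - lm,
                               seq_len(config$precursor_charge))
            add_mz <- c(loss_frag$mz[sel], prec_loss_mz)
            peaks_mz <- c(peaks_mz, add_mz)
            peaks_int <- c(peaks_int, rel * base * jit(length(add_mz)))
          }
        }
      }
      n_spur <- round(config$spurious_peak_fraction * length(peaks_mz))
      if (n_spur > 0) {
        peaks_mz <- c(peaks_mz, stats::runif(n_spur, 100,
                                             max(peaks_mz) + 50))
        peaks_int <- c(peaks_int, stats::runif(n_spur, 0.01, 0.3) * base)
      }
      rt <- .predict_rt(seqi, modified, config) +
        stats::rnorm(1, 0, config$rt_noise_sd)
      id <- paste0(ledger$peptide_id[i],
                   if (heavy) "_heavy" else "",
                   if (!modified) "_unmod" else "")
      spectrum(id, prec$mz, config$precursor_charge, rt,
               peaks_mz, peaks_int)
    })
  })
}

#' Run the full generator: proteome, digest, planting, abundances
#'
#' @param config A [sim_config()].
#' @param n_planted Number of planted peptides (default from
#'   `fraction_modified`).
#' @return List: proteome, peptides (digest table), ledger, abundances.
#' @export
simulate_study <- function(config, n_planted = NULL) {
  proteome <- generate_proteome(config)
  peptides <- digest_proteome(proteome, rules = list(trypsin(), gluc()),
                              max_missed = config$max_missed)
  ledger <- plant_modifications(peptides, config, n = n_planted)
  abundances <- simulate_abundances(ledger, config)
  list(proteome = proteome, peptides = peptides, ledger = ledger,
       abundances = abundances)
}
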