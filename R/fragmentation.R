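## Theoretical b/y fragmentation of (modified) peptides, with diagnostic
## neutral-loss variants restricted to modification-bearing ions and d4
## isotopologue ladders.

.default_fragment_charges <- function(precursor_charge) {
  if (precursor_charge >= 2) 1:2 else 1L
}

#' Theoretical b/y fragment ions
#'
#' Emits all b_i and y_i (i = 1..n-1) at each requested charge. For ions
#' whose residue span covers a modified site, neutral-loss variants are
#' additionally emitted per loss channel of the modification (channel A
#' subtracts the full adduct, restoring the unmodified backbone mass;
#' channel B subtracts adduct + water). With `heavy = TRUE` the
#' modification's isotope-variant mass is used, and losses shift with it
#' (the label leaves with the adduct).
#'
#' @param pep A [peptide()].
#' @param charges Fragment charges; default 1:2 when `precursor_charge >= 2`,
#'   else 1.
#' @param include_losses Emit neutral-loss variants for mod-containing ions.
#' @param heavy Use isotope-variant (d4) adduct masses.
#' @param carbamidomethyl Fixed +57.0215 Da on Cys.
#' @param precursor_charge Used only to pick default fragment charges.
#' @return Data frame: series, index, charge, loss, heavy, mz,
#'   contains_mod, n_mods.
#' @export
theoretical_fragments <- function(pep, charges = NULL, include_losses = TRUE,
                                  heavy = FALSE, carbamidomethyl = TRUE,
                                  precursor_charge = 2L) {
  stopifnot(inherits(pep, "peptide"))
  n <- nchar(pep$sequence)
  if (n < 2) stop("peptide must have length >= 2")
  if (is.null(charges)) charges <- .default_fragment_charges(precursor_charge)
  if (length(charges) == 0) stop("charge set must be non-empty")
  chars <- strsplit(pep$sequence, "")[[1]]
  res <- unname(.RESIDUE_MASS[chars])
  if (carbamidomethyl) res[chars == "C"] <- res[chars == "C"] + .CAM_MASS
  delta <- numeric(n)
  modded <- logical(n)
  loss_masses <- numeric(0)
  for (m in pep$mods) {
    d <- if (heavy && !is.null(m$spec$isotope_mass)) m$spec$isotope_mass
         else m$spec$delta_mass
    delta[m$site] <- delta[m$site] + d
    modded[m$site] <- TRUE
    if (length(m$spec$neutral_loss_masses) > 0) {
      lm <- m$spec$neutral_loss_masses
      if (heavy && !is.null(m$spec$isotope_mass)) {
        lm <- lm + (m$spec$isotope_mass - m$spec$delta_mass)
      }
      loss_masses <- lm  # channels shared across mods of one spec
    }
  }
  resm <- res + delta
  prefix <- cumsum(resm)
  total <- sum(resm) + .WATER_MASS
  i <- seq_len(n - 1L)
  b_neutral <- prefix[i]
  y_neutral <- total - prefix[n - i]
  cmod <- cumsum(modded)
  b_nmods <- cmod[i]
  y_nmods <- cmod[n] - cmod[n - i]

  base <- rbind(
    data.frame(series = "b", index = i, neutral = b_neutral, n_mods = b_nmods),
    data.frame(series = "y", index = i, neutral = y_neutral, n_mods = y_nmods)
  )
  base$contains_mod <- base$n_mods > 0

  rows <- list()
  for (z in sort(unique(as.integer(charges)))) {
    main <- data.frame(series = base$series, index = base$index, charge = z,
                       loss = "none", heavy = heavy,
                       mz = mz(base$neutral, z),
                       contains_mod = base$contains_mod,
                       n_mods = base$n_mods)
    rows[[length(rows) + 1L]] <- main
    if (include_losses && length(loss_masses) > 0) {
      sel <- base$contains_mod
      if (any(sel)) {
        for (ch in names(loss_masses)) {
          rows[[length(rows) + 1L]] <- data.frame(
            series = base$series[sel], index = base$index[sel], charge = z,
            loss = ch, heavy = heavy,
            mz = mz(base$neutral[sel] - loss_masses[[ch]], z),
            contains_mod = TRUE, n_mods = base$n_mods[sel])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precursor m/z descriptor for a (modified) peptide
#'
#' @param pep A [peptide()].
#' @param charge Precursor charge.
#' @param heavy Use the isotope-variant adduct mass.
#' @param carbamidomethyl Fixed Cys modification toggle.
#' @return List with `mz`, `charge`, `neutral_mass`.
#' @export
precursor_descriptor <- function(pep, charge = 2L, heavy = FALSE,
                                 carbamidomethyl = TRUE) {
  nm <- peptide_neutral_mass(pep, heavy = heavy,
                             carbamidomethyl = carbamidomethyl)
  list(mz = mz(nm, charge), charge = as.integer(charge), neutral_mass = nm)
}

#' Write a fragment table to a tab-separated file
#'
#' @param fragments Output of [theoretical_fragments()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
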