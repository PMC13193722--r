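## Elemental composition arithmetic, monoisotopic masses, and the
## modification registry (2HG ester adduct and friends).

# Monoisotopic atomic masses in Da (NIST/CODATA). "D" is deuterium (2H),
# kept as a distinct symbol so isotopologues are ordinary compositions.
.ATOMIC_MASS <- c(
  H = 1.00782503207,
  D = 2.01410177785,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

.PROTON_MASS <- 1.007276466621

#' Monoisotopic mass of a proton
#'
#' @return Proton mass in Da.
#' @export
proton_mass <- function() .PROTON_MASS

#' Construct an elemental composition
#'
#' A composition is a named vector of non-negative integer element counts.
#' Deuterium is the distinct symbol `D`, so isotopologues (e.g. the d4
#' 2-hydroxyglutaryl adduct) are ordinary compositions.
#'
#' @param ... Named integer counts, e.g. `composition(C = 5, H = 6, O = 4)`.
#' @return An `elemental_composition` object.
#' @export
composition <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    counts <- integer(0)
    names(counts) <- character(0)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all composition counts must be named by element symbol")
  }
  if (any(counts < 0)) stop("composition counts must be non-negative")
  if (any(counts != round(counts))) stop("composition counts must be integers")
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  structure(counts, class = "elemental_composition")
}

#' Parse a molecular formula string
#'
#' @param formula A formula such as `"C5H6O4"` or `"C5H2D4O4"`.
#' @return An `elemental_composition`.
#' @export
parse_formula <- function(formula) {
  if (inherits(formula, "elemental_composition")) return(formula)
  stopifnot(is.character(formula), length(formula) == 1)
  if (formula == "") return(composition())
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  sym <- sub("[0-9]*$", "", parts)
  num <- sub("^[A-Z][a-z]?", "", parts)
  num <- ifelse(num == "", 1L, as.integer(num))
  counts <- tapply(num, sym, sum)
  do.call(composition, as.list(counts))
}

#' Format a composition as a formula string
#'
#' @param comp An `elemental_composition`.
#' @return A character formula (Hill-ish order: C, H, then alphabetical).
#' @export
format_formula <- function(comp) {
  comp <- parse_formula(comp)
  if (length(comp) == 0) return("")
  sym <- names(comp)
  ord <- order(match(sym, c("C", "H"), nomatch = 3L), sym)
  paste0(sym[ord], ifelse(comp[ord] == 1, "", comp[ord]), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition> ", format_formula(x), "  (",
      sprintf("%.4f", composition_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

.comp_merge <- function(a, b, op) {
  sym <- union(names(a), names(b))
  av <- ifelse(sym %in% names(a), as.integer(a)[match(sym, names(a))], 0L)
  bv <- ifelse(sym %in% names(b), as.integer(b)[match(sym, names(b))], 0L)
  out <- op(av, bv)
  names(out) <- sym
  if (any(out < 0)) {
    stop("composition subtraction would give negative count for: ",
         paste(sym[out < 0], collapse = ", "))
  }
  do.call(composition, as.list(out))
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  .comp_merge(parse_formula(e1), parse_formula(e2), `+`)
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  .comp_merge(parse_formula(e1), parse_formula(e2), `-`)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp An `elemental_composition` or formula string.
#' @return Mass in Da (sum of count x tabulated monoisotopic atomic mass).
#' @examples
#' composition_mass("C5H6O4")  # 130.0266, the 2HG ester adduct
#' @export
composition_mass <- function(comp) {
  comp <- parse_formula(comp)
  if (length(comp) == 0) return(0)
  unknown <- setdiff(names(comp), names(.ATOMIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  sum(as.numeric(comp) * .ATOMIC_MASS[names(comp)])
}

.WATER_MASS <- 12 * 0 + 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]

# Residue (i.e. dehydrated amino acid) elemental compositions.
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, composition_mass, numeric(1))

#' Residue monoisotopic masses
#'
#' @return Named numeric vector of the 20 canonical residue masses (Da).
#' @export
residue_masses <- function() .RESIDUE_MASS

#' Define a modification
#'
#' @param name Modification name.
#' @param formula Net adduct composition (formula string or composition).
#' @param targets Character vector of one-letter residue codes the
#'   modification may sit on.
#' @param neutral_losses Named list of compositions/formulas lost as neutral
#'   fragments during MS/MS (labels are channel names).
#' @param isotope_variant Optional composition of the stable-isotope-labelled
#'   adduct (e.g. four H replaced by D).
#' @return A `modification_spec`.
#' @export
modification_spec <- function(name, formula, targets,
                              neutral_losses = list(),
                              isotope_variant = NULL) {
  comp <- parse_formula(formula)
  losses <- lapply(neutral_losses, parse_formula)
  if (length(losses) > 0 && is.null(names(losses))) {
    stop("neutral_losses must be a named list")
  }
  iso <- if (!is.null(isotope_variant)) parse_formula(isotope_variant)
  structure(
    list(
      name = name,
      targets = targets,
      delta_composition = comp,
      delta_mass = composition_mass(comp),
      neutral_losses = losses,
      neutral_loss_masses = vapply(losses, composition_mass, numeric(1)),
      isotope_variant = iso,
      isotope_mass = if (!is.null(iso)) composition_mass(iso) else NULL
    ),
    class = "modification_spec"
  )
}

#' @export
print.modification_spec <- function(x, ...) {
  cat("<modification> ", x$name, " +", sprintf("%.4f", x$delta_mass),
      " Da on ", paste(x$targets, collapse = "/"), "\n", sep = "")
  if (length(x$neutral_losses) > 0) {
    cat("  neutral losses: ",
        paste(sprintf("%s = %s (%.4f Da)", names(x$neutral_losses),
                      vapply(x$neutral_losses, format_formula, character(1)),
                      x$neutral_loss_masses),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$isotope_variant)) {
    cat("  isotope variant: ", format_formula(x$isotope_variant),
        sprintf(" (+%.4f Da vs light)", x$isotope_mass - x$delta_mass),
        "\n", sep = "")
  }
  invisible(x)
}

#' The 2-hydroxyglutaryl (2HG) ester modification
#'
#' The net adduct is C5H6O4 (+130.0266 Da) on Ser/Thr/Tyr hydroxyls.
#' Diagnostic neutral losses: channel A loses the full adduct (C5H6O4,
#' 130.0266 Da, restoring the unmodified backbone); channel B loses
#' C5H8O5 (148.0372 Da, adduct plus water, leaving a dehydro residue).
#' The isotope variant is the d4 adduct (C5H2D4O4) used in metabolic
#' flux labelling, +4.0251 Da relative to the light adduct.
#'
#' @param targets Residues carrying the ester; default S/T/Y (hydroxyl
#'   residues); extensible to K/C/D/E.
#' @return A `modification_spec`.
#' @export
mod_2hg <- function(targets = c("S", "T", "Y")) {
  modification_spec(
    name = "2HG",
    formula = "C5H6O4",
    targets = targets,
    neutral_losses = list(A = "C5H6O4", B = "C5H8O5"),
    isotope_variant = "C5H2D4O4"
  )
}

#' Carbamidomethylation of cysteine
#'
#' Fixed modification from chloroacetamide alkylation (+57.0215 Da, C2H3NO).
#'
#' @return A `modification_spec`.
#' @export
mod_carbamidomethyl <- function() {
  modification_spec("Carbamidomethyl", "C2H3NO", "C")
}

.CAM_MASS <- composition_mass("C2H3NO")

#' Shipped modification registry
#'
#' @return Named list of `modification_spec` objects.
#' @export
mod_registry <- function() {
  list(`2HG` = mod_2hg(), Carbamidomethyl = mod_carbamidomethyl())
}

#' Write / read a modification registry as editable JSON
#'
#' @param registry Named list of `modification_spec` objects.
#' @param path File path.
#' @return `write_mod_registry` returns `path` invisibly;
#'   `read_mod_registry` returns the registry list.
#' @export
write_mod_registry <- function(registry, path) {
  x <- lapply(registry, function(m) {
    list(
      name = m$name,
      formula = format_formula(m$delta_composition),
      targets = m$targets,
      neutral_losses = lapply(m$neutral_losses, format_formula),
      isotope_variant = if (!is.null(m$isotope_variant))
        format_formula(m$isotope_variant)
    )
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_mod_registry
#' @export
read_mod_registry <- function(path) {
  x <- jsonlite::read_json(path)
  out <- lapply(x, function(m) {
    modification_spec(
      name = m$name,
      formula = m$formula,
      targets = unlist(m$targets),
      neutral_losses = m$neutral_losses,
      isotope_variant = m$isotope_variant
    )
  })
  names(out) <- vapply(out, function(m) m$name, character(1))
  out
}

.validate_mods <- function(sequence, mods) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  sites <- vapply(mods, function(m) as.integer(m$site), integer(1))
  if (anyDuplicated(sites)) {
    stop("duplicate modification site: ",
         paste(sites[duplicated(sites)], collapse = ", "))
  }
  for (m in mods) {
    s <- as.integer(m$site)
    if (s < 1 || s > n) stop("modification site ", s, " outside peptide (length ", n, ")")
    res <- chars[s]
    if (!res %in% m$spec$targets) {
      stop("modification '", m$spec$name, "' at site ", s,
           " on residue '", res, "' which is not a target residue (",
           paste(m$spec$targets, collapse = "/"), ")")
    }
  }
  invisible(TRUE)
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' @param sequence Peptide sequence (one-letter codes) or a [peptide()] object.
#' @param mods List of modifications, each `list(site = <1-based index>,
#'   spec = <modification_spec>)`. Ignored when `sequence` is a peptide.
#' @param heavy Use each modification's isotope variant mass where defined.
#' @param carbamidomethyl Apply fixed +57.0215 Da to every cysteine
#'   (default TRUE, matching chloroacetamide alkylation).
#' @return Neutral mass in Da.
#' @export
peptide_neutral_mass <- function(sequence, mods = list(), heavy = FALSE,
                                 carbamidomethyl = TRUE) {
  if (inherits(sequence, "peptide")) {
    mods <- sequence$mods
    sequence <- sequence$sequence
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, names(.RESIDUE_MASS))
  if (length(bad) > 0) {
    stop("unknown residue code: ", paste(unique(bad), collapse = ", "))
  }
  .validate_mods(sequence, mods)
  mass <- sum(.RESIDUE_MASS[chars]) + .WATER_MASS
  if (carbamidomethyl) mass <- mass + .CAM_MASS * sum(chars == "C")
  for (m in mods) {
    d <- if (heavy && !is.null(m$spec$isotope_mass)) m$spec$isotope_mass
         else m$spec$delta_mass
    mass <- mass + d
  }
  mass
}

#' m/z of an ion
#'
#' @param neutral_mass Neutral mass in Da.
#' @param charge Positive integer charge.
#' @return (neutral_mass + charge x proton) / charge.
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * .PROTON_MASS) / charge
}

#' Neutral mass from observed m/z
#'
#' @param mz_value Observed m/z.
#' @param charge Positive integer charge.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz_value, charge) {
  if (any(charge < 1)) stop("charge must be a positive integer")
  mz_value * charge - charge * .PROTON_MASS
}
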