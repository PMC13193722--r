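## Spectrum container, peptide-spectrum matching, modification-site
## localization, diagnostic neutral-loss detection/binning, and heavy/light
## isotope-pair validation.

#' Construct an MS/MS spectrum
#'
#' Peaks are stored sorted by m/z; intensities must be finite and
#' non-negative.
#'
#' @param id Spectrum identifier.
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge.
#' @param rt Retention time in minutes.
#' @param mz Peak m/z values.
#' @param intensity Peak intensities.
#' @return A `spectrum` object.
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, rt, mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(intensity) > 0) {
    if (any(!is.finite(intensity)) || any(intensity < 0)) {
      stop("intensities must be finite and non-negative")
    }
  }
  ord <- order(mz)
  structure(list(id = as.character(id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 rt = as.numeric(rt),
                 mz = as.numeric(mz[ord]),
                 intensity = as.numeric(intensity[ord])),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", x$id, ": ", length(x$mz), " peaks, precursor ",
      sprintf("%.4f", x$precursor_mz), " (", x$precursor_charge, "+), RT ",
      sprintf("%.2f", x$rt), " min\n", sep = "")
  invisible(x)
}

# Greedy peak assignment: theoretical ions claim their nearest unused peak
# within tol_ppm, in table order. Returns peak index per ion (NA = no match).
.assign_peaks <- function(theo_mz, peak_mz, tol_ppm) {
  nt <- length(theo_mz)
  hit <- rep(NA_integer_, nt)
  np <- length(peak_mz)
  if (np == 0 || nt == 0) return(hit)
  used <- logical(np)
  pos <- findInterval(theo_mz, peak_mz)
  for (k in seq_len(nt)) {
    tol <- theo_mz[k] * tol_ppm * 1e-6
    cand <- c(pos[k], pos[k] + 1L)
    cand <- cand[cand >= 1 & cand <= np]
    cand <- cand[!used[cand] & abs(peak_mz[cand] - theo_mz[k]) <= tol]
    if (length(cand) > 0) {
      best <- cand[which.min(abs(peak_mz[cand] - theo_mz[k]))]
      hit[k] <- best
      used[best] <- TRUE
    }
  }
  hit
}

.psm <- function(spectrum, pep, frag, hit, score, heavy = FALSE) {
  base_peak <- if (length(spectrum$intensity) > 0) max(spectrum$intensity) else NA_real_
  matched <- which(!is.na(hit))
  matches <- frag[matched, c("series", "index", "charge", "loss",
                             "contains_mod", "n_mods", "mz"), drop = FALSE]
  names(matches)[names(matches) == "mz"] <- "theo_mz"
  matches$obs_mz <- spectrum$mz[hit[matched]]
  matches$intensity <- spectrum$intensity[hit[matched]]
  rownames(matches) <- NULL
  structure(list(
    spectrum_id = spectrum$id,
    peptide = pep,
    match_score = score,
    matched_ion_count = length(matched),
    matches = matches,
    precursor_neutral = neutral_mass(spectrum$precursor_mz,
                                     spectrum$precursor_charge),
    precursor_charge = spectrum$precursor_charge,
    rt = spectrum$rt,
    heavy = heavy,
    base_peak = base_peak,
    localization = NULL,
    nl_flags = NULL
  ), class = "psm")
}

#' @export
print.psm <- function(x, ...) {
  cat("<psm> ", x$spectrum_id, " <- ", x$peptide$sequence,
      sprintf(" score %.3f (%d ions)", x$match_score, x$matched_ion_count),
      "\n", sep = "")
  invisible(x)
}

.score_candidate <- function(spec, pep, tol_ppm, heavy, carbamidomethyl) {
  frag <- theoretical_fragments(pep, heavy = heavy,
                                carbamidomethyl = carbamidomethyl,
                                precursor_charge = spec$precursor_charge)
  hit <- .assign_peaks(frag$mz, spec$mz, tol_ppm)
  base_peak <- if (length(spec$intensity) > 0) max(spec$intensity) else 0
  rel <- if (base_peak > 0) spec$intensity[hit[!is.na(hit)]] / base_peak else numeric(0)
  score <- sum(log1p(rel))
  .psm(spec, pep, frag, hit, score, heavy = heavy)
}

#' Match a spectrum against candidate peptides
#'
#' Candidates are first filtered by precursor mass; each surviving candidate
#' is scored as the sum of log(1 + relative intensity) over theoretical ions
#' matched greedily within `tol_ppm` (each peak used once). Ties break by
#' fewer modifications, then lexicographic sequence.
#'
#' @param spec A [spectrum()].
#' @param candidates List of [peptide()] objects.
#' @param tol_ppm Fragment tolerance in ppm.
#' @param precursor_tol_ppm Precursor tolerance in ppm.
#' @param heavy Score with d4 isotope-variant masses.
#' @param carbamidomethyl Fixed Cys modification toggle.
#' @return List: `best` (a `psm` or NULL), `ranked` (list of psm, best
#'   first), `no_candidate` (TRUE when nothing passed the precursor filter).
#' @export
match_spectrum <- function(spec, candidates, tol_ppm = 10,
                           precursor_tol_ppm = 20, heavy = FALSE,
                           carbamidomethyl = TRUE) {
  stopifnot(tol_ppm > 0)
  obs_neutral <- neutral_mass(spec$precursor_mz, spec$precursor_charge)
  keep <- vapply(candidates, function(p) {
    nm <- peptide_neutral_mass(p, heavy = heavy,
                               carbamidomethyl = carbamidomethyl)
    abs(nm - obs_neutral) / nm * 1e6 <= precursor_tol_ppm
  }, logical(1))
  if (!any(keep)) {
    return(list(best = NULL, ranked = list(), no_candidate = TRUE))
  }
  psms <- lapply(candidates[keep], .score_candidate, spec = spec,
                 tol_ppm = tol_ppm, heavy = heavy,
                 carbamidomethyl = carbamidomethyl)
  nmods <- vapply(psms, function(p) length(p$peptide$mods), integer(1))
  seqs <- vapply(psms, function(p) p$peptide$sequence, character(1))
  scores <- vapply(psms, function(p) p$match_score, numeric(1))
  ord <- order(-scores, nmods, seqs)
  list(best = psms[[ord[1]]], ranked = psms[ord], no_candidate = FALSE)
}

#' Localize the modification site on a matched peptide
#'
#' Counts matched site-determining ions per candidate site (ions, including
#' neutral-loss variants, whose m/z differs between site hypotheses). The
#' best site wins; `delta_score` is best minus runner-up, with an `Inf`
#' sentinel when only one candidate site exists.
#'
#' @param psm A `psm` whose peptide carries exactly one variable modification.
#' @param spec The matched [spectrum()].
#' @param candidate_sites Candidate 1-based sites; default all target
#'   residues of the modification in the sequence.
#' @param tol_ppm Fragment tolerance in ppm.
#' @return The psm with `localization = list(best_site, runner_up_site,
#'   delta_score, scores)` filled in.
#' @export
localize_site <- function(psm, spec, candidate_sites = NULL, tol_ppm = 10) {
  pep <- psm$peptide
  if (length(pep$mods) == 0) stop("peptide carries no modification")
  m <- pep$mods[[1]]
  chars <- strsplit(pep$sequence, "")[[1]]
  if (is.null(candidate_sites)) {
    candidate_sites <- which(chars %in% m$spec$targets)
  }
  if (length(candidate_sites) < 1) stop("no candidate site on target residues")
  candidate_sites <- sort(unique(as.integer(candidate_sites)))
  hyps <- lapply(candidate_sites, function(s) {
    peptide(pep$sequence, mods = list(list(site = s, spec = m$spec)),
            protein_id = pep$protein_id, start = pep$start)
  })
  heavy <- isTRUE(psm$heavy)
  frags <- lapply(hyps, theoretical_fragments, heavy = heavy,
                  precursor_charge = psm$precursor_charge)
  key_of <- function(f) paste(f$series, f$index, f$charge, f$loss, sep = ":")
  keys <- lapply(frags, key_of)
  all_keys <- unique(unlist(keys))
  # a key is site-determining unless present in all hypotheses at one m/z
  mz_by_hyp <- sapply(seq_along(frags), function(h) {
    f <- frags[[h]]
    f$mz[match(all_keys, keys[[h]])]
  })
  mz_by_hyp <- matrix(mz_by_hyp, nrow = length(all_keys))
  spread <- apply(mz_by_hyp, 1, function(v) {
    if (any(is.na(v))) Inf else max(v) - min(v)
  })
  determining <- all_keys[spread > 1e-9]
  scores <- vapply(seq_along(hyps), function(h) {
    f <- frags[[h]]
    hit <- .assign_peaks(f$mz, spec$mz, tol_ppm)
    sum(!is.na(hit) & keys[[h]] %in% determining)
  }, numeric(1))
  ord <- order(-scores, candidate_sites)
  best <- candidate_sites[ord[1]]
  if (length(candidate_sites) == 1) {
    runner <- NA_integer_
    delta <- Inf
  } else {
    runner <- candidate_sites[ord[2]]
    delta <- scores[ord[1]] - scores[ord[2]]
  }
  psm$localization <- list(best_site = best, runner_up_site = runner,
                           delta_score = delta,
                           scores = data.frame(site = candidate_sites,
                                               score = scores))
  psm
}

#' Detect diagnostic neutral-loss ions
#'
#' Checks, per loss channel, (i) charge-reduced precursor-loss positions
#' (precursor neutral minus the loss, at every charge up to the precursor
#' charge) and (ii) all fragment loss variants, recording presence and the
#' maximum relative abundance as a fraction of the base peak.
#'
#' @param psm A `psm` whose peptide carries a modification with neutral-loss
#'   channels.
#' @param spec The matched [spectrum()].
#' @param tol_ppm Tolerance in ppm.
#' @param heavy Use d4-shifted loss masses.
#' @return The psm with `nl_flags` filled: per channel a list of
#'   `precursor_observed`, `fragment_observed`, `relative_abundance`
#'   (NA when the channel is absent).
#' @export
detect_neutral_loss <- function(psm, spec, tol_ppm = 10, heavy = FALSE) {
  pep <- psm$peptide
  specs <- Filter(function(m) length(m$spec$neutral_loss_masses) > 0, pep$mods)
  if (length(specs) == 0) {
    stop("neutral-loss detection undefined for an unmodified peptide")
  }
  loss_masses <- specs[[1]]$spec$neutral_loss_masses
  if (heavy && !is.null(specs[[1]]$spec$isotope_mass)) {
    loss_masses <- loss_masses +
      (specs[[1]]$spec$isotope_mass - specs[[1]]$spec$delta_mass)
  }
  base_peak <- if (length(spec$intensity) > 0) max(spec$intensity) else 0
  prec_neutral <- peptide_neutral_mass(pep, heavy = heavy)
  frag <- theoretical_fragments(pep, include_losses = TRUE, heavy = heavy,
                                precursor_charge = spec$precursor_charge)
  find_max_rel <- function(positions) {
    rel <- NA_real_
    seen <- FALSE
    for (p in positions) {
      tol <- p * tol_ppm * 1e-6
      sel <- spec$mz >= p - tol & spec$mz <= p + tol
      if (any(sel)) {
        seen <- TRUE
        r <- max(spec$intensity[sel]) / base_peak
        rel <- if (is.na(rel)) r else max(rel, r)
      }
    }
    list(seen = seen, rel = rel)
  }
  flags <- lapply(names(loss_masses), function(ch) {
    zs <- seq_len(max(1L, spec$precursor_charge))
    prec_pos <- mz(prec_neutral - loss_masses[[ch]], zs)
    pr <- find_max_rel(prec_pos)
    fr_mz <- frag$mz[frag$loss == ch]
    fr <- find_max_rel(fr_mz)
    rel <- suppressWarnings(max(c(pr$rel, fr$rel), na.rm = TRUE))
    if (!is.finite(rel)) rel <- NA_real_
    list(precursor_observed = pr$seen, fragment_observed = fr$seen,
         relative_abundance = rel)
  })
  names(flags) <- names(loss_masses)
  psm$nl_flags <- flags
  psm
}

#' Bin neutral-loss abundances across PSMs
#'
#' Bins each PSM's per-channel maximum relative abundance into
#' high (> 5% of base peak), mid (1-5%], low (0-1%], or absent.
#'
#' @param psms List of `psm` objects with `nl_flags` set.
#' @return Data frame with one row per channel: counts high, mid, low,
#'   absent (rows sum to `length(psms)`).
#' @export
nl_frequency_summary <- function(psms) {
  stopifnot(length(psms) > 0)
  channels <- names(psms[[1]]$nl_flags)
  out <- lapply(channels, function(ch) {
    rel <- vapply(psms, function(p) p$nl_flags[[ch]]$relative_abundance,
                  numeric(1))
    obs <- vapply(psms, function(p) {
      isTRUE(p$nl_flags[[ch]]$precursor_observed) ||
        isTRUE(p$nl_flags[[ch]]$fragment_observed)
    }, logical(1))
    absent <- sum(!obs)
    v <- rel[obs]
    bins <- cut(v, breaks = c(0, 0.01, 0.05, Inf),
                labels = c("low", "mid", "high"), right = TRUE)
    data.frame(channel = ch,
               high = sum(bins == "high"), mid = sum(bins == "mid"),
               low = sum(bins == "low"), absent = absent)
  })
  do.call(rbind, out)
}

.D4_SHIFT <- 4 * (.ATOMIC_MASS[["D"]] - .ATOMIC_MASS[["H"]])

#' Monoisotopic mass shift of the d4 adduct
#'
#' @return 4 x (2H - 1H) in Da (about 4.0251).
#' @export
d4_shift <- function() .D4_SHIFT

#' Pair light and heavy (d4) PSMs
#'
#' A light/heavy duo is validated when (i) precursor neutral masses differ
#' by 4.0251 Da per modification within `precursor_tol_ppm`, (ii) retention
#' times agree within `rt_tol_min`, and (iii) the matched fragment ladders
#' agree on every shared non-mod-containing ion and differ by the heavy
#' shift (scaled by charge) on every shared mod-containing ion. The check
#' is symmetric in its two inputs.
#'
#' @param psms_light,psms_heavy Lists of `psm` objects.
#' @param precursor_tol_ppm Precursor mass tolerance (ppm).
#' @param rt_tol_min Retention-time tolerance (minutes).
#' @param frag_tol_ppm Fragment m/z agreement tolerance (ppm).
#' @return List: `pairs` (data frame light_id, heavy_id, mass_diff, rt_diff,
#'   n_shared_ions), `unpaired_light`, `unpaired_heavy` (spectrum ids).
#' @export
find_isotope_pairs <- function(psms_light, psms_heavy,
                               precursor_tol_ppm = 10, rt_tol_min = 1,
                               frag_tol_ppm = 10) {
  stopifnot(length(psms_light) > 0, length(psms_heavy) > 0)
  ladder_ok <- function(a, b, n_mods_total) {
    ka <- paste(a$matches$series, a$matches$index, a$matches$charge,
                a$matches$loss, sep = ":")
    kb <- paste(b$matches$series, b$matches$index, b$matches$charge,
                b$matches$loss, sep = ":")
    shared <- intersect(ka, kb)
    if (length(shared) == 0) return(FALSE)
    ia <- match(shared, ka)
    ib <- match(shared, kb)
    dmz <- abs(b$matches$obs_mz[ib] - a$matches$obs_mz[ia])
    # the d4 label leaves with the adduct, so loss-variant ions of a
    # heavy/light duo coincide; only intact mod-containing ions shift
    shifted <- a$matches$contains_mod[ia] & a$matches$loss[ia] == "none"
    nmods_ion <- a$matches$n_mods[ia]
    zs <- a$matches$charge[ia]
    tol <- pmax(a$matches$obs_mz[ia], b$matches$obs_mz[ib]) * frag_tol_ppm * 1e-6
    ok_same <- all(dmz[!shifted] <= tol[!shifted])
    expected <- .D4_SHIFT * nmods_ion[shifted] / zs[shifted]
    ok_shift <- all(abs(dmz[shifted] - expected) <= tol[shifted])
    ok_same && ok_shift && any(!shifted) && any(shifted)
  }
  light_id <- vapply(psms_light, function(p) p$spectrum_id, character(1))
  heavy_id <- vapply(psms_heavy, function(p) p$spectrum_id, character(1))
  heavy_used <- logical(length(psms_heavy))
  pairs <- list()
  for (i in order(light_id)) {
    l <- psms_light[[i]]
    n_mods_total <- length(l$peptide$mods)
    expected <- .D4_SHIFT * n_mods_total
    best <- NA_integer_
    best_rt <- Inf
    for (j in order(heavy_id)) {
      if (heavy_used[j]) next
      h <- psms_heavy[[j]]
      dm <- abs(h$precursor_neutral - l$precursor_neutral)
      if (abs(dm - expected) / l$precursor_neutral * 1e6 > precursor_tol_ppm) next
      drt <- abs(h$rt - l$rt)
      if (drt > rt_tol_min) next
      if (!ladder_ok(l, h, n_mods_total)) next
      if (drt < best_rt) {
        best <- j
        best_rt <- drt
      }
    }
    if (!is.na(best)) {
      heavy_used[best] <- TRUE
      h <- psms_heavy[[best]]
      ka <- paste(l$matches$series, l$matches$index, l$matches$charge,
                  l$matches$loss, sep = ":")
      kb <- paste(h$matches$series, h$matches$index, h$matches$charge,
                  h$matches$loss, sep = ":")
      pairs[[length(pairs) + 1L]] <- data.frame(
        light_id = l$spectrum_id, heavy_id = h$spectrum_id,
        mass_diff = h$precursor_neutral - l$precursor_neutral,
        rt_diff = h$rt - l$rt,
        n_shared_ions = length(intersect(ka, kb)))
    }
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(light_id = character(0), heavy_id = character(0),
               mass_diff = numeric(0), rt_diff = numeric(0),
               n_shared_ions = integer(0))
  list(pairs = pairs,
       unpaired_light = setdiff(light_id, pairs$light_id),
       unpaired_heavy = setdiff(heavy_id, pairs$heavy_id))
}
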