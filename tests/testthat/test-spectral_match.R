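m2hg <- mod_2hg()

test_that("spectrum constructor sorts peaks and validates intensities", {
  s <- spectrum("a", 500, 2, 10, c(300, 100, 200), c(1, 2, 3))
  expect_equal(s$mz, c(100, 200, 300))
  expect_equal(s$intensity, c(2, 3, 1))
  expect_error(spectrum("a", 500, 2, 10, 100, -1), "non-negative")
})

test_that("self-match outranks a decoy and survives spurious peaks", {
  target <- peptide("LNSAGTK", mods = list(list(site = 3, spec = m2hg)))
  decoy <- peptide("LNSAGTK", mods = list(list(site = 6, spec = m2hg)))
  sp <- exact_spectrum(target, include_losses = TRUE)
  res <- match_spectrum(sp, list(decoy, target))
  expect_false(res$no_candidate)
  expect_equal(res$best$peptide$mods[[1]]$site, 3)
  expect_gt(res$best$match_score, res$ranked[[2]]$match_score)

  # 20% spurious peaks at random m/z do not change the ranking
  set.seed(405)
  n_spur <- round(0.2 * length(sp$mz))
  sp2 <- spectrum(sp$id, sp$precursor_mz, sp$precursor_charge, sp$rt,
                  c(sp$mz, runif(n_spur, 100, max(sp$mz))),
                  c(sp$intensity, runif(n_spur, 1, 30)))
  res2 <- match_spectrum(sp2, list(decoy, target))
  expect_equal(res2$best$peptide$mods[[1]]$site, 3)
})

test_that("spectra with no peaks or no candidates are handled", {
  target <- peptide("LNSAGTK", mods = list(list(site = 3, spec = m2hg)))
  prec <- precursor_descriptor(target, 2)
  empty <- spectrum("e", prec$mz, 2, 10, numeric(0), numeric(0))
  res <- match_spectrum(empty, list(target))
  expect_equal(res$best$match_score, 0)
  far <- spectrum("f", prec$mz + 50, 2, 10, 500, 1)
  expect_true(match_spectrum(far, list(target))$no_candidate)
})

test_that("site localization recovers planted sites", {
  # single candidate site: sentinel delta
  one <- peptide("GASAK", mods = list(list(site = 3, spec = m2hg)))
  sp1 <- exact_spectrum(one, include_losses = TRUE)
  psm1 <- match_spectrum(sp1, list(one))$best
  loc1 <- localize_site(psm1, sp1)$localization
  expect_equal(loc1$best_site, 3)
  expect_equal(loc1$delta_score, Inf)

  # two sites: planted site wins with positive delta
  for (site in c(2L, 4L)) {
    pep <- peptide("TSASK", mods = list(list(site = site, spec = m2hg)))
    sp <- exact_spectrum(pep, include_losses = TRUE)
    psm <- match_spectrum(sp, list(pep))$best
    loc <- localize_site(psm, sp)$localization
    expect_equal(loc$best_site, site)
    expect_gte(loc$delta_score, 1)
  }

  # spectrum carrying no site-determining ions: ambiguous, delta 0
  pep <- peptide("TSASK", mods = list(list(site = 2, spec = m2hg)))
  prec <- precursor_descriptor(pep, 2)
  blank <- spectrum("b", prec$mz, 2, 10, numeric(0), numeric(0))
  psmb <- match_spectrum(blank, list(pep))$best
  expect_equal(localize_site(psmb, blank)$localization$delta_score, 0)
})

test_that("noisy planted-site recovery stays above 95%", {
  cfg <- sim_config(seed = 17)  # default noise: 20% spurious, jitter CV 0.2
  study <- simulate_study(cfg, n_planted = 300)
  led <- study$ledger
  spectra <- simulate_spectra(led, cfg)
  ok <- vapply(seq_len(nrow(led)), function(i) {
    seqi <- led$sequence[i]
    cands <- lapply(which(strsplit(seqi, "")[[1]] %in% m2hg$targets),
                    function(s) peptide(seqi, mods = list(list(site = s, spec = m2hg))))
    best <- match_spectrum(spectra[[i]], cands, tol_ppm = 10)$best
    loc <- localize_site(best, spectra[[i]], tol_ppm = 10)$localization
    loc$best_site == led$site[i]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("neutral-loss detection reads precursor and fragment channels", {
  pep <- peptide("LNSAGTK", mods = list(list(site = 3, spec = m2hg)))
  prec <- precursor_descriptor(pep, 2)
  frag <- theoretical_fragments(pep, charges = 1L, include_losses = FALSE)
  # plant only a precursor channel-A loss peak at the z=1 position, 4% of base
  loss_pos <- mz(prec$neutral_mass - 130.0266, 1)
  sp <- spectrum("nl", prec$mz, 2, 10,
                 c(frag$mz, loss_pos), c(rep(100, nrow(frag)), 4))
  psm <- match_spectrum(sp, list(pep))$best
  flags <- detect_neutral_loss(psm, sp)$nl_flags
  expect_true(flags$A$precursor_observed)
  expect_false(flags$A$fragment_observed)
  expect_equal(flags$A$relative_abundance, 0.04, tolerance = 1e-6)
  expect_false(flags$B$precursor_observed || flags$B$fragment_observed)
  expect_true(is.na(flags$B$relative_abundance))
  expect_error(detect_neutral_loss(match_spectrum(sp, list(peptide("LNSAGTK")),
                                                  precursor_tol_ppm = 1e6)$best, sp),
               "unmodified")
})

test_that("neutral-loss binning follows the stated abundance boundaries", {
  mk <- function(rel) {
    structure(list(nl_flags = list(
      A = list(precursor_observed = !is.na(rel), fragment_observed = FALSE,
               relative_abundance = rel),
      B = list(precursor_observed = FALSE, fragment_observed = FALSE,
               relative_abundance = NA_real_))), class = "psm")
  }
  psms <- lapply(c(0.06, 0.03, 0.005, NA), mk)
  tab <- nl_frequency_summary(psms)
  a <- tab[tab$channel == "A", ]
  expect_equal(c(a$high, a$mid, a$low, a$absent), c(1, 1, 1, 1))
  expect_equal(sum(a$high, a$mid, a$low, a$absent), length(psms))
  b <- tab[tab$channel == "B", ]
  expect_equal(b$absent, 4)
  # boundary 5% falls in the mid bin; order of PSMs is irrelevant
  expect_equal(nl_frequency_summary(list(mk(0.05)))$mid[1], 1)
  tab_rev <- nl_frequency_summary(rev(psms))
  expect_equal(tab_rev[tab_rev$channel == "A", -1], a[, -1])
})

test_that("heavy/light pairing validates the fragment ladder rule", {
  light <- peptide("LNSAGTK", mods = list(list(site = 3, spec = m2hg)))
  sp_l <- exact_spectrum(light, id = "L1", include_losses = TRUE, rt = 30)
  sp_h <- exact_spectrum(light, id = "H1", heavy = TRUE,
                         include_losses = TRUE, rt = 30.1)
  psm_l <- match_spectrum(sp_l, list(light))$best
  psm_h <- match_spectrum(sp_h, list(light), heavy = TRUE)$best
  res <- find_isotope_pairs(list(psm_l), list(psm_h))
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$mass_diff, d4_shift(), tolerance = 1e-6)

  # symmetry: swapping inputs yields the same pair
  res_swap <- find_isotope_pairs(list(psm_h), list(psm_l))
  expect_equal(nrow(res_swap$pairs), 1L)

  # a light spectrum with no heavy partner is listed unpaired
  lone <- peptide("GASAK", mods = list(list(site = 3, spec = m2hg)))
  sp_lone <- exact_spectrum(lone, id = "L2", include_losses = TRUE, rt = 12)
  psm_lone <- match_spectrum(sp_lone, list(lone))$best
  res2 <- find_isotope_pairs(list(psm_l, psm_lone), list(psm_h))
  expect_equal(res2$unpaired_light, "L2")

  # constructed violation: a non-mod ion shifted in the heavy ladder
  psm_bad <- psm_h
  k <- which(!psm_bad$matches$contains_mod)[1]
  psm_bad$matches$obs_mz[k] <- psm_bad$matches$obs_mz[k] + 0.05
  res3 <- find_isotope_pairs(list(psm_l), list(psm_bad))
  expect_equal(nrow(res3$pairs), 0L)
})

test_that("MGF files round-trip spectra", {
  pep <- peptide("LNSAGTK", mods = list(list(site = 3, spec = m2hg)))
  sps <- list(exact_spectrum(pep, id = "one", rt = 12.5),
              exact_spectrum(peptide("GASAK"), id = "two", rt = 40))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sps, path)
  back <- read_mgf(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$id, "one")
  expect_equal(back[[1]]$mz, sps[[1]]$mz, tolerance = 1e-5)
  expect_equal(back[[1]]$rt, 12.5, tolerance = 1e-5)
  expect_equal(back[[2]]$precursor_charge, 2L)
})
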