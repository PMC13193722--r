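test_that("the generator is deterministic per seed", {
  cfg <- test_config(seed = 5)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  l1 <- plant_modifications(digest_proteome(p1), cfg, n = 20)
  l2 <- plant_modifications(digest_proteome(p2), cfg, n = 20)
  expect_identical(l1, l2)
  a1 <- simulate_abundances(l1, cfg)
  a2 <- simulate_abundances(l2, cfg)
  expect_identical(a1$areas, a2$areas)
  s1 <- simulate_spectra(l1[1:5, ], cfg)
  s2 <- simulate_spectra(l1[1:5, ], cfg)
  expect_identical(s1, s2)
  # a different seed changes the output
  expect_false(identical(p1, generate_proteome(test_config(seed = 6))))
})

test_that("proteome constraints are honoured", {
  expect_length(generate_proteome(test_config(n_proteins = 0)), 0)
  cfg <- test_config(seed = 2)
  prots <- generate_proteome(cfg)
  expect_length(prots, cfg$n_proteins)
  lens <- nchar(prots)
  expect_true(all(lens >= cfg$protein_length[1] &
                    lens <= cfg$protein_length[2]))
  for (p in prots) {
    chars <- strsplit(p, "")[[1]]
    expect_gte(sum(chars %in% c("K", "R")), 2)
    expect_gte(sum(chars %in% c("E", "D")), 2)
    expect_gte(sum(chars %in% c("S", "T", "Y")), 2)
  }
  expect_error(sim_config(protein_length = c(0L, 0L)), "infeasible")
})

test_that("planted sites follow the configured residue weights", {
  cfg <- sim_config(seed = 9)
  peptides <- digest_proteome(generate_proteome(cfg))
  ledger <- plant_modifications(peptides, cfg, n = 1000)
  expect_true(all(ledger$residue %in% c("S", "T", "Y")))
  props <- prop.table(table(factor(ledger$residue, c("S", "T", "Y"))))
  expect_equal(unname(props["S"]), 0.6, tolerance = 0.1)  # +/- 0.05 absolute
  expect_lt(abs(props[["S"]] - 0.6), 0.05)
  expect_lt(abs(props[["T"]] - 0.3), 0.05)
  expect_lt(abs(props[["Y"]] - 0.1), 0.05)
})

test_that("enantiomer assignment follows the configured probabilities", {
  cfg <- sim_config(seed = 10)
  peptides <- digest_proteome(generate_proteome(cfg))
  ledger <- plant_modifications(peptides, cfg, n = 500)
  props <- prop.table(table(factor(ledger$enantiomer, c("D", "L", "shared"))))
  expect_lt(abs(props[["D"]] - 0.45), 0.06)
  expect_lt(abs(props[["L"]] - 0.45), 0.06)
  expect_lt(abs(props[["shared"]] - 0.10), 0.06)
  # no planting requested -> empty ledger
  expect_equal(nrow(plant_modifications(peptides, cfg, n = 0)), 0L)
})

test_that("noiseless abundances hit the planted fold change exactly", {
  cfg <- test_config(seed = 3, abundance_cv = 0, n_background = 0L)
  peptides <- digest_proteome(generate_proteome(cfg))
  ledger <- plant_modifications(peptides, cfg, n = 10)
  ledger$true_fc <- 2
  am <- simulate_abundances(ledger, cfg)
  smp <- am$samples
  d_ids <- ledger$peptide_id[ledger$enantiomer == "D"]
  l_ids <- ledger$peptide_id[ledger$enantiomer == "L"]
  top_d <- smp$series == "D2HG" & smp$dose == 20
  veh <- smp$series == "vehicle"
  ratio <- rowMeans(am$areas[, top_d, drop = FALSE]) /
    rowMeans(am$areas[, veh, drop = FALSE])
  if (length(d_ids) > 0) expect_equal(unname(ratio[d_ids]),
                                      rep(2, length(d_ids)), tolerance = 1e-12)
  # the non-matching series stays flat
  if (length(l_ids) > 0) expect_equal(unname(ratio[l_ids]),
                                      rep(1, length(l_ids)), tolerance = 1e-12)
  # classify recovers 100% of planted peptides at top dose in this limit
  res <- classify_modified(am, "D2HG_20", "vehicle_0")
  expect_true(all(res$passed[match(d_ids, res$peptide)]))
  expect_false(any(res$passed[match(l_ids, res$peptide)]))
})

test_that("simulated spectra carry losses, heavy shifts, and RT structure", {
  cfg <- test_config(seed = 4, spurious_peak_fraction = 0,
                     intensity_jitter_cv = 0, rt_noise_sd = 0,
                     nl_probability = c(A = 1, B = 1))
  peptides <- digest_proteome(generate_proteome(cfg))
  ledger <- plant_modifications(peptides, cfg, n = 12)
  sp <- simulate_spectra(ledger, cfg)
  sp_h <- simulate_spectra(ledger, cfg, heavy = TRUE)
  sp_u <- simulate_spectra(ledger, cfg, modified = FALSE)
  for (i in seq_len(nrow(ledger))) {
    pep <- peptide(ledger$sequence[i],
                   mods = list(list(site = ledger$site[i], spec = mod_2hg())))
    psm <- match_spectrum(sp[[i]], list(pep))$best
    flags <- detect_neutral_loss(psm, sp[[i]])$nl_flags
    expect_true(flags$A$precursor_observed || flags$A$fragment_observed)
    expect_true(flags$B$precursor_observed || flags$B$fragment_observed)
    # heavy precursor sits exactly one d4 shift above the light precursor
    dm <- neutral_mass(sp_h[[i]]$precursor_mz, sp_h[[i]]$precursor_charge) -
      neutral_mass(sp[[i]]$precursor_mz, sp[[i]]$precursor_charge)
    expect_equal(dm, d4_shift(), tolerance = 1e-6)
    # modified peptides elute later than their unmodified counterparts
    expect_gt(sp[[i]]$rt, sp_u[[i]]$rt)
  }
})

test_that("null matrices have no structure for the classifier to find", {
  am <- simulate_null_abundances(300, seed = 21)
  res <- classify_modified(am, "treated", "control")
  expect_lt(mean(res$passed), 0.05)
  expect_equal(dim(am$areas), c(300L, 6L))
})
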