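make_am <- function(areas, conditions, series = conditions,
                    dose = as.numeric(factor(conditions)) - 1) {
  smp <- data.frame(sample = paste0("s", seq_len(ncol(areas))),
                    condition = conditions, series = series, dose = dose,
                    replicate = stats::ave(seq_len(ncol(areas)), conditions,
                                           FUN = seq_along))
  colnames(areas) <- smp$sample
  abundance_matrix(areas, smp)
}

test_that("TIC normalization equalizes column sums at the median TIC", {
  areas <- matrix(c(40, 60, 50, 150), 2, 2,
                  dimnames = list(c("p1", "p2"), NULL))
  am <- make_am(areas, c("a", "b"))
  norm <- tic_normalize(am)
  expect_equal(unname(colSums(norm$areas)), c(150, 150))
  # already-equal columns are unchanged
  eq <- make_am(matrix(c(1, 2, 1, 2), 2, 2), c("a", "b"))
  expect_equal(tic_normalize(eq)$areas, eq$areas)
  zero <- make_am(matrix(c(1, 2, 0, 0), 2, 2), c("a", "b"))
  expect_error(tic_normalize(zero), "s2")
})

test_that("raw-scale classification matches the hand-computed Welch oracle", {
  areas <- rbind(p1 = c(10, 11, 12, 14, 15, 16))
  am <- make_am(areas, rep(c("control", "treated"), each = 3))
  res <- classify_modified(am, "treated", "control", var_equal = FALSE,
                           log_transform = FALSE)
  expect_equal(res$fold_change, 15 / 11, tolerance = 1e-9)
  expect_equal(res$p_value, 0.008050, tolerance = 1e-3)
  expect_true(res$passed)
})

test_that("both classification gates must pass, and degenerate rows are flagged", {
  areas <- rbind(
    fc_only = c(100, 100, 100, 110, 110, 110),   # FC 1.1, p ~ 0
    identical = c(50, 50, 50, 50, 50, 50),        # FC 1
    zeroctrl = c(0, 0, 0, 10, 11, 12))            # control mean 0
  am <- make_am(areas, rep(c("control", "treated"), each = 3))
  res <- classify_modified(am, "treated", "control")
  expect_equal(res$passed, c(FALSE, FALSE, FALSE))
  expect_equal(res$fold_change[1], 1.1)
  expect_equal(res$fold_change[2], 1)
  expect_true(res$flagged[3])
  expect_true(is.na(res$fold_change[3]))
})

test_that("noiseless dose-responsive data is classified with certainty", {
  areas <- rbind(up = c(100, 100, 100, 200, 200, 200))
  am <- make_am(areas, rep(c("control", "treated"), each = 3))
  res <- classify_modified(am, "treated", "control")
  expect_equal(res$fold_change, 2)
  expect_equal(res$p_value, 0)
  expect_true(res$passed)
})

test_that("chirality calls follow the dose-response rule", {
  # noiseless: peptide responds in D only, in both, or in one dose only
  conds <- c(rep("vehicle_0", 3),
             rep(c("D2HG_5", "D2HG_10", "D2HG_20"), each = 3),
             rep(c("L2HG_5", "L2HG_10", "L2HG_20"), each = 3))
  series <- c(rep("vehicle", 3), rep("D2HG", 9), rep("L2HG", 9))
  dose <- c(rep(0, 3), rep(c(5, 10, 20), each = 3), rep(c(5, 10, 20), each = 3))
  base <- rep(100, 3)
  d_resp <- c(base, base * 1.5, base * 1.8, base * 2.5, base, base, base)
  both <- c(base, base * 1.5, base * 1.8, base * 2.5,
            base * 1.4, base * 1.7, base * 2.2)
  one_dose <- c(base, base, base, base * 2.5, base, base, base)
  areas <- rbind(donly = d_resp, shared = both, onedose = one_dose)
  colnames(areas) <- paste0("s", 1:21)
  am <- abundance_matrix(areas, data.frame(
    sample = colnames(areas), condition = conds, series = series,
    dose = dose, replicate = rep(1:3, 7)))
  res <- chirality_call(am)
  calls <- setNames(res$calls$call, res$calls$peptide)
  expect_equal(unname(calls["donly"]), "D")
  expect_equal(unname(calls["shared"]), "shared")
  expect_equal(unname(calls["onedose"]), "ambiguous")
  ev <- res$evidence
  expect_true(all(ev$passed[ev$peptide == "donly" & ev$series == "D2HG"]))
  expect_false(any(ev$passed[ev$peptide == "donly" & ev$series == "L2HG"]))
})

test_that("non-monotone dose profiles are not called", {
  conds <- c(rep("vehicle_0", 3),
             rep(c("D2HG_5", "D2HG_10", "D2HG_20"), each = 3),
             rep(c("L2HG_5", "L2HG_10", "L2HG_20"), each = 3))
  series <- c(rep("vehicle", 3), rep("D2HG", 9), rep("L2HG", 9))
  dose <- c(rep(0, 3), rep(c(5, 10, 20), each = 3), rep(c(5, 10, 20), each = 3))
  base <- rep(100, 3)
  # strong response at low dose that collapses at high dose
  areas <- rbind(peak = c(base, base * 3, base * 2.9, base * 1.3,
                          base, base, base))
  colnames(areas) <- paste0("s", 1:21)
  am <- abundance_matrix(areas, data.frame(
    sample = colnames(areas), condition = conds, series = series,
    dose = dose, replicate = rep(1:3, 7)))
  expect_equal(chirality_call(am)$calls$call, "ambiguous")
})

test_that("cross-group high-confidence filtering keeps consistent calls", {
  gc <- data.frame(
    peptide = c("a", "a", "a", "b", "c", "c", "d", "d"),
    group = c("g1", "g2", "g3", "g1", "g1", "g2", "g1", "g2"),
    call = c("D", "D", "D", "D", "D", "L", "ambiguous", "ambiguous"))
  out <- high_confidence_filter(gc)
  expect_equal(out$peptide, "a")
  expect_equal(out$n_groups, 3L)
  # min_groups = 1 admits single-group calls but still drops conflicts
  out1 <- high_confidence_filter(gc, min_groups = 1)
  expect_setequal(out1$peptide, c("a", "b"))
})

test_that("overlap analysis reproduces the published set arithmetic", {
  shared <- sprintf("shared%02d", 1:16)
  a <- c(shared, sprintf("donly%02d", 1:40))   # 56 D2HG high-confidence
  b <- c(shared, sprintf("lonly%03d", 1:114))  # 130 L2HG high-confidence
  ov <- overlap_sets(a, b)
  expect_equal(unname(ov$counts["a_specific"]), 40L)
  expect_equal(unname(ov$counts["b_specific"]), 114L)
  expect_equal(unname(ov$counts["shared"]), 16L)
  expect_equal(unname(ov$counts["a_specific"] + ov$counts["shared"]), 56L)
  expect_equal(unname(ov$counts["b_specific"] + ov$counts["shared"]), 130L)
  expect_equal(overlap_sets(c("x"), c("y"))$counts[["shared"]], 0L)
  same <- overlap_sets(a, a)
  expect_equal(same$counts[["a_specific"]], 0L)
  expect_equal(same$counts[["b_specific"]], 0L)
})

test_that("occupancy is the modified fraction with flagged degenerate input", {
  expect_equal(occupancy(25, 75), 0.25)
  expect_equal(occupancy(0, 10), 0)
  expect_equal(occupancy(10, 0), 1)
  expect_warning(res <- occupancy(c(1, 0), c(1, 0)), "undefined")
  expect_equal(res, c(0.5, NA))
  expect_error(occupancy(-1, 1), "non-negative")
})

test_that("paired RT test matches the hand-computed oracle", {
  rt_u <- c(10, 20, 30, 40)
  rt_m <- rt_u + c(0.8, 1.0, 1.2, 1.0)
  res <- paired_rt_test(rt_m, rt_u)
  expect_equal(res$mean_delta, 1.0)
  expect_equal(res$p_value, 0.001172, tolerance = 1e-3)
  expect_false(res$degenerate)
  # sign symmetry
  flip <- paired_rt_test(rt_u, rt_m)
  expect_equal(flip$mean_delta, -1.0)
  expect_equal(flip$p_value, res$p_value)
  # zero-variance deltas are reported degenerate
  deg <- paired_rt_test(rt_u + 1, rt_u)
  expect_true(deg$degenerate)
  expect_equal(deg$mean_delta, 1)
  expect_true(is.na(deg$p_value))
})
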