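## TIC normalization, the fold-change / p-value classification rule,
## dose-response chirality assignment, high-confidence filtering, overlap
## sets, occupancy, and the paired retention-time shift test.

#' Construct a peptide-by-sample abundance matrix
#'
#' @param areas Numeric matrix of peak areas (rows = peptide identifiers,
#'   columns = samples), all values >= 0.
#' @param samples Data frame with columns `sample`, `condition`, `series`,
#'   `dose`, `replicate`; one row per column of `areas`, in order.
#' @return An `abundance_matrix`.
#' @export
abundance_matrix <- function(areas, samples) {
  stopifnot(is.matrix(areas), nrow(samples) == ncol(areas))
  req <- c("sample", "condition", "series", "dose", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    stop("samples table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(areas < 0)) stop("peak areas must be non-negative")
  if (is.null(colnames(areas))) colnames(areas) <- samples$sample
  structure(list(areas = areas, samples = samples,
                 normalized = FALSE, tic = NULL),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix> ", nrow(x$areas), " peptides x ", ncol(x$areas),
      " samples (", length(unique(x$samples$condition)), " conditions",
      if (x$normalized) ", TIC-normalized", ")\n", sep = "")
  invisible(x)
}

#' Normalize peak areas to total ion current
#'
#' Each column is divided by its TIC (supplied, or computed as the column
#' sum) and rescaled by the median TIC, so that when TIC = column sum all
#' post-normalization column sums are equal.
#'
#' @param am An [abundance_matrix()].
#' @param tic Optional per-sample TIC values (named or in column order).
#' @return The normalized `abundance_matrix`.
#' @export
tic_normalize <- function(am, tic = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (is.null(tic)) tic <- colSums(am$areas)
  if (any(tic <= 0)) {
    bad <- colnames(am$areas)[tic <= 0]
    stop("non-positive TIC for sample(s): ", paste(bad, collapse = ", "))
  }
  ref <- stats::median(tic)
  am$areas <- sweep(am$areas, 2, ref / tic, `*`)
  am$normalized <- TRUE
  am$tic <- tic
  am
}

# Core FC / t-test classifier on two matrices of replicate areas.
# Fold change is always the ratio of raw-scale means; the t-test runs on
# log areas by default (peak areas are lognormal, so t-test assumptions
# hold on the log scale), falling back to the raw scale on request or when
# zeros make the log undefined.
.classify_mats <- function(tmat, cmat, fc_threshold, alpha, var_equal,
                           log_transform = TRUE) {
  stopifnot(ncol(tmat) >= 2, ncol(cmat) >= 2)
  n <- nrow(tmat)
  fc <- p <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tv <- tmat[i, ]
    cv <- cmat[i, ]
    mc <- mean(cv)
    mt <- mean(tv)
    if (mc == 0) {
      flagged[i] <- TRUE
      next
    }
    fc[i] <- mt / mc
    use_log <- log_transform && all(tv > 0) && all(cv > 0)
    xt <- if (use_log) log(tv) else tv
    xc <- if (use_log) log(cv) else cv
    if (stats::sd(xt) == 0 && stats::sd(xc) == 0) {
      # degenerate noiseless limit: means differ => certain, equal => null
      p[i] <- if (isTRUE(all.equal(mt, mc))) 1 else 0
    } else {
      p[i] <- tryCatch(
        stats::t.test(xt, xc, var.equal = var_equal)$p.value,
        error = function(e) NA_real_)
    }
  }
  list(fold_change = fc, p_value = p, flagged = flagged)
}

#' Classify peptides as modification-responsive
#'
#' Fold change is the ratio of treated to control replicate means on
#' (normalized) areas; the p-value comes from a two-tailed two-sample
#' t-test (Welch by default), without multiple-testing adjustment unless
#' requested. A peptide passes when fold change > `fc_threshold` AND
#' p < `alpha`.
#'
#' @param am An [abundance_matrix()] (normalize first with
#'   [tic_normalize()]).
#' @param treated,control Condition labels in `am$samples$condition`.
#' @param fc_threshold Fold-change gate (default 1.2).
#' @param alpha Significance gate (default 0.05).
#' @param var_equal Pooled-variance (Student) t-test, the default: with
#'   n = 3 replicates per group the Welch-Satterthwaite approximation is
#'   markedly conservative (type I error about 0.033 at nominal 0.05), and
#'   replicate groups share one CV by design. Set FALSE for Welch.
#' @param log_transform Run the t-test on log areas (default TRUE; peak
#'   areas are lognormal so t-test assumptions hold on the log scale).
#'   Fold change is always the ratio of raw-scale means.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame: peptide, fold_change, p_value, passed, flagged
#'   (TRUE when the control mean is zero and no call can be made).
#' @export
classify_modified <- function(am, treated, control, fc_threshold = 1.2,
                              alpha = 0.05, var_equal = TRUE,
                              log_transform = TRUE,
                              p_adjust = c("none", "BH")) {
  stopifnot(inherits(am, "abundance_matrix"))
  p_adjust <- match.arg(p_adjust)
  tcol <- am$samples$condition == treated
  ccol <- am$samples$condition == control
  if (sum(tcol) < 2 || sum(ccol) < 2) {
    stop("need >= 2 replicates per group (treated: ", sum(tcol),
         ", control: ", sum(ccol), ")")
  }
  res <- .classify_mats(am$areas[, tcol, drop = FALSE],
                        am$areas[, ccol, drop = FALSE],
                        fc_threshold, alpha, var_equal, log_transform)
  p <- res$p_value
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(
    peptide = rownames(am$areas),
    fold_change = res$fold_change,
    p_value = p,
    passed = !res$flagged & !is.na(res$fold_change) & !is.na(p) &
      res$fold_change > fc_threshold & p < alpha,
    flagged = res$flagged,
    row.names = NULL
  )
}

.mono_ok <- function(fc, tol) {
  if (length(fc) < 2) return(TRUE)
  if (any(!is.finite(fc))) return(FALSE)
  m <- cummax(fc)
  all(fc[-1] >= (1 - tol) * m[-length(m)])
}

#' Assign an enantiomer (chirality call) per peptide
#'
#' A dose series "responds" when at least `min_passing_doses` nonzero dose
#' levels pass the fold-change/p-value rule against vehicle AND the fold
#' changes are non-decreasing in dose (within a relative tolerance
#' `mono_tol` that absorbs replicate noise). A peptide is called D when
#' only the D series responds, L when only the L series responds, shared
#' when both do, ambiguous otherwise.
#'
#' @param am An [abundance_matrix()].
#' @param d_series,l_series,vehicle_series Labels in `am$samples$series`.
#' @param min_passing_doses Minimum passing dose levels per series.
#' @param fc_threshold,alpha,var_equal As in [classify_modified()].
#' @param mono_tol Relative tolerance of the monotonicity check.
#' @param log_transform As in [classify_modified()].
#' @return List: `calls` (peptide, call, d_responds, l_responds) and
#'   `evidence` (peptide, series, dose, fold_change, p_value, passed).
#' @export
chirality_call <- function(am, d_series = "D2HG", l_series = "L2HG",
                           vehicle_series = "vehicle",
                           min_passing_doses = 2, fc_threshold = 1.2,
                           alpha = 0.05, mono_tol = 0.2, var_equal = TRUE,
                           log_transform = TRUE) {
  stopifnot(inherits(am, "abundance_matrix"))
  smp <- am$samples
  vcol <- smp$series == vehicle_series
  if (sum(vcol) < 2) stop("need >= 2 vehicle replicates")
  cmat <- am$areas[, vcol, drop = FALSE]
  peptides <- rownames(am$areas)
  evidence <- list()
  responds <- list()
  for (s in c(d_series, l_series)) {
    doses <- sort(unique(smp$dose[smp$series == s & smp$dose > 0]))
    if (length(doses) < 2) stop("series '", s, "' needs >= 2 nonzero doses")
    fc_mat <- p_mat <- pass_mat <- matrix(NA_real_, length(peptides),
                                          length(doses))
    for (k in seq_along(doses)) {
      tcol <- smp$series == s & smp$dose == doses[k]
      res <- .classify_mats(am$areas[, tcol, drop = FALSE], cmat,
                            fc_threshold, alpha, var_equal, log_transform)
      fc_mat[, k] <- res$fold_change
      p_mat[, k] <- res$p_value
      pass_mat[, k] <- !res$flagged & !is.na(res$fold_change) &
        !is.na(res$p_value) & res$fold_change > fc_threshold &
        res$p_value < alpha
      evidence[[length(evidence) + 1L]] <- data.frame(
        peptide = peptides, series = s, dose = doses[k],
        fold_change = res$fold_change, p_value = res$p_value,
        passed = as.logical(pass_mat[, k]))
    }
    responds[[s]] <- vapply(seq_along(peptides), function(i) {
      sum(pass_mat[i, ], na.rm = TRUE) >= min_passing_doses &&
        .mono_ok(fc_mat[i, ], mono_tol)
    }, logical(1))
  }
  d_ok <- responds[[d_series]]
  l_ok <- responds[[l_series]]
  call <- ifelse(d_ok & l_ok, "shared",
          ifelse(d_ok, "D", ifelse(l_ok, "L", "ambiguous")))
  list(
    calls = data.frame(peptide = peptides, call = call,
                       d_responds = d_ok, l_responds = l_ok,
                       row.names = NULL),
    evidence = do.call(rbind, evidence)
  )
}

#' Cross-group high-confidence filter
#'
#' Retains peptides carrying the same non-ambiguous call in at least
#' `min_groups` independent dataset groups; peptides with conflicting
#' calls across groups are dropped.
#'
#' @param group_calls Data frame with columns `peptide`, `group`, `call`
#'   (values D / L / shared / ambiguous).
#' @param min_groups Minimum supporting groups.
#' @return Data frame: peptide, call, n_groups.
#' @export
high_confidence_filter <- function(group_calls, min_groups = 2) {
  stopifnot(all(c("peptide", "group", "call") %in% names(group_calls)))
  x <- group_calls[group_calls$call != "ambiguous", , drop = FALSE]
  if (nrow(x) == 0) {
    return(data.frame(peptide = character(0), call = character(0),
                      n_groups = integer(0)))
  }
  out <- lapply(split(x, x$peptide), function(d) {
    if (length(unique(d$call)) != 1) return(NULL)  # conflicting enantiomers
    ng <- length(unique(d$group))
    if (ng < min_groups) return(NULL)
    data.frame(peptide = d$peptide[1], call = d$call[1], n_groups = ng)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(peptide = character(0), call = character(0),
                      n_groups = integer(0)))
  }
  rownames(out) <- NULL
  out
}

#' Overlap analysis of two identifier sets
#'
#' @param a,b Character vectors of peptide/site identifiers.
#' @return List: `a_specific`, `b_specific`, `shared` (identifier vectors)
#'   and `counts` (named sizes; a_specific + shared = |A| etc.).
#' @export
overlap_sets <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  shared <- intersect(a, b)
  a_specific <- setdiff(a, b)
  b_specific <- setdiff(b, a)
  list(a_specific = a_specific, b_specific = b_specific, shared = shared,
       counts = c(a = length(a), b = length(b),
                  a_specific = length(a_specific),
                  b_specific = length(b_specific),
                  shared = length(shared)))
}

#' Semi-quantitative modification occupancy
#'
#' @param modified_area,unmodified_area Peak areas (>= 0); vectorized.
#' @return modified / (modified + unmodified); NA (with a warning) where
#'   both are zero.
#' @export
occupancy <- function(modified_area, unmodified_area) {
  if (any(modified_area < 0) || any(unmodified_area < 0)) {
    stop("areas must be non-negative")
  }
  total <- modified_area + unmodified_area
  out <- ifelse(total == 0, NA_real_, modified_area / total)
  if (any(total == 0)) {
    warning("occupancy undefined where modified and unmodified areas are both zero")
  }
  out
}

#' Paired retention-time shift test
#'
#' Tests whether modified peptides elute later than their unmodified
#' counterparts: paired two-tailed t-test on rt_modified - rt_unmodified.
#'
#' @param rt_modified,rt_unmodified Retention times (minutes), paired.
#' @return List: mean_delta, p_value, t, df, n, degenerate (TRUE when the
#'   deltas have zero variance, in which case p is NA).
#' @export
paired_rt_test <- function(rt_modified, rt_unmodified) {
  stopifnot(length(rt_modified) == length(rt_unmodified))
  n <- length(rt_modified)
  if (n < 3) stop("need >= 3 pairs")
  d <- rt_modified - rt_unmodified
  if (stats::sd(d) == 0) {
    return(list(mean_delta = mean(d), p_value = NA_real_, t = NA_real_,
                df = n - 1L, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(rt_modified, rt_unmodified, paired = TRUE)
  list(mean_delta = unname(tt$estimate), p_value = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter), n = n,
       degenerate = FALSE)
}
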