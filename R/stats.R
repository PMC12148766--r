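# Reader agreement, the peritumoral heterogeneity criterion, and the paired
# nonparametric testing of dose-function differences.

#' Binary reader-agreement summary
#'
#' Compares per-patient binary defect calls of a test arm against a
#' reference arm treated as ground truth, with or without attention to the
#' called lobe. In location mode a test positive counts as a true positive
#' only when its called lobe matches a reference called lobe; a
#' wrong-location positive on a reference-positive patient is scored as
#' discordant (a false positive), the stricter reading.
#'
#' @param reference,test data.frames with columns `patient`, `call`
#'   (logical), `location` (lobe label or `"none"`), e.g. from
#'   [simulate_reader()].
#' @param use_location score lobe agreement in addition to presence.
#' @param lobe_match `"any"` (default) or `"all"`: how multiple called
#'   lobes (comma-separated) must match in location mode.
#' @return A list of class `confusion_summary`: counts `tp`, `fp`, `tn`,
#'   `fn`, `n` and rates `sensitivity`, `precision`, `specificity`,
#'   `accuracy` (`NaN` with `undefined_rates` flag when a denominator is 0).
#' @export
binary_agreement <- function(reference, test, use_location = FALSE,
                             lobe_match = c("any", "all")) {
  lobe_match <- match.arg(lobe_match)
  if (!setequal(reference$patient, test$patient) ||
      anyDuplicated(reference$patient) || anyDuplicated(test$patient)) {
    extra <- c(setdiff(reference$patient, test$patient),
               setdiff(test$patient, reference$patient))
    stop_("patient sets differ or are duplicated (symmetric difference: %s)",
          paste(unique(extra), collapse = ", "))
  }
  test <- test[match(reference$patient, test$patient), ]
  rpos <- as.logical(reference$call)
  tpos <- as.logical(test$call)
  if (use_location) {
    split_lobes <- function(x) strsplit(as.character(x), ",[ ]*")
    rl <- split_lobes(reference$location)
    tl <- split_lobes(test$location)
    loc_ok <- vapply(seq_along(rl), function(i) {
      if (!rpos[i] || !tpos[i]) return(FALSE)
      if (lobe_match == "any") length(intersect(tl[[i]], rl[[i]])) > 0
      else all(tl[[i]] %in% rl[[i]]) && all(rl[[i]] %in% tl[[i]])
    }, logical(1))
    tp <- sum(tpos & rpos & loc_ok)
    fp <- sum(tpos & !rpos) + sum(tpos & rpos & !loc_ok)
    fn <- sum(!tpos & rpos)
    tn <- sum(!tpos & !rpos)
  } else {
    tp <- sum(tpos & rpos)
    fp <- sum(tpos & !rpos)
    fn <- sum(!tpos & rpos)
    tn <- sum(!tpos & !rpos)
  }
  n <- length(rpos)
  rate <- function(num, den) if (den == 0) NaN else num / den
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
              sensitivity = rate(tp, tp + fn),
              precision = rate(tp, tp + fp),
              specificity = rate(tn, tn + fp),
              accuracy = (tp + tn) / n)
  out$undefined_rates <- any(is.nan(unlist(out[c("sensitivity", "precision", "specificity")])))
  structure(out, class = "confusion_summary")
}

#' @exportS3Method base::print
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> n=%d TP=%d FP=%d TN=%d FN=%d | sens %.3f prec %.3f spec %.3f acc %.3f\n",
              x$n, x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$precision,
              x$specificity, x$accuracy))
  invisible(x)
}

#' Peritumoral lung-function heterogeneity criterion
#'
#' Quantifies the relative decrease of lung function near the tumor: the
#' peritumoral shell is the morphological expansion of the tumor by
#' `shell_mm` intersected with the lung, minus the tumor itself, and the
#' decrease is `1 - mean(f | shell) / mean(f | lung \ tumor)`. The
#' criterion passes when the decrease is at least `threshold` (inclusive;
#' the default 0.15 is the 15% functional-deficit trial entry level).
#'
#' @param f a [function_image()].
#' @param tumor_mask,lung_mask logical arrays (or `lung_mask`s) on the same
#'   grid.
#' @param shell_mm expansion radius in mm.
#' @param threshold required relative decrease.
#' @return list(`decrease`, `pass`, `n_shell`).
#' @export
heterogeneity_criterion <- function(f, tumor_mask, lung_mask, shell_mm = 30,
                                    threshold = 0.15) {
  tm <- as_mask_array(tumor_mask)
  lm <- as_mask_array(lung_mask)
  stopifnot(identical(dim(tm), f$dim), identical(dim(lm), f$dim))
  if (!any(tm)) stop_("tumor mask is empty")
  dm <- f$dim
  tix <- which(tm)
  lix <- which(lm & !tm)
  if (!length(lix)) stop_("no lung voxels outside the tumor")
  tw <- world_coords(arrayInd(tix, dm), f$spacing, f$origin)
  lw <- world_coords(arrayInd(lix, dm), f$spacing, f$origin)
  # min distance to any tumor voxel, chunked to bound memory
  mind <- rep(Inf, length(lix))
  step <- max(1L, floor(2e7 / length(tix)))
  for (s in seq(1L, length(lix), by = step)) {
    e <- min(s + step - 1L, length(lix))
    d2 <- outer(rowSums(lw[s:e, , drop = FALSE]^2), rowSums(tw^2), "+") -
      2 * lw[s:e, , drop = FALSE] %*% t(tw)
    mind[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  shell <- lix[mind <= shell_mm]
  shell <- shell[!is.na(f$values[shell])]
  if (!length(shell)) stop_("peritumoral shell is empty")
  lung_vals <- f$values[lix]
  lung_vals <- lung_vals[!is.na(lung_vals)]
  decrease <- 1 - mean(f$values[shell]) / mean(lung_vals)
  list(decrease = decrease, pass = decrease >= threshold,
       n_shell = length(shell))
}

#' Friedman test across methods with patients as blocks
#'
#' Mid-ranks within each patient; the chi-square statistic
#' `Q = 12 n / (k (k + 1)) * sum_j (Rbar_j - (k + 1) / 2)^2` with the
#' standard tie correction, referred to a chi-square with `k - 1` degrees
#' of freedom. Fully tied data yield statistic 0 and p 1.
#'
#' @param values numeric matrix, patients x methods, no missing cells.
#' @param alpha significance level for the returned flag.
#' @return A list of class `paired_test_result`: `comparison`, `statistic`,
#'   `df`, `p_value`, `alpha`, `significant`.
#' @export
friedman_test <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop_("need at least 2 patients and 2 methods")
  if (anyNA(values)) stop_("missing cells are not supported (no imputation)")
  R <- t(apply(values, 1L, rank))
  rbar <- colMeans(R)
  Q <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  ties <- apply(values, 1L, function(row) {
    t <- table(row); sum(t^3 - t)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  stat <- if (C <= 0) 0 else Q / C
  p <- if (C <= 0) 1 else pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(comparison = "friedman", statistic = stat, df = k - 1,
                 p_value = p, alpha = alpha, significant = p < alpha),
            class = "paired_test_result")
}

#' @exportS3Method base::print
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> %s: statistic %.4g, p %.4g (alpha %.3g)%s\n",
              x$comparison, x$statistic, x$p_value, x$alpha,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

# two-sided Wilcoxon signed-rank p-value for differences d (zeros dropped).
# Exact via the signed-rank distribution when n <= exact_max and |d| is
# tie-free, else normal approximation with tie and continuity corrections.
signed_rank_p <- function(d, exact_max = 25L, continuity = TRUE) {
  n_in <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(p = 1, statistic = NA_real_, n = 0L, zeros_dropped = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  tied <- anyDuplicated(abs(d)) > 0L
  if (n <= exact_max && !tied) {
    p <- 2 * min(psignrank(W, n), psignrank(W - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- W - mu
    if (continuity) z <- z - sign(z) * 0.5
    z <- z / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(p = p, statistic = W, n = n, zeros_dropped = n < n_in)
}

#' Post-hoc pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Two-sided signed-rank test of each test arm against the reference arm.
#' Zero differences are dropped (their count is reported). The
#' family-wise alpha is divided by the number of comparisons and truncated
#' (not rounded) to 3 decimals, so 0.05 over 3 comparisons gives the
#' conventional 0.016.
#'
#' @param reference numeric vector of per-patient reference values.
#' @param tests named list of numeric vectors (same length), one per
#'   comparison.
#' @param family_alpha family-wise significance level.
#' @param m number of comparisons for the correction (default
#'   `length(tests)`).
#' @return list of `paired_test_result`s, one per comparison; each carries
#'   `statistic` (W), `p_value`, `alpha` (adjusted), `significant`,
#'   `n_used` and `all_zero` flag.
#' @export
posthoc_wilcoxon <- function(reference, tests, family_alpha = 0.05,
                             m = length(tests)) {
  stopifnot(is.list(tests), length(tests) >= 1L, !is.null(names(tests)))
  adj <- floor(family_alpha / m * 1000) / 1000
  out <- lapply(names(tests), function(nm) {
    d <- tests[[nm]] - reference
    if (length(d) != length(reference)) stop_("unequal sample sizes for %s", nm)
    nz <- sum(d != 0)
    if (nz == 0L) {
      return(structure(list(comparison = nm, statistic = NA_real_,
                            p_value = 1, alpha = adj, significant = FALSE,
                            n_used = 0L, all_zero = TRUE),
                       class = "paired_test_result"))
    }
    if (nz < 5L) stop_("fewer than 5 nonzero differences for %s", nm)
    sr <- signed_rank_p(d)
    structure(list(comparison = nm, statistic = sr$statistic,
                   p_value = sr$p, alpha = adj,
                   significant = sr$p < adj, n_used = sr$n,
                   all_zero = FALSE),
              class = "paired_test_result")
  })
  names(out) <- names(tests)
  out
}

#' Type-I error calibration of the post-hoc test
#'
#' Simulates `n_families` families of `m` null comparisons (paired samples
#' drawn from the same distribution), applies the signed-rank test at the
#' Bonferroni-adjusted alpha, and reports the empirical rejection rate with
#' its binomial standard error. The p-value path is identical to
#' [posthoc_wilcoxon()] (verified in the test suite); the simulation is
#' vectorized for speed.
#'
#' @param n_families number of simulated families.
#' @param m comparisons per family.
#' @param n paired samples per comparison.
#' @param family_alpha family-wise level before correction.
#' @param seed integer seed.
#' @return list(`rate`, `alpha`, `n_tests`, `se`).
#' @export
wilcoxon_null_calibration <- function(n_families = 5000L, m = 3L, n = 63L,
                                      family_alpha = 0.05, seed = NULL) {
  adj <- floor(family_alpha / m * 1000) / 1000
  with_seed(seed, {
    total <- n_families * m
    p <- numeric(total)
    for (i in seq_len(total)) {
      d <- rnorm(n)
      p[i] <- signed_rank_p(d)$p
    }
    rate <- mean(p < adj)
    list(rate = rate, alpha = adj, n_tests = total,
         se = sqrt(adj * (1 - adj) / total))
  })
}
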