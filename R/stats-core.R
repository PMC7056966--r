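## Statistical primitives used by every pipeline stage: 2x2 chi-square,
## Wald-Wolfowitz runs test, BH-FDR, the nested treatment/line mixed model,
## ddPCR Poisson quantification and one-tailed Welch t-tests.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Tests homogeneity of two sequence classes (rows) with respect to
#' variant/invariant site counts (columns).  No continuity correction is
#' applied: the densities being contrasted come from thousands of sites, where
#' the Yates correction only biases the statistic downwards.
#'
#' @param table 2x2 matrix of non-negative counts (rows = sequence classes,
#'   columns = variant/invariant sites).
#' @return list with `statistic`, `dof` (always 1) and `p`.
#' @examples
#' # synonymous vs intergenic: variant and invariant site counts
#' chi_square_2x2(matrix(c(19, 6922, 987, 292055), nrow = 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("'table' must be 2x2")
  if (any(table < 0) || any(!is.finite(table))) stop("counts must be non-negative and finite")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: table is untestable")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Wald-Wolfowitz runs test for serial association
#'
#' Classifies each value as above or below `center` (values exactly equal to
#' the center are dropped), counts crossings — adjacent pairs lying on
#' opposite sides — and compares the count with its null expectation
#' `2 n1 n2 / (n1 + n2)` under random ordering.  Fewer crossings than expected
#' indicate positive serial association (e.g. adjacent genome windows
#' deviating in the same direction); more indicate alternation.
#'
#' @param values numeric vector, length >= 3, not all equal.
#' @param center split point; defaults to `median(values)`.
#' @param exact if TRUE and the post-split length is <= `exact_max`, the
#'   p-value is computed by exhaustive enumeration of all arrangements of the
#'   above/below labels instead of the normal approximation.
#' @param exact_max maximum length for the exact mode (default 12).
#'
#' @details The normal-approximation p-value applies a continuity correction
#'   of 0.5 to the discrete crossing count; for balanced splits at n <= 10
#'   it agrees with the exact enumeration within 0.05.  The exact p is the
#'   doubled smaller tail, capped at 1.
#' @return object of class `runs_test` with fields `n_values`, `n_above`,
#'   `n_below`, `observed_crossings`, `expected_crossings`, `variance`, `z`,
#'   `p_value`, `method`, and `degenerate` (TRUE when all values fall on one
#'   side, in which case `p_value` is NA).
#' @export
runs_test <- function(values, center = NULL, exact = FALSE, exact_max = 12L) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values")
  if (length(unique(values)) == 1L) stop("all values are equal")
  if (is.null(center)) center <- median(values)
  side <- sign(values - center)
  side <- side[side != 0]                      # ties at the center are dropped
  n1 <- sum(side > 0); n2 <- sum(side < 0); n <- n1 + n2
  res <- list(n_values = length(values), n_above = n1, n_below = n2,
              observed_crossings = NA_integer_, expected_crossings = NA_real_,
              variance = NA_real_, z = NA_real_, p_value = NA_real_,
              method = "normal", degenerate = FALSE)
  class(res) <- "runs_test"
  if (n1 == 0L || n2 == 0L) {
    res$degenerate <- TRUE
    res$observed_crossings <- 0L
    return(res)
  }
  obs <- sum(side[-1] != side[-n])             # crossings = runs - 1
  e_cross <- 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  res$observed_crossings <- as.integer(obs)
  res$expected_crossings <- e_cross
  res$variance <- v
  res$z <- (obs - e_cross) / sqrt(v)
  if (exact && n <= exact_max) {
    res$method <- "exact"
    res$p_value <- runs_exact_p(n1, n2, obs)
  } else {
    ## continuity-corrected two-sided normal p (the crossing count is
    ## discrete; without the 0.5 correction the approximation is poor for
    ## small windows counts)
    z_cc <- max(0, (abs(obs - e_cross) - 0.5) / sqrt(v))
    res$p_value <- 2 * pnorm(-z_cc)
  }
  res
}

## Exact two-sided p (doubled smaller tail) by enumerating all
## C(n1+n2, n1) label arrangements.
runs_exact_p <- function(n1, n2, observed) {
  n <- n1 + n2
  idx <- utils::combn(n, n1)
  crossings <- apply(idx, 2, function(pos) {
    side <- rep(-1L, n); side[pos] <- 1L
    sum(side[-1] != side[-n])
  })
  min(1, 2 * min(mean(crossings <= observed), mean(crossings >= observed)))
}

#' @export
print.runs_test <- function(x, ...) {
  cat("Wald-Wolfowitz runs test\n")
  cat(sprintf("  values: %d (above %d / below %d)\n", x$n_values, x$n_above, x$n_below))
  if (x$degenerate) {
    cat("  degenerate: all values on one side of the center\n")
  } else {
    cat(sprintf("  crossings: observed %d, expected %.2f (var %.2f)\n",
                x$observed_crossings, x$expected_crossings, x$variance))
    cat(sprintf("  z = %.3f, p = %.4g (%s)\n", x$z, x$p_value, x$method))
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values in the input order, clipped to 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same order and length.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Nested treatment/line mixed model
#'
#' Fits `response ~ treatment + (1 | line)` with line (uniquely labelled, so
#' implicitly nested within treatment) as a random intercept, and tests the
#' treatment fixed effect.  This is the per-window / per-repeat-pair test of a
#' mutation-accumulation design: replicates within lines, lines within
#' treatments.  When the line variance component is estimated at zero the
#' mixed fit is singular and the function falls back to a nested ANOVA in
#' which treatment is tested against the line-within-treatment stratum; the
#' `method` field records which path produced the p-value.
#'
#' @param response numeric response per sample.
#' @param treatment treatment label per sample (2 levels).
#' @param line line label per sample; labels must not be shared across
#'   treatments.
#' @param method `"satterthwaite"` (default; denominator df per lmerTest) or
#'   `"lrt"` (likelihood-ratio test against the no-treatment model).
#' @return list with `treatment_estimate` (difference second level minus
#'   first, response scale), `treatment_p`, `line_variance`, `line_p`
#'   (line-effect p from the nested ANOVA stratum), and `method`.
#' @export
nested_treatment_model <- function(response, treatment,
                                   line, method = c("satterthwaite", "lrt")) {
  method <- match.arg(method)
  treatment <- factor(treatment)
  line <- factor(line)
  if (nlevels(treatment) < 2L) stop("need >= 2 treatment levels")
  tab <- table(treatment, line)
  lines_per_trt <- rowSums(tab > 0)
  if (any(lines_per_trt < 2L))
    stop("need >= 2 lines per treatment (missing in: ",
         paste(names(lines_per_trt)[lines_per_trt < 2], collapse = ", "), ")")
  if (any(colSums(tab > 0) > 1L))
    stop("line labels must be unique to one treatment (nested design)")
  reps <- colSums(tab)
  if (any(reps[reps > 0] < 2L))
    stop("need >= 2 replicates per line (missing in: ",
         paste(colnames(tab)[reps > 0 & reps < 2], collapse = ", "), ")")
  dat <- data.frame(y = as.numeric(response), trt = treatment, line = line)
  if (var(dat$y) == 0)
    return(list(treatment_estimate = 0, treatment_p = 1, line_variance = 0,
                line_p = 1, method = "degenerate"))

  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ trt + (1 | line), data = dat,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  line_var <- vc$vcov[vc$grp == "line"]
  est <- lme4::fixef(fit)[[2]]

  if (isTRUE(lme4::isSingular(fit, tol = 1e-5)) || line_var <= 0) {
    ## zero line variance: nested ANOVA, treatment over the line stratum
    av <- summary(aov(y ~ trt + Error(line), data = dat))
    trt_tab <- av[["Error: line"]][[1]]
    p <- trt_tab["trt", "Pr(>F)"]
    line_ms <- trt_tab["Residuals", "Mean Sq"]
    resid_tab <- av[["Error: Within"]][[1]]
    f_line <- line_ms / resid_tab["Residuals", "Mean Sq"]
    line_p <- pf(f_line, trt_tab["Residuals", "Df"],
                 resid_tab["Residuals", "Df"], lower.tail = FALSE)
    used <- "nested-anova"
  } else if (method == "lrt") {
    fit0 <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | line), data = dat, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    fit1 <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ trt + (1 | line), data = dat, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    p <- anova(fit0, fit1)[2, "Pr(>Chisq)"]
    used <- "mixed-lrt"
  } else {
    cf <- coef(summary(fit))
    p <- cf[2, "Pr(>|t|)"]
    used <- "mixed-satterthwaite"
  }
  line_p <- if (used == "nested-anova") line_p else {
    ## line effect assessed on the same nested ANOVA decomposition
    av <- summary(aov(y ~ trt + Error(line), data = dat))
    f_line <- av[["Error: line"]][[1]]["Residuals", "Mean Sq"] /
      av[["Error: Within"]][[1]]["Residuals", "Mean Sq"]
    pf(f_line, av[["Error: line"]][[1]]["Residuals", "Df"],
       av[["Error: Within"]][[1]]["Residuals", "Df"], lower.tail = FALSE)
  }
  list(treatment_estimate = unname(est), treatment_p = unname(p),
       line_variance = max(0, line_var), line_p = unname(line_p),
       method = used)
}

#' ddPCR Poisson copy-number quantification
#'
#' In droplet digital PCR the template is partitioned into thousands of
#' droplets; the per-droplet copy count is Poisson, so the mean copies per
#' droplet is recovered from the fraction of *negative* droplets:
#' `lambda = -ln(1 - n_positive/n_total)`, and concentration is
#' `lambda / droplet_volume_ul` copies per microlitre.
#'
#' @param n_positive number of positive droplets.
#' @param n_total total droplets read (> 0).
#' @param droplet_volume_ul droplet volume in microlitres (Bio-Rad QX200
#'   droplets are ~0.85 nl = 0.00085 ul).
#' @return list with `n_positive`, `n_total`, `lambda`, `copies_per_ul`,
#'   `droplet_volume_ul`.
#' @export
ddpcr_poisson_copies <- function(n_positive, n_total, droplet_volume_ul = 0.00085) {
  stopifnot(n_total > 0, droplet_volume_ul > 0, n_positive >= 0)
  if (n_positive > n_total) stop("n_positive exceeds n_total")
  if (n_positive == n_total)
    stop("saturated: every droplet positive, copy number not estimable")
  lambda <- -log(1 - n_positive / n_total)
  list(n_positive = as.integer(n_positive), n_total = as.integer(n_total),
       lambda = lambda, copies_per_ul = lambda / droplet_volume_ul,
       droplet_volume_ul = droplet_volume_ul)
}

#' One-tailed Welch t-test
#'
#' Tests `mean(group_high) > mean(group_low)` without assuming equal
#' variances.
#'
#' @param group_high,group_low numeric vectors, each >= 2 values.
#' @return one-tailed p-value; NA with a warning when both groups are
#'   constant with equal means (the statistic is undefined).
#' @export
one_tailed_t <- function(group_high, group_low) {
  stopifnot(length(group_high) >= 2L, length(group_low) >= 2L)
  if (var(group_high) == 0 && var(group_low) == 0) {
    if (mean(group_high) == mean(group_low)) {
      warning("both groups constant with equal means: p undefined")
      return(NA_real_)
    }
    return(if (mean(group_high) > mean(group_low)) 0 else 1)
  }
  t.test(group_high, group_low, alternative = "greater", var.equal = FALSE)$p.value
}

#' Write a TSV report of test results
#'
#' @param results data.frame with at least columns `statistic`, `df`, `p`;
#'   a BH-adjusted column `p_adj` is appended if absent.
#' @param path output path.
#' @return the augmented data.frame, invisibly.
#' @export
write_stats_tsv <- function(results, path) {
  stopifnot(is.data.frame(results), all(c("statistic", "df", "p") %in% names(results)))
  if (!"p_adj" %in% names(results)) results$p_adj <- bh_fdr(results$p)
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}
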