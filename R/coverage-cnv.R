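## Windowed copy-number analysis: per-position depth, CPMM windows,
## nucleotide-composition correction, spatial runs test and the nested
## treatment/line divergence scan.

#' Per-position read depth over the genome
#'
#' Depth at a position is the number of mapped, non-duplicate alignment
#' records whose reference span (CIGAR M/D/N/=/X operations) covers it.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @param genome_length reference length.
#' @param min_mapq mapping-quality floor (default 0 = no filter).
#' @return object of class `depth_profile`: `depth` (integer per position)
#'   and `total_mapped` (number of mapped records used).
#' @export
depth_profile <- function(alignments, genome_length, min_mapq = 0L) {
  a <- alignments
  keep <- !flag_has(a$flag, FLAG_UNMAPPED) & !flag_has(a$flag, FLAG_DUP) &
    a$mapq >= min_mapq
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) {
    return(structure(list(depth = integer(genome_length), total_mapped = 0L),
                     class = "depth_profile"))
  }
  w <- cigar_ref_width(a$cigar)
  if (any(a$pos < 0) || any(a$pos + w > genome_length))
    stop("alignment record beyond genome bounds")
  cov <- IRanges::coverage(IRanges::IRanges(start = a$pos + 1L, width = w),
                           width = genome_length)
  structure(list(depth = as.integer(cov), total_mapped = nrow(a)),
            class = "depth_profile")
}

## tile the genome into fixed windows (0-based half-open); the trailing
## partial window is kept but will be flagged excluded
tile_windows <- function(genome_length, window_size) {
  starts <- seq(0L, genome_length - 1L, by = window_size)
  data.frame(window = seq_along(starts),
             start = starts,
             end = pmin(starts + window_size, genome_length))
}

#' CPMM values averaged in fixed windows for one sample
#'
#' Depth is normalised to counts per million mapped reads,
#' `CPMM(p) = depth(p) * 1e6 / total_mapped`, and averaged over
#' non-overlapping windows.  Windows overlapping a plastid-derived insertion
#' (mtpt) by one or more bp are excluded, as are the first and last windows
#' (edge artifacts of cutting the circular map) and any trailing partial
#' window.
#'
#' @param profile `depth_profile`.
#' @param genome `annotated_genome` (provides sequence for GC/homopolymer
#'   covariates and mtpt intervals).
#' @param window_size window width in bp (default 500).
#' @param min_run homopolymer threshold (runs > `min_run` bp are counted).
#' @return list with `windows` (data.frame: window, start, end, gc,
#'   homopolymers, excluded, reason) and `cpmm` (numeric per window).
#' @export
cpmm_windows <- function(profile, genome, window_size = 500L, min_run = 7L) {
  stopifnot(inherits(profile, "depth_profile"), inherits(genome, "annotated_genome"))
  L <- genome$length
  if (L < 3L * window_size) stop("genome shorter than 3 windows")
  if (profile$total_mapped == 0L) stop("zero mapped reads: CPMM undefined")
  win <- tile_windows(L, window_size)
  cpmm_pos <- profile$depth * 1e6 / profile$total_mapped
  runs <- homopolymer_runs(genome$sequence, min_run)
  win$gc <- NA_real_; win$homopolymers <- NA_integer_
  cpmm <- numeric(nrow(win))
  for (i in seq_len(nrow(win))) {
    s <- win$start[i]; e <- win$end[i]
    cpmm[i] <- mean(cpmm_pos[(s + 1L):e])
    win$gc[i] <- gc_content(substr(genome$sequence, s + 1L, e))
    win$homopolymers[i] <- homopolymer_count(runs, s, e)
  }
  excluded <- rep(FALSE, nrow(win)); reason <- rep("", nrow(win))
  mark <- function(idx, why) {
    excluded[idx] <<- TRUE
    reason[idx] <<- ifelse(reason[idx] == "", why, paste(reason[idx], why, sep = ";"))
  }
  mark(1L, "edge"); mark(nrow(win), "edge")
  if (win$end[nrow(win)] - win$start[nrow(win)] < window_size)
    mark(nrow(win), "partial")
  if (nrow(genome$mtpt)) for (j in seq_len(nrow(genome$mtpt))) {
    ov <- interval_overlap(win$start, win$end, genome$mtpt$start[j], genome$mtpt$end[j])
    mark(which(ov >= 1L), "mtpt")
  }
  win$excluded <- excluded; win$reason <- reason
  list(windows = win, cpmm = cpmm)
}

#' Assemble a multi-sample window matrix
#'
#' @param per_sample named list of [cpmm_windows()] results (one per sample;
#'   identical window definitions required).
#' @return object of class `window_matrix`: `windows` data.frame, `cpmm`
#'   samples x windows matrix, `samples`.
#' @export
window_matrix <- function(per_sample) {
  stopifnot(length(per_sample) >= 1L)
  win <- per_sample[[1]]$windows
  for (s in per_sample)
    if (!identical(s$windows$start, win$start)) stop("window definitions differ")
  cpmm <- do.call(rbind, lapply(per_sample, `[[`, "cpmm"))
  rownames(cpmm) <- names(per_sample)
  structure(list(windows = win, cpmm = cpmm,
                 samples = names(per_sample)),
            class = "window_matrix")
}

#' @export
print.window_matrix <- function(x, ...) {
  cat(sprintf("window_matrix: %d samples x %d windows (%d retained)\n",
              nrow(x$cpmm), ncol(x$cpmm), sum(!x$windows$excluded)))
  invisible(x)
}

#' Nucleotide-composition model of window CPMM
#'
#' Ordinary least squares of window CPMM on GC fraction and the count of
#' long homopolymers, the two local-composition features known to bias
#' amplification-based sequencing.  Residuals carry the copy-number signal
#' after composition correction.
#'
#' @param cpmm numeric CPMM per window.
#' @param gc GC fraction per window.
#' @param homopolymers homopolymer count per window.
#' @return list with `coefficients`, `residuals`, `fitted`, `r_squared`.
#' @export
composition_model <- function(cpmm, gc, homopolymers) {
  stopifnot(length(cpmm) == length(gc), length(gc) == length(homopolymers))
  if (length(cpmm) < 4L) stop("need >= 4 windows to fit the composition model")
  dat <- data.frame(cpmm = cpmm, gc = gc, hp = homopolymers)
  terms <- c("gc", "hp")[c(var(gc) > 0, var(homopolymers) > 0)]
  if (length(terms) < 2L)
    warning("constant predictor dropped from composition model")
  f <- if (length(terms)) paste("cpmm ~", paste(terms, collapse = " + "))
       else "cpmm ~ 1"
  fit <- lm(as.formula(f), data = dat)
  r2 <- if (var(cpmm) > 0) summary(fit)$r.squared else 0
  list(coefficients = coef(fit), residuals = unname(residuals(fit)),
       fitted = unname(predict(fit)), r_squared = r2)
}

#' Composition-corrected residuals for every sample of a window matrix
#'
#' Fits [composition_model()] per sample on retained windows.
#'
#' @param wm `window_matrix`.
#' @return matrix (samples x windows) of residuals; excluded windows are NA.
#' @export
composition_residuals <- function(wm) {
  keep <- !wm$windows$excluded
  res <- matrix(NA_real_, nrow(wm$cpmm), ncol(wm$cpmm),
                dimnames = dimnames(wm$cpmm))
  for (s in seq_len(nrow(wm$cpmm))) {
    fit <- composition_model(wm$cpmm[s, keep], wm$windows$gc[keep],
                             wm$windows$homopolymers[keep])
    res[s, keep] <- fit$residuals
  }
  res
}

#' Runs test for spatial coherence of window values
#'
#' Applies the Wald-Wolfowitz runs test to retained windows in genomic
#' order, centred at their median: fewer crossings of the median than
#' expected mean adjacent windows deviate in the same direction.
#'
#' @param wm `window_matrix`.
#' @param sample sample name or index to test, or `"mean"` (default) for the
#'   across-sample average profile.
#' @param ... passed to [runs_test()].
#' @return [runs_test()] result.
#' @export
spatial_runs_test <- function(wm, sample = "mean", ...) {
  keep <- !wm$windows$excluded
  if (sum(keep) < 3L) stop("need >= 3 retained windows")
  values <- if (identical(sample, "mean")) colMeans(wm$cpmm[, keep, drop = FALSE])
            else wm$cpmm[sample, keep]
  runs_test(values, ...)
}

#' Windowed copy-number divergence scan
#'
#' For every retained window, fits the nested treatment/line mixed model to
#' the per-sample response (raw CPMM or composition-model residuals) and
#' reports treatment and line p-values with Benjamini-Hochberg adjustment
#' across windows (per effect), plus the per-window treatment ratio.
#'
#' @param wm `window_matrix`.
#' @param treatment,line design labels, one per sample (line labels unique
#'   to their treatment).
#' @param response `"raw"` (CPMM) or `"residual"` (composition-corrected).
#' @param fdr significance threshold on adjusted p (default 0.05).
#' @param ratio_numerator treatment level used as the ratio numerator;
#'   defaults to the second factor level.
#' @return object of class `cnv_scan`: data.frame with one row per retained
#'   window (`window`, `start`, `end`, `ratio`, `treatment_p`,
#'   `treatment_p_adj`, `line_p`, `line_p_adj`, `significant`, `method`),
#'   plus attributes `response` and `fdr`.
#' @export
window_divergence_scan <- function(wm, treatment, line,
                                   response = c("raw", "residual"),
                                   fdr = 0.05, ratio_numerator = NULL) {
  response <- match.arg(response)
  stopifnot(length(treatment) == nrow(wm$cpmm), length(line) == nrow(wm$cpmm))
  values <- if (response == "raw") wm$cpmm else composition_residuals(wm)
  keep <- which(!wm$windows$excluded)
  trt <- factor(treatment)
  if (is.null(ratio_numerator)) ratio_numerator <- levels(trt)[2]
  num <- trt == ratio_numerator
  rows <- lapply(keep, function(w) {
    y <- values[, w]
    if (var(y) == 0) {
      return(data.frame(window = wm$windows$window[w], start = wm$windows$start[w],
                        end = wm$windows$end[w], ratio = 1,
                        treatment_p = 1, line_p = 1, method = "degenerate"))
    }
    m <- nested_treatment_model(y, treatment, line)
    raw <- wm$cpmm[, w]   # ratio always on the CPMM scale
    data.frame(window = wm$windows$window[w], start = wm$windows$start[w],
               end = wm$windows$end[w],
               ratio = mean(raw[num]) / mean(raw[!num]),
               treatment_p = m$treatment_p, line_p = m$line_p,
               method = m$method)
  })
  out <- do.call(rbind, rows)
  out$treatment_p_adj <- bh_fdr(out$treatment_p)
  out$line_p_adj <- bh_fdr(out$line_p)
  out$significant <- out$treatment_p_adj < fdr
  rownames(out) <- NULL
  attr(out, "response") <- response
  attr(out, "fdr") <- fdr
  class(out) <- c("cnv_scan", "data.frame")
  out
}

#' Correlation of window profiles between two datasets
#'
#' Pearson correlation of mean CPMM over windows retained in both matrices.
#'
#' @param wm_a,wm_b `window_matrix` objects over the same window tiling.
#' @return Pearson r (NA with a warning when either profile is constant).
#' @export
coverage_correlation <- function(wm_a, wm_b) {
  stopifnot(identical(wm_a$windows$start, wm_b$windows$start))
  keep <- !wm_a$windows$excluded & !wm_b$windows$excluded
  if (sum(keep) < 3L) stop("need >= 3 shared retained windows")
  a <- colMeans(wm_a$cpmm[, keep, drop = FALSE])
  b <- colMeans(wm_b$cpmm[, keep, drop = FALSE])
  if (var(a) == 0 || var(b) == 0) {
    warning("constant profile: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}
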