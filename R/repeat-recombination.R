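## Repeat-pair discovery on the circular mitogenome and quantification of
## recombinant vs parental genome conformations from paired-read geometry.
##
## A recombinant conformation produced by crossover between two repeat
## copies is detected by read pairs linking the flank of one copy to the
## *opposite* flank of the other: for direct repeats the mates keep
## forward/reverse orientation (L1 -> R2 or L2 -> R1); for inverted repeats
## the crossover flips the downstream segment, so junction-spanning mates
## map to the same reference strand (L1+L2 both forward, R1+R2 both
## reverse).

#' Discover repeat pairs by k-mer seeding and gapless extension
#'
#' Self-comparison of the genome (both orientations).  Exact shared k-mers
#' seed candidate pairs; seeds on a common diagonal are clustered and
#' extended gaplessly with an X-drop rule, then trimmed to the
#' maximal-identity span.  Identity is computed over the extended alignment.
#' The circular origin is handled by scanning the sequence extended by
#' `max_len` and reducing coordinates modulo the genome length.
#'
#' @param genome `annotated_genome` or character sequence.
#' @param min_len,max_len repeat length range for scan inclusion (pairs
#'   outside the range are reported with `in_range = FALSE`).
#' @param min_identity minimum nucleotide identity (default 0.80).
#' @param k seed k-mer size (default 12).
#' @param min_report shortest pair worth reporting (default 50 bp).
#' @return data.frame with `copy1_start`, `copy1_end`, `copy2_start`,
#'   `copy2_end` (0-based half-open), `orientation` (`direct`/`inverted`),
#'   `length`, `identity`, `in_range`.
#' @export
find_repeat_pairs <- function(genome, min_len = 100L, max_len = 500L,
                              min_identity = 0.80, k = 12L, min_report = 50L) {
  seq0 <- if (inherits(genome, "annotated_genome")) genome$sequence else toupper(genome)
  L <- nchar(seq0)
  if (L <= 2L * max_len) stop("genome too short relative to max_len")
  ext <- paste0(seq0, substr(seq0, 1L, max_len))
  hits <- rbind(seed_extend_pairs(ext, ext, k, same = TRUE),
                seed_extend_pairs(ext, revcomp(ext), k, same = FALSE))
  if (!nrow(hits)) return(empty_repeat_pairs())
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$orientation == "inverted") {
      ## coordinates of copy2 are in revcomp(ext) space; map back
      n_ext <- nchar(ext)
      s2 <- n_ext - h$copy2_end; e2 <- n_ext - h$copy2_start
      h$copy2_start <- s2; h$copy2_end <- e2
    }
    ## reduce to [0, L); drop duplicates arising from the circular extension
    h$copy1_start <- h$copy1_start %% L
    h$copy2_start <- h$copy2_start %% L
    h$copy1_end <- h$copy1_start + h$length
    h$copy2_end <- h$copy2_start + h$length
    ## canonical order: copy with the smaller start first
    if (h$copy2_start < h$copy1_start) {
      tmp <- h[c("copy1_start", "copy1_end")]
      h[c("copy1_start", "copy1_end")] <- h[c("copy2_start", "copy2_end")]
      h[c("copy2_start", "copy2_end")] <- tmp
    }
    ## self-match or overlapping copies (tandem) are not usable pairs
    if (interval_overlap(h$copy1_start, h$copy1_end,
                         h$copy2_start, h$copy2_end) > 0) next
    out[[length(out) + 1L]] <- h
  }
  if (!length(out)) return(empty_repeat_pairs())
  res <- do.call(rbind, out)
  ## non-redundancy: among pairs sharing overlapping copy1 AND copy2 spans,
  ## keep the longest
  res <- res[order(-res$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (res$orientation[i] == res$orientation[j] &&
          interval_overlap(res$copy1_start[i], res$copy1_end[i],
                           res$copy1_start[j], res$copy1_end[j]) > 0 &&
          interval_overlap(res$copy2_start[i], res$copy2_end[i],
                           res$copy2_start[j], res$copy2_end[j]) > 0) {
        keep[i] <- FALSE
        break
      }
    }
  }
  res <- res[keep & res$length >= min_report & res$identity >= min_identity, ,
             drop = FALSE]
  if (!nrow(res)) return(empty_repeat_pairs())
  res$in_range <- res$length >= min_len & res$length <= max_len
  res <- res[order(res$copy1_start, res$copy2_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_repeat_pairs <- function() {
  data.frame(copy1_start = integer(), copy1_end = integer(),
             copy2_start = integer(), copy2_end = integer(),
             orientation = character(), length = integer(),
             identity = numeric(), in_range = logical())
}

## shared-kmer seeding between strings a and b plus diagonal clustering and
## gapless extension; returns pairs in the coordinate systems of a and b
seed_extend_pairs <- function(a, b, k, same, max_kmer_occ = 24L,
                              cluster_gap = 60L) {
  na <- nchar(a)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  kmers_a <- substring(a, 1:(na - k + 1L), k:na)
  idx_b <- if (same) NULL else {
    kb <- substring(b, 1:(nchar(b) - k + 1L), k:nchar(b))
    split(seq_along(kb), kb)
  }
  idx_a <- split(seq_along(kmers_a), kmers_a)
  seeds <- list()
  if (same) {
    for (pos in idx_a) {
      if (length(pos) < 2L || length(pos) > max_kmer_occ) next
      cmb <- utils::combn(pos, 2L)
      seeds[[length(seeds) + 1L]] <- data.frame(i = cmb[1, ], j = cmb[2, ])
    }
  } else {
    common <- intersect(names(idx_a), names(idx_b))
    ia <- idx_a[common]; ib <- idx_b[common]
    for (m in seq_along(common)) {
      pa <- ia[[m]]; pb <- ib[[m]]
      if (length(pa) * length(pb) > max_kmer_occ^2) next
      seeds[[length(seeds) + 1L]] <- expand.grid(i = pa, j = pb)
    }
  }
  if (!length(seeds)) return(empty_seed_hits())
  seeds <- do.call(rbind, seeds)
  seeds <- seeds[seeds$i != seeds$j | !same, , drop = FALSE]
  if (same) seeds <- seeds[seeds$j > seeds$i, , drop = FALSE]
  if (!nrow(seeds)) return(empty_seed_hits())
  seeds$diag <- seeds$j - seeds$i
  hits <- list()
  for (d in unique(seeds$diag)) {
    s <- sort(seeds$i[seeds$diag == d])
    grp <- cumsum(c(1L, diff(s) > cluster_gap))
    for (g in unique(grp)) {
      lo <- min(s[grp == g]); hi <- max(s[grp == g]) + k - 1L
      span <- extend_gapless(av, bv, lo, lo + d, hi - lo + 1L, same, d)
      if (is.null(span)) next
      hits[[length(hits) + 1L]] <- data.frame(
        copy1_start = span$start - 1L, copy1_end = span$start - 1L + span$len,
        copy2_start = span$start - 1L + d, copy2_end = span$start - 1L + d + span$len,
        orientation = if (same) "direct" else "inverted",
        length = span$len, identity = span$identity)
    }
  }
  if (!length(hits)) return(empty_seed_hits())
  do.call(rbind, hits)
}

empty_seed_hits <- function() {
  data.frame(copy1_start = integer(), copy1_end = integer(),
             copy2_start = integer(), copy2_end = integer(),
             orientation = character(), length = integer(), identity = numeric())
}

## gapless X-drop extension of a seeded span, then trim to the
## maximal-identity window (flanking mismatches removed)
extend_gapless <- function(av, bv, i0, j0, len, same, d,
                           match = 1, mismatch = -2, xdrop = 12) {
  n <- length(av)
  ## extend right
  score <- best <- 0; right <- i0 + len - 1L
  i <- i0 + len; j <- j0 + len
  while (i <= n && j <= n && (!same || j - i == d)) {
    if (same && i > j0 - 1L) break          # don't run copy1 into copy2
    score <- score + if (av[i] == bv[j]) match else mismatch
    if (score > best) { best <- score; right <- i }
    if (score < best - xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  ## extend left
  score <- best <- 0; left <- i0
  i <- i0 - 1L; j <- j0 - 1L
  while (i >= 1L && j >= 1L) {
    if (same && j < i0 + len) { }            # left extension cannot collide
    score <- score + if (av[i] == bv[j]) match else mismatch
    if (score > best) { best <- score; left <- i }
    if (score < best - xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  ## trim flanking mismatches
  ai <- left:right; bi <- ai + d
  m <- av[ai] == bv[bi]
  if (!any(m)) return(NULL)
  first <- which(m)[1]; last <- tail(which(m), 1)
  ai <- ai[first:last]
  span_len <- length(ai)
  if (span_len < 20L) return(NULL)
  identity <- mean(av[ai] == bv[ai + d])
  list(start = ai[1], len = span_len, identity = identity)
}

## anchored in the left flank of a repeat copy starting at s: the mate
## starts within the flank window and before the copy (it may extend into
## the repeat — the flank anchor is what makes it informative)
anchored_left <- function(m, s, w) m$pos >= s - w && m$pos < s

## anchored in the right flank of a copy ending at e: the mate ends past
## the copy, within the flank window
anchored_right <- function(m, e, w) {
  m_end <- m$pos + m$len
  m_end > e && m_end <= e + w
}

## mate wholly inside a repeat copy: cannot be assigned to either copy
inside_copy <- function(m, rp) {
  (m$pos >= rp$copy1_start && m$pos + m$len <= rp$copy1_end) ||
  (m$pos >= rp$copy2_start && m$pos + m$len <= rp$copy2_end)
}

#' Classify a read pair against a repeat pair
#'
#' Labels the four repeat flanks L1/R1 (copy 1) and L2/R2 (copy 2).  A mate
#' is anchored in a left flank when it starts within the flank window before
#' the copy (it may read into the repeat), and in a right flank when it ends
#' past the copy within the window.  A pair anchored in the left and right
#' flank of one copy, forward/reverse orientation, with implied insert
#' within `insert_mean +/- k_sd * insert_sd`, is parental for that copy.  A
#' pair linking the left flank of one copy to the opposite flank of the
#' other, with mate orientations consistent with the repeat orientation
#' (inverted repeats flip the expected strand of the far mate) and a
#' junction-implied insert inside the same window, is recombinant for that
#' junction.  Mates lying wholly inside a repeat copy are never used
#' (multi-mapping ambiguity); everything else — including pairs matching
#' more than one hypothesis — is uninformative.
#'
#' @param pos1,pos2 0-based leftmost reference positions of the two mates.
#' @param strand1,strand2 `"+"`/`"-"` mate strands.
#' @param len1,len2 aligned reference lengths of the mates.
#' @param repeat_pair one row of [find_repeat_pairs()].
#' @param insert_mean,insert_sd fragment-length model.
#' @param k_sd concordance window half-width in SDs (default 4).
#' @return one of `"parental_copy1"`, `"parental_copy2"`,
#'   `"recombinant_AB"`, `"recombinant_BA"`, `"uninformative"`.
#' @export
classify_read_pair <- function(pos1, strand1, len1, pos2, strand2, len2,
                               repeat_pair, insert_mean, insert_sd, k_sd = 4) {
  rp <- as.list(repeat_pair)
  w <- ceiling(insert_mean + k_sd * insert_sd)
  lo_ins <- insert_mean - k_sd * insert_sd
  hi_ins <- insert_mean + k_sd * insert_sd
  rep_len <- rp$length %||% (rp$copy1_end - rp$copy1_start)
  s1 <- rp$copy1_start; e1 <- rp$copy1_end
  s2 <- rp$copy2_start; e2 <- rp$copy2_end
  inverted <- identical(rp$orientation, "inverted")
  mates <- list(list(pos = pos1, strand = strand1, len = len1),
                list(pos = pos2, strand = strand2, len = len2))
  if (inside_copy(mates[[1]], rp) || inside_copy(mates[[2]], rp))
    return("uninformative")
  in_L <- function(m, s) anchored_left(m, s, w)
  in_R <- function(m, e) anchored_right(m, e, w)
  ok_ins <- function(x) x >= lo_ins && x <= hi_ins
  calls <- character(0)
  for (ord in list(c(1, 2), c(2, 1))) {
    f <- mates[[ord[1]]]; r <- mates[[ord[2]]]
    ## parental: fwd mate in L_i, rev mate in R_i, reference-frame insert
    if (f$strand == "+" && r$strand == "-") {
      if (in_L(f, s1) && in_R(r, e1) && ok_ins(r$pos + r$len - f$pos))
        calls <- c(calls, "parental_copy1")
      if (in_L(f, s2) && in_R(r, e2) && ok_ins(r$pos + r$len - f$pos))
        calls <- c(calls, "parental_copy2")
    }
    if (!inverted) {
      ## direct repeat: junction joins L1 to R2 (or L2 to R1), orientations
      ## stay forward/reverse; the pair must additionally be discordant on
      ## the reference (otherwise a plain fragment between close copies
      ## would mimic a junction)
      if (f$strand == "+" && r$strand == "-" &&
          !ok_ins(r$pos + r$len - f$pos)) {
        if (in_L(f, s1) && in_R(r, e2) &&
            ok_ins((s1 - f$pos) + rep_len + (r$pos + r$len - e2)))
          calls <- c(calls, "recombinant_AB")
        if (in_L(f, s2) && in_R(r, e1) &&
            ok_ins((s2 - f$pos) + rep_len + (r$pos + r$len - e1)))
          calls <- c(calls, "recombinant_BA")
      }
    } else {
      ## inverted repeat: junction-spanning mates map to the same strand
      if (f$strand == "+" && r$strand == "+") {
        if (in_L(f, s1) && in_L(r, s2) &&
            ok_ins((s1 - f$pos) + rep_len + (s2 - r$pos)))
          calls <- c(calls, "recombinant_AB")
      }
      if (f$strand == "-" && r$strand == "-") {
        if (in_R(f, e1) && in_R(r, e2) &&
            ok_ins((f$pos + f$len - e1) + rep_len + (r$pos + r$len - e2)))
          calls <- c(calls, "recombinant_BA")
      }
    }
  }
  calls <- unique(calls)
  if (length(calls) == 1L) calls else "uninformative"
}

#' Count parental and recombinant conformations for each repeat pair
#'
#' Pairs mates by read name and classifies every pair against every repeat
#' pair with [classify_read_pair()].
#'
#' @param alignments alignment data.frame (paired records).
#' @param repeat_pairs data.frame from [find_repeat_pairs()] (in-range rows
#'   are used).
#' @param insert_mean,insert_sd fragment-length model.
#' @param k_sd concordance window (default 4 SD).
#' @return data.frame with one row per repeat pair: `pair`, `parental`,
#'   `recombinant`, `recombinant_AB`, `recombinant_BA`.
#' @export
count_conformations <- function(alignments, repeat_pairs, insert_mean, insert_sd,
                                k_sd = 4) {
  rp <- repeat_pairs[repeat_pairs$in_range %||% TRUE, , drop = FALSE]
  a <- alignments[!flag_has(alignments$flag, FLAG_UNMAPPED) &
                  !flag_has(alignments$flag, FLAG_DUP), , drop = FALSE]
  a$strand <- ifelse(flag_has(a$flag, FLAG_REVERSE), "-", "+")
  a$rlen <- cigar_ref_width(a$cigar)
  first <- a[flag_has(a$flag, FLAG_READ1), ]
  second <- a[flag_has(a$flag, FLAG_READ2), ]
  shared <- intersect(first$qname, second$qname)
  first <- first[match(shared, first$qname), ]
  second <- second[match(shared, second$qname), ]
  out <- lapply(seq_len(nrow(rp)), function(pi) {
    r <- rp[pi, ]
    w <- ceiling(insert_mean + k_sd * insert_sd)
    ## restrict to read pairs near the repeat pair before classifying
    near <- function(p, l) {
      interval_overlap(p, p + l, r$copy1_start - w, r$copy1_end + w) > 0 |
      interval_overlap(p, p + l, r$copy2_start - w, r$copy2_end + w) > 0
    }
    cand <- which(near(first$pos, first$rlen) | near(second$pos, second$rlen))
    tally <- c(parental_copy1 = 0L, parental_copy2 = 0L,
               recombinant_AB = 0L, recombinant_BA = 0L, uninformative = 0L)
    for (i in cand) {
      cl <- classify_read_pair(first$pos[i], first$strand[i], first$rlen[i],
                               second$pos[i], second$strand[i], second$rlen[i],
                               r, insert_mean, insert_sd, k_sd)
      tally[cl] <- tally[cl] + 1L
    }
    data.frame(pair = pi,
               parental = tally[["parental_copy1"]] + tally[["parental_copy2"]],
               recombinant = tally[["recombinant_AB"]] + tally[["recombinant_BA"]],
               recombinant_AB = tally[["recombinant_AB"]],
               recombinant_BA = tally[["recombinant_BA"]])
  })
  do.call(rbind, out)
}

#' Recombinant fraction per repeat pair with Wilson confidence interval
#'
#' @param counts data.frame from [count_conformations()].
#' @param conf confidence level (default 0.95).
#' @return the input with `fraction`, `ci_lo`, `ci_hi`, `informative`
#'   columns appended; repeat pairs with zero informative read pairs carry
#'   NA fractions.
#' @export
recombinant_fraction <- function(counts, conf = 0.95) {
  n <- counts$parental + counts$recombinant
  counts$informative <- n
  counts$fraction <- ifelse(n > 0, counts$recombinant / n, NA_real_)
  ci <- t(vapply(seq_len(nrow(counts)), function(i)
    wilson_interval(counts$recombinant[i], n[i], conf), numeric(2)))
  counts$ci_lo <- ci[, 1]; counts$ci_hi <- ci[, 2]
  counts
}

#' Treatment/line divergence scan over recombinant fractions
#'
#' Nested mixed model per repeat pair on per-sample recombinant fractions,
#' with BH-FDR across repeat pairs.
#'
#' @param fractions matrix (samples x repeat pairs) of recombinant fractions.
#' @param treatment,line design labels per sample.
#' @param fdr significance threshold (default 0.05).
#' @return data.frame per repeat pair: `pair`, `treatment_p`,
#'   `treatment_p_adj`, `line_p`, `line_p_adj`, `significant`, `method`.
#' @export
recombination_divergence_scan <- function(fractions, treatment, line, fdr = 0.05) {
  fractions <- as.matrix(fractions)
  rows <- lapply(seq_len(ncol(fractions)), function(p) {
    y <- fractions[, p]
    if (all(is.na(y)) || var(y, na.rm = TRUE) == 0)
      return(data.frame(pair = p, treatment_p = 1, line_p = 1,
                        method = "degenerate"))
    m <- nested_treatment_model(y, treatment, line)
    data.frame(pair = p, treatment_p = m$treatment_p, line_p = m$line_p,
               method = m$method)
  })
  out <- do.call(rbind, rows)
  out$treatment_p_adj <- bh_fdr(out$treatment_p)
  out$line_p_adj <- bh_fdr(out$line_p)
  out$significant <- out$treatment_p_adj < fdr
  rownames(out) <- NULL
  out
}
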