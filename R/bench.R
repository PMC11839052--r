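## Benchmark machinery: truth matching, recall/precision/F1, background
## subtraction, population completeness/accuracy/error with per-sample
## genotyping metrics, pairwise overlap-rate matrices, and the two
## simulation benchmark protocols (reference-based detection and
## population-scale merging + genotyping).

## candidate (call, truth) pairs under the span or insertion rule
match_pairs <- function(calls, truth, min_ro = 0.8, ins_shift = 12,
                        ins_lendiff = 0.2) {
  if (!nrow(calls) || !nrow(truth))
    return(data.frame(call = integer(0), truth = integer(0),
                      score = numeric(0)))
  svtype <- unique(c(calls$svtype, truth$svtype))
  if (length(svtype) > 1L) stop("mixed svtypes in match")
  out <- list()
  if (svtype == "INS") {
    for (i in seq_len(nrow(calls))) {
      j <- which(truth$ref_name == calls$ref_name[i] &
                 abs(truth$ref_start - calls$ref_start[i]) <= ins_shift)
      if (!length(j)) next
      ld <- abs(truth$length[j] - calls$length[i]) /
        pmax(truth$length[j], calls$length[i])
      ok <- ld <= ins_lendiff
      if (any(ok))
        out[[length(out) + 1L]] <- data.frame(
          call = i, truth = j[ok], score = 1 - ld[ok])
    }
  } else {
    ir_c <- iranges0(calls$ref_start, calls$ref_end)
    ir_t <- iranges0(truth$ref_start, truth$ref_end)
    hit <- IRanges::findOverlaps(ir_c, ir_t)
    i <- S4Vectors::queryHits(hit); j <- S4Vectors::subjectHits(hit)
    same <- calls$ref_name[i] == truth$ref_name[j]
    i <- i[same]; j <- j[same]
    if (length(i)) {
      ro <- ro_interval(calls$ref_start[i], calls$ref_end[i],
                        truth$ref_start[j], truth$ref_end[j])
      ok <- ro >= min_ro
      out[[1]] <- data.frame(call = i[ok], truth = j[ok], score = ro[ok])
    }
  }
  do.call(rbind, out) %||%
    data.frame(call = integer(0), truth = integer(0), score = numeric(0))
}

#' Match calls against a truth set
#'
#' Greedy best-overlap one-to-one matching: span SVs match at reciprocal
#' overlap >= `min_ro`; insertions (zero reference span) match when
#' breakpoints are within `ins_shift` and lengths within `ins_lendiff`.
#' Unmatched calls are FP, unmatched truth FN.
#'
#' @param calls,truth call tables of a single svtype.
#' @param min_ro reciprocal-overlap threshold for span SVs.
#' @param ins_shift,ins_lendiff insertion matching rule.
#' @return list of class `svnet_match` with integer index vectors `TP`
#'   (rows of `calls`), `FP`, `FN` (rows of `truth`), and `pairs`.
#' @export
match_truth <- function(calls, truth, min_ro = 0.8, ins_shift = 12,
                        ins_lendiff = 0.2) {
  p <- match_pairs(calls, truth, min_ro, ins_shift, ins_lendiff)
  p <- p[order(-p$score, p$call, p$truth), , drop = FALSE]
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  keep <- logical(nrow(p))
  for (k in seq_len(nrow(p))) {
    if (used_c[p$call[k]] || used_t[p$truth[k]]) next
    used_c[p$call[k]] <- TRUE; used_t[p$truth[k]] <- TRUE
    keep[k] <- TRUE
  }
  structure(list(TP = p$call[keep], FP = which(!used_c),
                 FN = which(!used_t), pairs = p[keep, , drop = FALSE],
                 min_ro = min_ro),
            class = "svnet_match")
}

#' Recall, precision and F1 from a match result
#'
#' @param match a `svnet_match` (or list with TP/FP/FN index vectors).
#' @return named numeric vector `recall`, `precision`, `f1` (0/0 = 0).
#' @export
prf <- function(match) {
  tp <- length(match$TP); fp <- length(match$FP); fn <- length(match$FN)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  c(recall = recall, precision = precision, f1 = f1)
}

#' Subtract a background callset
#'
#' Removes from `calls` any call matching the background set under the
#' span rule (RO >= `ro`) or the insertion shift/length rule; used to
#' isolate planted events when both genomes already diverge from the
#' reference.
#'
#' @param calls,background call tables (any mix of svtypes).
#' @param ro span-overlap threshold.
#' @param ins_shift,ins_lendiff insertion rule.
#' @return `calls` minus background matches.
#' @export
subtract_background <- function(calls, background, ro = 0.5,
                                ins_shift = 12, ins_lendiff = 0.2) {
  drop <- logical(nrow(calls))
  for (tp in unique(calls$svtype)) {
    ci <- which(calls$svtype == tp)
    bg <- background[background$svtype == tp, , drop = FALSE]
    if (!nrow(bg)) next
    p <- match_pairs(calls[ci, , drop = FALSE], bg, ro, ins_shift,
                     ins_lendiff)
    drop[ci[unique(p$call)]] <- TRUE
  }
  calls[!drop, , drop = FALSE]
}

#' Pairwise overlap-rate matrix across callsets
#'
#' Entry (i, j) is the fraction of calls in set i with a match in set j
#' (80% reciprocal overlap for spans; shift/length rule for insertions).
#'
#' @param callsets named list of call tables.
#' @param ro reciprocal-overlap threshold.
#' @param ins_shift,ins_lendiff insertion rule.
#' @return square numeric matrix with unit diagonal.
#' @export
overlap_matrix <- function(callsets, ro = 0.8, ins_shift = 12,
                           ins_lendiff = 0.2) {
  n <- length(callsets)
  if (n < 2L) stop("need at least two callsets")
  m <- diag(1, n)
  dimnames(m) <- list(names(callsets), names(callsets))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- callsets[[i]]; b <- callsets[[j]]
    if (!nrow(a)) { m[i, j] <- NA; next }
    matched <- 0L
    for (tp in unique(a$svtype)) {
      ai <- a[a$svtype == tp, , drop = FALSE]
      bi <- b[b$svtype == tp, , drop = FALSE]
      if (!nrow(bi)) next
      matched <- matched + length(unique(
        match_pairs(ai, bi, ro, ins_shift, ins_lendiff)$call))
    }
    m[i, j] <- matched / nrow(a)
  }
  m
}

#' Evaluate a merged, genotyped callset against a planted population
#'
#' Applies the genotype-frequency background filter (sites with ALT
#' frequency above `freq_num/freq_den` are excluded as pre-existing
#' variants, unless the reference is the genome the events were planted
#' on), matches the retained sites to the truth at RO >= `match_ro`
#' (insertions by shift/length), and reports completeness (TP / planted,
#' %), accuracy (TP / predicted, %), error (FP / predicted, %), plus
#' per-sample genotyping accuracy / error / missing over TP sites.
#'
#' @param sites merged site table.
#' @param gt state matrix (sites x samples, entries ALT/REF/MISSING), or
#'   `NULL` to skip genotype metrics.
#' @param truth planted event table.
#' @param truth_gt 0/1 matrix events x samples.
#' @param ref_is_origin reference is the planting genome (frequency
#'   filter exemption).
#' @param freq_num,freq_den frequency-filter fraction.
#' @param match_ro span matching threshold.
#' @param ins_shift,ins_lendiff insertion matching rule.
#' @return list with `completeness`, `accuracy`, `error` (percent), the
#'   matched site table `tp` (with `truth_id`), and `per_sample`
#'   (accuracy/error/missing percent per sample, svtype and size class).
#' @export
population_eval <- function(sites, gt, truth, truth_gt,
                            ref_is_origin = FALSE, freq_num = 19,
                            freq_den = 21, match_ro = 0.5,
                            ins_shift = 12, ins_lendiff = 0.2) {
  if (!is.null(gt) && !identical(colnames(gt), colnames(truth_gt)))
    stop("sample sets of prediction and truth differ")
  keep <- rep(TRUE, nrow(sites))
  if (!ref_is_origin && !is.null(gt)) {
    altf <- rowSums(gt == "ALT") / ncol(gt)
    keep <- altf <= freq_num / freq_den
  }
  retained <- sites[keep, , drop = FALSE]
  tp_rows <- list(); n_tp <- 0L; n_fp <- 0L
  for (tp in unique(retained$svtype)) {
    ci <- which(retained$svtype == tp)
    tr <- truth[truth$svtype == tp, , drop = FALSE]
    if (!nrow(tr)) { n_fp <- n_fp + length(ci); next }
    m <- match_truth(retained[ci, , drop = FALSE], tr, min_ro = match_ro,
                     ins_shift = ins_shift, ins_lendiff = ins_lendiff)
    n_tp <- n_tp + length(m$TP); n_fp <- n_fp + length(m$FP)
    if (length(m$TP)) {
      t_tab <- retained[ci[m$pairs$call], , drop = FALSE]
      t_tab$truth_id <- tr$id[m$pairs$truth]
      tp_rows[[length(tp_rows) + 1L]] <- t_tab
    }
  }
  tp_tab <- do.call(rbind, tp_rows) %||% retained[0, , drop = FALSE]
  res <- list(
    completeness = 100 * n_tp / nrow(truth),
    accuracy = if (nrow(retained)) 100 * n_tp / nrow(retained) else 0,
    error = if (nrow(retained)) 100 * n_fp / nrow(retained) else 0,
    n_retained = nrow(retained), tp = tp_tab)
  if (!is.null(gt) && nrow(tp_tab)) {
    samples <- colnames(gt)
    per <- list()
    truth_len <- truth$length[match(tp_tab$truth_id, truth$id)]
    size_class <- ifelse(truth_len > 50, "sv",
                         ifelse(truth_len < 50, "indel", "boundary"))
    for (s in samples) {
      g <- gt[match(tp_tab$id, rownames(gt)), s]
      planted <- truth_gt[match(tp_tab$truth_id, rownames(truth_gt)), s]
      correct <- (g == "ALT" & planted == 1) | (g == "REF" & planted == 0)
      wrong <- (g == "ALT" & planted == 0) | (g == "REF" & planted == 1)
      missing <- g == "MISSING"
      for (tp2 in c(unique(tp_tab$svtype), "ALL")) {
        for (sz in c("sv", "indel", "ALL")) {
          idx <- (tp2 == "ALL" | tp_tab$svtype == tp2) &
                 (sz == "ALL" | size_class == sz)
          if (!any(idx)) next
          per[[length(per) + 1L]] <- data.frame(
            sample = s, svtype = tp2, size_class = sz,
            n = sum(idx),
            accuracy = 100 * sum(correct[idx]) / sum(idx),
            error = 100 * sum(wrong[idx]) / sum(idx),
            missing = 100 * sum(missing[idx]) / sum(idx),
            stringsAsFactors = FALSE)
        }
      }
    }
    res$per_sample <- do.call(rbind, per)
  }
  res
}
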