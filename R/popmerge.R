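## Merging per-sample SV calls into a non-redundant population call set.
## Span SVs (DEL/INV/TRA/DUP) merge by reciprocal overlap; insertions by
## breakpoint shift, length ratio and inserted-sequence identity.

#' Reciprocal overlap of two intervals
#'
#' `min(|a∩b|/|a|, |a∩b|/|b|)` for 0-based half-open intervals on the
#' same sequence; 0 when disjoint.  Vectorized and symmetric.
#'
#' @param a,b numeric length-2 vectors `c(start, end)`, or matrices with
#'   two columns for the vectorized form.
#' @return fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
  ro_interval(a[, 1], a[, 2], b[, 1], b[, 2])
}

#' Global sequence identity
#'
#' End-to-end (Needleman-Wunsch, unit match/mismatch/gap costs, no free
#' end gaps) alignment identity: matched columns over total alignment
#' columns.  Identical strings short-circuit to 1.
#'
#' @param a,b non-empty nucleotide strings.
#' @return fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a == b) return(1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 1)
  ncols <- nchar(as.character(Biostrings::pattern(pa)))
  Biostrings::nmatch(pa) / ncols
}

## single-linkage closure over an edge list; returns component id per node
components_of <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, 0L)
}

pick_representative <- function(idx, calls) {
  len <- calls$length[idx]
  med <- sort(len)[ceiling(length(len) / 2)]   # lower median
  cand <- idx[len == med]
  cand[order(calls$ref_start[cand], calls$sample[cand])][1]
}

#' Merge span-type SV calls across samples
#'
#' Single-linkage clustering over the "reciprocal overlap at least
#' `ro_threshold`" relation after coordinate sorting; each cluster is
#' represented by the member whose length is the cluster median (ties:
#' smaller start).  Translocations additionally require an identical
#' donor query sequence to merge.
#'
#' @param calls per-sample calls, all of one span svtype
#'   (DEL/INV/TRA/DUP).
#' @param ro_threshold reciprocal-overlap cutoff (default 0.9).
#' @return object of class `svnet_merged`: list with `sites` (one row per
#'   merged event: id, representative coordinates, support) and `members`
#'   (site id x originating call).
#' @export
merge_span_svs <- function(calls, ro_threshold = 0.9) {
  if (length(unique(calls$svtype)) > 1L)
    stop("mixed svtypes passed to merge_span_svs")
  if (nrow(calls) == 0L)
    return(structure(list(sites = data.frame(), members = data.frame()),
                     class = "svnet_merged"))
  svtype <- calls$svtype[1]
  if (svtype == "INS") stop("use merge_insertions for INS calls")
  calls <- sort_calls(calls)
  ir <- iranges0(calls$ref_start, calls$ref_end)
  hit <- IRanges::findOverlaps(ir, ir)
  i <- S4Vectors::queryHits(hit); j <- S4Vectors::subjectHits(hit)
  keep <- i < j & calls$ref_name[i] == calls$ref_name[j]
  if (svtype == "TRA")
    keep <- keep & calls$query_name[i] == calls$query_name[j]
  i <- i[keep]; j <- j[keep]
  ro <- ro_interval(calls$ref_start[i], calls$ref_end[i],
                    calls$ref_start[j], calls$ref_end[j])
  edges <- cbind(i, j)[ro >= ro_threshold, , drop = FALSE]
  comp <- components_of(nrow(calls), edges)
  build_merged(calls, comp, substr(svtype, 1, 3))
}

build_merged <- function(calls, comp, prefix) {
  comp_ids <- unique(comp)
  starts <- vapply(comp_ids, function(cid) min(calls$ref_start[comp == cid]), 0)
  chroms <- vapply(comp_ids, function(cid) calls$ref_name[comp == cid][1], "")
  comp_ids <- comp_ids[order(chroms, starts)]
  sites <- list(); members <- list()
  for (k in seq_along(comp_ids)) {
    idx <- which(comp == comp_ids[k])
    rep_i <- pick_representative(idx, calls)
    id <- sprintf("%s%05d", prefix, k)
    sites[[k]] <- data.frame(
      id = id, svtype = calls$svtype[rep_i],
      ref_name = calls$ref_name[rep_i], ref_start = calls$ref_start[rep_i],
      ref_end = calls$ref_end[rep_i], length = calls$length[rep_i],
      seq = calls$seq[rep_i], query_name = calls$query_name[rep_i],
      support = length(unique(calls$sample[idx])),
      stringsAsFactors = FALSE)
    members[[k]] <- data.frame(id = id, sample = calls$sample[idx],
                               ref_name = calls$ref_name[idx],
                               ref_start = calls$ref_start[idx],
                               ref_end = calls$ref_end[idx],
                               length = calls$length[idx],
                               stringsAsFactors = FALSE)
  }
  structure(list(sites = do.call(rbind, sites),
                 members = do.call(rbind, members)),
            class = "svnet_merged")
}

#' @export
print.svnet_merged <- function(x, ...) {
  cat(sprintf("<merged SV set> %d sites from %d calls\n",
              nrow(x$sites), nrow(x$members)))
  invisible(x)
}

#' Merge insertion calls across samples
#'
#' Two insertions cluster when their breakpoints differ by at most
#' `max_shift`, their lengths by at most `max_len_diff` (relative to the
#' longer), and their inserted sequences align end-to-end at identity at
#' least `min_identity`; clusters are single-linkage closures.
#'
#' @param calls per-sample INS calls (must carry `seq`).
#' @param max_shift maximum breakpoint shift in bases.
#' @param max_len_diff maximum relative length difference.
#' @param min_identity minimum global sequence identity.
#' @return `svnet_merged`, as [merge_span_svs()].
#' @export
merge_insertions <- function(calls, max_shift = 12, max_len_diff = 0.20,
                             min_identity = 0.50) {
  if (nrow(calls) == 0L)
    return(structure(list(sites = data.frame(), members = data.frame()),
                     class = "svnet_merged"))
  if (any(calls$svtype != "INS")) stop("merge_insertions expects INS calls")
  if (any(is.na(calls$seq) | !nzchar(calls$seq)))
    stop("INS call without sequence")
  calls <- sort_calls(calls)
  ## neighbor sweep: only calls within max_shift can pair
  n <- nrow(calls)
  edges <- list()
  for (i in seq_len(n - 1)) {
    j <- i + 1L
    while (j <= n && calls$ref_name[j] == calls$ref_name[i] &&
           calls$ref_start[j] - calls$ref_start[i] <= max_shift) {
      ld <- abs(calls$length[i] - calls$length[j]) /
        max(calls$length[i], calls$length[j])
      if (ld <= max_len_diff &&
          sequence_identity(calls$seq[i], calls$seq[j]) >= min_identity)
        edges[[length(edges) + 1L]] <- c(i, j)
      j <- j + 1L
    }
  }
  edges <- do.call(rbind, edges) %||% matrix(0L, 0, 2)
  comp <- components_of(n, edges)
  build_merged(calls, comp, "INS")
}

#' Merge a full per-sample callset by SV type
#'
#' @param calls combined calls of all samples and types (no CPX).
#' @param ro_threshold,max_shift,max_len_diff,min_identity thresholds
#'   passed to the per-type mergers.
#' @return `svnet_merged` covering all types, sites coordinate-sorted
#'   with per-type id prefixes.
#' @export
merge_calls <- function(calls, ro_threshold = 0.9, max_shift = 12,
                        max_len_diff = 0.20, min_identity = 0.50) {
  sites <- list(); members <- list()
  for (tp in intersect(c("DEL", "INS", "DUP", "INV", "TRA"),
                       unique(calls$svtype))) {
    sub <- calls[calls$svtype == tp, , drop = FALSE]
    m <- if (tp == "INS")
      merge_insertions(sub, max_shift, max_len_diff, min_identity)
    else merge_span_svs(sub, ro_threshold)
    sites[[tp]] <- m$sites
    members[[tp]] <- m$members
  }
  structure(list(sites = do.call(rbind, sites),
                 members = do.call(rbind, members)),
            class = "svnet_merged")
}
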