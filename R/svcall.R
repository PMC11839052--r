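## Per-sample variant calling from the filtered net: deletions,
## insertions, complex loci (from chain gaps), inversions and
## translocations (from classified fills), tandem duplications (from
## reference multi-coverage), and SNVs (from single-coverage columns).

SV_CALL_COLS <- c("sample", "svtype", "ref_name", "ref_start", "ref_end",
                  "query_name", "query_start", "query_end", "strand",
                  "length", "size_class", "seq", "source")

empty_calls <- function() {
  df <- data.frame(sample = character(0), svtype = character(0),
                   ref_name = character(0), ref_start = numeric(0),
                   ref_end = numeric(0), query_name = character(0),
                   query_start = numeric(0), query_end = numeric(0),
                   strand = character(0), length = numeric(0),
                   size_class = character(0), seq = character(0),
                   source = character(0), stringsAsFactors = FALSE)
  df
}

size_class_of <- function(len, min_sv = 50) {
  ifelse(len >= min_sv, "sv", "indel")
}

sort_calls <- function(calls) {
  calls <- calls[order(calls$ref_name, calls$ref_start, calls$ref_end,
                       calls$svtype), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call gap variants (DEL/INS/CPX) from one chain
#'
#' Each inter-segment gap of a chain is classified by its two gap sides:
#' reference-only gaps are deletions, query-only gaps insertions; when
#' both sides gap and the smaller side is below `cpx_min` the locus is
#' double-reported as a deletion plus an insertion (unbalanced
#' substitution), otherwise it is a complex locus (CPX).
#'
#' @param chain a `svnet_chain`.
#' @param ref_genome,query_genome named `DNAStringSet`s (allele sequence
#'   extraction).
#' @param min_sv SV/indel size threshold in bases (events `>= min_sv` are
#'   class `"sv"`, smaller ones `"indel"`).
#' @param cpx_min minimum smaller-side gap for a double-sided gap to be
#'   reported as CPX.
#' @param sample sample name recorded in the calls.
#' @return data.frame of calls (CPX rows carry `svtype = "CPX"` and are
#'   conventionally excluded from merging/genotyping).
#' @export
call_gap_variants <- function(chain, ref_genome, query_genome,
                              min_sv = 50, cpx_min = 20,
                              sample = "sample") {
  g <- chain_gaps(chain)
  rsz <- genome_sizes(ref_genome); qsz <- genome_sizes(query_genome)
  if (nrow(g) &&
      (any(g$ref_end > rsz[[chain$ref_name]]) ||
       any(g$query_end > qsz[[chain$query_name]])))
    stop("validation error: gap coordinates outside genome bounds")
  if (!nrow(g)) return(empty_calls())
  minus <- chain$strand == "-"
  rstr <- as.character(as_dna(ref_genome)[[chain$ref_name]])
  qstr <- as.character(as_dna(query_genome)[[chain$query_name]])
  small <- g$dr > 0 & g$dq > 0 & pmin(g$dr, g$dq) < cpx_min
  is_del <- g$dr > 0 & (g$dq == 0 | small)
  is_ins <- g$dq > 0 & (g$dr == 0 | small)
  is_cpx <- g$dr > 0 & g$dq > 0 & !small
  row_of <- function(svtype, idx, len, rs, re, qs, qe, seqs) {
    if (!length(idx)) return(NULL)
    data.frame(sample = sample, svtype = svtype,
               ref_name = chain$ref_name, ref_start = rs, ref_end = re,
               query_name = chain$query_name, query_start = qs,
               query_end = qe, strand = chain$strand, length = len,
               size_class = size_class_of(len, min_sv), seq = seqs,
               source = chain$id, stringsAsFactors = FALSE)
  }
  di <- which(is_del)
  dseq <- if (length(di)) substring(rstr, g$ref_start[di] + 1,
                                    g$ref_end[di]) else character(0)
  del <- row_of("DEL", di, g$dr[di], g$ref_start[di], g$ref_end[di],
                g$query_start[di], g$query_start[di], dseq)
  ii <- which(is_ins)
  iseq <- if (length(ii)) substring(qstr, g$query_start[ii] + 1,
                                    g$query_end[ii]) else character(0)
  if (minus && length(ii)) iseq <- revcomp_chr(iseq)
  ## unbalanced double gaps report the insertion at the right breakpoint
  ipos <- ifelse(g$dr[ii] > 0, g$ref_end[ii], g$ref_start[ii])
  ins <- row_of("INS", ii, g$dq[ii], ipos, ipos,
                g$query_start[ii], g$query_end[ii], iseq)
  xi <- which(is_cpx)
  cpx <- row_of("CPX", xi, pmax(g$dr[xi], g$dq[xi]), g$ref_start[xi],
                g$ref_end[xi], g$query_start[xi], g$query_end[xi],
                NA_character_)
  sort_calls(rbind(del, ins, cpx) %||% empty_calls())
}

#' Call inversions from classified net fills
#'
#' @param net a classified (and typically filtered) `svnet_net`.
#' @param sample sample name.
#' @return one INV call per retained `inv` fill, coordinate-sorted.
#' @export
call_inversions <- function(net, sample = "sample") {
  f <- net$fills[net$fills$type == "inv", , drop = FALSE]
  if (!nrow(f)) return(empty_calls())
  out <- lapply(seq_len(nrow(f)), function(i) {
    ch <- net$chains[[f$chain[i]]]
    data.frame(sample = sample, svtype = "INV", ref_name = f$ref_name[i],
               ref_start = f$ref_start[i], ref_end = f$ref_end[i],
               query_name = ch$query_name, query_start = ch$query_start,
               query_end = ch$query_end, strand = ch$strand,
               length = f$ref_end[i] - f$ref_start[i],
               size_class = size_class_of(f$ref_end[i] - f$ref_start[i]),
               seq = NA_character_, source = ch$id,
               stringsAsFactors = FALSE)
  })
  sort_calls(do.call(rbind, out))
}

#' Call translocations from classified net fills
#'
#' @param net a classified `svnet_net`.
#' @param sample sample name.
#' @return one TRA call per `tra` fill carrying both the reference
#'   interval and the donor query interval; no sequence payload.
#' @export
call_translocations <- function(net, sample = "sample") {
  f <- net$fills[net$fills$type == "tra", , drop = FALSE]
  if (!nrow(f)) return(empty_calls())
  out <- lapply(seq_len(nrow(f)), function(i) {
    ch <- net$chains[[f$chain[i]]]
    data.frame(sample = sample, svtype = "TRA", ref_name = f$ref_name[i],
               ref_start = f$ref_start[i], ref_end = f$ref_end[i],
               query_name = ch$query_name, query_start = ch$query_start,
               query_end = ch$query_end, strand = ch$strand,
               length = f$ref_end[i] - f$ref_start[i],
               size_class = size_class_of(f$ref_end[i] - f$ref_start[i]),
               seq = NA_character_, source = ch$id,
               stringsAsFactors = FALSE)
  })
  sort_calls(do.call(rbind, out))
}

#' Call tandem duplications from reference multi-coverage
#'
#' A duplication is reported where a secondary chain maps a distinct
#' query interval onto a reference unit already covered (reciprocal
#' overlap at least `min_ro`) by a higher-scoring chain, or where
#' consecutive segments within one chain overlap on the query.  The
#' reference interval is the duplicated unit; the estimated copy number
#' is recorded in `seq`-free metadata column `copies`.
#'
#' @param net a `svnet_net` (used for the primary coverage).
#' @param chains the full chain list (duplications need secondary
#'   coverage that netting discards).
#' @param min_ro minimum reciprocal overlap between the secondary chain
#'   span and its reference multi-coverage.
#' @param sample sample name.
#' @return data.frame of DUP calls with an extra `copies` column.
#' @export
call_duplications <- function(net, chains, min_ro = 0.8,
                              sample = "sample") {
  if (!length(chains)) return(cbind(empty_calls(), copies = integer(0)))
  sc <- vapply(chains, `[[`, 0, "score")
  chains <- chains[order(sc, decreasing = TRUE)]
  out <- list()
  ## reference aligned intervals of each chain
  ivs <- lapply(chains, function(ch)
    IRanges::reduce(iranges0(ch$blocks$ref_start, ch$blocks$ref_end)))
  rn <- vapply(chains, `[[`, "", "ref_name")
  qn <- vapply(chains, `[[`, "", "query_name")
  for (i in seq_along(chains)[-1]) {
    prim <- which(seq_along(chains) < i & rn == rn[i])
    if (!length(prim)) next
    cov <- IRanges::reduce(do.call(c, ivs[prim]))
    unit <- iranges0(chains[[i]]$ref_start, chains[[i]]$ref_end)
    ov <- sum(IRanges::width(IRanges::intersect(unit, cov)))
    w <- IRanges::width(unit)
    if (ov == 0 || min(ov / w, 1) < min_ro) next
    ## query intervals must be distinct from the primary mapping there
    qdistinct <- TRUE
    for (p in prim) {
      if (qn[p] != qn[i]) next
      seg <- chains[[p]]$blocks
      hit <- seg$ref_end > chains[[i]]$ref_start &
             seg$ref_start < chains[[i]]$ref_end
      if (any(hit)) {
        qov <- pmax(0, pmin(seg$query_end[hit], chains[[i]]$query_end) -
                       pmax(seg$query_start[hit], chains[[i]]$query_start))
        if (sum(qov) > 0.5 * (chains[[i]]$query_end -
                              chains[[i]]$query_start)) qdistinct <- FALSE
      }
    }
    if (!qdistinct) next
    len <- chains[[i]]$ref_end - chains[[i]]$ref_start
    out[[length(out) + 1L]] <- data.frame(
      sample = sample, svtype = "DUP", ref_name = rn[i],
      ref_start = chains[[i]]$ref_start, ref_end = chains[[i]]$ref_end,
      query_name = qn[i], query_start = chains[[i]]$query_start,
      query_end = chains[[i]]$query_end, strand = chains[[i]]$strand,
      length = len, size_class = size_class_of(len), seq = NA_character_,
      source = chains[[i]]$id, copies = 2L, stringsAsFactors = FALSE)
  }
  ## merge duplicate units reported by several extra copies: copy count
  res <- do.call(rbind, out)
  if (is.null(res)) return(cbind(empty_calls(), copies = integer(0)))
  key <- paste(res$ref_name, res$ref_start, res$ref_end)
  n_extra <- table(key)
  res <- res[!duplicated(key), , drop = FALSE]
  res$copies <- as.integer(n_extra[paste(res$ref_name, res$ref_start,
                                         res$ref_end)]) + 1L
  sort_calls(res)
}

#' Call SNVs from single-coverage aligned segments
#'
#' Every aligned column with differing A/C/G/T bases yields a call;
#' columns containing N are skipped; minus-strand query bases are
#' reverse-complemented before comparison.
#'
#' @param single_cov gapless segments from [project_single_coverage()].
#' @param ref_genome,query_genome named `DNAStringSet`s.
#' @param sample sample name.
#' @return data.frame with `sample`, `ref_name`, `pos` (0-based),
#'   `ref_base`, `alt_base`.
#' @export
call_snvs <- function(single_cov, ref_genome, query_genome,
                      sample = "sample") {
  out <- list()
  acgt <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
  for (i in seq_len(nrow(single_cov))) {
    s <- single_cov[i, ]
    r <- charToRaw(genome_subseq(ref_genome, s$ref_name, s$ref_start,
                                 s$ref_end))
    q <- charToRaw(genome_subseq(query_genome, s$query_name,
                                 s$query_start, s$query_end,
                                 revcomp = (s$strand == "-")))
    d <- which(r != q & (r %in% acgt) & (q %in% acgt))
    if (!length(d)) next
    out[[length(out) + 1L]] <- data.frame(
      sample = sample, ref_name = s$ref_name, pos = s$ref_start + d - 1L,
      ref_base = rawToChar(r[d], multiple = TRUE),
      alt_base = rawToChar(q[d], multiple = TRUE),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(sample = character(0), ref_name = character(0),
               pos = numeric(0), ref_base = character(0),
               alt_base = character(0))
  res <- res[order(res$ref_name, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call all variant classes for one sample
#'
#' Convenience wrapper running the per-class callers over a classified,
#' filtered net: gap variants from every retained syntenic fill (gaps
#' explained by a child fill are suppressed), inversions and
#' translocations from classified fills, duplications from reference
#' multi-coverage.  An insertion-shaped top-chain gap that coincides with
#' a called duplication unit (the extra copy) is reported once, as DUP.
#'
#' @param net a classified, filtered `svnet_net`.
#' @param chains the full (pre-net) chain list, for duplication calling.
#' @param ref_genome,query_genome named `DNAStringSet`s.
#' @param sample sample name.
#' @param min_sv,cpx_min see [call_gap_variants()].
#' @param call_snv also call SNVs (off by default; SNV genotyping runs
#'   jointly later from single-coverage segments).
#' @return list with `calls` (DEL/INS/DUP/INV/TRA), `cpx`, and optionally
#'   `snvs`.
#' @export
call_variants <- function(net, chains, ref_genome, query_genome,
                          sample = "sample", min_sv = 50, cpx_min = 20,
                          call_snv = FALSE) {
  f <- net$fills
  gapcalls <- list()
  for (i in seq_len(nrow(f))) {
    if (!f$type[i] %in% c("top", "syn")) next
    ch <- net$chains[[f$chain[i]]]
    cc <- call_gap_variants(ch, ref_genome, query_genome, min_sv = min_sv,
                            cpx_min = cpx_min, sample = sample)
    cc <- cc[cc$ref_start >= f$ref_start[i] - 1 &
             cc$ref_end <= f$ref_end[i] + 1, , drop = FALSE]
    ## suppress gaps explained by a child fill (inversion/translocation)
    kids <- f[!is.na(f$parent) & f$parent == f$fill[i], , drop = FALSE]
    if (nrow(kids) && nrow(cc)) {
      drop <- rep(FALSE, nrow(cc))
      span <- cc$ref_end > cc$ref_start
      for (k in seq_len(nrow(kids))) {
        ov <- pmax(0, pmin(cc$ref_end, kids$ref_end[k]) -
                      pmax(cc$ref_start, kids$ref_start[k]))
        drop <- drop | (span & ov >= 0.5 * (cc$ref_end - cc$ref_start))
      }
      cc <- cc[!drop, , drop = FALSE]
    }
    gapcalls[[length(gapcalls) + 1L]] <- cc
  }
  gapcalls <- do.call(rbind, gapcalls) %||% empty_calls()
  cpx <- gapcalls[gapcalls$svtype == "CPX", , drop = FALSE]
  gapcalls <- gapcalls[gapcalls$svtype != "CPX", , drop = FALSE]
  dups <- call_duplications(net, chains, sample = sample)
  if (nrow(dups)) {
    ## drop the insertion shadow of each duplication's extra copy
    ins <- gapcalls$svtype == "INS"
    shadow <- rep(FALSE, nrow(gapcalls))
    for (k in seq_len(nrow(dups))) {
      cand <- ins & gapcalls$ref_name == dups$ref_name[k] &
        pmin(abs(gapcalls$ref_start - dups$ref_end[k]),
             abs(gapcalls$ref_start - dups$ref_start[k])) <= 50 &
        abs(gapcalls$length - dups$length[k]) /
          pmax(gapcalls$length, dups$length[k]) <= 0.2
      shadow <- shadow | cand
    }
    gapcalls <- gapcalls[!shadow, , drop = FALSE]
  }
  calls <- sort_calls(rbind(gapcalls,
                            dups[, SV_CALL_COLS, drop = FALSE],
                            call_inversions(net, sample),
                            call_translocations(net, sample)))
  res <- list(calls = calls, cpx = sort_calls(cpx), dups = dups)
  if (call_snv) {
    sc <- project_single_coverage(net)
    res$snvs <- call_snvs(sc, ref_genome, query_genome, sample)
  }
  res
}
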