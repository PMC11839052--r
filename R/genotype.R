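## Re-genotyping: every merged site is classified ALT / REF / MISSING in
## every sample from the local alignment context of that sample's
## single-coverage whole-genome alignment; insertions can additionally be
## verified by global realignment of the local windows (Stretcher-style
## affine-gap Needleman-Wunsch).

#' Index a sample's single-coverage alignment for genotyping
#'
#' Precomputes the inter-segment gap table (per chain) so windows can be
#' extracted cheaply.
#'
#' @param single_cov gapless segments from [project_single_coverage()].
#' @return object of class `svnet_sample_aln`.
#' @export
sample_alignment <- function(single_cov) {
  seg <- single_cov[order(single_cov$chain, single_cov$ref_start), ,
                    drop = FALSE]
  gaps <- list()
  for (ch in unique(seg$chain)) {
    s <- seg[seg$chain == ch, , drop = FALSE]
    n <- nrow(s)
    if (n < 2L) next
    plus <- s$strand[1] == "+"
    g <- data.frame(
      ref_name = s$ref_name[-n],
      ref_start = s$ref_end[-n], ref_end = s$ref_start[-1],
      query_name = s$query_name[-n],
      query_start = if (plus) s$query_end[-n] else s$query_end[-1],
      query_end = if (plus) s$query_start[-1] else s$query_start[-n],
      strand = s$strand[-n], chain = ch, stringsAsFactors = FALSE)
    g$dr <- g$ref_end - g$ref_start
    g$dq <- g$query_end - g$query_start
    gaps[[length(gaps) + 1L]] <- g[g$dr > 0 | g$dq > 0, , drop = FALSE]
  }
  gaps <- do.call(rbind, gaps) %||%
    data.frame(ref_name = character(0), ref_start = numeric(0),
               ref_end = numeric(0), query_name = character(0),
               query_start = numeric(0), query_end = numeric(0),
               strand = character(0), chain = character(0),
               dr = numeric(0), dq = numeric(0))
  seg <- seg[order(seg$ref_name, seg$ref_start), , drop = FALSE]
  gaps <- gaps[order(gaps$ref_name, gaps$ref_start), , drop = FALSE]
  structure(list(segments = seg, gaps = gaps), class = "svnet_sample_aln")
}

#' Extract the local alignment window around a site
#'
#' @param aln a [sample_alignment()].
#' @param ref_name,start,end site interval (0-based half-open; `start ==
#'   end` for insertions).
#' @param flank window flank in bases (default 2 kb each side).
#' @return list with `segments`, `gaps` (rows intersecting the window),
#'   `window` (the clipped window), `clipped`, and `any_alignment`.
#' @export
extract_window <- function(aln, ref_name, start, end, flank = 2000) {
  lo <- max(0, start - flank); hi <- end + flank
  seg <- aln$segments
  si <- which(seg$ref_name == ref_name & seg$ref_end > lo &
              seg$ref_start < hi)
  gp <- aln$gaps
  gi <- which(gp$ref_name == ref_name & gp$ref_end >= lo &
              gp$ref_start <= hi)
  list(segments = seg[si, , drop = FALSE], gaps = gp[gi, , drop = FALSE],
       window = c(lo, hi), clipped = (start - flank < 0),
       any_alignment = length(si) > 0L)
}

gt_call <- function(state, reason, observed = NA_real_, ratio = NA_real_,
                    identity = NA_real_) {
  list(state = state, reason = reason, observed = observed,
       ratio = ratio, identity = identity)
}

aligned_bases_in <- function(segments, start, end) {
  if (!nrow(segments)) return(0)
  sum(pmax(0, pmin(segments$ref_end, end) - pmax(segments$ref_start, start)))
}

#' Genotype a deletion site in one sample
#'
#' ALT when the window contains a reference-side gap whose interval has
#' reciprocal overlap at least `ro_min` with the site; REF when the site
#' interval is essentially covered by aligned columns (residual gap at
#' most `(1 - ro_min)` of the site length); MISSING otherwise.
#'
#' @param window from [extract_window()].
#' @param site one merged-site row (svtype DEL).
#' @param ro_min reciprocal-overlap threshold.
#' @return list with `state` (`ALT`/`REF`/`MISSING`) and evidence fields.
#' @export
genotype_deletion <- function(window, site, ro_min = 0.5) {
  if (site$svtype != "DEL") stop("genotype_deletion expects a DEL site")
  if (!window$any_alignment) return(gt_call("MISSING", "no_alignment"))
  g <- window$gaps
  g <- g[g$dr > 0 & g$dq <= pmax(10, 0.2 * g$dr), , drop = FALSE]
  if (nrow(g)) {
    ro <- ro_interval(g$ref_start, g$ref_end,
                      rep(site$ref_start, nrow(g)),
                      rep(site$ref_end, nrow(g)))
    best <- which.max(ro)
    if (ro[best] >= ro_min)
      return(gt_call("ALT", "gap_match", observed = g$dr[best],
                     ratio = g$dr[best] / site$length,
                     identity = ro[best]))
  }
  len <- site$ref_end - site$ref_start
  aligned <- aligned_bases_in(window$segments, site$ref_start, site$ref_end)
  if (len - aligned <= (1 - ro_min) * len)
    return(gt_call("REF", "continuous", observed = aligned / len))
  gt_call("MISSING", "ambiguous")
}

locate_insertion_gaps <- function(window, pos, max_shift) {
  g <- window$gaps
  g[g$dq > 0 & g$dr <= pmax(10, 0.2 * g$dq) &
    abs(g$ref_start - pos) <= max_shift, , drop = FALSE]
}

#' Genotype an insertion site from window alignment evidence
#'
#' Looks for a query-side gap at the site breakpoint matching the
#' inserted length within `max_len_diff` and the inserted sequence at
#' identity at least `min_identity`; REF when the alignment runs
#' continuously across the breakpoint (largest local insertion below
#' 50 bp and below `0.2 *` site length); MISSING otherwise.
#'
#' @param window from [extract_window()].
#' @param site merged INS site (carries `seq`).
#' @param query_genome query assembly (`DNAStringSet`) for inserted
#'   sequence extraction.
#' @param max_shift breakpoint tolerance (bases).
#' @param max_len_diff,min_identity length and identity thresholds.
#' @return genotype call list, as [genotype_deletion()].
#' @export
genotype_insertion_aln <- function(window, site, query_genome,
                                   max_shift = 12, max_len_diff = 0.20,
                                   min_identity = 0.50) {
  if (site$svtype != "INS") stop("expects an INS site")
  if (!window$any_alignment) return(gt_call("MISSING", "no_alignment"))
  pos <- site$ref_start
  g <- locate_insertion_gaps(window, pos, max_shift)
  if (nrow(g)) {
    ld <- abs(g$dq - site$length) / pmax(g$dq, site$length)
    cand <- which(ld <= max_len_diff)
    for (i in cand[order(ld[cand])]) {
      ins_seq <- genome_subseq(query_genome, g$query_name[i],
                               g$query_start[i], g$query_end[i],
                               revcomp = (g$strand[i] == "-"))
      idn <- sequence_identity(ins_seq, site$seq)
      if (idn >= min_identity)
        return(gt_call("ALT", "gap_match", observed = g$dq[i],
                       ratio = ld[i], identity = idn))
    }
  }
  ## continuity check near the breakpoint
  near <- window$gaps[abs(window$gaps$ref_start - pos) <= max_shift + 50 &
                      window$gaps$dq > 0, , drop = FALSE]
  biggest <- if (nrow(near)) max(near$dq) else 0
  spanned <- nrow(window$segments) > 0 &&
    min(window$segments$ref_start) <= pos - 10 &&
    max(window$segments$ref_end) >= pos + 10
  if (spanned && biggest < 50 && biggest < 0.2 * site$length)
    return(gt_call("REF", "continuous"))
  gt_call("MISSING", "ambiguous")
}

#' Genotype an insertion by global realignment of local windows
#'
#' Stretcher-style global alignment (unit substitution scores, affine
#' gap open 16 / extend 4) of the sample's local sequence against the
#' reference window; an inserted run at the breakpoint matching the site
#' length within `max_len_diff` and the site sequence at identity at
#' least `min_identity` is ALT; a continuous alignment is REF.
#'
#' @param site merged INS site.
#' @param sample_seq sample-side window sequence.
#' @param ref_seq reference window sequence.
#' @param site_offset 0-based offset of the breakpoint inside `ref_seq`.
#' @param max_shift,max_len_diff,min_identity thresholds as elsewhere.
#' @return genotype call list.
#' @export
genotype_insertion <- function(site, sample_seq, ref_seq, site_offset,
                               max_shift = 12, max_len_diff = 0.20,
                               min_identity = 0.50) {
  if (!nzchar(sample_seq) || !nzchar(ref_seq))
    return(gt_call("MISSING", "no_alignment"))
  if (n_run_length(sample_seq) >= 10)
    return(gt_call("MISSING", "assembly_gap"))
  ## fast paths: byte-identical windows
  spliced <- paste0(substr(ref_seq, 1, site_offset), site$seq,
                    substr(ref_seq, site_offset + 1, nchar(ref_seq)))
  if (sample_seq == spliced)
    return(gt_call("ALT", "gap_match", observed = site$length, ratio = 0,
                   identity = 1))
  if (sample_seq == ref_seq) return(gt_call("REF", "continuous"))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(ref_seq, sample_seq, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 16, gapExtension = 4)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ins_col <- p == "-"
  rl <- rle(ins_col)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
  ref_before <- cumsum(!ins_col)   # ref offset after each column
  best <- NULL
  for (k in which(rl$values)) {
    run_pos <- if (starts[k] == 1) 0 else ref_before[starts[k] - 1]
    run_len <- rl$lengths[k]
    if (abs(run_pos - site_offset) > max_shift) next
    if (abs(run_len - site$length) / max(run_len, site$length) >
        max_len_diff) next
    ins_seq <- paste(s[starts[k]:ends[k]], collapse = "")
    idn <- sequence_identity(ins_seq, site$seq)
    if (idn >= min_identity &&
        (is.null(best) || idn > best$identity))
      best <- gt_call("ALT", "gap_match", observed = run_len,
                      ratio = abs(run_len - site$length) /
                        max(run_len, site$length), identity = idn)
  }
  if (!is.null(best)) return(best)
  near <- which(rl$values &
                abs(ifelse(starts == 1, 0, ref_before[pmax(1, starts - 1)]) -
                    site_offset) <= max_shift + 50)
  biggest <- if (length(near)) max(rl$lengths[near]) else 0
  if (biggest < 50 && biggest < 0.2 * site$length)
    return(gt_call("REF", "continuous"))
  gt_call("MISSING", "ambiguous")
}

n_run_length <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L) 0L else max(attr(m, "match.length"))
}

#' Genotype a small indel (< 50 bp)
#'
#' ALT when an indel of matching sign with length within 20% occurs
#' within `shift_tol` of the site position; REF when the alignment is
#' continuous there; MISSING otherwise.
#'
#' @param window from [extract_window()].
#' @param site merged site of length < 50 (svtype DEL or INS).
#' @param shift_tol positional tolerance (bases).
#' @param max_len_diff relative length tolerance.
#' @return genotype call list.
#' @export
genotype_small_indel <- function(window, site, shift_tol = 12,
                                 max_len_diff = 0.20) {
  if (!window$any_alignment) return(gt_call("MISSING", "no_alignment"))
  pos <- site$ref_start
  g <- window$gaps
  if (site$svtype == "DEL") {
    g <- g[g$dr > 0 & g$dq <= 0.2 * g$dr &
           abs(g$ref_start - pos) <= shift_tol, , drop = FALSE]
    obs <- g$dr
  } else {
    g <- g[g$dq > 0 & g$dr <= 0.2 * g$dq &
           abs(g$ref_start - pos) <= shift_tol, , drop = FALSE]
    obs <- g$dq
  }
  if (length(obs)) {
    ld <- abs(obs - site$length) / pmax(obs, site$length)
    if (any(ld <= max_len_diff)) {
      i <- which.min(ld)
      return(gt_call("ALT", "gap_match", observed = obs[i], ratio = ld[i]))
    }
  }
  span <- c(min(pos, site$ref_start) - 2, max(pos + 1, site$ref_end) + 2)
  aligned <- aligned_bases_in(window$segments, span[1], span[2])
  if (aligned >= 0.8 * (span[2] - span[1]))
    return(gt_call("REF", "continuous"))
  gt_call("MISSING", "ambiguous")
}

#' Genotype all merged sites in one sample
#'
#' Dispatches on site class: deletions and small indels are read from
#' the window gap structure, insertions from window gap structure with
#' inserted-sequence verification (falling back to global realignment
#' when the evidence is ambiguous and genomes are supplied), and
#' DUP/INV/TRA sites from call membership plus window coverage.
#'
#' @param sites merged site table (`svnet_merged$sites`).
#' @param aln [sample_alignment()] of this sample.
#' @param sample sample name.
#' @param ref_genome,query_genome assemblies (sequence-level checks; the
#'   query genome is required for insertion verification).
#' @param members `svnet_merged$members` (membership evidence for
#'   symbolic types).
#' @param flank window flank (bases).
#' @param ro_min,max_shift,max_len_diff,min_identity thresholds.
#' @return data.frame with `id`, `state`, `reason`.
#' @export
genotype_sample <- function(sites, aln, sample, ref_genome = NULL,
                            query_genome = NULL, members = NULL,
                            flank = 2000, ro_min = 0.5, max_shift = 12,
                            max_len_diff = 0.20, min_identity = 0.50) {
  n <- nrow(sites)
  state <- character(n); reason <- character(n)
  member_ids <- if (!is.null(members))
    unique(members$id[members$sample == sample]) else character(0)
  for (i in seq_len(n)) {
    site <- sites[i, ]
    w <- extract_window(aln, site$ref_name, site$ref_start, site$ref_end,
                        flank = flank)
    res <- if (site$svtype %in% c("DUP", "INV", "TRA")) {
      if (site$id %in% member_ids) gt_call("ALT", "gap_match")
      else if (!w$any_alignment) gt_call("MISSING", "no_alignment")
      else {
        aligned <- aligned_bases_in(w$segments, site$ref_start,
                                    site$ref_end)
        len <- max(1, site$ref_end - site$ref_start)
        if (aligned >= ro_min * len) gt_call("REF", "continuous")
        else gt_call("MISSING", "ambiguous")
      }
    } else if (site$length < 50) {
      genotype_small_indel(w, site, shift_tol = max_shift,
                           max_len_diff = max_len_diff)
    } else if (site$svtype == "DEL") {
      genotype_deletion(w, site, ro_min = ro_min)
    } else {
      r <- if (!is.null(query_genome))
        genotype_insertion_aln(w, site, query_genome,
                               max_shift = max_shift,
                               max_len_diff = max_len_diff,
                               min_identity = min_identity)
      else gt_call("MISSING", "no_alignment")
      if (r$state == "MISSING" && r$reason == "ambiguous" &&
          !is.null(ref_genome) && !is.null(query_genome) &&
          nrow(w$segments)) {
        ## realignment fallback over the query span of the window
        qlo <- min(w$segments$query_start); qhi <- max(w$segments$query_end)
        qn <- w$segments$query_name[1]
        minus <- w$segments$strand[1] == "-"
        sseq <- genome_subseq(query_genome, qn, qlo, qhi, revcomp = minus)
        rlo <- max(0, site$ref_start - flank)
        rhi <- min(genome_sizes(ref_genome)[[site$ref_name]],
                   site$ref_end + flank)
        rseq <- genome_subseq(ref_genome, site$ref_name, rlo, rhi)
        r <- genotype_insertion(site, sseq, rseq,
                                site_offset = site$ref_start - rlo,
                                max_shift = max_shift,
                                max_len_diff = max_len_diff,
                                min_identity = min_identity)
      }
      r
    }
    state[i] <- res$state; reason[i] <- res$reason
  }
  data.frame(id = sites$id, state = state, reason = reason,
             stringsAsFactors = FALSE)
}

#' Genotype SNV positions across one sample
#'
#' @param single_cov single-coverage segments of the sample.
#' @param query_genome the sample assembly.
#' @param positions data.frame with `ref_name` and `pos` (0-based),
#'   coordinate-sorted.
#' @return character vector of observed bases (strand-corrected) or
#'   `NA` where unaligned or N.
#' @export
genotype_snv <- function(single_cov, query_genome, positions) {
  out <- rep(NA_character_, nrow(positions))
  seg <- single_cov[order(single_cov$ref_name, single_cov$ref_start), ,
                    drop = FALSE]
  for (nm in unique(positions$ref_name)) {
    pi <- which(positions$ref_name == nm)
    s <- seg[seg$ref_name == nm, , drop = FALSE]
    if (!nrow(s)) next
    idx <- findInterval(positions$pos[pi], s$ref_start)
    ok <- idx >= 1 & positions$pos[pi] < s$ref_end[pmax(1, idx)]
    for (k in which(ok)) {
      srow <- s[idx[k], ]
      p <- positions$pos[pi[k]]
      q0 <- if (srow$strand == "+") srow$query_start + (p - srow$ref_start)
            else srow$query_end - 1 - (p - srow$ref_start)
      b <- genome_subseq(query_genome, srow$query_name, q0, q0 + 1,
                         revcomp = (srow$strand == "-"))
      if (b %in% c("A", "C", "G", "T")) out[pi[k]] <- b
    }
  }
  out
}

## ---- VCF ---------------------------------------------------------------

#' Write merged, genotyped sites as VCF 4.2
#'
#' Deletions anchor at the base left of the removed interval (`REF` =
#' anchor + deleted sequence, `ALT` = anchor, `SVLEN` negative);
#' insertions anchor likewise (`ALT` = anchor + inserted sequence,
#' `SVLEN` positive); DUP/INV/TRA are emitted symbolically with `END`.
#' Genotypes are homozygous-diploid calls `1/1`, `0/0` or `./.` per
#' sample (assemblies are haploid consensus sequences).
#'
#' @param sites merged site table.
#' @param gt character matrix sites x samples with entries `ALT`, `REF`,
#'   `MISSING` (or already-encoded `1/1` etc.).
#' @param ref_genome reference `DNAStringSet` (REF alleles are extracted
#'   and verified from it).
#' @param path output file.
#' @param mech optional per-site mechanism labels written to `INFO/MECH`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, gt, ref_genome, path, mech = NULL) {
  samples <- colnames(gt)
  stopifnot(nrow(gt) == nrow(sites))
  code <- function(x) {
    y <- x
    y[x == "ALT"] <- "1/1"; y[x == "REF"] <- "0/0"; y[x == "MISSING"] <- "./."
    y
  }
  enc <- apply(gt, 2, code)
  if (is.null(dim(enc))) enc <- matrix(enc, nrow = nrow(sites))
  lines <- c("##fileformat=VCFv4.2",
             "##source=svnet",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End, 1-based inclusive\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed SV length\">",
             "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Samples reporting the call\">",
             "##INFO=<ID=MECH,Number=1,Type=String,Description=\"Formation mechanism\">",
             "##INFO=<ID=MECH_ALL,Number=.,Type=String,Description=\"All passing mechanism labels\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    svlen <- if (st$svtype == "DEL") -st$length else st$length
    if (st$svtype %in% c("DEL", "INS")) {
      a0 <- st$ref_start - 1
      if (a0 < 0) stop("site at sequence start lacks an anchor base")
      anchor <- genome_subseq(ref_genome, st$ref_name, a0, a0 + 1)
      if (st$svtype == "DEL") {
        refal <- genome_subseq(ref_genome, st$ref_name, a0, st$ref_end)
        altal <- anchor
        endpos <- st$ref_end
      } else {
        refal <- anchor
        altal <- paste0(anchor, st$seq)
        endpos <- st$ref_start
      }
      pos1 <- a0 + 1
    } else {
      a0 <- st$ref_start
      refal <- genome_subseq(ref_genome, st$ref_name, a0, a0 + 1)
      altal <- paste0("<", st$svtype, ">")
      endpos <- st$ref_end
      pos1 <- a0 + 1
    }
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SUPPORT=%d", st$svtype,
                    as.integer(endpos), as.integer(svlen),
                    as.integer(st$support))
    if (!is.null(mech)) {
      m <- mech[mech$id == st$id, , drop = FALSE]
      if (nrow(m))
        info <- paste0(info, ";MECH=", m$mechanism[1],
                       if (!is.na(m$all[1]) && nzchar(m$all[1]))
                         paste0(";MECH_ALL=", m$all[1]) else "")
    }
    rows[i] <- paste(c(st$ref_name, pos1, st$id, refal, altal, ".", "PASS",
                       info, "GT", enc[i, ]), collapse = "\t")
  }
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' Light-weight reader for round-trips and benchmark input: returns the
#' site table (0-based half-open internal coordinates) and the GT matrix.
#'
#' @param path VCF file.
#' @return list with `sites` and `gt`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  cols <- strsplit(sub("^#", "", hdr[length(hdr)]), "\t")[[1]]
  samples <- cols[-(1:9)]
  if (!length(body))
    return(list(sites = data.frame(), gt = matrix(character(0), 0, 0)))
  f <- do.call(rbind, strsplit(body, "\t"))
  info_get <- function(info, key) {
    v <- sub(paste0(".*", key, "=([^;]*).*"), "\\1", info)
    ifelse(grepl(paste0(key, "="), info), v, NA)
  }
  svtype <- info_get(f[, 8], "SVTYPE")
  svlen <- as.numeric(info_get(f[, 8], "SVLEN"))
  endpos <- as.numeric(info_get(f[, 8], "END"))
  pos1 <- as.numeric(f[, 2])
  ref_start <- ifelse(svtype %in% c("DEL", "INS"), pos1, pos1 - 1)
  ref_end <- ifelse(svtype == "DEL", endpos,
                    ifelse(svtype == "INS", ref_start, endpos))
  seq <- ifelse(svtype == "INS", substring(f[, 5], 2), NA)
  sites <- data.frame(id = f[, 3], svtype = svtype,
                      ref_name = f[, 1], ref_start = ref_start,
                      ref_end = ref_end, length = abs(svlen), seq = seq,
                      support = as.integer(info_get(f[, 8], "SUPPORT")),
                      mech = info_get(f[, 8], "MECH"),
                      stringsAsFactors = FALSE)
  gt <- f[, -(1:9), drop = FALSE]
  dimnames(gt) <- list(sites$id, samples)
  list(sites = sites, gt = gt)
}
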