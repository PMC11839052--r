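## Alignment format I/O: PAF (with cg:Z cigar), MAF, AXT and MUMmer delta
## are normalized to the internal block table (0-based half-open, query
## coordinates on the forward strand).  AXT and MAF can be written back
## bit-compatibly with the UCSC dialects (AXT minus-strand query
## coordinates in reverse-complement frame, 1-based inclusive).

#' Read pairwise whole-genome alignments
#'
#' @param path file path.
#' @param format one of `"paf"`, `"maf"`, `"axt"`, `"delta"`.
#' @param query_sizes named vector of query sequence lengths; required to
#'   place minus-strand AXT records on the forward strand (AXT carries no
#'   query size field).  MAF/PAF/delta carry sizes inline.
#' @param ref_sizes optional named vector used for coordinate validation.
#' @return an [alignment_blocks()] table.  PAF records without a `cg:Z`
#'   tag are kept with `cigar = NA` and counted in
#'   `attr(x, "n_gapless_flagged")`.
#' @export
parse_alignments <- function(path, format = c("paf", "maf", "axt", "delta"),
                             query_sizes = NULL, ref_sizes = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  blocks <- switch(format,
    paf = parse_paf_lines(lines),
    maf = parse_maf_lines(lines),
    axt = parse_axt_lines(lines, query_sizes),
    delta = parse_delta_lines(lines))
  validate_blocks(blocks, sizes_ref = ref_sizes, sizes_query = query_sizes)
  blocks
}

parse_err <- function(i, msg) stop("parse error at line ", i, ": ", msg)

parse_paf_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- vector("list", n)
  flagged <- 0L
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) parse_err(i, "PAF record has fewer than 12 fields")
    qs <- as.numeric(f[3]); qe <- as.numeric(f[4])
    ts <- as.numeric(f[8]); te <- as.numeric(f[9])
    if (anyNA(c(qs, qe, ts, te))) parse_err(i, "non-numeric coordinate")
    if (qe > as.numeric(f[2]) || te > as.numeric(f[7]))
      stop("validation error: coordinate exceeds declared sequence size (line ",
           i, ")")
    cg <- NA_character_
    if (length(f) > 12L) {
      tag <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
      if (length(tag)) cg <- sub("^cg:Z:", "", tag[1])
    }
    if (is.na(cg)) flagged <- flagged + 1L
    out[[i]] <- alignment_blocks(
      ref_name = f[6], ref_start = ts, ref_end = te,
      query_name = f[1], query_start = qs, query_end = qe,
      strand = f[5], score = as.numeric(f[10]), cigar = cg)
  }
  res <- do.call(rbind, out)
  res <- res %||% alignment_blocks()
  class(res) <- c("svnet_blocks", "data.frame")
  attr(res, "n_gapless_flagged") <- flagged
  res
}

## derive a cigar from two equal-length gapped sequence strings
gapped_to_cigar <- function(ref_txt, q_txt) {
  r <- strsplit(ref_txt, "", fixed = TRUE)[[1]]
  q <- strsplit(q_txt, "", fixed = TRUE)[[1]]
  if (length(r) != length(q)) stop("alignment rows of unequal length")
  op <- ifelse(r == "-", "I", ifelse(q == "-", "D", "M"))
  if (any(r == "-" & q == "-")) stop("double-gap column")
  rl <- rle(op)
  cigar_build(rl$values, rl$lengths)
}

parse_maf_lines <- function(lines) {
  s_idx <- grep("^s ", lines)
  a_idx <- grep("^a", lines)
  out <- list()
  for (a in a_idx) {
    s_here <- s_idx[s_idx > a]
    s_here <- s_here[s_here <= a + 4L]  # the two s lines directly follow
    if (length(s_here) < 2L) parse_err(a, "MAF block lacks two 's' lines")
    sc <- sub("^a\\s*(score=)?", "", lines[a])
    score <- suppressWarnings(as.numeric(sc))
    parse_s <- function(i) {
      f <- strsplit(gsub("\\s+", " ", trimws(lines[i])), " ")[[1]]
      if (length(f) < 7L) parse_err(i, "malformed MAF 's' line")
      list(name = f[2], start = as.numeric(f[3]), size = as.numeric(f[4]),
           strand = f[5], src_size = as.numeric(f[6]), text = f[7])
    }
    rr <- parse_s(s_here[1]); qq <- parse_s(s_here[2])
    if (rr$strand != "+") parse_err(s_here[1], "reference row must be '+'")
    ## MAF start is strand-relative: on '-', forward = srcSize - start - size
    qstart <- if (qq$strand == "+") qq$start else qq$src_size - qq$start - qq$size
    blk <- alignment_blocks(
      ref_name = rr$name, ref_start = rr$start, ref_end = rr$start + rr$size,
      query_name = qq$name, query_start = qstart, query_end = qstart + qq$size,
      strand = qq$strand,
      score = if (is.na(score)) rr$size else score,
      cigar = gapped_to_cigar(rr$text, qq$text))
    if (blk$query_end > qq$src_size)
      stop("validation error: MAF query coordinate exceeds srcSize")
    out[[length(out) + 1L]] <- blk
  }
  res <- do.call(rbind, out) %||% alignment_blocks()
  class(res) <- c("svnet_blocks", "data.frame")
  res
}

parse_axt_lines <- function(lines, query_sizes = NULL) {
  lines <- lines[!grepl("^#", lines)]
  keep <- which(nzchar(trimws(lines)))
  out <- list()
  i <- 1L
  while (i <= length(keep)) {
    h <- strsplit(gsub("\\s+", " ", trimws(lines[keep[i]])), " ")[[1]]
    if (length(h) < 9L) parse_err(keep[i], "malformed AXT header")
    if (i + 2L > length(keep)) parse_err(keep[i], "truncated AXT record")
    ref_txt <- trimws(lines[keep[i + 1L]])
    q_txt <- trimws(lines[keep[i + 2L]])
    ts <- as.numeric(h[3]) - 1; te <- as.numeric(h[4])      # 1-based incl -> 0-based half-open
    qs <- as.numeric(h[6]) - 1; qe <- as.numeric(h[7])
    strand <- h[8]
    if (strand == "-") {
      ## AXT minus-strand query coords are in reverse-complement frame
      if (is.null(query_sizes) || !h[5] %in% names(query_sizes))
        stop("query_sizes required to restore minus-strand AXT coordinates (",
             h[5], ")")
      L <- as.numeric(query_sizes[[h[5]]])
      fs <- L - qe; fe <- L - qs
      qs <- fs; qe <- fe
    }
    out[[length(out) + 1L]] <- alignment_blocks(
      ref_name = h[2], ref_start = ts, ref_end = te,
      query_name = h[5], query_start = qs, query_end = qe,
      strand = strand, score = as.numeric(h[9]),
      cigar = gapped_to_cigar(ref_txt, q_txt))
    i <- i + 3L
  }
  res <- do.call(rbind, out) %||% alignment_blocks()
  class(res) <- c("svnet_blocks", "data.frame")
  res
}

## MUMmer delta: per-alignment header "rs re qs qe err ..." (1-based
## inclusive, qs > qe on the minus strand) followed by signed gap
## distances terminated by 0.  A positive d means the reference has an
## unmatched base (D op) |d|-1 columns after the previous indel; negative
## means the query has one (I op).
parse_delta_lines <- function(lines) {
  out <- list()
  i <- 1L
  ref <- NULL; qry <- NULL; rlen <- NA; qlen <- NA
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      f <- strsplit(gsub("\\s+", " ", sub("^>", "", ln)), " ")[[1]]
      if (length(f) < 4L) parse_err(i, "malformed delta sequence header")
      ref <- f[1]; qry <- f[2]
      rlen <- as.numeric(f[3]); qlen <- as.numeric(f[4])
      i <- i + 1L
      next
    }
    f <- suppressWarnings(as.numeric(strsplit(gsub("\\s+", " ", ln), " ")[[1]]))
    if (length(f) >= 7L && !anyNA(f[1:4]) && !is.null(ref)) {
      rs <- f[1]; re <- f[2]; qs <- f[3]; qe <- f[4]
      strand <- if (qs <= qe) "+" else "-"
      ## gap run
      deltas <- numeric(0)
      i <- i + 1L
      repeat {
        if (i > length(lines)) parse_err(i - 1L, "unterminated delta gap list")
        d <- suppressWarnings(as.numeric(trimws(lines[i])))
        if (is.na(d)) parse_err(i, "non-numeric delta value")
        i <- i + 1L
        if (d == 0) break
        deltas <- c(deltas, d)
      }
      ref_span <- re - rs + 1
      q_span <- abs(qe - qs) + 1
      op <- character(0); len <- numeric(0)
      pos <- 0  # columns consumed on the side not gapped
      rleft <- ref_span; qleft <- q_span
      for (d in deltas) {
        m <- abs(d) - 1
        if (m > 0) { op <- c(op, "M"); len <- c(len, m); rleft <- rleft - m; qleft <- qleft - m }
        if (d > 0) { op <- c(op, "D"); len <- c(len, 1); rleft <- rleft - 1 }
        else { op <- c(op, "I"); len <- c(len, 1); qleft <- qleft - 1 }
      }
      if (rleft != qleft) parse_err(i - 1L, "inconsistent delta gap encoding")
      if (rleft > 0) { op <- c(op, "M"); len <- c(len, rleft) }
      q0 <- if (strand == "+") qs - 1 else qe - 1
      q1 <- if (strand == "+") qe else qs
      if (q1 > qlen || re > rlen)
        stop("validation error: delta coordinate exceeds declared size")
      out[[length(out) + 1L]] <- alignment_blocks(
        ref_name = ref, ref_start = rs - 1, ref_end = re,
        query_name = qry, query_start = q0, query_end = q1,
        strand = strand, score = sum(len[op == "M"]),
        cigar = cigar_build(op, len))
      next
    }
    i <- i + 1L
  }
  res <- do.call(rbind, out) %||% alignment_blocks()
  class(res) <- c("svnet_blocks", "data.frame")
  res
}

## ---- writers -----------------------------------------------------------

block_row_text <- function(b, genome_ref, genome_query) {
  cg <- if (is.na(b$cigar) || !nzchar(b$cigar))
    paste0(b$ref_end - b$ref_start, "M") else b$cigar
  ops <- cigar_parse(cg)
  rseq <- genome_subseq(genome_ref, b$ref_name, b$ref_start, b$ref_end)
  qseq <- genome_subseq(genome_query, b$query_name, b$query_start, b$query_end,
                        revcomp = (b$strand == "-"))
  rout <- character(0); qout <- character(0)
  ri <- 1L; qi <- 1L
  for (j in seq_len(nrow(ops))) {
    L <- ops$len[j]
    switch(ops$op[j],
      M = { rout <- c(rout, substr(rseq, ri, ri + L - 1L))
            qout <- c(qout, substr(qseq, qi, qi + L - 1L))
            ri <- ri + L; qi <- qi + L },
      D = { rout <- c(rout, substr(rseq, ri, ri + L - 1L))
            qout <- c(qout, strrep("-", L)); ri <- ri + L },
      I = { rout <- c(rout, strrep("-", L))
            qout <- c(qout, substr(qseq, qi, qi + L - 1L)); qi <- qi + L })
  }
  list(ref = paste(rout, collapse = ""), query = paste(qout, collapse = ""))
}

#' Write alignment blocks as AXT or MAF
#'
#' The inverse of [parse_alignments()]: `parse(write(x))` reproduces the
#' coordinates, strand and cigar of `x`.
#'
#' @param blocks an [alignment_blocks()] table (cigars or gapless).
#' @param path output file.
#' @param format `"axt"` or `"maf"`.
#' @param genome_ref,genome_query named `DNAStringSet`s providing the
#'   aligned sequences.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(blocks, path, format = c("axt", "maf"),
                             genome_ref, genome_query) {
  format <- match.arg(format)
  genome_ref <- as_dna(genome_ref)
  genome_query <- as_dna(genome_query)
  miss <- setdiff(unique(c(blocks$ref_name, blocks$query_name)),
                  c(names(genome_ref), names(genome_query)))
  if (!all(blocks$ref_name %in% names(genome_ref)) ||
      !all(blocks$query_name %in% names(genome_query)))
    stop("block references unknown sequence name: ",
         paste(miss, collapse = ","))
  qsz <- genome_sizes(genome_query)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "maf") writeLines(c("##maf version=1 scoring=svnet", ""), con)
  else writeLines("# axt generated by svnet", con)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    txt <- block_row_text(b, genome_ref, genome_query)
    if (format == "axt") {
      qs <- b$query_start; qe <- b$query_end
      if (b$strand == "-") {            # reverse-complement frame
        L <- qsz[[b$query_name]]
        tmp <- qs; qs <- L - qe; qe <- L - tmp
      }
      writeLines(c(paste(i - 1L, b$ref_name, b$ref_start + 1L, b$ref_end,
                         b$query_name, qs + 1L, qe, b$strand,
                         format(b$score, scientific = FALSE)),
                   txt$ref, txt$query, ""), con)
    } else {
      L <- qsz[[b$query_name]]
      qstart <- if (b$strand == "+") b$query_start else L - b$query_end
      writeLines(c(paste0("a score=", format(b$score, scientific = FALSE)),
                   paste("s", b$ref_name, format(b$ref_start, scientific = FALSE),
                         format(b$ref_end - b$ref_start, scientific = FALSE), "+",
                         format(genome_sizes(genome_ref)[[b$ref_name]],
                                scientific = FALSE), txt$ref),
                   paste("s", b$query_name, format(qstart, scientific = FALSE),
                         format(b$query_end - b$query_start, scientific = FALSE),
                         b$strand, format(L, scientific = FALSE), txt$query),
                   ""), con)
    }
  }
  invisible(path)
}

## ---- split genome ------------------------------------------------------

#' Split large chromosomes into overlapping windows
#'
#' Large, repetitive assemblies are easier on aligner memory when the
#' query is cut into windows (default 20 Mb) overlapping by a fixed
#' amount (default 2 Mb); [restore_coordinates()] lifts alignments of the
#' segments back to source coordinates.
#'
#' @param genome named `DNAStringSet` (or character vector).
#' @param window,overlap window and overlap sizes in bases
#'   (`window > overlap >= 0`); consecutive segment starts differ by
#'   `window - overlap` and the final segment ends at the source end.
#' @return list with `assembly` (segments, named `source:start-end` in
#'   1-based inclusive display coordinates) and `manifest`
#'   (segment/source/offset/length table).
#' @export
split_genome <- function(genome, window = 2e7, overlap = 2e6) {
  if (window <= overlap || overlap < 0) stop("config error: window must exceed overlap")
  genome <- as_dna(genome)
  stride <- window - overlap
  segs <- list(); man <- list()
  for (nm in names(genome)) {
    L <- Biostrings::width(genome[nm])
    starts <- 0
    while (tail(starts, 1) + window < L) starts <- c(starts, tail(starts, 1) + stride)
    ends <- pmin(starts + window, L)
    for (k in seq_along(starts)) {
      seg_name <- sprintf("%s:%d-%d", nm, starts[k] + 1, ends[k])
      segs[[seg_name]] <- Biostrings::subseq(genome[[nm]], starts[k] + 1, ends[k])
      man[[length(man) + 1L]] <- data.frame(
        segment = seg_name, source = nm, offset = starts[k],
        length = ends[k] - starts[k])
    }
  }
  list(assembly = Biostrings::DNAStringSet(segs),
       manifest = do.call(rbind, man))
}

#' Restore split-segment alignment coordinates to source coordinates
#'
#' @param blocks alignments whose query side refers to split segments.
#' @param manifest the manifest returned by [split_genome()].
#' @return blocks with query coordinates shifted by the segment offset and
#'   renamed to the source; alignments duplicated inside overlap zones
#'   (identical coordinates and strand after restoring) are collapsed.
#' @export
restore_coordinates <- function(blocks, manifest) {
  if (nrow(blocks) == 0L) return(blocks)
  idx <- match(blocks$query_name, manifest$segment)
  if (anyNA(idx)) stop("query name(s) absent from manifest: ",
                       paste(unique(blocks$query_name[is.na(idx)]), collapse = ","))
  blocks$query_start <- blocks$query_start + manifest$offset[idx]
  blocks$query_end <- blocks$query_end + manifest$offset[idx]
  blocks$query_name <- manifest$source[idx]
  src_len <- tapply(manifest$offset + manifest$length, manifest$source, max)
  if (any(blocks$query_end > src_len[blocks$query_name]))
    stop("validation error: restored coordinate exceeds source length")
  key <- with(blocks, paste(ref_name, ref_start, ref_end, query_name,
                            query_start, query_end, strand))
  res <- blocks[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a (optionally gzipped) FASTA assembly, uppercased
#'
#' @param path FASTA file.
#' @return named `DNAStringSet`; soft-masking is recorded in
#'   `metadata(x)$masked` as a per-sequence `IRanges` list.
#' @export
read_assembly <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  masked <- lapply(seq_along(x), function(i) {
    m <- gregexpr("[acgtn]+", as.character(x[[i]]))[[1]]
    if (m[1] == -1L) return(IRanges::IRanges())
    IRanges::IRanges(start = as.integer(m), width = attr(m, "match.length"))
  })
  names(masked) <- names(x)
  up <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(up) <- names(x)
  S4Vectors::metadata(up)$masked <- masked
  up
}
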