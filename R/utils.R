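#' @useDynLib svnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import IRanges
#' @importFrom methods is
#' @importFrom stats rbinom runif rgeom setNames
#' @importFrom utils head tail read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## ---- CIGAR arithmetic -------------------------------------------------
## Ops: M aligned columns, I insertion in query (consumes query),
## D deletion from query (consumes reference).

#' Parse a CIGAR string into op/length pairs
#'
#' @param cigar character scalar such as `"100M10D90M"`; only ops M, I, D
#'   (alignment match, query insertion, query deletion) are accepted.
#' @return data.frame with columns `op` and `len`.
#' @export
cigar_parse <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  m <- gregexpr("(\\d+)([MIDX=])", cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed cigar: ", cigar)
  op <- substring(toks, nchar(toks), nchar(toks))
  ## X/= are treated as M (aligned column with/without identity)
  op[op %in% c("X", "=")] <- "M"
  data.frame(op = op, len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

cigar_build <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (length(op) == 0L) return("")
  ## merge adjacent equal ops
  grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
  len <- vapply(split(len, grp), sum, 0)
  op <- op[!duplicated(grp)]
  paste0(as.integer(len), op, collapse = "")
}

cigar_spans <- function(cigar) {
  cg <- cigar_parse(cigar)
  c(ref = sum(cg$len[cg$op %in% c("M", "D")]),
    query = sum(cg$len[cg$op %in% c("M", "I")]))
}

## ---- alignment block container ---------------------------------------

#' Construct a table of alignment blocks
#'
#' The internal alignment representation: one row per local alignment
#' between the reference and a query assembly.  All coordinates are
#' 0-based half-open; query coordinates always refer to the query
#' *forward* strand regardless of `strand`.  For minus-strand blocks the
#' CIGAR (and any derived aligned segment) walks the reference forward
#' and the query from `query_end` downwards.
#'
#' @param ref_name,ref_start,ref_end reference sequence name and interval.
#' @param query_name,query_start,query_end query sequence name and interval.
#' @param strand `"+"` or `"-"`.
#' @param score alignment score (arbitrary units; defaults to aligned span).
#' @param cigar CIGAR strings over ops M/I/D, or `NA` for blocks whose
#'   internal gap structure is unknown (kept, but excluded from base-level
#'   operations).
#' @return data.frame of class `svnet_blocks`.
#' @export
alignment_blocks <- function(ref_name = character(), ref_start = integer(),
                             ref_end = integer(), query_name = character(),
                             query_start = integer(), query_end = integer(),
                             strand = character(), score = NULL,
                             cigar = NA_character_) {
  n <- length(ref_start)
  if (is.null(score)) score <- as.numeric(ref_end - ref_start)
  df <- data.frame(ref_name = as.character(ref_name),
                   ref_start = as.numeric(ref_start),
                   ref_end = as.numeric(ref_end),
                   query_name = as.character(query_name),
                   query_start = as.numeric(query_start),
                   query_end = as.numeric(query_end),
                   strand = as.character(strand),
                   score = as.numeric(score),
                   cigar = rep_len(as.character(cigar), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("svnet_blocks", "data.frame")
  df
}

validate_blocks <- function(blocks, sizes_ref = NULL, sizes_query = NULL) {
  if (nrow(blocks) == 0L) return(invisible(blocks))
  bad <- which(blocks$ref_end <= blocks$ref_start |
               blocks$query_end <= blocks$query_start)
  if (length(bad))
    stop("validation error: empty interval in block(s) ",
         paste(head(bad, 5), collapse = ","))
  if (!all(blocks$strand %in% c("+", "-")))
    stop("validation error: strand must be '+' or '-'")
  has_cg <- !is.na(blocks$cigar) & nzchar(blocks$cigar)
  for (i in which(has_cg)) {
    sp <- cigar_spans(blocks$cigar[i])
    if (sp["ref"] != blocks$ref_end[i] - blocks$ref_start[i] ||
        sp["query"] != blocks$query_end[i] - blocks$query_start[i])
      stop("validation error: cigar spans disagree with coordinates in block ", i)
  }
  chk <- function(nm, end, sizes, what) {
    if (is.null(sizes)) return()
    known <- nm %in% names(sizes)
    if (any(known & end > sizes[nm]))
      stop("validation error: ", what, " coordinate exceeds declared size")
  }
  chk(blocks$ref_name, blocks$ref_end, sizes_ref, "reference")
  chk(blocks$query_name, blocks$query_end, sizes_query, "query")
  invisible(blocks)
}

#' Expand alignment blocks into gapless aligned segments
#'
#' Each CIGAR `M` run becomes one row; blocks without a CIGAR are kept as
#' a single segment when their two spans agree and dropped (with a
#' warning) otherwise.
#'
#' @param blocks an [alignment_blocks()] table.
#' @return data.frame with the same coordinate columns plus `block` (the
#'   originating row index); every row satisfies
#'   `ref_end - ref_start == query_end - query_start`.
#' @export
blocks_to_segments <- function(blocks) {
  ## fast path: gapless blocks (single M run) expand to themselves
  cg <- blocks$cigar
  gapless <- !is.na(cg) & grepl("^[0-9]+M$", cg)
  if (all(gapless)) {
    seg <- data.frame(ref_start = blocks$ref_start,
                      ref_end = blocks$ref_end,
                      query_start = blocks$query_start,
                      query_end = blocks$query_end,
                      block = seq_len(nrow(blocks)),
                      ref_name = blocks$ref_name,
                      query_name = blocks$query_name,
                      strand = blocks$strand, stringsAsFactors = FALSE)
    return(seg)
  }
  out <- vector("list", nrow(blocks))
  dropped <- 0L
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (is.na(b$cigar) || !nzchar(b$cigar)) {
      if (b$ref_end - b$ref_start == b$query_end - b$query_start) {
        out[[i]] <- data.frame(ref_start = b$ref_start, ref_end = b$ref_end,
                               query_start = b$query_start,
                               query_end = b$query_end, block = i)
      } else dropped <- dropped + 1L
      next
    }
    cg <- cigar_parse(b$cigar)
    r <- b$ref_start
    q <- if (b$strand == "+") b$query_start else b$query_end
    rs <- numeric(0); re <- numeric(0); qs <- numeric(0); qe <- numeric(0)
    for (j in seq_len(nrow(cg))) {
      L <- cg$len[j]
      switch(cg$op[j],
        M = {
          rs <- c(rs, r); re <- c(re, r + L)
          if (b$strand == "+") { qs <- c(qs, q); qe <- c(qe, q + L); q <- q + L }
          else { qs <- c(qs, q - L); qe <- c(qe, q); q <- q - L }
          r <- r + L
        },
        D = { r <- r + L },
        I = { q <- if (b$strand == "+") q + L else q - L })
    }
    out[[i]] <- data.frame(ref_start = rs, ref_end = re,
                           query_start = qs, query_end = qe, block = i)
  }
  if (dropped > 0L)
    warning(dropped, " block(s) without cigar and unequal spans skipped")
  seg <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(seg))
    seg <- data.frame(ref_start = numeric(0), ref_end = numeric(0),
                      query_start = numeric(0), query_end = numeric(0),
                      block = integer(0))
  seg$ref_name <- blocks$ref_name[seg$block]
  seg$query_name <- blocks$query_name[seg$block]
  seg$strand <- blocks$strand[seg$block]
  seg
}

## ---- sequences --------------------------------------------------------

#' Extract a genome subsequence by 0-based half-open coordinates
#'
#' @param genome a named `DNAStringSet` (or named character vector).
#' @param name sequence name.
#' @param start0,end0 0-based half-open interval.
#' @param revcomp reverse-complement the result.
#' @return character scalar.
#' @export
genome_subseq <- function(genome, name, start0, end0, revcomp = FALSE) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!name %in% names(genome)) stop("unknown sequence name: ", name)
  s <- Biostrings::subseq(genome[[name]], start = start0 + 1L, end = end0)
  if (revcomp) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Named vector of sequence lengths of an assembly
#'
#' @param genome named `DNAStringSet` or character vector.
#' @return named numeric vector of lengths in bases.
#' @export
genome_sizes <- function(genome) {
  if (is.character(genome)) setNames(nchar(genome), names(genome))
  else setNames(Biostrings::width(genome), names(genome))
}

as_dna <- function(x) {
  if (is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(unlist(x))
}

## ---- intervals ---------------------------------------------------------

## reciprocal overlap of 0-based half-open intervals (vectorized)
ro_interval <- function(s1, e1, s2, e2) {
  if (any(e1 <= s1) || any(e2 <= s2)) stop("zero-length interval")
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

iranges0 <- function(start0, end0) {
  IRanges::IRanges(start = as.integer(start0) + 1L, end = as.integer(end0))
}

from_iranges0 <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
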