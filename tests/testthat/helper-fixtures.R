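## Shared fixture builders: everything is generated in code at test time.

rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## a pair of toy genomes plus n random gapless-or-cigar blocks consistent
## with them (for format round-trips)
random_block_fixture <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    ref <- Biostrings::DNAStringSet(c(r1 = rand_seq(5000), r2 = rand_seq(3000)))
    qry <- Biostrings::DNAStringSet(c(q1 = rand_seq(5000), q2 = rand_seq(4000)))
    rows <- lapply(seq_len(n), function(i) {
      rn <- sample(names(ref), 1); qn <- sample(names(qry), 1)
      strand <- sample(c("+", "-"), 1)
      nops <- sample(1:4, 1)
      ops <- c("M", sample(c("M", "I", "D"), nops - 1, replace = TRUE))
      lens <- sample(5:40, nops, replace = TRUE)
      ## normalize: start and end on M, merge handled by cigar_build
      ops[nops] <- "M"
      cg <- svnet:::cigar_build(ops, lens)
      lens <- svnet:::cigar_parse(cg)$len
      ops <- svnet:::cigar_parse(cg)$op
      rspan <- sum(lens[ops %in% c("M", "D")])
      qspan <- sum(lens[ops %in% c("M", "I")])
      rs <- sample(0:(Biostrings::width(ref[rn]) - rspan - 1), 1)
      qs <- sample(0:(Biostrings::width(qry[qn]) - qspan - 1), 1)
      alignment_blocks(ref_name = rn, ref_start = rs, ref_end = rs + rspan,
                       query_name = qn, query_start = qs,
                       query_end = qs + qspan, strand = strand,
                       score = rspan, cigar = cg)
    })
    blocks <- do.call(rbind, rows)
    class(blocks) <- c("svnet_blocks", "data.frame")
    list(ref = ref, qry = qry, blocks = blocks)
  })
}

## a chain built directly from block coordinates
toy_chain <- function(rs, re, qs, qe, ref = "r", qry = "q", strand = "+",
                      id = "c0001", score = NULL) {
  blocks <- alignment_blocks(
    ref_name = ref, ref_start = rs, ref_end = re, query_name = qry,
    query_start = qs, query_end = qe, strand = strand,
    cigar = paste0(re - rs, "M"))
  ch <- structure(list(id = id, blocks = blocks,
                       score = score %||% sum(re - rs),
                       ref_name = ref, query_name = qry, strand = strand,
                       ref_start = min(rs), ref_end = max(re),
                       query_start = min(qs), query_end = max(qe)),
                  class = "svnet_chain")
  ch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force per-base coverage of segments on one side
brute_coverage <- function(seg, side = "ref") {
  s <- seg[[paste0(side, "_start")]]; e <- seg[[paste0(side, "_end")]]
  nm <- seg[[paste0(side, "_name")]]
  out <- list()
  for (u in unique(nm)) {
    idx <- nm == u
    cov <- integer(max(e[idx]))
    for (k in which(idx)) {
      rng <- (s[k] + 1):e[k]
      cov[rng] <- cov[rng] + 1L
    }
    out[[u]] <- cov
  }
  out
}

## exhaustive optimal one-to-one matching cardinality (small instances)
brute_best_matching <- function(pairs, n_call, n_truth) {
  if (!nrow(pairs)) return(0L)
  best <- 0L
  recurse <- function(k, used_c, used_t, count) {
    if (count + (nrow(pairs) - k + 1) <= best) return()
    if (k > nrow(pairs)) { best <<- max(best, count); return() }
    ## take pair k if free
    if (!used_c[pairs$call[k]] && !used_t[pairs$truth[k]]) {
      used_c[pairs$call[k]] <- TRUE; used_t[pairs$truth[k]] <- TRUE
      recurse(k + 1, used_c, used_t, count + 1L)
      used_c[pairs$call[k]] <- FALSE; used_t[pairs$truth[k]] <- FALSE
    }
    recurse(k + 1, used_c, used_t, count)
  }
  recurse(1L, logical(n_call), logical(n_truth), 0L)
  best
}

## cached acceptance-scale runs (shared by several criteria blocks)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_population_run <- function() {
  if (is.null(.acceptance_cache$popA))
    .acceptance_cache$popA <- benchmark_population(
      seed = 101, n_genomes = 21, n_chrom = 2, chrom_length = 2.5e6,
      n_del = 450, n_ins = 450, n_dup = 100, sv_size = c(50, 10000))
  .acceptance_cache$popA
}

acceptance_divergence_run <- function() {
  if (is.null(.acceptance_cache$popC))
    .acceptance_cache$popC <- benchmark_population(
      seed = 303, n_genomes = 21, n_chrom = 2, chrom_length = 2.5e6,
      n_del = 450, n_ins = 450, n_dup = 100, sv_size = c(50, 10000),
      n_small = 300, small_size = c(5, 49),
      divergence = list(sub_rate = 0.02, indel_rate = 0.002))
  .acceptance_cache$popC
}
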