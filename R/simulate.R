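## Synthetic-data generators: random reference genomes with a planted
## repeat/TE library, SV-mutated genomes (reference-based design),
## divergence-mutated genomes, population-scale genome sets from a 0/1
## genotype matrix, and the exact truth alignments implied by an edit
## script.  Every generator is a pure function of (inputs, seed).

## ---- edit scripts ------------------------------------------------------
## An edit script is a data.frame with columns
##   type     one of sub / del / ins / inv / dup
##   ref_name, ref_start, ref_end   0-based half-open (ins: start == end)
##   seq      replacement (sub) or inserted sequence (ins); NA otherwise
##   copies   total copy count for dup (>= 2); NA otherwise
## Edits are non-overlapping on the reference and applied left to right.

empty_edits <- function() {
  data.frame(type = character(0), ref_name = character(0),
             ref_start = numeric(0), ref_end = numeric(0),
             seq = character(0), copies = integer(0),
             stringsAsFactors = FALSE)
}

sort_edits <- function(edits) {
  edits <- edits[order(edits$ref_name, edits$ref_start, edits$ref_end), ,
                 drop = FALSE]
  rownames(edits) <- NULL
  edits
}

#' Replay an edit script on a reference genome
#'
#' @param ref named `DNAStringSet` (or character vector).
#' @param edits an edit-script data.frame (see package internals /
#'   [simulate_svs()]); non-overlapping, 0-based half-open.
#' @return `DNAStringSet` of the edited genome.
#' @export
apply_edits <- function(ref, edits) {
  ref <- as_dna(ref)
  out <- lapply(names(ref), function(nm) {
    s <- as.character(ref[[nm]])
    e <- sort_edits(edits[edits$ref_name == nm, , drop = FALSE])
    if (!nrow(e)) return(s)
    if (any(e$ref_start < c(0, e$ref_end[-nrow(e)])))
      stop("overlapping edits on ", nm)
    if (!all(e$type %in% c("sub", "del", "ins", "inv", "dup")))
      stop("unknown edit type")
    ## unedited gaps between consecutive edits (vectorized)
    gap_s <- c(0, e$ref_end)
    gap_e <- c(e$ref_start, nchar(s))
    gaps <- substring(s, gap_s + 1, gap_e)
    repl <- character(nrow(e))
    tp <- e$type
    repl[tp == "sub" | tp == "ins"] <- e$seq[tp == "sub" | tp == "ins"]
    repl[tp == "del"] <- ""
    iv <- which(tp == "inv")
    if (length(iv))
      repl[iv] <- revcomp_chr(substring(s, e$ref_start[iv] + 1,
                                        e$ref_end[iv]))
    dp <- which(tp == "dup")
    if (length(dp))
      repl[dp] <- strrep(substring(s, e$ref_start[dp] + 1, e$ref_end[dp]),
                         e$copies[dp])
    pieces <- character(2L * nrow(e) + 1L)
    pieces[seq(1, length(pieces), by = 2)] <- gaps
    pieces[seq(2, length(pieces) - 1, by = 2)] <- repl
    paste(pieces, collapse = "")
  })
  res <- Biostrings::DNAStringSet(unlist(out))
  names(res) <- names(ref)
  res
}

random_dna <- function(n, gc = 0.42) {
  if (n == 0) return("")
  codes <- c(65L, 67L, 71L, 84L)  # A C G T
  intToUtf8(codes[sample.int(4L, n, replace = TRUE,
                             prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                      (1 - gc) / 2))])
}

#' Generate a random reference genome with a planted repeat library
#'
#' A fraction of the genome consists of copies of a small library of
#' repeat/TE elements, enabling TE-derived insertion simulation and
#' repeat-context tests.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (bases).
#' @param gc GC fraction.
#' @param repeat_fraction fraction of bases belonging to planted repeat
#'   copies.
#' @param n_families number of repeat families in the library.
#' @param seed RNG seed (the generator is deterministic given it).
#' @return list with `genome` (`DNAStringSet`), `te_library`
#'   (`DNAStringSet`, one entry per family) and `te_sites`
#'   (data.frame of planted copies).
#' @export
make_genome <- function(n_chrom = 2, chrom_length = 1e6, gc = 0.42,
                        repeat_fraction = 0.15, n_families = 6,
                        seed = 1) {
  stopifnot(n_chrom >= 1, chrom_length > 0, gc > 0, gc < 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  with_seed(seed, {
    fam_len <- round(runif(n_families, 300, 3000))
    lib <- Biostrings::DNAStringSet(vapply(fam_len, random_dna, "", gc = gc))
    names(lib) <- sprintf("TE_fam%02d", seq_len(n_families))
    chroms <- character(n_chrom)
    sites <- list()
    for (ci in seq_len(n_chrom)) {
      s <- random_dna(chrom_length, gc)
      target <- repeat_fraction * chrom_length
      placed <- 0
      used <- IRanges::IRanges()
      fams <- integer(0); starts <- numeric(0)
      while (placed < target) {
        f <- sample(n_families, 1)
        L <- fam_len[f]
        pos <- floor(runif(1, 0, chrom_length - L))
        cand <- IRanges::IRanges(pos + 1, pos + L)
        if (length(IRanges::findOverlaps(cand, used))) next
        used <- c(used, cand)
        placed <- placed + L
        fams <- c(fams, f); starts <- c(starts, pos)
        sites[[length(sites) + 1L]] <- data.frame(
          ref_name = sprintf("chr%02d", ci), start = pos, end = pos + L,
          family = names(lib)[f], stringsAsFactors = FALSE)
      }
      ## splice all copies in one reconstruction pass
      if (length(starts)) {
        o <- order(starts)
        fams <- fams[o]; starts <- starts[o]
        ends <- starts + fam_len[fams]
        gap_s <- c(0, ends); gap_e <- c(starts, chrom_length)
        pieces <- character(2L * length(starts) + 1L)
        pieces[seq(1, length(pieces), by = 2)] <-
          substring(s, gap_s + 1, gap_e)
        pieces[seq(2, length(pieces) - 1, by = 2)] <-
          as.character(lib)[fams]
        s <- paste(pieces, collapse = "")
      }
      chroms[ci] <- s
    }
    genome <- Biostrings::DNAStringSet(chroms)
    names(genome) <- sprintf("chr%02d", seq_len(n_chrom))
    list(genome = genome, te_library = lib,
         te_sites = do.call(rbind, sites) %||%
           data.frame(ref_name = character(0), start = numeric(0),
                      end = numeric(0), family = character(0)))
  })
}

#' SV simulation specification
#'
#' @param n_del,n_ins,n_dup,n_inv event counts.
#' @param del_size,ins_size,dup_size,inv_size length-2 size ranges (bp);
#'   sizes are drawn log-uniformly within the range.
#' @param te_fraction fraction of insertions whose sequence is sampled
#'   from the planted repeat library rather than random.
#' @param spacing minimum distance between planted events (bases).
#' @param end_margin events are kept this far from chromosome ends.
#' @param dup_copies total tandem copy number of duplications.
#' @param seed RNG seed.
#' @return list of class `svnet_sv_spec`.
#' @export
sv_spec <- function(n_del = 0, n_ins = 0, n_dup = 0, n_inv = 0,
                    del_size = c(50, 10000), ins_size = c(50, 10000),
                    dup_size = c(200, 5000), inv_size = c(1000, 20000),
                    te_fraction = 0.3, spacing = 500, end_margin = 1000,
                    dup_copies = 2, seed = 1) {
  stopifnot(n_del >= 0, n_ins >= 0, n_dup >= 0, n_inv >= 0,
            spacing >= 0, all(c(del_size, ins_size, dup_size, inv_size) > 0))
  structure(list(n_del = n_del, n_ins = n_ins, n_dup = n_dup,
                 n_inv = n_inv, del_size = del_size, ins_size = ins_size,
                 dup_size = dup_size, inv_size = inv_size,
                 te_fraction = te_fraction, spacing = spacing,
                 end_margin = end_margin, dup_copies = dup_copies,
                 seed = seed), class = "svnet_sv_spec")
}

rsize <- function(n, range) {
  round(exp(runif(n, log(range[1]), log(range[2]))))
}

te_derived_seq <- function(len, te_library) {
  f <- sample(length(te_library), 1)
  el <- as.character(te_library[[f]])
  if (nchar(el) >= len) {
    off <- floor(runif(1, 0, nchar(el) - len))
    substr(el, off + 1, off + len)
  } else {
    substr(strrep(el, ceiling(len / nchar(el))), 1, len)
  }
}

## place non-overlapping events on a genome, respecting spacing, end
## margins, N runs and caller-supplied forbidden ranges
place_events <- function(counts_types, sizes, genome, spacing, end_margin,
                         avoid = NULL, max_attempts = 1000) {
  sizes_all <- genome_sizes(genome)
  chrom <- names(sizes_all)
  blocked <- lapply(chrom, function(nm) {
    b <- IRanges::IRanges(c(1, max(1, sizes_all[[nm]] - end_margin + 1)),
                          c(min(end_margin, sizes_all[[nm]]), sizes_all[[nm]]))
    nruns <- gregexpr("N+", as.character(as_dna(genome)[[nm]]))[[1]]
    if (nruns[1] != -1L)
      b <- c(b, IRanges::IRanges(as.integer(nruns),
                                 width = attr(nruns, "match.length")))
    if (!is.null(avoid)) {
      av <- avoid[avoid$ref_name == nm, , drop = FALSE]
      if (nrow(av)) b <- c(b, iranges0(av$ref_start, av$ref_end))
    }
    IRanges::reduce(b)
  })
  names(blocked) <- chrom
  ## place the largest events first: late placements only need small
  ## free gaps, so dense configurations still succeed
  ev <- do.call(rbind, lapply(seq_along(counts_types), function(k) {
    if (counts_types[k] == 0L) return(NULL)
    data.frame(typek = k, len = sizes[[k]][seq_len(counts_types[k])])
  }))
  if (is.null(ev))
    return(data.frame(typek = integer(0), ref_name = character(0),
                      ref_start = numeric(0), len = numeric(0)))
  ev <- ev[order(-ev$len), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(ev))) {
    ok <- FALSE
    L <- ev$len[r]
    for (att in seq_len(max_attempts)) {
      nm <- sample(chrom, 1, prob = sizes_all)
      pos <- floor(runif(1, end_margin, sizes_all[[nm]] - end_margin - L))
      cand <- IRanges::IRanges(max(1, pos + 1 - spacing), pos + L + spacing)
      if (length(IRanges::findOverlaps(cand, blocked[[nm]]))) next
      blocked[[nm]] <- IRanges::reduce(c(blocked[[nm]], cand))
      out[[length(out) + 1L]] <- data.frame(
        typek = ev$typek[r], ref_name = nm, ref_start = pos, len = L,
        stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("cannot place event after ", max_attempts,
           " attempts; reduce counts or sizes")
  }
  do.call(rbind, out) %||%
    data.frame(typek = integer(0), ref_name = character(0),
               ref_start = numeric(0), len = numeric(0))
}

#' Plant structural variants into a reference genome
#'
#' Events are placed uniformly at random without overlap, at least
#' `spacing` bases apart, away from chromosome ends and N runs.
#' Deletions remove reference bases, insertions add TE-derived (with
#' probability `te_fraction`) or random sequence, duplications repeat the
#' unit in place (tandem), inversions reverse-complement.  Truth
#' coordinates are in the reference frame.
#'
#' @param ref named `DNAStringSet`.
#' @param spec an [sv_spec()].
#' @param te_library optional `DNAStringSet` used for TE-derived
#'   insertions (e.g. from [make_genome()]).
#' @param avoid optional data.frame (`ref_name`, `ref_start`, `ref_end`)
#'   of reference ranges events must not touch.
#' @return list with `genome` (the mutated assembly), `truth` (planted
#'   event table with `id`, type, interval, length, `seq`) and `edits`
#'   (the edit script replaying ref -> genome).
#' @export
simulate_svs <- function(ref, spec, te_library = NULL, avoid = NULL) {
  ref <- as_dna(ref)
  stopifnot(inherits(spec, "svnet_sv_spec"))
  with_seed(spec$seed, {
    counts <- c(DEL = spec$n_del, INS = spec$n_ins, DUP = spec$n_dup,
                INV = spec$n_inv)
    sizes <- list(rsize(spec$n_del, spec$del_size),
                  rsize(spec$n_ins, spec$ins_size),
                  rsize(spec$n_dup, spec$dup_size),
                  rsize(spec$n_inv, spec$inv_size))
    total <- sum(unlist(sizes))
    if (total >= 0.5 * sum(genome_sizes(ref)))
      stop("total event footprint exceeds half the genome")
    pl <- place_events(counts, sizes, ref, spec$spacing, spec$end_margin,
                       avoid = avoid)
    if (!nrow(pl)) {
      tr <- data.frame(id = character(0), svtype = character(0),
                       ref_name = character(0), ref_start = numeric(0),
                       ref_end = numeric(0), length = numeric(0),
                       seq = character(0), copies = integer(0))
      return(list(genome = ref, truth = tr, edits = empty_edits()))
    }
    pl$svtype <- names(counts)[pl$typek]
    truth <- list(); edits <- list()
    for (i in seq_len(nrow(pl))) {
      tp <- pl$svtype[i]; nm <- pl$ref_name[i]
      s <- pl$ref_start[i]; L <- pl$len[i]
      seq <- NA_character_; e <- s + L; copies <- NA_integer_
      etype <- tolower(tp)
      if (tp == "DEL") {
        seq <- genome_subseq(ref, nm, s, e)
        etype <- "del"
      } else if (tp == "INS") {
        e <- s
        seq <- if (!is.null(te_library) && length(te_library) &&
                   runif(1) < spec$te_fraction)
          te_derived_seq(L, te_library) else random_dna(L)
        etype <- "ins"
      } else if (tp == "DUP") {
        copies <- spec$dup_copies
        etype <- "dup"
      } else etype <- "inv"
      truth[[i]] <- data.frame(id = sprintf("truth_%s_%04d", tp, i),
                               svtype = tp, ref_name = nm, ref_start = s,
                               ref_end = e, length = L, seq = seq,
                               copies = copies, stringsAsFactors = FALSE)
      edits[[i]] <- data.frame(type = etype, ref_name = nm, ref_start = s,
                               ref_end = e, seq = seq, copies = copies,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$ref_name, truth$ref_start), , drop = FALSE]
    truth$id <- sprintf("truth%05d", seq_len(nrow(truth)))
    rownames(truth) <- NULL
    edits <- sort_edits(do.call(rbind, edits))
    list(genome = apply_edits(ref, edits), truth = truth, edits = edits)
  })
}

#' Simulate background sequence divergence
#'
#' Applies iid substitutions and small indels (geometric sizes, mean
#' `indel_mean`) to a reference, returning the edit script so that exact
#' truth alignments remain available.
#'
#' @param ref named `DNAStringSet`.
#' @param sub_rate per-base substitution rate (0-0.2).
#' @param indel_rate per-base indel initiation rate (0-0.2).
#' @param indel_mean mean indel size (geometric).
#' @param seed RNG seed.
#' @return list with `genome` and `edits`.
#' @export
simulate_divergence <- function(ref, sub_rate = 0.02, indel_rate = 0.002,
                                indel_mean = 3, seed = 1) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.2, indel_rate >= 0,
            indel_rate <= 0.2)
  ref <- as_dna(ref)
  with_seed(seed, {
    edits <- list()
    for (nm in names(ref)) {
      L <- genome_sizes(ref)[[nm]]
      s <- as.character(ref[[nm]])
      ## indels first: they block substitution positions
      n_ind <- rbinom(1, L, indel_rate)
      ipos <- sort(sample.int(L - 60, n_ind)) - 1
      ilen <- rgeom(n_ind, 1 / indel_mean) + 1
      is_del <- runif(n_ind) < 0.5
      ## drop indels that collide with the previous one
      if (n_ind > 1) {
        keep <- c(TRUE, diff(ipos) > (ifelse(is_del, ilen, 1)[-n_ind] + 2))
        ipos <- ipos[keep]; ilen <- ilen[keep]; is_del <- is_del[keep]
      }
      ind <- if (length(ipos)) data.frame(
        type = ifelse(is_del, "del", "ins"), ref_name = nm,
        ref_start = ipos, ref_end = ifelse(is_del, ipos + ilen, ipos),
        seq = ifelse(is_del, NA_character_,
                     vapply(ilen, random_dna, "")),
        copies = NA_integer_, stringsAsFactors = FALSE) else empty_edits()
      n_sub <- rbinom(1, L, sub_rate)
      spos <- sample.int(L, n_sub) - 1
      ## keep substitutions clear of indel footprints
      if (nrow(ind)) {
        bad <- IRanges::overlapsAny(
          iranges0(spos, spos + 1),
          iranges0(ind$ref_start - 1, ind$ref_end + 1))
        spos <- spos[!bad]
      }
      spos <- sort(spos)
      altpool <- c("A", "C", "G", "T")
      if (length(spos)) {
        refb <- substring(s, spos + 1, spos + 1)
        alt <- vapply(refb, function(b)
          sample(setdiff(altpool, b), 1), "", USE.NAMES = FALSE)
      } else alt <- character(0)
      sub <- if (length(spos)) data.frame(
        type = "sub", ref_name = nm, ref_start = spos,
        ref_end = spos + 1, seq = alt, copies = NA_integer_,
        stringsAsFactors = FALSE) else empty_edits()
      edits[[nm]] <- rbind(ind, sub)
    }
    edits <- sort_edits(do.call(rbind, edits))
    list(genome = apply_edits(ref, edits), edits = edits)
  })
}

#' Simulate a population of genome assemblies from planted SVs
#'
#' Builds the 0/1 genotype matrix (each of the first `n_genomes - 1`
#' genomes carries each event with probability 0.5; the last genome
#' carries all events), optionally stacks shared background divergence
#' under the events, and returns per-genome edit scripts.  Genomes are
#' materialized lazily via [apply_edits()]/[population_genome()].
#'
#' @param ref named `DNAStringSet`.
#' @param truth planted event table from [simulate_svs()] (types
#'   DEL/INS/DUP; coordinates in the reference frame).
#' @param n_genomes number of genomes (last one carries all events).
#' @param seed RNG seed for the genotype matrix.
#' @param divergence optional edit script (from [simulate_divergence()])
#'   shared by every genome; divergence edits within 20 bp of an event
#'   carried by a genome are dropped for that genome.
#' @return list with `truth`, `genotypes` (events x genomes 0/1 matrix),
#'   `scripts` (per-genome edit scripts) and `samples` (genome names).
#' @export
simulate_population <- function(ref, truth, n_genomes = 21, seed = 1,
                                divergence = NULL) {
  stopifnot(n_genomes >= 1, nrow(truth) >= 1)
  if (any(truth$svtype %in% c("INV", "TRA")))
    stop("population simulation plants DEL/INS/DUP events only")
  samples <- sprintf("g%02d", seq_len(n_genomes))
  gt <- with_seed(seed, {
    m <- matrix(rbinom(nrow(truth) * (n_genomes - 1), 1, 0.5),
                nrow = nrow(truth))
    cbind(m, 1L)
  })
  dimnames(gt) <- list(truth$id, samples)
  ev_edits <- truth
  ev_edits$type <- tolower(ev_edits$svtype)
  scripts <- lapply(seq_len(n_genomes), function(g) {
    carried <- which(gt[, g] == 1L)
    ev <- ev_edits[carried, c("type", "ref_name", "ref_start", "ref_end",
                              "seq", "copies"), drop = FALSE]
    if (!is.null(divergence)) {
      div <- divergence
      if (nrow(ev) && nrow(div)) {
        near <- rep(FALSE, nrow(div))
        for (nm in unique(ev$ref_name)) {
          di <- which(div$ref_name == nm)
          if (!length(di)) next
          e <- ev[ev$ref_name == nm, , drop = FALSE]
          near[di] <- IRanges::overlapsAny(
            iranges0(div$ref_start[di] - 20, div$ref_end[di] + 20),
            iranges0(e$ref_start - 1, e$ref_end + 1))
        }
        div <- div[!near, , drop = FALSE]
      }
      ev <- rbind(div, ev)
    }
    sort_edits(ev)
  })
  names(scripts) <- samples
  list(truth = truth, genotypes = gt, scripts = scripts, samples = samples)
}

#' Materialize one population genome
#'
#' @param ref reference `DNAStringSet`.
#' @param pop result of [simulate_population()].
#' @param sample sample name or index.
#' @return `DNAStringSet`.
#' @export
population_genome <- function(ref, pop, sample) {
  apply_edits(ref, pop$scripts[[sample]])
}

#' Exact truth alignment implied by an edit script
#'
#' Emits the gapless aligned blocks of the pairwise alignment implied by
#' replaying `edits` on `ref`: substitutions stay inside aligned columns,
#' indels and SV gaps separate blocks, inversions become minus-strand
#' blocks, duplications contribute extra same-unit blocks for the extra
#' copies.  Optional fragmentation splits blocks at random positions
#' without changing any implied alignment column.
#'
#' @param ref named `DNAStringSet`.
#' @param edits edit script (query = `apply_edits(ref, edits)`).
#' @param query_prefix name prefix of query sequences (same chromosome
#'   names by default).
#' @param fragmentation optional list `(mean_len, seed)`.
#' @return an [alignment_blocks()] table.
#' @export
edits_to_alignment <- function(ref, edits, query_prefix = "",
                               fragmentation = NULL) {
  ref <- as_dna(ref)
  acc <- new.env(parent = emptyenv())
  acc$rn <- character(0); acc$rs <- numeric(0); acc$re <- numeric(0)
  acc$qn <- character(0); acc$qs <- numeric(0); acc$qe <- numeric(0)
  acc$st <- character(0)
  for (nm in names(ref)) {
    qn <- paste0(query_prefix, nm)
    L <- genome_sizes(ref)[[nm]]
    e <- sort_edits(edits[edits$ref_name == nm &
                          edits$type != "sub", , drop = FALSE])
    n_emit_max <- 3L * nrow(e) + 2L
    rs <- numeric(n_emit_max); re <- numeric(n_emit_max)
    qs <- numeric(n_emit_max); qe <- numeric(n_emit_max)
    st <- character(n_emit_max)
    k_emit <- 0L
    r <- 0; q <- 0
    emit <- function(a, b, c_, d, strand = "+") {
      if (b <= a) return()
      k_emit <<- k_emit + 1L
      rs[k_emit] <<- a; re[k_emit] <<- b
      qs[k_emit] <<- c_; qe[k_emit] <<- d; st[k_emit] <<- strand
    }
    for (i in seq_len(nrow(e))) {
      s <- e$ref_start[i]; en <- e$ref_end[i]
      if (s > r) { emit(r, s, q, q + (s - r)); q <- q + (s - r); r <- s }
      w <- en - s
      switch(e$type[i],
        del = { r <- en },
        ins = { q <- q + nchar(e$seq[i]) },
        inv = { emit(s, en, q, q + w, "-"); r <- en; q <- q + w },
        dup = {
          k <- e$copies[i]
          emit(s, en, q, q + w)            # unit against first copy
          q <- q + w
          for (cp in seq_len(k - 1)) {     # extra copies: multi-coverage
            emit(s, en, q, q + w)
            q <- q + w
          }
          r <- en
        })
    }
    if (r < L) emit(r, L, q, q + (L - r))
    idx <- seq_len(k_emit)
    acc$rn <- c(acc$rn, rep(nm, k_emit)); acc$rs <- c(acc$rs, rs[idx])
    acc$re <- c(acc$re, re[idx]); acc$qn <- c(acc$qn, rep(qn, k_emit))
    acc$qs <- c(acc$qs, qs[idx]); acc$qe <- c(acc$qe, qe[idx])
    acc$st <- c(acc$st, st[idx])
  }
  blocks <- alignment_blocks(
    ref_name = acc$rn, ref_start = acc$rs, ref_end = acc$re,
    query_name = acc$qn, query_start = acc$qs, query_end = acc$qe,
    strand = acc$st, score = acc$re - acc$rs,
    cigar = paste0(format(acc$re - acc$rs, trim = TRUE,
                          scientific = FALSE), "M"))
  if (!is.null(fragmentation)) {
    blocks <- with_seed(fragmentation$seed %||% 1, {
      frag <- list()
      for (i in seq_len(nrow(blocks))) {
        b <- blocks[i, ]
        w <- b$ref_end - b$ref_start
        cuts <- sort(unique(pmin(w - 1, pmax(1, cumsum(
          rgeom(ceiling(w / max(2, fragmentation$mean_len)) + 1,
                1 / max(2, fragmentation$mean_len)) + 1)))))
        cuts <- cuts[cuts < w]
        bounds <- c(0, cuts, w)
        for (k in seq_len(length(bounds) - 1)) {
          lo <- bounds[k]; hi <- bounds[k + 1]
          qs <- if (b$strand == "+") b$query_start + lo else b$query_end - hi
          qe <- if (b$strand == "+") b$query_start + hi else b$query_end - lo
          frag[[length(frag) + 1L]] <- alignment_blocks(
            ref_name = b$ref_name, ref_start = b$ref_start + lo,
            ref_end = b$ref_start + hi, query_name = b$query_name,
            query_start = qs, query_end = qe, strand = b$strand,
            score = hi - lo, cigar = paste0(hi - lo, "M"))
        }
      }
      res <- do.call(rbind, frag)
      class(res) <- c("svnet_blocks", "data.frame")
      res
    })
  }
  blocks
}
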