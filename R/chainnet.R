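## Chains and nets: collinear runs of local alignments (chains), their
## hierarchical single-coverage organization (nets), fill classification
## (syntenic / inversion / translocation) and projection to single
## coverage on both genomes.

#' Piecewise-linear gap cost model
#'
#' Concave, monotone non-decreasing cost of joining two blocks across a
#' gap, with separate tables for one-sided gaps (bases missing from only
#' one genome) and two-sided gaps.  The default plateaus at large gaps so
#' that megabase gaps — large insertions/deletions — can stay inside one
#' chain once enough aligned material has accumulated.
#'
#' @param breaks_one,costs_one breakpoints (gap length in bases) and costs
#'   for one-sided gaps.
#' @param breaks_two,costs_two same for two-sided gaps.
#' @return object of class `svnet_gap_model`.
#' @export
gap_cost_model <- function(breaks_one = c(0, 100, 1000, 1e4, 1e5, 1e7),
                           costs_one = c(0, 50, 150, 300, 600, 1000),
                           breaks_two = c(0, 100, 1000, 1e4, 1e5, 1e7),
                           costs_two = c(0, 60, 180, 360, 700, 1200)) {
  stopifnot(length(breaks_one) == length(costs_one),
            length(breaks_two) == length(costs_two),
            !is.unsorted(costs_one), !is.unsorted(costs_two),
            costs_one[1] == 0, costs_two[1] == 0)
  structure(list(breaks_one = breaks_one, costs_one = costs_one,
                 breaks_two = breaks_two, costs_two = costs_two),
            class = "svnet_gap_model")
}

#' @rdname gap_cost_model
#' @param model a `svnet_gap_model`.
#' @param dr,dq reference-side and query-side gap lengths (vectorized).
#' @export
gap_cost <- function(model, dr, dq = 0) {
  pl <- function(x, brk, cst) {
    y <- stats::approx(brk, cst, xout = pmin(x, max(brk)), rule = 2)$y
    y
  }
  two <- dr > 0 & dq > 0
  out <- numeric(length(dr))
  out[!two] <- pl(dr[!two] + dq[!two], model$breaks_one, model$costs_one)
  out[two] <- pl(dr[two] + dq[two], model$breaks_two, model$costs_two)
  out
}

new_chain <- function(id, blocks, score) {
  structure(list(id = id, blocks = blocks, score = score,
                 ref_name = blocks$ref_name[1],
                 query_name = blocks$query_name[1],
                 strand = blocks$strand[1],
                 ref_start = min(blocks$ref_start),
                 ref_end = max(blocks$ref_end),
                 query_start = min(blocks$query_start),
                 query_end = max(blocks$query_end)),
            class = "svnet_chain")
}

#' @export
print.svnet_chain <- function(x, ...) {
  cat(sprintf("<chain %s> %s:%d-%d %s %s:%d-%d score=%.0f blocks=%d\n",
              x$id, x$ref_name, x$ref_start, x$ref_end, x$strand,
              x$query_name, x$query_start, x$query_end, x$score,
              nrow(x$blocks)))
  invisible(x)
}

#' Build collinear chains from alignment blocks
#'
#' Best-predecessor dynamic programming within each (reference, query,
#' strand) partition: a block joins a chain when the block score exceeds
#' the gap cost of connecting it to its best predecessor.  Every input
#' block is assigned to exactly one chain; chains scoring below
#' `min_score` are dropped.
#'
#' @param blocks an [alignment_blocks()] table for one reference/query
#'   genome pair.
#' @param gap_model a [gap_cost_model()].
#' @param min_score minimum chain score retained.
#' @return list of `svnet_chain` objects sorted by descending score.
#' @export
chain_blocks <- function(blocks, gap_model = gap_cost_model(),
                         min_score = 25) {
  if (nrow(blocks) == 0L) return(list())
  ## deterministic canonical order
  o <- order(blocks$ref_name, blocks$ref_start, blocks$query_start,
             blocks$strand)
  blocks <- blocks[o, , drop = FALSE]
  part <- paste(blocks$ref_name, blocks$query_name, blocks$strand)
  chains <- list()
  for (p in unique(part)) {
    sub <- blocks[part == p, , drop = FALSE]
    minus <- sub$strand[1] == "-"
    res <- .chain_dp(sub$ref_start, sub$ref_end, sub$query_start,
                     sub$query_end, sub$score, minus,
                     gap_model$breaks_one, gap_model$costs_one,
                     gap_model$breaks_two, gap_model$costs_two)
    used <- logical(nrow(sub))
    for (i in order(res$dp, decreasing = TRUE)) {
      if (used[i]) next
      run <- integer(0)
      j <- i
      while (j >= 1 && !used[j]) {
        run <- c(j, run)
        used[j] <- TRUE
        j <- res$pred[j] + 1L   # C++ 0-based
      }
      cb <- sub[run, , drop = FALSE]
      ## recompute the score of the (possibly truncated) run
      sc <- sum(cb$score)
      if (nrow(cb) > 1L) {
        dr <- cb$ref_start[-1] - cb$ref_end[-nrow(cb)]
        dq <- if (!minus) cb$query_start[-1] - cb$query_end[-nrow(cb)]
              else cb$query_start[-nrow(cb)] - cb$query_end[-1]
        sc <- sc - sum(gap_cost(gap_model, dr, dq))
      }
      chains[[length(chains) + 1L]] <- list(blocks = cb, score = sc)
    }
  }
  chains <- chains[order(vapply(chains, `[[`, 0, "score"),
                         decreasing = TRUE)]
  chains <- chains[vapply(chains, `[[`, 0, "score") >= min_score]
  lapply(seq_along(chains), function(i)
    new_chain(sprintf("c%04d", i), chains[[i]]$blocks, chains[[i]]$score))
}

chain_gaps <- function(chain) {
  seg <- blocks_to_segments(chain$blocks)
  seg <- seg[order(seg$ref_start), , drop = FALSE]
  n <- nrow(seg)
  if (n < 2L)
    return(data.frame(ref_start = numeric(0), ref_end = numeric(0),
                      query_start = numeric(0), query_end = numeric(0),
                      dr = numeric(0), dq = numeric(0)))
  minus <- chain$strand == "-"
  gq_s <- if (!minus) seg$query_end[-n] else seg$query_end[-1]
  gq_e <- if (!minus) seg$query_start[-1] else seg$query_start[-n]
  g <- data.frame(ref_start = seg$ref_end[-n], ref_end = seg$ref_start[-1],
                  query_start = gq_s, query_end = gq_e)
  g$dr <- g$ref_end - g$ref_start
  g$dq <- g$query_end - g$query_start
  g[g$dr > 0 | g$dq > 0, , drop = FALSE]
}

#' Organize chains into a hierarchical net
#'
#' Chains are inserted best-first; a chain contributes a fill wherever at
#' least `min_space` reference bases are not yet covered by previously
#' netted aligned blocks.  A fill landing inside the gap of an already
#' placed chain becomes a child of that chain's fill; chains contributing
#' no fill are discarded.
#'
#' @param chains list of `svnet_chain` (sorted defensively by score).
#' @param min_space minimum uncovered reference bases for a fill.
#' @return object of class `svnet_net`: list with `fills` (one row per
#'   fill: interval, chain, level, parent, type) and `chains` (the chains
#'   participating in the net, indexed by id).
#' @export
net_chains <- function(chains, min_space = 1) {
  chains <- chains[order(vapply(chains, `[[`, 0, "score"),
                         decreasing = TRUE)]
  covered <- list()   # ref_name -> IRanges of netted aligned bases
  fills <- list()
  kept <- list()
  fid <- 0L
  for (ch in chains) {
    rn <- ch$ref_name
    cov <- covered[[rn]] %||% IRanges::IRanges()
    span <- iranges0(ch$ref_start, ch$ref_end)
    claim <- IRanges::setdiff(span, cov)
    if (length(claim) == 0L) next
    cand <- IRanges::reduce(claim)
    blk <- IRanges::reduce(iranges0(ch$blocks$ref_start, ch$blocks$ref_end))
    contributed <- FALSE
    for (k in seq_along(cand)) {
      newal <- IRanges::intersect(cand[k], blk)
      if (sum(IRanges::width(newal)) < min_space) next
      c0 <- from_iranges0(cand[k])
      mid <- floor((c0$start + c0$end) / 2)
      ## deepest existing fill whose interval contains the candidate
      parent <- NA_integer_; level <- 1L
      if (length(fills)) {
        fdf <- do.call(rbind, fills)
        hit <- which(fdf$ref_name == rn & fdf$ref_start <= mid &
                     fdf$ref_end > mid)
        if (length(hit)) {
          h <- hit[which.max(fdf$level[hit])]
          parent <- fdf$fill[h]
          level <- fdf$level[h] + 1L
          ## trim candidate to the parent-chain gap containing it
          pg <- chain_gaps(kept[[fdf$chain[h]]])
          gi <- which(pg$ref_start <= mid & pg$ref_end > mid)
          if (length(gi)) {
            c0$start <- max(c0$start, pg$ref_start[gi[1]])
            c0$end <- min(c0$end, pg$ref_end[gi[1]])
          }
        }
      }
      if (c0$end - c0$start < min_space) next
      fid <- fid + 1L
      fills[[fid]] <- data.frame(fill = fid, ref_name = rn,
                                 ref_start = c0$start, ref_end = c0$end,
                                 chain = ch$id, level = level,
                                 parent = parent, type = "top",
                                 stringsAsFactors = FALSE)
      contributed <- TRUE
    }
    if (contributed) {
      covered[[rn]] <- IRanges::union(cov, blk)
      kept[[ch$id]] <- ch
    }
  }
  fdf <- do.call(rbind, fills)
  if (is.null(fdf))
    fdf <- data.frame(fill = integer(0), ref_name = character(0),
                      ref_start = numeric(0), ref_end = numeric(0),
                      chain = character(0), level = integer(0),
                      parent = integer(0), type = character(0))
  fdf <- fdf[order(fdf$ref_name, fdf$ref_start, fdf$level), , drop = FALSE]
  rownames(fdf) <- NULL
  structure(list(fills = fdf, chains = kept), class = "svnet_net")
}

#' @export
print.svnet_net <- function(x, ...) {
  cat(sprintf("<net> %d fills, %d chains, %d reference sequence(s)\n",
              nrow(x$fills), length(x$chains),
              length(unique(x$fills$ref_name))))
  invisible(x)
}

#' Classify net fills as syntenic, inversion or translocation
#'
#' A non-top fill is `inv` when its chain lies on the same query sequence
#' as the parent chain but on the opposite strand within `max_dist` of
#' the parent's local query position, `syn` when same sequence and strand
#' and query-collinear, `tra` otherwise.
#'
#' @param net a `svnet_net`.
#' @param max_dist maximum query-side displacement (bases) for a
#'   same-sequence fill to still count as locally placed.
#' @return the net with `fills$type` set.
#' @export
classify_fills <- function(net, max_dist = 1e6) {
  f <- net$fills
  for (i in seq_len(nrow(f))) {
    if (f$level[i] == 1L) { f$type[i] <- "top"; next }
    pc <- net$chains[[f$chain[match(f$parent[i], f$fill)]]]
    cc <- net$chains[[f$chain[i]]]
    if (cc$query_name != pc$query_name) { f$type[i] <- "tra"; next }
    ## parent's query gap at this fill
    pg <- chain_gaps(pc)
    mid <- floor((f$ref_start[i] + f$ref_end[i]) / 2)
    gi <- which(pg$ref_start <= mid & pg$ref_end > mid)
    win <- if (length(gi))
      c(pg$query_start[gi[1]] - max_dist, pg$query_end[gi[1]] + max_dist)
    else c(pc$query_start - max_dist, pc$query_end + max_dist)
    near <- cc$query_start < win[2] && cc$query_end > win[1]
    f$type[i] <- if (!near) "tra"
      else if (cc$strand != pc$strand) "inv" else "syn"
  }
  net$fills <- f
  net
}

#' Filter a net to syntenic/orthologous fills
#'
#' @param net a classified `svnet_net`.
#' @param policy `"top_only"` keeps level-1 fills and `syn` children;
#'   `"top_plus_rearrangement"` additionally keeps `inv`/`tra` fills
#'   covering at least `min_gap_cover` of their parent gap.
#' @param min_gap_cover minimum fraction of the parent-chain gap an
#'   inv/tra fill must span to be retained.
#' @return the filtered net.
#' @export
filter_synnet <- function(net, policy = c("top_plus_rearrangement",
                                          "top_only"),
                          min_gap_cover = 0.5) {
  policy <- tryCatch(match.arg(policy),
                     error = function(e) stop("config error: unknown policy"))
  f <- net$fills
  keep <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    if (f$level[i] == 1L || f$type[i] == "syn") { keep[i] <- TRUE; next }
    if (policy == "top_only") next
    if (!f$type[i] %in% c("inv", "tra")) next
    pc <- net$chains[[f$chain[match(f$parent[i], f$fill)]]]
    pg <- chain_gaps(pc)
    mid <- floor((f$ref_start[i] + f$ref_end[i]) / 2)
    gi <- which(pg$ref_start <= mid & pg$ref_end > mid)
    gw <- if (length(gi)) pg$dr[gi[1]] else (pc$ref_end - pc$ref_start)
    keep[i] <- gw > 0 && (f$ref_end[i] - f$ref_start[i]) / gw >= min_gap_cover
  }
  ## drop subtrees of removed fills
  repeat {
    orphan <- !is.na(f$parent) & keep &
      !(f$parent %in% f$fill[keep])
    if (!any(orphan)) break
    keep[orphan] <- FALSE
  }
  net$fills <- f[keep, , drop = FALSE]
  net$chains <- net$chains[unique(net$fills$chain)]
  net
}

clip_segments <- function(seg, lo, hi) {
  ns <- pmax(seg$ref_start, lo)
  ne <- pmin(seg$ref_end, hi)
  ok <- ne > ns
  seg <- seg[ok, , drop = FALSE]
  if (!nrow(seg)) return(seg)
  dl <- pmax(seg$ref_start, lo) - seg$ref_start
  dr <- seg$ref_end - pmin(seg$ref_end, hi)
  plus <- seg$strand == "+"
  seg$query_start <- seg$query_start + ifelse(plus, dl, dr)
  seg$query_end <- seg$query_end - ifelse(plus, dr, dl)
  seg$ref_start <- ns[ok]
  seg$ref_end <- ne[ok]
  seg
}

## trim `seg` rows against already covered intervals on one side
trim_side <- function(seg, covered_ir, side = c("ref", "query")) {
  side <- match.arg(side)
  s_col <- paste0(side, "_start"); e_col <- paste0(side, "_end")
  keep_ir <- IRanges::setdiff(iranges0(seg[[s_col]], seg[[e_col]]),
                              covered_ir)
  hits <- IRanges::findOverlaps(iranges0(seg[[s_col]], seg[[e_col]]), keep_ir)
  if (length(hits) == 0L) return(seg[0, , drop = FALSE])
  i <- S4Vectors::queryHits(hits)
  piece <- from_iranges0(IRanges::pintersect(
    iranges0(seg[[s_col]], seg[[e_col]])[i],
    keep_ir[S4Vectors::subjectHits(hits)]))
  out <- seg[i, , drop = FALSE]
  dl <- piece$start - out[[s_col]]
  dr <- out[[e_col]] - piece$end
  plus <- out$strand == "+"
  ## on '+' the two starts correspond; on '-' a start trim on one side
  ## trims the other side's end
  same <- plus
  o_s <- if (side == "ref") "query_start" else "ref_start"
  o_e <- if (side == "ref") "query_end" else "ref_end"
  out[[o_s]] <- out[[o_s]] + ifelse(same, dl, dr)
  out[[o_e]] <- out[[o_e]] - ifelse(same, dr, dl)
  out[[s_col]] <- piece$start
  out[[e_col]] <- piece$end
  out
}

#' Project a filtered net to single coverage on both genomes
#'
#' Returns gapless aligned segments covering every reference base and
#' every query base at most once; where fills claim the same query bases
#' the higher-scoring chain wins and the loser is trimmed.
#'
#' @param net a (filtered) `svnet_net`.
#' @return data.frame of gapless segments (`ref_*`, `query_*`, `strand`)
#'   with `chain` and `fill` provenance columns.
#' @export
project_single_coverage <- function(net) {
  f <- net$fills
  if (nrow(f) == 0L)
    return(data.frame(ref_name = character(0), ref_start = numeric(0),
                      ref_end = numeric(0), query_name = character(0),
                      query_start = numeric(0), query_end = numeric(0),
                      strand = character(0), chain = character(0),
                      fill = integer(0)))
  sc <- vapply(net$chains[f$chain], `[[`, 0, "score")
  out <- list()
  cov_ref <- list(); cov_q <- list()
  for (i in order(sc, decreasing = TRUE)) {
    ch <- net$chains[[f$chain[i]]]
    seg <- blocks_to_segments(ch$blocks)
    seg <- clip_segments(seg, f$ref_start[i], f$ref_end[i])
    if (!nrow(seg)) next
    rn <- f$ref_name[i]; qn <- ch$query_name
    seg <- trim_side(seg, cov_ref[[rn]] %||% IRanges::IRanges(), "ref")
    if (nrow(seg))
      seg <- trim_side(seg, cov_q[[qn]] %||% IRanges::IRanges(), "query")
    if (!nrow(seg)) next
    cov_ref[[rn]] <- IRanges::union(cov_ref[[rn]] %||% IRanges::IRanges(),
                                    iranges0(seg$ref_start, seg$ref_end))
    cov_q[[qn]] <- IRanges::union(cov_q[[qn]] %||% IRanges::IRanges(),
                                  iranges0(seg$query_start, seg$query_end))
    seg$chain <- ch$id
    seg$fill <- f$fill[i]
    out[[length(out) + 1L]] <- seg
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ref_name, res$ref_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Serialize a net as nested fill/gap text or JSON
#'
#' @param net a `svnet_net`.
#' @param path output file.
#' @param format `"net"` (nested text, one `fill` line per fill with
#'   class annotation) or `"json"`.
#' @return `path` invisibly.
#' @export
write_net <- function(net, path, format = c("net", "json")) {
  format <- match.arg(format)
  f <- net$fills
  if (format == "json") {
    jsonlite::write_json(f, path, dataframe = "rows", auto_unbox = TRUE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in unique(f$ref_name)) {
    writeLines(paste("net", rn), con)
    sub <- f[f$ref_name == rn, , drop = FALSE]
    emit <- function(parent, depth) {
      rows <- if (is.na(parent)) which(sub$level == 1L)
              else which(!is.na(sub$parent) & sub$parent == parent)
      for (r in rows[order(sub$ref_start[rows])]) {
        writeLines(sprintf("%sfill %d %d %s %s id=%d class=%s level=%d",
                           strrep(" ", depth), sub$ref_start[r],
                           sub$ref_end[r] - sub$ref_start[r], sub$chain[r],
                           sub$type[r], sub$fill[r], sub$type[r],
                           sub$level[r]), con)
        emit(sub$fill[r], depth + 1L)
      }
    }
    emit(NA, 1L)
  }
  invisible(path)
}
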