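## Simulation benchmark protocols.  Two designs mirror the standard
## assembly-SV evaluation settings: a reference-based single-genome
## detection benchmark (F1 against planted truth) and a population-scale
## merging + re-genotyping benchmark (completeness and per-sample
## genotyping accuracy / error / missing), optionally with shared
## background divergence between the population and the reference.

#' Reference-based detection benchmark
#'
#' Generates a synthetic reference, plants deletions, insertions, tandem
#' duplications and inversions, derives the exact truth alignment, runs
#' chaining/netting/calling, and scores deletion+insertion detection
#' against the planted truth (reciprocal overlap >= `match_ro` for
#' spans, shift/length rule for insertions).
#'
#' @param seed integer seed driving every random choice.
#' @param n_chrom,chrom_length genome shape.
#' @param n_del,n_ins,n_dup,n_inv planted event counts.
#' @param del_size,ins_size,dup_size,inv_size size ranges (log-uniform).
#' @param match_ro truth-match reciprocal overlap.
#' @return list with `metrics` (recall/precision/f1, percent), `matches`
#'   per type, `truth` and `calls`.
#' @export
benchmark_detection <- function(seed = 1, n_chrom = 2,
                                chrom_length = 2.5e6, n_del = 300,
                                n_ins = 200, n_dup = 20, n_inv = 5,
                                del_size = c(50, 4000),
                                ins_size = c(50, 2000),
                                dup_size = c(200, 2000),
                                inv_size = c(1000, 20000),
                                match_ro = 0.8) {
  gen <- make_genome(n_chrom = n_chrom, chrom_length = chrom_length,
                     repeat_fraction = 0.1, seed = seed)
  spec <- sv_spec(n_del = n_del, n_ins = n_ins, n_dup = n_dup,
                  n_inv = n_inv, del_size = del_size,
                  ins_size = ins_size, dup_size = dup_size,
                  inv_size = inv_size, te_fraction = 0.3,
                  seed = seed + 1L)
  sim <- simulate_svs(gen$genome, spec, te_library = gen$te_library)
  blocks <- edits_to_alignment(gen$genome, sim$edits)
  ps <- process_sample(blocks, gen$genome, sim$genome, sample = "sim")
  tp <- 0L; fp <- 0L; fn <- 0L
  matches <- list()
  for (tpn in c("DEL", "INS")) {
    calls <- ps$calls[ps$calls$svtype == tpn, , drop = FALSE]
    truth <- sim$truth[sim$truth$svtype == tpn, , drop = FALSE]
    m <- match_truth(calls, truth, min_ro = match_ro)
    matches[[tpn]] <- m
    tp <- tp + length(m$TP); fp <- fp + length(m$FP)
    fn <- fn + length(m$FN)
  }
  pr <- prf(list(TP = seq_len(tp), FP = seq_len(fp), FN = seq_len(fn)))
  list(metrics = 100 * pr, matches = matches, truth = sim$truth,
       calls = ps$calls, sample = ps)
}

#' Population-scale merging and genotyping benchmark
#'
#' Simulates a population of genome assemblies (each of the first
#' `n_genomes - 1` carries each planted event with probability 0.5, the
#' last carries all), optionally on top of shared background divergence
#' from the reference, runs the full per-sample call path, merges,
#' filters background by genotype frequency (unless the reference is the
#' planting genome), re-genotypes every site in every sample, and
#' evaluates completeness plus per-sample genotyping accuracy / error /
#' missing against the planted genotype matrix.
#'
#' @param seed integer seed.
#' @param n_genomes population size.
#' @param n_chrom,chrom_length genome shape.
#' @param n_del,n_ins,n_dup planted SV counts (sizes `sv_size`).
#' @param sv_size SV size range (bp, log-uniform).
#' @param n_small additional small indels (half deletions, half
#'   insertions, sizes `small_size`).
#' @param small_size small-indel size range.
#' @param divergence `NULL`, or list with `sub_rate` and `indel_rate`:
#'   shared background divergence applied between the population and the
#'   genotyping reference.
#' @param match_ro truth-match reciprocal overlap (population rule).
#' @param freq_num,freq_den genotype-frequency background filter.
#' @return list with `summary` (named numbers, percent), `eval` (the
#'   [population_eval()] result), `merged`, `gt`, `truth`, `pop`.
#' @export
benchmark_population <- function(seed = 1, n_genomes = 21, n_chrom = 2,
                                 chrom_length = 2.5e6, n_del = 450,
                                 n_ins = 450, n_dup = 100,
                                 sv_size = c(50, 10000), n_small = 0,
                                 small_size = c(5, 49),
                                 divergence = NULL, match_ro = 0.5,
                                 freq_num = 19, freq_den = 21) {
  gen <- make_genome(n_chrom = n_chrom, chrom_length = chrom_length,
                     repeat_fraction = 0.1, seed = seed)
  ref <- gen$genome
  div <- NULL
  if (!is.null(divergence)) {
    ## shared background divergence; divergence edits landing within
    ## 20 bp of a carried event are dropped per carrier by
    ## simulate_population, so planted breakpoints stay exact
    div <- simulate_divergence(ref, sub_rate = divergence$sub_rate,
                               indel_rate = divergence$indel_rate,
                               seed = seed + 11L)
  }
  spec_big <- sv_spec(n_del = n_del, n_ins = n_ins, n_dup = n_dup,
                      del_size = sv_size, ins_size = sv_size,
                      dup_size = sv_size, te_fraction = 0.3,
                      seed = seed + 2L)
  sim_big <- simulate_svs(ref, spec_big, te_library = gen$te_library)
  truth <- sim_big$truth
  if (n_small > 0) {
    avoid2 <- data.frame(ref_name = truth$ref_name,
                         ref_start = truth$ref_start - 20,
                         ref_end = truth$ref_end + 20)
    spec_small <- sv_spec(n_del = ceiling(n_small / 2),
                          n_ins = floor(n_small / 2),
                          del_size = small_size, ins_size = small_size,
                          te_fraction = 0, seed = seed + 3L)
    sim_small <- simulate_svs(ref, spec_small, avoid = avoid2)
    truth <- rbind(truth, sim_small$truth)
    truth <- truth[order(truth$ref_name, truth$ref_start), , drop = FALSE]
    truth$id <- sprintf("truth%05d", seq_len(nrow(truth)))
    rownames(truth) <- NULL
  }
  pop <- simulate_population(ref, truth, n_genomes = n_genomes,
                             seed = seed + 4L,
                             divergence = if (!is.null(div)) div$edits)
  cfg <- svnet_config(reference = ref,
                      samples = setNames(
                        rep(list(list()), n_genomes), pop$samples),
                      ref_is_origin = is.null(divergence),
                      freq_num = freq_num, freq_den = freq_den)
  calls <- list(); alns <- list(); qgs <- list()
  for (nm in pop$samples) {
    blocks <- edits_to_alignment(ref, pop$scripts[[nm]])
    qg <- apply_edits(ref, pop$scripts[[nm]])
    ps <- process_sample(blocks, ref, qg, sample = nm, cfg = cfg)
    calls[[nm]] <- ps$calls
    alns[[nm]] <- sample_alignment(ps$single_cov)
    qgs[[nm]] <- qg
  }
  merged <- merge_calls(do.call(rbind, calls), ro_threshold = cfg$ro_merge,
                        max_shift = cfg$ins_shift,
                        max_len_diff = cfg$ins_lendiff,
                        min_identity = cfg$ins_identity)
  sites <- merged$sites
  if (!is.null(divergence)) {
    ## reference is not the planting backbone: variants reported by
    ## (almost) every sample are pre-existing divergence, not planted SVs
    bg <- sites$support > freq_num / freq_den * n_genomes
    sites <- sites[!bg, , drop = FALSE]
  }
  gt <- matrix(NA_character_, nrow(sites), n_genomes,
               dimnames = list(sites$id, pop$samples))
  for (nm in pop$samples) {
    g <- genotype_sample(sites, alns[[nm]], nm, ref_genome = ref,
                         query_genome = qgs[[nm]],
                         members = merged$members, flank = cfg$flank,
                         ro_min = cfg$ro_genotype,
                         max_shift = cfg$ins_shift,
                         max_len_diff = cfg$ins_lendiff,
                         min_identity = cfg$ins_identity)
    gt[, nm] <- g$state
  }
  ev <- population_eval(sites, gt, truth, pop$genotypes,
                        ref_is_origin = is.null(divergence),
                        freq_num = freq_num, freq_den = freq_den,
                        match_ro = match_ro)
  ## headline numbers
  sv_truth <- truth[truth$length > 50, , drop = FALSE]
  recall_sv <- 100 * sum(sv_truth$id %in% ev$tp$truth_id) / nrow(sv_truth)
  ps <- ev$per_sample
  mean_of <- function(svtype, size, col) {
    sub <- ps[ps$svtype == svtype & ps$size_class == size, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    mean(sub[[col]])
  }
  pooled <- function(col) {
    sub <- ps[ps$svtype %in% c("DEL", "INS") & ps$size_class == "ALL", ,
              drop = FALSE]
    agg <- tapply(sub[[col]] * sub$n, sub$sample, sum) /
      tapply(sub$n, sub$sample, sum)
    mean(agg)
  }
  summary <- c(
    recall_sv = recall_sv,
    completeness = ev$completeness,
    accuracy = ev$accuracy,
    error_rate = ev$error,
    del_acc_sv = mean_of("DEL", "sv", "accuracy"),
    ins_acc_sv = mean_of("INS", "sv", "accuracy"),
    del_acc_indel = mean_of("DEL", "indel", "accuracy"),
    ins_acc_indel = mean_of("INS", "indel", "accuracy"),
    gt_error = pooled("error"),
    gt_missing = pooled("missing"))
  list(summary = summary, eval = ev, merged = merged, sites = sites,
       gt = gt, truth = truth, pop = pop)
}
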