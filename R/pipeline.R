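## End-to-end orchestration: convert -> chain/net -> call -> merge ->
## genotype -> annotate over many samples, with per-stage resumability
## and per-sample quarantine.

#' Pipeline run configuration
#'
#' @param reference reference assembly: FASTA path or named
#'   `DNAStringSet`.
#' @param samples named list; each element a list with `alignment` (path
#'   or an [alignment_blocks()] table), optional `format`
#'   (paf/maf/axt/delta, for paths) and `assembly` (path or
#'   `DNAStringSet` of the query genome).
#' @param out_dir output directory (created).
#' @param te_library,cds_library optional FASTA paths or `DNAStringSet`s
#'   for mechanism annotation.
#' @param min_sv SV/indel size boundary (bp).
#' @param cpx_min double-sided gap size reported as complex.
#' @param ro_merge reciprocal-overlap merge threshold (span SVs).
#' @param ins_shift,ins_lendiff,ins_identity insertion merge thresholds.
#' @param flank genotyping window flank (bp).
#' @param ro_genotype deletion genotyping reciprocal overlap.
#' @param net_policy fill retention policy (see [filter_synnet()]).
#' @param min_space,inv_max_dist,min_gap_cover net construction knobs.
#' @param min_chain_score minimum chain score.
#' @param freq_num,freq_den genotype-frequency background filter.
#' @param ref_is_origin reference is the genome the population derives
#'   from (disables the frequency filter, as for a self-reference run).
#' @param call_snv also produce a joint SNV table.
#' @param seed seed recorded with the run.
#' @return object of class `svnet_config`.
#' @export
svnet_config <- function(reference, samples, out_dir = tempfile("svnet_"),
                         te_library = NULL, cds_library = NULL,
                         min_sv = 50, cpx_min = 20, ro_merge = 0.9,
                         ins_shift = 12, ins_lendiff = 0.20,
                         ins_identity = 0.50, flank = 2000,
                         ro_genotype = 0.5,
                         net_policy = "top_plus_rearrangement",
                         min_space = 1, inv_max_dist = 1e6,
                         min_gap_cover = 0.5, min_chain_score = 25,
                         freq_num = 19, freq_den = 21,
                         ref_is_origin = TRUE, call_snv = FALSE,
                         seed = 1) {
  stopifnot(length(samples) >= 1, !is.null(names(samples)),
            ro_merge > 0, ro_merge <= 1, ins_lendiff >= 0,
            ins_lendiff <= 1, flank >= 0, min_sv > 0)
  cfg <- structure(as.list(environment()), class = "svnet_config")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [svnet_config()]
#'   arguments; `samples` is a map name -> (alignment, format, assembly).
#' @return `svnet_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$reference) || is.null(y$samples))
    stop("config error: 'reference' and 'samples' are required")
  args <- y
  args$samples <- lapply(y$samples, function(s) s)
  do.call(svnet_config, args)
}

config_fingerprint <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("out_dir"))]
  keep <- keep[order(names(keep))]
  paste(deparse(lapply(keep, function(x)
    if (is.character(x) || is.numeric(x) || is.logical(x)) x else
      class(x))), collapse = "")
}

load_genome_input <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    read_assembly(x) else as_dna(x)
}

load_alignment_input <- function(x, format = NULL, query_sizes = NULL) {
  if (is.data.frame(x)) return(x)
  parse_alignments(x, format = format %||% "paf",
                   query_sizes = query_sizes)
}

#' Process one sample: chains, net, single coverage and calls
#'
#' @param blocks alignments of the sample against the reference.
#' @param ref_genome,query_genome assemblies.
#' @param sample sample name.
#' @param cfg a [svnet_config()] (thresholds; a default one is built
#'   when omitted).
#' @return list with `chains`, `net`, `single_cov`, `calls`, `cpx`.
#' @export
process_sample <- function(blocks, ref_genome, query_genome,
                           sample = "sample", cfg = NULL) {
  if (is.null(cfg))
    cfg <- svnet_config(reference = ref_genome,
                        samples = setNames(list(list()), sample))
  chains <- chain_blocks(blocks, min_score = cfg$min_chain_score)
  net <- net_chains(chains, min_space = cfg$min_space)
  net <- classify_fills(net, max_dist = cfg$inv_max_dist)
  net <- filter_synnet(net, policy = cfg$net_policy,
                       min_gap_cover = cfg$min_gap_cover)
  single_cov <- project_single_coverage(net)
  cv <- call_variants(net, chains, ref_genome, query_genome,
                      sample = sample, min_sv = cfg$min_sv,
                      cpx_min = cfg$cpx_min)
  list(chains = chains, net = net, single_cov = single_cov,
       calls = cv$calls, cpx = cv$cpx)
}

stage_path <- function(out_dir, stage, sample = NULL) {
  file.path(out_dir, "state",
            paste0(stage, if (!is.null(sample)) paste0("_", sample),
                   ".rds"))
}

stage_fresh <- function(path, fp_file, fp) {
  file.exists(path) && file.exists(fp_file) &&
    identical(readLines(fp_file, warn = FALSE), fp)
}

#' Run the full pipeline over all configured samples
#'
#' Stages run in order convert, chainnet+call (per sample,
#' independently; failing samples are quarantined and reported), merge,
#' genotype, annotate.  Stage outputs are cached under `out_dir/state`
#' keyed by a configuration fingerprint, so an unchanged rerun skips
#' completed stages.
#'
#' @param cfg a [svnet_config()].
#' @return list with `merged`, `gt` (state matrix), `vcfs` (paths),
#'   `failed` (named list of quarantined sample errors) and `log`
#'   (per-stage counts).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "svnet_config"))
  dir.create(file.path(cfg$out_dir, "state"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "calls"), showWarnings = FALSE)
  fp <- config_fingerprint(cfg)
  fp_file <- file.path(cfg$out_dir, "state", "fingerprint")
  logf <- file.path(cfg$out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  ref_genome <- load_genome_input(cfg$reference)
  log <- list()
  failed <- list()
  results <- list()
  for (nm in names(cfg$samples)) {
    sp <- stage_path(cfg$out_dir, "call", nm)
    if (stage_fresh(sp, fp_file, fp)) {
      results[[nm]] <- readRDS(sp)
      log_line("call\t%s\tskipped (cached)", nm)
      next
    }
    res <- tryCatch({
      s <- cfg$samples[[nm]]
      if (is.null(s$alignment))
        stop("missing alignment input for sample ", nm)
      qg <- load_genome_input(s$assembly)
      blocks <- load_alignment_input(s$alignment, s$format,
                                     query_sizes = genome_sizes(qg))
      out <- process_sample(blocks, ref_genome, qg, sample = nm,
                            cfg = cfg)
      out$query_genome <- qg
      saveRDS(out, sp)
      log_line("call\t%s\tchains=%d fills=%d calls=%d cpx=%d", nm,
               length(out$chains), nrow(out$net$fills), nrow(out$calls),
               nrow(out$cpx))
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[nm]] <- conditionMessage(res)
      log_line("call\t%s\tFAILED: %s", nm, conditionMessage(res))
    } else results[[nm]] <- res
  }
  if (!length(results))
    stop("all samples failed: ",
         paste(names(failed), unlist(failed), collapse = "; "))
  ## merge
  all_calls <- do.call(rbind, lapply(results, `[[`, "calls"))
  merged <- merge_calls(all_calls, ro_threshold = cfg$ro_merge,
                        max_shift = cfg$ins_shift,
                        max_len_diff = cfg$ins_lendiff,
                        min_identity = cfg$ins_identity)
  log_line("merge\tsites=%d from calls=%d", nrow(merged$sites),
           nrow(all_calls))
  ## background frequency flag (support-based prefilter)
  sites <- merged$sites
  if (!cfg$ref_is_origin) {
    bg <- sites$support > cfg$freq_num / cfg$freq_den * length(results)
    log_line("merge\tbackground-flagged=%d", sum(bg))
    sites <- sites[!bg, , drop = FALSE]
  }
  ## genotype
  gt <- matrix(NA_character_, nrow(sites), length(results),
               dimnames = list(sites$id, names(results)))
  for (nm in names(results)) {
    aln <- sample_alignment(results[[nm]]$single_cov)
    g <- genotype_sample(sites, aln, nm, ref_genome = ref_genome,
                         query_genome = results[[nm]]$query_genome,
                         members = merged$members, flank = cfg$flank,
                         ro_min = cfg$ro_genotype,
                         max_shift = cfg$ins_shift,
                         max_len_diff = cfg$ins_lendiff,
                         min_identity = cfg$ins_identity)
    gt[, nm] <- g$state
    log_line("genotype\t%s\talt=%d ref=%d missing=%d", nm,
             sum(g$state == "ALT"), sum(g$state == "REF"),
             sum(g$state == "MISSING"))
  }
  ## annotate
  mech <- NULL
  if (!is.null(cfg$te_library) || !is.null(cfg$cds_library)) {
    te <- if (!is.null(cfg$te_library))
      load_genome_input(cfg$te_library)
    cds <- if (!is.null(cfg$cds_library))
      load_genome_input(cfg$cds_library)
    mech <- annotate_mechanisms(sites, ref_genome, te_library = te,
                                cds_library = cds)
    log_line("annotate\tlabeled=%d", sum(mech$mechanism != "UNCLASSIFIED"))
  }
  ## VCF output, one file per SV type
  vcfs <- character(0)
  for (tp in unique(sites$svtype)) {
    idx <- sites$svtype == tp
    p <- file.path(cfg$out_dir, paste0(tp, ".vcf"))
    write_vcf(sites[idx, , drop = FALSE],
              gt[idx, , drop = FALSE], ref_genome, p, mech = mech)
    vcfs[tp] <- p
  }
  ## per-sample call tables
  for (nm in names(results))
    write.table(results[[nm]]$calls,
                file.path(cfg$out_dir, "calls", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  snvs <- NULL
  if (isTRUE(cfg$call_snv)) {
    snv_list <- lapply(names(results), function(nm)
      call_snvs(results[[nm]]$single_cov, ref_genome,
                results[[nm]]$query_genome, sample = nm))
    snvs <- do.call(rbind, snv_list)
  }
  writeLines(fp, fp_file)
  if (length(failed))
    warning("quarantined sample(s): ",
            paste(names(failed), collapse = ", "))
  list(merged = merged, sites = sites, gt = gt, vcfs = vcfs, mech = mech,
       snvs = snvs, failed = failed, out_dir = cfg$out_dir)
}
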