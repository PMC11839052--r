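make_pair_genomes <- function(ref_len = 3000, seed = 2) {
  withr::with_seed(seed, {
    r <- rand_seq(ref_len)
    list(ref = Biostrings::DNAStringSet(c(r = r)), ref_chr = r)
  })
}

test_that("chain gaps classify as DEL, INS, double-report or CPX", {
  g <- make_pair_genomes()
  q <- Biostrings::DNAStringSet(c(q = rand_seq(3000, seed = 3)))
  ## segments: [0,100)x[0,100); DEL 120; [220,320)x[100,200);
  ## INS 30 at 320; [320,420)x[230,330); double 30/10 (unbalanced);
  ## [450,550)x[340,440); double 500/480 -> CPX; [1050,1150)x[920,1020)
  ch <- toy_chain(rs = c(0, 220, 320, 450, 1050),
                  re = c(100, 320, 420, 550, 1150),
                  qs = c(0, 100, 230, 340, 920),
                  qe = c(100, 200, 330, 440, 1020),
                  ref = "r", qry = "q")
  calls <- call_gap_variants(ch, g$ref, q, sample = "s1")
  expect_equal(calls$svtype, c("DEL", "INS", "DEL", "INS", "CPX"))
  expect_equal(calls$length, c(120, 30, 30, 10, 500))
  expect_equal(calls$size_class, c("sv", "indel", "indel", "indel", "sv"))
  ## allele sequences re-extract from the right genome
  expect_equal(calls$seq[1], substr(g$ref_chr, 101, 220))
  expect_equal(calls$seq[2], substr(as.character(q[[1]]), 201, 230))
  ## cpx boundary: min side >= cpx_min stays CPX, below it double-reports
  expect_equal(sum(calls$svtype == "CPX"), 1L)
})

test_that("gap coordinates outside the genome raise a validation error", {
  g <- make_pair_genomes(ref_len = 300)
  q <- Biostrings::DNAStringSet(c(q = rand_seq(300, seed = 3)))
  ch <- toy_chain(rs = c(0, 400), re = c(100, 500), qs = c(0, 100),
                  qe = c(100, 200), ref = "r", qry = "q")
  expect_error(call_gap_variants(ch, g$ref, q), "outside genome bounds")
})

test_that("planted events are recovered exactly at zero divergence", {
  gen <- make_genome(n_chrom = 2, chrom_length = 2e5, seed = 13)
  spec <- sv_spec(n_del = 8, n_ins = 8, n_dup = 3, n_inv = 2,
                  del_size = c(60, 800), ins_size = c(60, 800),
                  dup_size = c(200, 500), inv_size = c(1200, 4000),
                  te_fraction = 0.5, seed = 14)
  sim <- simulate_svs(gen$genome, spec, te_library = gen$te_library)
  ps <- process_sample(edits_to_alignment(gen$genome, sim$edits),
                       gen$genome, sim$genome, sample = "s")
  for (tp in c("DEL", "INS", "DUP", "INV")) {
    calls <- ps$calls[ps$calls$svtype == tp, , drop = FALSE]
    truth <- sim$truth[sim$truth$svtype == tp, , drop = FALSE]
    expect_equal(
      sort(paste(calls$ref_name, calls$ref_start, calls$length)),
      sort(paste(truth$ref_name, truth$ref_start, truth$length)),
      label = tp)
  }
  ## DEL sequences equal the reference substring of their interval
  del <- ps$calls[ps$calls$svtype == "DEL", ]
  for (i in seq_len(nrow(del)))
    expect_equal(del$seq[i],
                 genome_subseq(gen$genome, del$ref_name[i],
                               del$ref_start[i], del$ref_end[i]))
  ## INS sequences equal the planted insertion
  ins <- merge(ps$calls[ps$calls$svtype == "INS", ],
               sim$truth[sim$truth$svtype == "INS", ],
               by = c("ref_name", "ref_start"))
  expect_true(all(ins$seq.x == ins$seq.y))
  ## calls are coordinate-sorted and deterministic
  ps2 <- process_sample(edits_to_alignment(gen$genome, sim$edits),
                        gen$genome, sim$genome, sample = "s")
  expect_identical(ps$calls, ps2$calls)
  expect_false(is.unsorted(order(ps$calls$ref_name, ps$calls$ref_start)))
})

test_that("inversion fills yield INV calls at the planted interval", {
  gen <- make_genome(n_chrom = 1, chrom_length = 1e5, seed = 23)
  spec <- sv_spec(n_inv = 2, inv_size = c(3000, 8000), seed = 24)
  sim <- simulate_svs(gen$genome, spec)
  ps <- process_sample(edits_to_alignment(gen$genome, sim$edits),
                       gen$genome, sim$genome, sample = "s")
  inv <- ps$calls[ps$calls$svtype == "INV", ]
  tru <- sim$truth[order(sim$truth$ref_start), ]
  expect_equal(inv$ref_start, tru$ref_start)
  expect_equal(inv$ref_end, tru$ref_end)
  ## no spurious DEL/INS at the inversion site
  expect_equal(nrow(ps$calls), 2L)
  ## empty net -> no inversions
  expect_equal(nrow(call_inversions(net_chains(list()))), 0L)
})

test_that("translocated fills become TRA with the donor query interval", {
  top <- toy_chain(rs = c(0, 6000), re = c(4000, 10000),
                   qs = c(0, 6000), qe = c(4000, 10000), id = "c0001",
                   score = 8000)
  tra <- toy_chain(rs = 4000, re = 6000, qs = 100, qe = 2100, qry = "q5",
                   id = "c0002", score = 1800)
  net <- filter_synnet(classify_fills(net_chains(list(top, tra))))
  calls <- call_translocations(net, sample = "s")
  expect_equal(calls$svtype, "TRA")
  expect_equal(calls$query_name, "q5")
  expect_equal(calls$ref_start, 4000)
  syn_only <- filter_synnet(classify_fills(net_chains(list(top))))
  expect_equal(nrow(call_translocations(syn_only)), 0L)
})

test_that("tandem duplications are called from reference multi-coverage", {
  gen <- make_genome(n_chrom = 1, chrom_length = 1e5, seed = 31)
  spec <- sv_spec(n_dup = 1, dup_size = c(2000, 2000), seed = 32)
  sim <- simulate_svs(gen$genome, spec)
  ps <- process_sample(edits_to_alignment(gen$genome, sim$edits),
                       gen$genome, sim$genome, sample = "s")
  dup <- ps$calls[ps$calls$svtype == "DUP", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$length, 2000)
  expect_equal(dup$ref_start, sim$truth$ref_start)
  ## the extra copy is not double-reported as an insertion
  expect_equal(nrow(ps$calls), 1L)
  ## three-copy tandem records its copy number
  spec3 <- sv_spec(n_dup = 1, dup_size = c(1000, 1000), dup_copies = 3,
                   seed = 33)
  sim3 <- simulate_svs(gen$genome, spec3)
  blocks3 <- edits_to_alignment(gen$genome, sim3$edits)
  chains3 <- chain_blocks(blocks3)
  net3 <- net_chains(chains3)
  d3 <- call_duplications(net3, chains3)
  expect_equal(d3$copies, 3L)
  ## no multi-coverage -> no duplications
  expect_equal(nrow(call_duplications(net3, chains3[1])), 0L)
})

test_that("SNVs are called per differing aligned column, skipping N", {
  ref <- Biostrings::DNAStringSet(c(r = "ACGTACGTNA"))
  qry <- Biostrings::DNAStringSet(c(q = "ACGAACGTTA"))
  seg <- data.frame(ref_name = "r", ref_start = 0, ref_end = 10,
                    query_name = "q", query_start = 0, query_end = 10,
                    strand = "+")
  snv <- call_snvs(seg, ref, qry, sample = "s")
  expect_equal(snv$pos, 3)        # ref N column at 8 is skipped
  expect_equal(snv$ref_base, "T")
  expect_equal(snv$alt_base, "A")
  ## identical sequences: empty
  same <- Biostrings::DNAStringSet(c(q = as.character(ref[[1]])))
  expect_equal(nrow(call_snvs(seg, ref, same, sample = "s")), 0L)
  ## minus strand: query base reverse-complemented before comparison
  qm <- Biostrings::DNAStringSet(c(q = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ACGAACGTTA")))))
  segm <- transform(seg, strand = "-")
  snvm <- call_snvs(segm, ref, qm, sample = "s")
  expect_equal(snvm$pos, 3)
})
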