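test_that("genome generation is deterministic with controlled composition", {
  g1 <- make_genome(n_chrom = 1, chrom_length = 1e5, gc = 0.5, seed = 61)
  g2 <- make_genome(n_chrom = 1, chrom_length = 1e5, gc = 0.5, seed = 61)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_false(identical(
    as.character(make_genome(n_chrom = 1, chrom_length = 1e5,
                             seed = 62)$genome),
    as.character(g1$genome)))
  gc <- Biostrings::letterFrequency(g1$genome, c("G", "C"))
  expect_lt(abs(sum(gc) / 1e5 - 0.5), 0.01)
  ## planted repeat copies really are library sequence
  s <- g1$te_sites[1, ]
  fam <- as.character(g1$te_library[[s$family]])
  expect_equal(genome_subseq(g1$genome, s$ref_name, s$start, s$end), fam)
})

test_that("SV planting conserves length and replays byte-identically", {
  gen <- make_genome(n_chrom = 2, chrom_length = 8e4, seed = 63)
  spec <- sv_spec(n_del = 6, n_ins = 6, n_dup = 2, n_inv = 1,
                  del_size = c(50, 600), ins_size = c(50, 600),
                  dup_size = c(100, 300), inv_size = c(1000, 2000),
                  seed = 64)
  sim <- simulate_svs(gen$genome, spec, te_library = gen$te_library)
  tr <- sim$truth
  expected <- sum(genome_sizes(gen$genome)) -
    sum(tr$length[tr$svtype == "DEL"]) +
    sum(tr$length[tr$svtype == "INS"]) +
    sum(tr$length[tr$svtype == "DUP"] * (tr$copies[tr$svtype == "DUP"] - 1))
  expect_equal(sum(genome_sizes(sim$genome)), expected)
  ## edit script replay
  expect_identical(as.character(apply_edits(gen$genome, sim$edits)),
                   as.character(sim$genome))
  ## events respect spacing and do not overlap
  for (nm in unique(tr$ref_name)) {
    t2 <- tr[tr$ref_name == nm, ]
    t2 <- t2[order(t2$ref_start), ]
    if (nrow(t2) > 1)
      expect_true(all(t2$ref_start[-1] - t2$ref_end[-nrow(t2)] >= 500))
  }
  ## zero counts: identity
  none <- simulate_svs(gen$genome, sv_spec(seed = 65))
  expect_identical(as.character(none$genome), as.character(gen$genome))
})

test_that("population design gives each genome about half the events", {
  gen <- make_genome(n_chrom = 1, chrom_length = 6e5, seed = 66)
  spec <- sv_spec(n_del = 120, n_ins = 120, del_size = c(50, 500),
                  ins_size = c(50, 500), seed = 67)
  sim <- simulate_svs(gen$genome, spec)
  pop <- simulate_population(gen$genome, sim$truth, n_genomes = 11,
                             seed = 68)
  gtm <- pop$genotypes
  expect_equal(dim(gtm), c(240L, 11L))
  expect_true(all(gtm[, 11] == 1L))          # last genome carries all
  frac <- colSums(gtm[, 1:10]) / nrow(gtm)
  expect_true(all(frac >= 0.4 & frac <= 0.6))
  ## deterministic
  expect_identical(gtm, simulate_population(gen$genome, sim$truth,
                                            n_genomes = 11,
                                            seed = 68)$genotypes)
  ## materialized genome equals replaying its script
  g3 <- population_genome(gen$genome, pop, "g03")
  expect_identical(as.character(g3),
                   as.character(apply_edits(gen$genome,
                                            pop$scripts[["g03"]])))
  expect_error(simulate_population(gen$genome,
                                   transform(sim$truth, svtype = "INV"),
                                   3, 1), "DEL/INS/DUP")
})

test_that("divergence rates are realized within tolerance", {
  gen <- make_genome(n_chrom = 1, chrom_length = 1e6, seed = 69,
                     repeat_fraction = 0)
  div <- simulate_divergence(gen$genome, sub_rate = 0.02,
                             indel_rate = 0.002, seed = 70)
  n_sub <- sum(div$edits$type == "sub")
  expect_lt(abs(n_sub - 20000) / 20000, 0.05)  # within 5% of requested
  n_ind <- sum(div$edits$type != "sub")
  expect_lt(abs(n_ind - 2000) / 2000, 0.1)
  ## zero rates: identity; same seed: identical
  none <- simulate_divergence(gen$genome, 0, 0, seed = 71)
  expect_identical(as.character(none$genome), as.character(gen$genome))
  again <- simulate_divergence(gen$genome, sub_rate = 0.02,
                               indel_rate = 0.002, seed = 70)
  expect_identical(div$edits, again$edits)
  expect_error(simulate_divergence(gen$genome, 0.5, 0, seed = 1))
})

test_that("edit scripts induce the exact truth alignment", {
  gen <- make_genome(n_chrom = 1, chrom_length = 5e4, seed = 72)
  ## no edits: one full-length block
  b0 <- edits_to_alignment(gen$genome, svnet:::empty_edits())
  expect_equal(nrow(b0), 1L)
  expect_equal(b0$ref_end, 5e4)
  expect_equal(b0$query_end, 5e4)
  ## a single 100 bp deletion: two blocks separated on the reference only
  del <- data.frame(type = "del", ref_name = names(gen$genome)[1],
                    ref_start = 1000, ref_end = 1100, seq = NA,
                    copies = NA)
  b1 <- edits_to_alignment(gen$genome, del)
  expect_equal(nrow(b1), 2L)
  expect_equal(b1$ref_start, c(0, 1100))
  expect_equal(b1$query_start, c(0, 1000))
  ## fragmentation changes the blocks but not the induced chain span
  spec <- sv_spec(n_del = 4, n_ins = 4, del_size = c(60, 300),
                  ins_size = c(60, 300), seed = 73)
  sim <- simulate_svs(gen$genome, spec)
  whole <- chain_blocks(edits_to_alignment(gen$genome, sim$edits))
  frag <- chain_blocks(edits_to_alignment(
    gen$genome, sim$edits, fragmentation = list(mean_len = 2000, seed = 74)))
  span <- function(ch) vapply(ch, function(c)
    paste(c$ref_name, c$ref_start, c$ref_end, c$query_start, c$query_end),
    "")
  expect_setequal(span(whole), span(frag))
  ## inversions become minus-strand blocks over the same interval
  inv <- data.frame(type = "inv", ref_name = names(gen$genome)[1],
                    ref_start = 2000, ref_end = 3000, seq = NA,
                    copies = NA)
  bi <- edits_to_alignment(gen$genome, inv)
  expect_equal(bi$strand, c("+", "-", "+"))
  expect_equal(bi$ref_start[2], 2000)
  expect_equal(bi$query_start[2], 2000)
})
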