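## build a sample alignment holding given segments (one chain)
mk_aln <- function(rs, re, qs = rs, qe = re, strand = "+",
                   chrom = "chr1", qchrom = "chr1") {
  seg <- data.frame(ref_name = chrom, ref_start = rs, ref_end = re,
                    query_name = qchrom, query_start = qs, query_end = qe,
                    strand = strand, chain = "c0001", fill = 1L,
                    stringsAsFactors = FALSE)
  sample_alignment(seg)
}

mk_site <- function(svtype, start, end, len = end - start, seq = NA,
                    id = "DEL00001", chrom = "chr1") {
  data.frame(id = id, svtype = svtype, ref_name = chrom, ref_start = start,
             ref_end = end, length = len, seq = seq, query_name = "chr1",
             support = 1L, stringsAsFactors = FALSE)
}

test_that("deletion genotyping reads ALT/REF/MISSING from the window gaps", {
  ## deletion gap [1000,1200): carrier
  aln <- mk_aln(rs = c(0, 1200), re = c(1000, 3000),
                qs = c(0, 1000), qe = c(1000, 2800))
  site <- mk_site("DEL", 1000, 1200)
  w <- extract_window(aln, "chr1", 1000, 1200)
  expect_equal(genotype_deletion(w, site)$state, "ALT")
  ## clean alignment across the span: reference genotype
  ref_aln <- mk_aln(0, 3000)
  expect_equal(genotype_deletion(extract_window(ref_aln, "chr1", 1000, 1200),
                                 site)$state, "REF")
  ## no alignment at all
  far <- extract_window(ref_aln, "chr2", 1000, 1200)
  g <- genotype_deletion(far, site)
  expect_equal(g$state, "MISSING")
  expect_equal(g$reason, "no_alignment")
  ## partial overlap below the RO threshold is not ALT
  half <- mk_aln(rs = c(0, 1100), re = c(700, 3000),
                 qs = c(0, 700), qe = c(700, 2600))
  gh <- genotype_deletion(extract_window(half, "chr1", 1000, 1200), site,
                          ro_min = 0.5)
  expect_false(gh$state == "ALT")
  expect_error(genotype_deletion(w, mk_site("INS", 1, 1, 5)), "DEL")
})

test_that("insertion genotyping verifies length and inserted sequence", {
  ins_seq <- rand_seq(300, seed = 11)
  qg <- Biostrings::DNAStringSet(c(chr1 = paste0(
    rand_seq(1000, seed = 12), ins_seq, rand_seq(1000, seed = 13))))
  aln <- mk_aln(rs = c(0, 1000), re = c(1000, 2000),
                qs = c(0, 1300), qe = c(1000, 2300))
  site <- mk_site("INS", 1000, 1000, len = 300, seq = ins_seq,
                  id = "INS00001")
  w <- extract_window(aln, "chr1", 1000, 1000)
  g <- genotype_insertion_aln(w, site, qg)
  expect_equal(g$state, "ALT")
  expect_gte(g$identity, 0.99)
  ## sample without the insertion: continuous alignment
  plain <- mk_aln(0, 2000)
  expect_equal(genotype_insertion_aln(
    extract_window(plain, "chr1", 1000, 1000), site, qg)$state, "REF")
  ## matching length but unrelated sequence fails the identity check
  site2 <- mk_site("INS", 1000, 1000, len = 300,
                   seq = rand_seq(300, seed = 99), id = "INS00002")
  expect_false(genotype_insertion_aln(w, site2, qg,
                                      min_identity = 0.75)$state == "ALT")
})

test_that("realignment insertion genotyping recovers planted inserts", {
  withr::with_seed(17, {
    refw <- rand_seq(800)
    ins <- rand_seq(120)
    site <- mk_site("INS", 400, 400, len = 120, seq = ins, id = "INS00001")
    carrier <- paste0(substr(refw, 1, 400), ins, substr(refw, 401, 800))
    expect_equal(genotype_insertion(site, carrier, refw, 400)$state, "ALT")
    expect_equal(genotype_insertion(site, refw, refw, 400)$state, "REF")
    ## the same decision holds when the windows carry point divergence
    div <- strsplit(carrier, "")[[1]]
    idx <- sample(seq_along(div), 15)
    div[idx] <- sample(c("A", "C", "G", "T"), 15, replace = TRUE)
    g <- genotype_insertion(site, paste(div, collapse = ""), refw, 400)
    expect_equal(g$state, "ALT")
    ## an all-N window is an assembly gap
    expect_equal(genotype_insertion(site, strrep("N", 800), refw, 400)$state,
                 "MISSING")
    expect_equal(genotype_insertion(site, "", refw, 400)$reason,
                 "no_alignment")
  })
})

test_that("small-indel genotyping tolerates breakpoint shift", {
  site <- mk_site("DEL", 1000, 1007, id = "DEL00001")
  carrier <- mk_aln(rs = c(0, 1010), re = c(1003, 3000),
                    qs = c(0, 1003), qe = c(1003, 2993))  # 7 bp del at 1003
  g <- genotype_small_indel(extract_window(carrier, "chr1", 1000, 1007),
                            site)
  expect_equal(g$state, "ALT")
  expect_equal(g$observed, 7)
  expect_equal(genotype_small_indel(
    extract_window(mk_aln(0, 3000), "chr1", 1000, 1007), site)$state, "REF")
  none <- sample_alignment(data.frame(ref_name = character(0),
                                      ref_start = numeric(0),
                                      ref_end = numeric(0),
                                      query_name = character(0),
                                      query_start = numeric(0),
                                      query_end = numeric(0),
                                      strand = character(0),
                                      chain = character(0),
                                      fill = integer(0)))
  expect_equal(genotype_small_indel(
    extract_window(none, "chr1", 1000, 1007), site)$state, "MISSING")
  ## indel of the wrong size is not the planted allele
  site_big <- mk_site("DEL", 1003, 1033, len = 30, id = "DEL00002")
  gb <- genotype_small_indel(extract_window(carrier, "chr1", 1003, 1033),
                             site_big)
  expect_false(gb$state == "ALT")
})

test_that("genotyping is monotone in the identity threshold", {
  ins_a <- rand_seq(100, seed = 31)
  qg <- Biostrings::DNAStringSet(c(chr1 = paste0(
    rand_seq(500, seed = 32), ins_a, rand_seq(500, seed = 33))))
  aln <- mk_aln(rs = c(0, 500), re = c(500, 1000),
                qs = c(0, 600), qe = c(500, 1100))
  ## site sequence shares ~half its bases with the observed insert
  half <- paste0(substr(ins_a, 1, 50), rand_seq(50, seed = 34))
  site <- mk_site("INS", 500, 500, len = 100, seq = half, id = "INS00001")
  w <- extract_window(aln, "chr1", 500, 500)
  states <- vapply(c(0.9, 0.5, 0.2), function(th)
    genotype_insertion_aln(w, site, qg, min_identity = th)$state, "")
  ## once ALT at a high threshold, lower thresholds keep it ALT
  alt_at <- states == "ALT"
  expect_true(all(alt_at[cumsum(alt_at) > 0]))
})

test_that("VCF writing follows the anchor-base conventions and round-trips", {
  withr::with_seed(41, {
    ref <- Biostrings::DNAStringSet(c(chr1 = rand_seq(3000)))
    ins_seq <- rand_seq(70)
    sites <- rbind(mk_site("DEL", 1000, 1100, id = "DEL00001"),
                   mk_site("INS", 1500, 1500, len = 70, seq = ins_seq,
                           id = "INS00001"),
                   mk_site("INV", 2000, 2600, id = "INV00001"))
    gt <- matrix(c("ALT", "REF", "MISSING",
                   "REF", "ALT", "ALT"), nrow = 3,
                 dimnames = list(sites$id, c("s1", "s2")))
    tmp <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(sites, gt, ref, tmp)
    lines <- readLines(tmp)
    rec <- strsplit(grep("^chr1", lines, value = TRUE), "\t")
    ## DEL of [1000,1100): POS = 1000, REF 101 bp, ALT 1 bp, SVLEN -100
    expect_equal(rec[[1]][2], "1000")
    expect_equal(nchar(rec[[1]][4]), 101L)
    expect_equal(nchar(rec[[1]][5]), 1L)
    expect_true(grepl("SVLEN=-100", rec[[1]][8]))
    ## REF allele matches the genome at POS
    expect_equal(rec[[1]][4], genome_subseq(ref, "chr1", 999, 1100))
    ## INS: ALT = anchor + insert; INV symbolic with END
    expect_equal(nchar(rec[[2]][5]), 71L)
    expect_equal(rec[[3]][5], "<INV>")
    expect_true(grepl("END=2600", rec[[3]][8]))
    ## round trip reproduces the genotype matrix
    back <- read_vcf(tmp)
    expect_equal(unname(back$gt),
                 unname(ifelse(gt == "ALT", "1/1",
                               ifelse(gt == "REF", "0/0", "./."))))
    expect_equal(back$sites$ref_start, sites$ref_start)
    expect_equal(back$sites$seq[2], ins_seq)
    ## the file is consumable by an independent VCF reader
    if (nzchar(Sys.which("bcftools"))) {
      out <- system2("bcftools", c("view", tmp), stdout = TRUE,
                     stderr = FALSE)
      expect_equal(sum(!startsWith(out, "#")), 3L)
    }
  })
})

test_that("SNV genotyping reports strand-corrected bases or missing", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  qry <- Biostrings::DNAStringSet(c(chr1 = "ACGAACGTAC"))
  seg <- data.frame(ref_name = "chr1", ref_start = 0, ref_end = 10,
                    query_name = "chr1", query_start = 0, query_end = 10,
                    strand = "+", chain = "c1", fill = 1L)
  pos <- data.frame(ref_name = "chr1", pos = c(3, 5))
  expect_equal(genotype_snv(seg, qry, pos), c("A", "C"))
  ## unaligned position
  pos2 <- data.frame(ref_name = "chr2", pos = 3)
  expect_true(is.na(genotype_snv(seg, qry, pos2)))
})
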