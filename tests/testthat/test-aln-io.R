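test_that("PAF records parse to normalized blocks with expanded cigars", {
  tmp <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    "q1\t1000\t100\t290\t+\tr1\t2000\t500\t700\t190\t200\t60\tcg:Z:100M10D90M",
    "q1\t1000\t400\t450\t-\tr1\t2000\t900\t950\t50\t50\t60\tcg:Z:50M",
    "q2\t800\t0\t100\t+\tr1\t2000\t0\t100\t100\t100\t60"), tmp)
  b <- parse_alignments(tmp, "paf")
  expect_equal(nrow(b), 3L)
  expect_equal(unname(unlist(b[1, c("ref_start", "ref_end",
                                    "query_start", "query_end")])),
               c(500, 700, 100, 290))
  expect_equal(b$cigar[1], "100M10D90M")
  ## cigar-consumed spans equal coordinate spans
  cg <- cigar_parse(b$cigar[1])
  expect_equal(sum(cg$len[cg$op %in% c("M", "D")]), 200)
  expect_equal(sum(cg$len[cg$op %in% c("M", "I")]), 190)
  ## record without cg tag is kept but flagged
  expect_true(is.na(b$cigar[3]))
  expect_equal(attr(b, "n_gapless_flagged"), 1L)
})

test_that("malformed and overflowing PAF records raise informative errors", {
  tmp <- withr::local_tempfile(fileext = ".paf")
  writeLines("q1\t1000\t100", tmp)
  expect_error(parse_alignments(tmp, "paf"), "line 1")
  writeLines("q1\t200\t100\t300\t+\tr1\t2000\t500\t700\t190\t200\t60", tmp)
  expect_error(parse_alignments(tmp, "paf"), "exceeds declared")
})

test_that("AXT 1-based inclusive coordinates convert to the internal frame", {
  fx <- random_block_fixture(1, seed = 42)
  tmp <- withr::local_tempfile(fileext = ".axt")
  rseq <- strrep("A", 200); qseq <- strrep("A", 200)
  writeLines(c("0 r1 501 700 q1 101 300 + 100", rseq, qseq, ""), tmp)
  b <- parse_alignments(tmp, "axt")
  expect_equal(b$ref_start, 500); expect_equal(b$ref_end, 700)
  expect_equal(b$query_start, 100); expect_equal(b$query_end, 300)
})

test_that("MAF minus-strand query coordinates convert to the forward strand", {
  tmp <- withr::local_tempfile(fileext = ".maf")
  txt <- strrep("A", 50)
  writeLines(c("##maf version=1", "",
               "a score=50",
               paste("s r1 200 50 + 2000", txt),
               paste("s q1 100 50 - 1000", txt), ""), tmp)
  b <- parse_alignments(tmp, "maf")
  ## forward = srcSize - start - size = 1000 - 100 - 50
  expect_equal(b$query_start, 850)
  expect_equal(b$query_end, 900)
  expect_equal(b$strand, "-")
})

test_that("AXT and MAF writing round-trips coordinates, strand and cigar", {
  fx <- random_block_fixture(60, seed = 7)
  qsizes <- setNames(Biostrings::width(fx$qry), names(fx$qry))
  for (fmt in c("axt", "maf")) {
    tmp <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_alignments(fx$blocks, tmp, fmt, fx$ref, fx$qry)
    b <- parse_alignments(tmp, fmt, query_sizes = qsizes)
    for (col in c("ref_name", "ref_start", "ref_end", "query_name",
                  "query_start", "query_end", "strand", "cigar"))
      expect_equal(b[[col]], fx$blocks[[col]], label = paste(fmt, col))
  }
})

test_that("empty and single-block writes are valid", {
  fx <- random_block_fixture(1, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".axt")
  write_alignments(fx$blocks[0, ], tmp, "axt", fx$ref, fx$qry)
  expect_equal(nrow(parse_alignments(tmp, "axt")), 0L)
  gapless <- fx$blocks[1, ]
  gapless$cigar <- paste0(gapless$ref_end - gapless$ref_start, "M")
  gapless$query_end <- gapless$query_start +
    (gapless$ref_end - gapless$ref_start)
  write_alignments(gapless, tmp, "axt", fx$ref, fx$qry)
  lines <- readLines(tmp)
  seqs <- lines[nzchar(lines) & !grepl("^[#0-9]", lines)]
  expect_equal(nchar(seqs[1]), nchar(seqs[2]))
  expect_error(write_alignments(transform(gapless, ref_name = "nope"),
                                tmp, "axt", fx$ref, fx$qry),
               "unknown sequence")
})

test_that("MUMmer delta gap encoding translates to the correct cigar", {
  tmp <- withr::local_tempfile(fileext = ".delta")
  ## alignment: 10 matches, deletion of 1 (ref base unmatched at column
  ## 11), 5 matches, insertion of 1 in query, 4 matches
  writeLines(c("/ref /qry", "NUCMER", ">r1 q1 2000 1000",
               "101 120 201 220 3 3 0", "11", "-6", "0"), tmp)
  b <- parse_alignments(tmp, "delta")
  expect_equal(b$ref_start, 100); expect_equal(b$ref_end, 120)
  expect_equal(b$query_start, 200); expect_equal(b$query_end, 220)
  expect_equal(b$cigar, "10M1D5M1I4M")
  sp <- svnet:::cigar_spans(b$cigar)
  expect_equal(unname(sp["ref"]), 20)
  expect_equal(unname(sp["query"]), 20)
})

test_that("split_genome tiles with the configured overlap", {
  g <- Biostrings::DNAStringSet(c(chr1 = rand_seq(50, seed = 1)))
  sp <- split_genome(g, window = 20, overlap = 2)
  expect_equal(sp$manifest$offset, c(0, 18, 36))
  expect_equal(sp$manifest$length, c(20, 20, 14))
  ## source reconstructs from segments minus overlaps
  rebuilt <- paste0(substr(as.character(sp$assembly[[1]]), 1, 20),
                    substr(as.character(sp$assembly[[2]]), 3, 20),
                    substr(as.character(sp$assembly[[3]]), 3, 14))
  expect_equal(rebuilt, as.character(g[[1]]))
  ## shorter than window: single segment; overlap 0: disjoint tiling
  expect_equal(nrow(split_genome(g, window = 100, overlap = 10)$manifest), 1L)
  m0 <- split_genome(g, window = 10, overlap = 0)$manifest
  expect_equal(m0$offset, seq(0, 40, by = 10))
  expect_error(split_genome(g, window = 10, overlap = 10), "config error")
})

test_that("restore_coordinates lifts, validates and deduplicates", {
  man <- data.frame(segment = c("s1", "s2"), source = "chrA",
                    offset = c(0, 18e6), length = c(2e7, 2e6 + 300))
  b <- alignment_blocks(ref_name = "r", ref_start = c(10, 10, 50),
                        ref_end = c(210, 210, 90),
                        query_name = c("s1", "s2", "s2"),
                        query_start = c(18e6, 0, 100) + c(0, 0, 0),
                        query_end = c(18e6 + 200, 200, 300),
                        strand = "+")
  r <- restore_coordinates(b, man)
  ## offset addition and overlap-zone dedup: rows 1 and 2 coincide
  expect_equal(nrow(r), 2L)
  expect_equal(r$query_start, c(18e6, 18e6 + 100))
  expect_true(all(r$query_name == "chrA"))
  expect_error(restore_coordinates(
    alignment_blocks(ref_name = "r", ref_start = 0, ref_end = 10,
                     query_name = "sX", query_start = 0, query_end = 10,
                     strand = "+"), man), "absent from manifest")
  bad <- alignment_blocks(ref_name = "r", ref_start = 0, ref_end = 10,
                          query_name = "s2", query_start = 2e6 + 200,
                          query_end = 2e6 + 400, strand = "+")
  expect_error(restore_coordinates(bad, man), "exceeds source length")
})
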