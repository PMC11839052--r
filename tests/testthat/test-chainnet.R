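test_that("collinear blocks join when the gap cost is below the block score", {
  b <- alignment_blocks(ref_name = "r", ref_start = c(0, 150),
                        ref_end = c(100, 250), query_name = "q",
                        query_start = c(0, 160), query_end = c(100, 260),
                        strand = "+", score = c(100, 100),
                        cigar = c("100M", "100M"))
  ch <- chain_blocks(b)
  expect_length(ch, 1L)
  expect_equal(nrow(ch[[1]]$blocks), 2L)
  ## the default model prices the 50/60 two-sided gap below one block
  expect_lt(gap_cost(gap_cost_model(), 50, 60), 100)
  ## strand mismatch is never joined
  b2 <- b; b2$strand[2] <- "-"
  expect_length(chain_blocks(b2), 2L)
})

test_that("every input block lands in exactly one chain, deterministically", {
  fx <- random_block_fixture(40, seed = 9)
  ch1 <- chain_blocks(fx$blocks, min_score = 0)
  ch2 <- chain_blocks(fx$blocks[sample(nrow(fx$blocks)), ], min_score = 0)
  n1 <- sum(vapply(ch1, function(c) nrow(c$blocks), 0L))
  expect_equal(n1, nrow(fx$blocks))
  key <- function(chs) sort(vapply(chs, function(c)
    paste(c$ref_name, c$ref_start, c$ref_end, c$strand, nrow(c$blocks)), ""))
  expect_equal(key(ch1), key(ch2))
})

test_that("netting builds the fill hierarchy and discards redundant chains", {
  top <- toy_chain(rs = c(0, 6000), re = c(4000, 10000),
                   qs = c(0, 6000), qe = c(4000, 10000), id = "c0001",
                   score = 8000)
  child <- toy_chain(rs = 4000, re = 6000, qs = 20000, qe = 22000,
                     id = "c0002", score = 2000)
  dup <- toy_chain(rs = 0, re = 4000, qs = 30000, qe = 34000,
                   id = "c0003", score = 500)  # same ref span, lower score
  net <- net_chains(list(top, child, dup))
  expect_equal(nrow(net$fills), 2L)
  expect_equal(net$fills$level, c(1L, 2L))
  expect_equal(net$fills$ref_start, c(0, 4000))
  expect_equal(net$fills$parent[2], net$fills$fill[1])
  expect_false("c0003" %in% names(net$chains))
  ## disjoint chains become two top fills
  net2 <- net_chains(list(toy_chain(0, 100, 0, 100),
                          toy_chain(500, 600, 500, 600, id = "c0002")))
  expect_equal(net2$fills$level, c(1L, 1L))
  expect_equal(nrow(net_chains(list())$fills), 0L)
})

test_that("fills classify as syn, inv or tra by query placement", {
  top <- toy_chain(rs = c(0, 6000), re = c(4000, 10000),
                   qs = c(0, 6000), qe = c(4000, 10000), id = "c0001",
                   score = 8000)
  inv <- toy_chain(rs = 4000, re = 6000, qs = 4000, qe = 6000,
                   strand = "-", id = "c0002", score = 2000)
  syn <- toy_chain(rs = 4000, re = 6000, qs = 4100, qe = 6100,
                   id = "c0003", score = 1500)
  tra <- toy_chain(rs = 4000, re = 6000, qs = 0, qe = 2000, qry = "q2",
                   id = "c0004", score = 1200)
  far <- toy_chain(rs = 4000, re = 6000, qs = 8e6, qe = 8e6 + 2000,
                   id = "c0005", score = 1100)
  for (case in list(c("c0002", "inv"), c("c0003", "syn"),
                    c("c0004", "tra"), c("c0005", "tra"))) {
    net <- classify_fills(net_chains(list(top, get(
      c(c0002 = "inv", c0003 = "syn", c0004 = "tra", c0005 = "far")[case[1]]))))
    expect_equal(net$fills$type[net$fills$level == 2L], case[2],
                 label = case[1])
  }
})

test_that("filter_synnet applies the retention policy", {
  top <- toy_chain(rs = c(0, 6000), re = c(4000, 10000),
                   qs = c(0, 6000), qe = c(4000, 10000), id = "c0001",
                   score = 8000)
  inv_big <- toy_chain(rs = 4100, re = 5900, qs = 4100, qe = 5900,
                       strand = "-", id = "c0002", score = 1800)
  net <- classify_fills(net_chains(list(top, inv_big)))
  kept <- filter_synnet(net, "top_plus_rearrangement")
  expect_true("inv" %in% kept$fills$type)   # covers 90% of the gap
  only <- filter_synnet(net, "top_only")
  expect_false("inv" %in% only$fills$type)
  expect_error(filter_synnet(net, "bogus"), "config error")
  empty <- net_chains(list())
  expect_equal(nrow(filter_synnet(classify_fills(empty),
                                  "top_only")$fills), 0L)
})

test_that("syn children are kept under either policy", {
  top <- toy_chain(rs = c(0, 6000), re = c(4000, 10000),
                   qs = c(0, 6000), qe = c(4000, 10000), id = "c0001",
                   score = 8000)
  syn_small <- toy_chain(rs = 4000, re = 4200, qs = 4000, qe = 4200,
                         id = "c0002", score = 200)  # 10% of the gap
  net <- classify_fills(net_chains(list(top, syn_small)))
  for (pol in c("top_only", "top_plus_rearrangement"))
    expect_true("syn" %in% filter_synnet(net, pol)$fills$type, label = pol)
})

test_that("single-coverage projection trims query-side double coverage", {
  ## two fills claiming overlapping query bases: loser trimmed by overlap
  a <- toy_chain(rs = 0, re = 1000, qs = 0, qe = 1000, id = "c0001",
                 score = 1000)
  b <- toy_chain(rs = 5000, re = 6000, qs = 900, qe = 1900, id = "c0002",
                 score = 900)
  net <- classify_fills(net_chains(list(a, b)))
  seg <- project_single_coverage(net)
  expect_equal(sum(seg$ref_end - seg$ref_start), 1900)  # 100 bp trimmed
  loser <- seg[seg$chain == "c0002", ]
  expect_equal(loser$query_start, 1000)
  for (side in c("ref", "query"))
    expect_true(all(unlist(brute_coverage(seg, side)) <= 1L), label = side)
})

test_that("per-base coverage never exceeds one on either genome", {
  fx <- random_block_fixture(50, seed = 21)
  ## make blocks gapless so coordinates stay diagonal
  w <- pmin(fx$blocks$ref_end - fx$blocks$ref_start,
            fx$blocks$query_end - fx$blocks$query_start)
  b <- fx$blocks
  b$ref_end <- b$ref_start + w
  b$query_end <- b$query_start + w
  b$cigar <- paste0(w, "M")
  net <- filter_synnet(classify_fills(net_chains(chain_blocks(b))),
                       "top_plus_rearrangement")
  seg <- project_single_coverage(net)
  for (side in c("ref", "query"))
    expect_true(all(unlist(brute_coverage(seg, side)) <= 1L), label = side)
})

test_that("nets serialize as nested fill text and as JSON", {
  top <- toy_chain(rs = c(0, 6000), re = c(4000, 10000),
                   qs = c(0, 6000), qe = c(4000, 10000), id = "c0001",
                   score = 8000)
  child <- toy_chain(rs = 4000, re = 6000, qs = 4100, qe = 6100,
                     id = "c0002", score = 1500)
  net <- classify_fills(net_chains(list(top, child)))
  txt <- withr::local_tempfile(fileext = ".net")
  write_net(net, txt, "net")
  lines <- readLines(txt)
  expect_equal(sum(grepl("^net ", lines)), 1L)
  expect_equal(sum(grepl("fill", lines)), 2L)
  ## the child fill line is indented one level deeper
  expect_true(grepl("^  fill", lines[grepl("class=syn", lines)]))
  js <- withr::local_tempfile(fileext = ".json")
  write_net(net, js, "json")
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(back), 2L)
  expect_equal(back$level, net$fills$level)
})

test_that("an indel-only truth alignment nets as one top fill per chromosome", {
  gen <- make_genome(n_chrom = 2, chrom_length = 5e4, seed = 5)
  div <- simulate_divergence(gen$genome, sub_rate = 0, indel_rate = 0.001,
                             seed = 6)
  blocks <- edits_to_alignment(gen$genome, div$edits)
  ch <- chain_blocks(blocks)
  expect_length(ch, 2L)
  net <- net_chains(ch)
  expect_equal(nrow(net$fills), 2L)
  expect_true(all(net$fills$level == 1L))
  ## single coverage output equals the truth blocks
  seg <- project_single_coverage(net)
  expect_equal(sum(seg$ref_end - seg$ref_start),
               sum(blocks$ref_end - blocks$ref_start))
})
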