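test_that("pieces anchor to their truth loci on either strand", {
  sim <- tiny_sim()
  cl <- sim$clones[c(2, 10, 25), ]
  pieces <- stats::setNames(vapply(seq_len(nrow(cl)), function(i)
    substr(sim$genome$chromosomes[[cl$chrom[i]]], cl$start[i] + 1, cl$end[i]),
    character(1)), cl$clone_id)
  anc <- anchor_pieces(pieces, sim$genome)
  expect_setequal(anc$anchored$seq_id, cl$clone_id)
  got <- anc$anchored[match(cl$clone_id, anc$anchored$seq_id), ]
  expect_equal(got$anchor_start, cl$start)
  expect_true(all(got$orientation == "+"))

  # reverse-complemented input: orientation flips, anchor unchanged
  rc_pieces <- stats::setNames(revcomp(pieces[1]), names(pieces)[1])
  anc2 <- anchor_pieces(rc_pieces, sim$genome)
  expect_equal(anc2$anchored$orientation, "-")
  expect_equal(anc2$anchored$anchor_start, cl$start[1])

  # unmappable sequence lands in the unanchored list
  anc3 <- anchor_pieces(c(junk = random_seq(5000, seed = 71)), sim$genome)
  expect_equal(anc3$unanchored, "junk")
})

test_that("neighbor merging enforces the span and identity thresholds", {
  params <- gpm_params()
  left <- random_seq(8000, seed = 61)
  right_tail <- random_seq(6500, seed = 62)

  # b begins with the exact last 1500 bp of a: merged, conservation holds
  b1 <- paste0(substr(left, 6501, 8000), right_tail)
  m1 <- merge_neighbors(list(seq_id = "a", sequence = left),
                        list(seq_id = "b", sequence = b1), params)
  expect_equal(m1$type, "merged")
  expect_equal(nchar(m1$piece$sequence), 8000 + nchar(b1) - 1500)
  expect_identical(m1$piece$sequence, paste0(left, right_tail))

  # 800 bp exact overlap: below minOverlapSeqToSeq -> gap
  b2 <- paste0(substr(left, 7201, 8000), right_tail)
  expect_equal(merge_neighbors(list(seq_id = "a", sequence = left),
                               list(seq_id = "b", sequence = b2), params)$type,
               "gap")

  # 1200 bp overlap at 98% identity: below identitySeqToSeq -> gap
  ov <- substr(left, 6801, 8000)
  ov98 <- plant_subs(ov, seq(25, 1200, by = 50))  # 24 subs / 1200 = 2%
  b3 <- paste0(ov98, right_tail)
  expect_equal(merge_neighbors(list(seq_id = "a", sequence = left),
                               list(seq_id = "b", sequence = b3), params)$type,
               "gap")

  # 1200 bp at 99.5%: accepted
  ov995 <- plant_subs(ov, seq(100, 1200, by = 200))  # 6 subs / 1200 = 0.5%
  b4 <- paste0(ov995, right_tail)
  m4 <- merge_neighbors(list(seq_id = "a", sequence = left),
                        list(seq_id = "b", sequence = b4), params)
  expect_equal(m4$type, "merged")
  expect_gte(m4$identity, params$identity_seq)

  # piece contained in its neighbor is dropped as redundant
  inner <- substr(left, 3001, 7000)
  mc <- merge_neighbors(list(seq_id = "a", sequence = left),
                        list(seq_id = "b", sequence = inner), params)
  expect_equal(mc$type, "contained")
})

test_that("exactly one overlap copy is kept, clean copies preferred", {
  expect_identical(keep_one_copy("ACGTACGT", "ACGTACGT"), "ACGTACGT")
  expect_identical(keep_one_copy("ACNNACGT", "ACGTACGT"), "ACGTACGT")
  expect_identical(keep_one_copy("ACGTACGT", "ACNNACGT"), "ACGTACGT")
  expect_warning(out <- keep_one_copy("ANGT", "ACNT"), "both")
  expect_identical(out, "ANGT")
})

test_that("pseudomolecule folding merges what overlaps and records open gaps", {
  sim <- tiny_sim()
  truth <- sim$genome$chromosomes[[1]]
  # three tiled pieces with >= 1 kb overlaps, then one distant piece
  cuts <- list(c(1, 60000), c(55001, 120000), c(118001, 180000),
               c(250001, 310000))
  pieces <- stats::setNames(vapply(cuts, function(x)
    substr(truth, x[1], x[2]), character(1)),
    sprintf("p%d", seq_along(cuts)))
  anc <- anchor_pieces(pieces, sim$genome)
  ps <- build_pseudomolecules(anc, pieces)
  expect_length(ps, 1L)
  expect_equal(ps$chr01$contig_count, 2L)
  expect_equal(ps$chr01$gaps$status, "open")
  expect_identical(ps$chr01$runs[[1]]$sequence, substr(truth, 1, 180000))
  # determinism: identical input, byte-identical output
  ps2 <- build_pseudomolecules(anchor_pieces(pieces, sim$genome), pieces)
  expect_identical(pseudo_sequence(ps$chr01), pseudo_sequence(ps2$chr01))
  # open gaps appear as 100-N runs in the exported sequence
  expect_match(pseudo_sequence(ps$chr01), strrep("N", 100), fixed = TRUE)
})

test_that("gap filling requires a fully connecting bridge and closes the contig count", {
  sim <- tiny_sim()
  truth <- sim$genome$chromosomes[[1]]
  pieces <- stats::setNames(
    c(substr(truth, 1, 80000), substr(truth, 120001, 200000)),
    c("L", "R"))
  anc <- anchor_pieces(pieces, sim$genome)
  ps <- build_pseudomolecules(anc, pieces)
  expect_equal(ps$chr01$contig_count, 2L)

  # a contig overlapping only the left flank leaves the gap open
  half_bridge <- substr(truth, 75001, 110000)
  res_half <- fill_gaps(ps, c(hb = half_bridge), extend_ends = FALSE)
  expect_equal(res_half$pseudos$chr01$contig_count, 2L)
  expect_equal(res_half$gap_report$status, "open")

  # a spanning bridge fills the gap, reducing the contig count by one,
  # and restores the truth sequence across both junctions
  bridge <- substr(truth, 75001, 125000)
  res <- fill_gaps(ps, c(hb = half_bridge, br = bridge), extend_ends = FALSE)
  expect_equal(res$pseudos$chr01$contig_count, 1L)
  expect_equal(res$gap_report$status, "filled")
  expect_equal(res$gap_report$filler_seq_id, "br")
  expect_identical(res$pseudos$chr01$runs[[1]]$sequence, substr(truth, 1, 200000))
})

test_that("end extension grows a pseudomolecule outward from terminal overlaps", {
  sim <- tiny_sim()
  truth <- sim$genome$chromosomes[[1]]
  pieces <- c(mid = substr(truth, 50001, 150000))
  anc <- anchor_pieces(pieces, sim$genome)
  ps <- build_pseudomolecules(anc, pieces)
  ext <- fill_gaps(ps, c(head = substr(truth, 1, 55000),
                         tail = substr(truth, 145001, 200000)))
  expect_identical(ext$pseudos$chr01$runs[[1]]$sequence, substr(truth, 1, 200000))
  expect_setequal(ext$gap_report$status, "end_extended")
})

test_that("repeat-confused pieces are placed by the physical-map order", {
  # plant a 2-copy repeat, build a piece lying inside one copy
  g <- make_genome(1, 200000, 0, seed = 81)
  s <- g$chromosomes[[1]]
  block <- substr(s, 40001, 48000)
  s <- paste0(substr(s, 1, 139999), block, substr(s, 148000, 200000))
  g$chromosomes[[1]] <- substr(s, 1, 200000)
  piece <- substr(g$chromosomes[[1]], 40001, 48000)
  flank_l <- substr(g$chromosomes[[1]], 20001, 42000)
  flank_r <- substr(g$chromosomes[[1]], 46001, 70000)
  pieces <- c(a = flank_l, b = piece, c = flank_r)
  pm_order <- data.frame(seq_id = c("a", "b", "c"), contig_id = "ctg",
                         rank = 1:3)
  anc <- anchor_pieces(pieces, g, pm_order = pm_order)
  got <- anc$anchored[anc$anchored$seq_id == "b", ]
  expect_true(got$flagged)
  # placed between its map neighbors (first repeat copy), not at the
  # distant second copy near 140 kb
  expect_gte(got$anchor_start, 20000)
  expect_lte(got$anchor_start, 46000)
})
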