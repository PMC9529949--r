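mkEnh <- function(start0, end0, id = "e1", chrom = "chr1", resource = "r") {
  gr0(chrom, start0, end0, enhancer_id = id, resource = resource)
}

test_that("eRNA regions are centred on the floored midpoint and clamped at 0", {
  r <- ernaRegions(mkEnh(10000L, 11000L), halfWidth = 3000L)
  expect_equal(r$midpoint, 10500L)
  expect_equal(GenomicRanges::start(r) - 1L, 7500L)   # 0-based start
  expect_equal(GenomicRanges::end(r), 13500L)         # 0-based end
  # clamped at the chromosome start
  r2 <- ernaRegions(mkEnh(100L, 200L), halfWidth = 3000L)
  expect_equal(r2$midpoint, 150L)
  expect_equal(GenomicRanges::start(r2) - 1L, 0L)
  expect_equal(GenomicRanges::end(r2), 3150L)
  # odd span: floor midpoint
  r3 <- ernaRegions(mkEnh(0L, 5L), halfWidth = 3000L)
  expect_equal(r3$midpoint, 2L)
  expect_equal(GenomicRanges::start(r3) - 1L, 0L)
  expect_equal(GenomicRanges::end(r3), 3002L)
  expect_error(ernaRegions(mkEnh(0L, 5L), halfWidth = 0L), "halfWidth")
})

test_that("gene-overlap filter removes >=1 bp overlaps, keeps adjacency", {
  region <- ernaRegions(mkEnh(10000L, 11000L))  # [7500, 13500)
  gOverlap <- gr0("chr1", 13499L, 20000L, gene_id = "g1", gene_name = "g1",
                  biotype = "protein_coding")
  gAdjacent <- gr0("chr1", 13500L, 20000L, gene_id = "g1", gene_name = "g1",
                   biotype = "protein_coding")
  expect_length(suppressMessages(filterGeneOverlapping(region, gOverlap)), 0L)
  expect_length(suppressMessages(filterGeneOverlapping(region, gAdjacent)), 1L)
  expect_error(filterGeneOverlapping(region, gOverlap[0]), "empty")
})

test_that("contact-domain assignment respects the half-open window boundary", {
  region <- ernaRegions(mkEnh(10000L, 11000L))  # midpoint 10500
  # window is [0, 103000): a gene starting at 0-based 102999 is in,
  # one starting at 103000 is out
  gIn <- gr0("chr1", 102999L, 110000L, gene_id = "in", gene_name = "in",
             biotype = "lncRNA")
  gOut <- gr0("chr1", 103000L, 110000L, gene_id = "out", gene_name = "out",
              biotype = "lncRNA")
  expect_equal(assignErrgs(region, gIn, 185000L)$gene_id, "in")
  expect_equal(nrow(assignErrgs(region, gOut, 185000L)), 0L)
  # a gene fully containing the window is assigned (overlap is symmetric)
  gBig <- gr0("chr1", 0L, 500000L, gene_id = "big", gene_name = "big",
              biotype = "protein_coding")
  expect_equal(assignErrgs(region, gBig, 185000L)$gene_id, "big")
  expect_error(assignErrgs(region, gIn, 0L), "domainLength")
})

test_that("resource intersection behaves as a set intersection", {
  per <- list(r1 = c("A", "B", "C"), r2 = c("A", "B"),
              r3 = c("A", "B", "D"), r4 = c("A", "B"))
  expect_equal(intersectResources(per)$final, c("A", "B"))
  per$r2 <- character()
  expect_equal(intersectResources(per)$final, character())  # absorbing
  expect_equal(intersectResources(list(r1 = c("B", "A")))$final, c("A", "B"))
})

test_that("identifyErrgs equals the all-pairs brute force on random instances", {
  set.seed(7)
  for (rep in 1:5) {
    inst <- random_instance(nEnh = 300L, nGenes = 120L, nResources = 3L)
    want <- orc_identify(inst$enhancers, inst$genes)
    enhGr <- lapply(names(inst$enhancers), function(r)
      enh_df_to_gr(inst$enhancers[[r]], r))
    names(enhGr) <- names(inst$enhancers)
    asn <- suppressWarnings(identifyErrgs(enhGr, genes_df_to_gr(inst$genes)))
    expect_identical(errgPerResource(asn), want$perResource)
    expect_identical(errgFinal(asn), want$final)
    expect_identical(pairs_key(asn), want$pairs)
  }
})

test_that("final eRRG set shrinks with resources and grows with domain length", {
  set.seed(8)
  inst <- random_instance(nEnh = 400L, nGenes = 150L, nResources = 4L)
  enhGr <- lapply(names(inst$enhancers), function(r)
    enh_df_to_gr(inst$enhancers[[r]], r))
  names(enhGr) <- names(inst$enhancers)
  genes <- genes_df_to_gr(inst$genes)
  prev <- NULL
  for (k in 1:4) {
    asn <- suppressWarnings(identifyErrgs(enhGr[seq_len(k)], genes))
    if (!is.null(prev)) expect_true(all(errgFinal(asn) %in% prev))
    prev <- errgFinal(asn)
  }
  small <- suppressWarnings(identifyErrgs(enhGr, genes, domainLength = 50000L))
  large <- suppressWarnings(identifyErrgs(enhGr, genes, domainLength = 250000L))
  expect_true(all(errgFinal(small) %in% errgFinal(large)))
})

test_that("removing a gene never adds pairs but can rescue filtered regions", {
  # gene gBlock overlaps the eRNA region; gene gFar sits in the domain window
  enh <- mkEnh(100000L, 101000L)              # midpoint 100500, region [97500, 103500)
  gBlock <- gr0("chr1", 103000L, 104000L, gene_id = "gBlock",
                gene_name = "gBlock", biotype = "protein_coding")
  gFar <- gr0("chr1", 150000L, 151000L, gene_id = "gFar",
              gene_name = "gFar", biotype = "protein_coding")
  both <- suppressWarnings(identifyErrgs(list(r = enh), c(gBlock, gFar)))
  expect_length(errgFinal(both), 0L)          # region filtered by gBlock
  without <- suppressWarnings(identifyErrgs(list(r = enh), gFar))
  expect_equal(errgFinal(without), "gFar")    # region rescued
  # every pair present with the full annotation persists in the subset run
  expect_true(all(pairs_key(both) %in% pairs_key(without)))
})

test_that("identifyErrgs over disjoint per-resource targets yields an empty final set", {
  gA <- gr0("chr1", 150000L, 151000L, gene_id = "gA", gene_name = "gA",
            biotype = "protein_coding")
  gB <- gr0("chr2", 150000L, 151000L, gene_id = "gB", gene_name = "gB",
            biotype = "lncRNA")
  enh1 <- mkEnh(100000L, 101000L, id = "a", chrom = "chr1", resource = "r1")
  enh2 <- mkEnh(100000L, 101000L, id = "b", chrom = "chr2", resource = "r2")
  genes <- suppressWarnings(c(gA, gB))  # disjoint seqlevels are intended here
  asn <- identifyErrgs(list(r1 = enh1, r2 = enh2), genes)
  expect_equal(errgPerResource(asn), list(r1 = "gA", r2 = "gB"))
  expect_length(errgFinal(asn), 0L)
})

test_that("ErrgAssignment validity rejects inconsistent final sets", {
  asn <- identifyErrgs(list(r = mkEnh(100000L, 101000L)),
                       gr0("chr1", 150000L, 151000L, gene_id = "g",
                           gene_name = "g", biotype = "other"))
  bad <- asn
  bad@final <- c("g", "not_there")
  expect_error(methods::validObject(bad), "intersection")
})
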