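mkGroups <- function(nHigh, nLow, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(nHigh + nLow))
  setNames(rep(c("high", "low"), c(nHigh, nLow)), samples)
}

test_that("DMP calling applies the strict effect-size cutoff", {
  set.seed(1)
  n <- 12
  g <- mkGroups(n, n)
  pass <- c(rnorm(n, 0.80, 0.01), rnorm(n, 0.60, 0.01))
  fail <- c(rnorm(n, 0.70, 0.01), rnorm(n, 0.60, 0.01))
  beta <- rbind(pass = pass, fail = fail)
  beta[beta < 0] <- 0; beta[beta > 1] <- 1
  colnames(beta) <- names(g)
  r <- callDmps(beta, g)
  tab <- r$table
  expect_equal(tab$call[tab$probe_id == "pass"], "hyper")   # dbeta ~ 0.20
  expect_equal(tab$call[tab$probe_id == "fail"], "ns")      # dbeta ~ 0.10, strict > 0.15
  expect_equal(r$nHyper + r$nHypo + sum(tab$call == "ns"), nrow(beta))
  expect_error(callDmps(beta - 2, g), "\\[0, 1\\]")
})

test_that("probe-level Welch t matches t.test and probes map to genes", {
  set.seed(2)
  g <- mkGroups(8, 10)
  beta <- matrix(runif(40 * 18, 0.2, 0.8), nrow = 40,
                 dimnames = list(sprintf("cg%02d", 1:40), names(g)))
  r <- callDmps(beta, g)
  for (i in c(1, 7, 23)) {
    ref <- stats::t.test(beta[i, 1:8], beta[i, 9:18])
    expect_equal(r$table$pvalue[i], ref$p.value, tolerance = 1e-10)
  }
  # gene mapping collects genes behind called probes
  planted <- rbind(hypo1 = c(rep(0.30, 8), rep(0.70, 10)),
                   hyper1 = c(rep(0.80, 8), rep(0.40, 10)))
  planted <- planted + matrix(rnorm(2 * 18, 0, 0.01), nrow = 2)
  colnames(planted) <- names(g)
  pm <- data.frame(probe_id = c("hypo1", "hyper1"), chrom = "chr1",
                   position = c(1L, 2L), gene_id = c("GX", "GY"))
  r2 <- callDmps(rbind(beta, planted), g, probeMap = pm)
  expect_equal(r2$hypoGenes, "GX")
  expect_equal(r2$hyperGenes, "GY")
})

test_that("DMP recovery: planted effects found, permuted labels near-silent", {
  set.seed(3)
  g <- mkGroups(25, 25)
  nNull <- 300; nPlant <- 40
  base <- runif(nNull + nPlant, 0.35, 0.62)
  mean <- matrix(base, nrow = nNull + nPlant, ncol = 50)
  mean[nNull + seq_len(nPlant), 1:25] <- mean[nNull + seq_len(nPlant), 1:25] + 0.3
  beta <- matrix(pmin(1, pmax(0, rnorm(length(mean), mean, 0.05))),
                 nrow = nrow(mean),
                 dimnames = list(sprintf("cg%03d", seq_len(nrow(mean))), names(g)))
  r <- callDmps(beta, g)
  called <- r$table$call != "ns"
  expect_gte(mean(called[nNull + seq_len(nPlant)]), 0.95)   # sensitivity
  expect_lte(mean(called[seq_len(nNull)]), 0.05)            # false-call rate
  # permuting labels removes the signal
  gPerm <- setNames(sample(g), names(g))
  rPerm <- callDmps(beta, gPerm)
  expect_lte(mean(rPerm$table$call != "ns"), 0.05)
})

test_that("SNV classes collapse purine references to the pyrimidine strand", {
  expect_equal(snvClass("G", "A"), "C>T")
  expect_equal(snvClass("C", "T"), "C>T")
  expect_equal(snvClass("A", "C"), "T>G")
  expect_equal(snvClass("G", "T"), "C>A")
  expect_equal(snvClass(c("T", "A"), c("C", "G")), c("T>C", "T>C"))
  expect_true(is.na(snvClass("AC", "-")))
  expect_true(is.na(snvClass("C", "C")))
})

test_that("mutation matrix binarizes, filters silent records and counts classes", {
  rec <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2"),
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    chrom = "chr1", position = 1:5,
    ref = c("G", "C", "C", "-", "T"),
    alt = c("A", "A", "T", "AC", "G"),
    variant_class = c("Missense_Mutation", "Missense_Mutation", "Silent",
                      "Frame_Shift_Ins", "Missense_Mutation"),
    variant_type = c("SNP", "SNP", "SNP", "INS", "SNP"),
    vaf = c(0.2, 0.4, 0.3, 0.5, 0.6),
    stringsAsFactors = FALSE
  )
  mm <- mutationMatrix(rec, samples = c("s1", "s2", "s3"))
  expect_equal(mm$matrix["gA", "s1"], 1L)  # two records, still 1
  expect_equal(mm$matrix["gB", "s1"], 0L)  # silent-only does not qualify
  expect_equal(unname(mm$matrix[, "s3"]), c(0L, 0L, 0L))
  mmS <- mutationMatrix(rec, samples = c("s1", "s2", "s3"), includeSilent = TRUE)
  expect_equal(mmS$matrix["gB", "s1"], 1L)
  expect_equal(mm$snvClassCounts["s1", "C>T"], 2L)  # G>A collapsed + C>T silent
  expect_equal(mm$typeCounts["s2", "INS"], 1L)
  expect_equal(unname(mm$vafMedian["s1"]), 0.3)
  # invariant to record order and duplication
  mm2 <- mutationMatrix(rec[c(5, 3, 1, 2, 4, 1), ], samples = c("s1", "s2", "s3"))
  expect_identical(mm2$matrix, mm$matrix)
  expect_error(mutationMatrix(rec, samples = "s1"), "outside the sample list")
  rec$variant_class[1] <- "Weird_Class"
  expect_warning(mutationMatrix(rec, samples = c("s1", "s2", "s3")), "unknown")
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  expect_equal(fisherExact(rbind(c(3, 1), c(1, 3)))$p.value, 34 / 70)
  expect_equal(fisherExact(rbind(c(0, 5), c(5, 0)))$p.value, 2 / 252)
  expect_equal(fisherExact(rbind(c(2, 2), c(2, 2)))$p.value, 1)
  expect_equal(fisherExact(rbind(c(5, 0), c(0, 15)))$odds.ratio, Inf)
  expect_error(fisherExact(rbind(c(-1, 2), c(3, 4))), "non-negative")
  # random tables against both the enumeration oracle and fisher.test
  set.seed(4)
  for (i in 1:40) {
    tb <- matrix(sample(0:12, 4, replace = TRUE), 2)
    got <- fisherExact(tb)$p.value
    expect_equal(got, orc_fisher(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]))
    expect_equal(got, stats::fisher.test(tb)$p.value, tolerance = 1e-10)
  }
})

test_that("differential mutation tests genes above the floor with raw p", {
  g <- mkGroups(10, 10)
  mat <- matrix(0L, nrow = 3, ncol = 20,
                dimnames = list(c("allHigh", "rare", "balanced"), names(g)))
  mat["allHigh", 1:10] <- 1L                # 10/10 high, 0/10 low
  mat["rare", 1:2] <- 1L                    # below min_mutated
  mat["balanced", c(1:5, 11:15)] <- 1L      # identical in both groups
  dm <- differentialMutation(mat, g, minMutated = 5L)
  expect_setequal(dm$gene_id, c("allHigh", "balanced"))
  expect_equal(dm$pvalue[dm$gene_id == "allHigh"], 2 / choose(20, 10))
  expect_equal(dm$pvalue[dm$gene_id == "balanced"], 1)
  expect_true(dm$call[dm$gene_id == "allHigh"])
})

test_that("burden contrasts compare per-sample counts between risk groups", {
  set.seed(5)
  g <- mkGroups(15, 15)
  rec <- do.call(rbind, lapply(names(g), function(s) {
    n <- if (g[[s]] == "high") 8L else 2L
    data.frame(sample = s, gene_id = sprintf("g%d", seq_len(n)),
               chrom = "chr1", position = seq_len(n),
               ref = "C", alt = "T", variant_class = "Missense_Mutation",
               variant_type = "SNP", vaf = runif(n, 0.1, 0.6),
               stringsAsFactors = FALSE)
  }))
  mm <- mutationMatrix(rec, samples = names(g))
  bc <- mutationBurdenContrast(mm, g)
  missense <- bc[bc$metric == "class:Missense_Mutation", ]
  expect_equal(missense$medianHigh, 8)
  expect_equal(missense$medianLow, 2)
  expect_lt(missense$pvalue, 0.001)
})

test_that("co-occurrence labels pairs by odds-ratio direction", {
  samples <- sprintf("s%02d", 1:20)
  mat <- matrix(0L, 3, 20, dimnames = list(c("gi", "gj", "gk"), samples))
  mat["gi", 1:5] <- 1L
  mat["gj", 1:5] <- 1L        # identical to gi
  mat["gk", 6:10] <- 1L       # disjoint from gi
  co <- cooccurrence(mat, topK = 3)
  ij <- co[co$gene_i == "gi" & co$gene_j == "gj", ]
  expect_equal(ij$label, "co-occurring")
  expect_equal(ij$odds.ratio, Inf)
  expect_equal(ij$pvalue, fisherExact(rbind(c(5, 0), c(0, 15)))$p.value)
  ik <- co[co$gene_i == "gi" & co$gene_j == "gk", ]
  expect_equal(ik$label, "exclusive")
  expect_equal(ik$odds.ratio, 0)
  expect_error(cooccurrence(mat, topK = 1), ">= 2")
})

test_that("co-occurrence on independent mutations controls false positives", {
  set.seed(6)
  nPairHits <- 0L; nPairs <- 0L
  for (s in 1:5) {
    mat <- matrix(rbinom(12 * 120, 1, 0.3), nrow = 12,
                  dimnames = list(sprintf("g%02d", 1:12), sprintf("s%03d", 1:120)))
    co <- cooccurrence(mat, topK = 12)
    nPairHits <- nPairHits + sum(co$pvalue < 0.05)
    nPairs <- nPairs + nrow(co)
  }
  frac <- nPairHits / nPairs
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nPairs))
})
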