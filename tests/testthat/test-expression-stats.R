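test_that("unexpressed genes are dropped, unknown ids warned about", {
  m <- rbind(allZero = c(0, 0, 0), oneHit = c(0, 3, 0), expr = c(5, 2, 9))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(filterUnexpressed(m), c("oneHit", "expr"))
  expect_warning(kept <- filterUnexpressed(m, c("expr", "ghost")), "absent")
  expect_equal(kept, "expr")
  expect_warning(filterUnexpressed(m, "allZero"), "no genes")
})

test_that("per-gene mean and CV match hand values and flag zero means", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0, 0))
  colnames(m) <- paste0("s", 1:3)
  s <- perGeneSummary(m)
  expect_equal(s$mean, c(4, 5, 0))
  expect_equal(s$cv[1], 50)     # sd = 2, mean = 4
  expect_equal(s$cv[2], 0)
  expect_true(is.na(s$cv[3]) && !s$cv_defined[3])
  expect_error(perGeneSummary(m[, 1, drop = FALSE]), "2 samples")
})

test_that("Wilcoxon rank-sum: exact small-sample path matches enumeration", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 1 / 3)  # 2 * P(W <= 3) = 2/6
  expect_equal(r$statistic, 3)
  expect_equal(r$method, "exact")
  # identical samples (ties -> corrected normal path) give p = 1
  same <- wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  # all no-tie partitions up to pooled n = 7 equal full enumeration
  for (n in 2:7) {
    for (nx in 1:(n - 1)) {
      subsets <- utils::combn(n, nx)
      for (j in seq_len(ncol(subsets))) {
        x <- subsets[, j]
        y <- setdiff(seq_len(n), x)
        expect_equal(wilcoxonRankSum(x, y)$p.value, orc_wilcox(x, y))
      }
    }
  }
})

test_that("Wilcoxon normal approximation agrees with the standard corrected test", {
  set.seed(5)
  for (i in 1:25) {
    x <- sample(0:20, 15, replace = TRUE)   # plenty of ties
    y <- sample(0:20, 18, replace = TRUE) + sample(0:2, 18, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(wilcoxonRankSum(x, y)$p.value, ref$p.value, tolerance = 1e-12)
  }
  # large planted shift is overwhelmingly significant
  set.seed(6)
  big <- wilcoxonRankSum(rnorm(60, 2), rnorm(60, 0))
  expect_lt(big$p.value, 0.001)
  expect_error(wilcoxonRankSum(numeric(), 1), "non-empty")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    q <- bhAdjust(p)
    expect_equal(q, orc_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone on sorted p
  }
})

test_that("random-set comparison is seeded, degenerate-safe and detects planted signal", {
  set.seed(2)
  m <- matrix(rnbinom(60 * 30, mu = 10, size = 5), nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:30)))
  r1 <- compareToRandomSets(m, rownames(m)[1:20], nSets = 20, seed = 9)
  r2 <- compareToRandomSets(m, rownames(m)[1:20], nSets = 20, seed = 9)
  expect_identical(r1, r2)
  # errgSet == universe: every draw is the whole set, p = 1
  deg <- compareToRandomSets(m, rownames(m), nSets = 5, seed = 1)
  expect_equal(deg$pMean, 1)
  expect_equal(deg$errgMean, deg$randomMean)
  expect_error(compareToRandomSets(m, rownames(m), universe = rownames(m)[1:10]),
               "smaller")
})

test_that("planted high-expression genes beat random sets across seeds", {
  set.seed(3)
  mu <- c(rep(80, 25), rep(10, 75))
  hits <- 0L
  for (s in 1:100) {
    m <- matrix(rnbinom(100 * 25, mu = rep(mu, 25), size = 5), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:25)))
    r <- compareToRandomSets(m, rownames(m)[1:25], nSets = 30, seed = s)
    if (r$errgMean > r$randomMean && r$pMean < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("DE statistics: null genes and exact fold-change limits", {
  # identical values in both groups -> log2fc 0, p 1
  m <- rbind(flat = rep(7, 8), filler = rep(13, 8))
  colnames(m) <- paste0("s", 1:8)
  g <- setNames(rep(c("tumor", "normal"), each = 4), colnames(m))
  de <- deStats(m, g)
  expect_equal(de$log2fc[de$gene_id == "flat"], 0)
  expect_equal(de$pvalue[de$gene_id == "flat"], 1)
  # tumor CPM exactly twice normal CPM -> log2fc -> 1 as pc -> 0
  m2 <- rbind(target = c(200, 200, 200, 100, 100, 100),
              rest = c(800, 800, 800, 900, 900, 900))
  colnames(m2) <- paste0("s", 1:6)
  g2 <- setNames(rep(c("tumor", "normal"), each = 3), colnames(m2))
  de2 <- deStats(m2, g2, pseudocount = 1e-9)
  expect_equal(de2$log2fc[de2$gene_id == "target"], 1, tolerance = 1e-6)
  expect_error(deStats(m2, g2[-1]), "without a group")
})

test_that("DE thresholds are strict and partition the table", {
  de <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(1.5, -2, 0.5, 3, 1.0),
    fdr = c(0.01, 0.04, 0.001, 0.2, 0.01)
  )
  r <- applyDeThresholds(de)
  expect_equal(r$table$call, c("up", "down", "ns", "ns", "ns"))
  expect_equal(r$nUp + r$nDown + sum(r$table$call == "ns"), nrow(de))
  empty <- applyDeThresholds(de[0, ])
  expect_equal(c(empty$nUp, empty$nDown), c(0L, 0L))
})

test_that("DE-count resampling matches the hypergeometric expectation", {
  calls <- list(up = sprintf("g%02d", 1:4), down = character())
  universe <- sprintf("g%02d", 1:10)
  r <- resampleDeCounts(calls, universe, setSize = 5, nReps = 2000, seed = 4)
  expectUp <- 5 * 4 / 10
  se <- sqrt(5 * (4 / 10) * (6 / 10) * (10 - 5) / (10 - 1) / 2000)
  expect_lt(abs(r$meanUp - expectUp), 3 * se)
  # drawing the whole universe is deterministic
  full <- resampleDeCounts(calls, universe, setSize = 10, nReps = 50, seed = 1)
  expect_equal(full$meanUp, 4)
  expect_equal(var(full$upCounts), 0)
  expect_identical(resampleDeCounts(calls, universe, 5, 100, seed = 8),
                   resampleDeCounts(calls, universe, 5, 100, seed = 8))
  expect_error(resampleDeCounts(calls, universe, 11), "exceeds")
})

test_that("built-in DE test holds its nominal type-I error under the null", {
  set.seed(21)
  n <- 400
  m <- matrix(rnbinom(n * 50, mu = 50, size = 5), nrow = n,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:50)))
  g <- setNames(rep(c("tumor", "normal"), each = 25), colnames(m))
  de <- deStats(m, g)
  frac <- mean(de$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(frac, 0.05 + 3 * se)
  expect_gt(frac, 0.05 - 3 * se - 0.02)  # mild discreteness slack
})
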