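# Expression characterization of eRRGs: mean/CV contrasts against random
# gene sets, a built-in rank-based DE stage, thresholding, and the
# random-gene resampling null for DE counts.

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated, first column gene ids, remaining columns one per
#' sample; values must be non-negative. Duplicated gene or sample ids
#' are an error.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene ids as row names.
#' @export
readExpressionMatrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(ids)) .stopf("duplicate gene ids in %s", path)
  if (anyDuplicated(colnames(m))) .stopf("duplicate sample ids in %s", path)
  if (anyNA(m) || any(m < 0)) .stopf("expression values must be non-negative and complete")
  rownames(m) <- ids
  m
}

#' Read sample group labels
#'
#' Tab-separated two-column table `sample`, `group`.
#'
#' @param path path to the TSV file.
#' @return named character vector of group labels, names are sample ids.
#' @export
readSampleGroups <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("sample", "group") %in% colnames(tab))) {
    .stopf("groups file %s needs columns 'sample' and 'group'", path)
  }
  if (anyDuplicated(tab$sample)) .stopf("duplicate sample ids in %s", path)
  setNames(tab$group, tab$sample)
}

#' Drop genes with no expression in any sample
#'
#' Retains the genes of `geneSet` with a value > 0 in at least one
#' sample of `mat`. Ids absent from the matrix are dropped with a
#' warning; an empty result is a warning, not an error.
#'
#' @param mat expression matrix (genes x samples).
#' @param geneSet character vector of gene ids (default: all rows).
#' @return character vector of retained gene ids, in `geneSet` order.
#' @export
filterUnexpressed <- function(mat, geneSet = rownames(mat)) {
  missing <- setdiff(geneSet, rownames(mat))
  if (length(missing)) {
    .warnf("%d gene ids absent from the matrix were dropped (e.g. %s)",
           length(missing), paste(head(missing, 3L), collapse = ", "))
    geneSet <- intersect(geneSet, rownames(mat))
  }
  expressed <- rownames(mat)[rowSums(mat > 0) > 0L]
  kept <- geneSet[geneSet %in% expressed]
  if (!length(kept)) .warnf("no genes with non-zero expression remain")
  kept
}

#' Per-gene mean and coefficient of variation
#'
#' The CV is reported in percent, `100 * sd / mean`, with the sample
#' (n-1) standard deviation; it is undefined (NA, flagged in
#' `cv_defined`) for genes with zero mean.
#'
#' @param mat expression matrix (genes x samples).
#' @param samples optional character vector of sample ids to restrict to.
#' @return `data.frame` with columns `gene_id`, `mean`, `cv`, `cv_defined`.
#' @export
perGeneSummary <- function(mat, samples = NULL) {
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(mat))
    if (length(missing)) .stopf("unknown samples: %s", paste(head(missing, 5L), collapse = ", "))
    mat <- mat[, samples, drop = FALSE]
  }
  if (ncol(mat) < 2L) .stopf("at least 2 samples are required for the CV")
  m <- rowMeans(mat)
  v <- (rowSums(mat^2) - ncol(mat) * m^2) / (ncol(mat) - 1L)
  v[v < 0] <- 0  # guard against negative rounding error
  cv <- ifelse(m > 0, 100 * sqrt(v) / m, NA_real_)
  data.frame(gene_id = rownames(mat), mean = m, cv = cv,
             cv_defined = m > 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Reports the rank-sum statistic of `x` (midranks under ties) and a
#' two-sided p-value. When the pooled size is at most 12 and there are
#' no ties, the p-value is exact (tail of the rank-sum permutation
#' distribution, equal to full enumeration of all rank assignments);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `statistic` (rank sum of `x`), `p.value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p.value  # exact, 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) .stopf("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) .stopf("missing values are not allowed")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n <= 12L) {
    U <- W - nx * (nx + 1) / 2
    p <- 2 * min(pwilcox(U, nx, ny), 1 - pwilcox(U - 1, nx, ny))
    p <- min(1, p)
    return(list(statistic = W, p.value = p, method = "exact"))
  }
  E <- nx * (n + 1) / 2
  tiesTab <- table(r)
  V <- nx * ny / 12 * ((n + 1) - sum(tiesTab^3 - tiesTab) / (n * (n - 1)))
  d <- W - E
  if (V <= 0) {
    p <- 1
  } else {
    z <- (d - sign(d) * 0.5) / sqrt(V)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = W, p.value = p, method = "normal")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with `p_(1) <= ... <= p_(n)`, the adjusted value
#' is `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of FDR-adjusted values.
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) .stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Compare eRRG expression to size-matched random gene sets
#'
#' Draws `nSets` random gene sets of the same size as the eRRG set from
#' `universe` (without replacement within each set, seeded), pools the
#' per-gene means and CVs of every drawn gene instance, and compares
#' them to the eRRG per-gene means and CVs with [wilcoxonRankSum()].
#'
#' @param mat expression matrix.
#' @param errgSet character vector of eRRG gene ids (must be rows of `mat`).
#' @param universe character vector of candidate gene ids
#'   (default: all rows); must be at least as large as `errgSet`.
#' @param nSets number of random sets (default 100).
#' @param seed integer seed; the same seed reproduces the report exactly.
#' @return list with `errgMean` (mean of per-gene means), `errgCv`
#'   (mean per-gene CV), `randomMean`, `randomCv`, `pMean`, `pCv`,
#'   `nSets`, `setSize`.
#' @export
compareToRandomSets <- function(mat, errgSet, universe = rownames(mat),
                                nSets = 100L, seed = NULL) {
  if (!all(errgSet %in% rownames(mat))) .stopf("errgSet contains ids absent from the matrix")
  if (!all(universe %in% rownames(mat))) .stopf("universe contains ids absent from the matrix")
  if (length(universe) < length(errgSet)) {
    .stopf("universe (%d) is smaller than the eRRG set (%d)",
           length(universe), length(errgSet))
  }
  summ <- perGeneSummary(mat)
  rownames(summ) <- summ$gene_id
  draws <- .withSeed(seed, {
    replicate(nSets, sample(universe, length(errgSet), replace = FALSE),
              simplify = FALSE)
  })
  pooled <- unlist(draws, use.names = FALSE)
  eMeans <- summ[errgSet, "mean"]
  rMeans <- summ[pooled, "mean"]
  eCv <- summ[errgSet, "cv"]
  rCv <- summ[pooled, "cv"]
  list(
    errgMean = mean(eMeans),
    errgCv = mean(eCv, na.rm = TRUE),
    randomMean = mean(rMeans),
    randomCv = mean(rCv, na.rm = TRUE),
    pMean = wilcoxonRankSum(eMeans, rMeans)$p.value,
    pCv = wilcoxonRankSum(eCv[!is.na(eCv)], rCv[!is.na(rCv)])$p.value,
    nSets = nSets,
    setSize = length(errgSet)
  )
}

#' Built-in per-gene differential-expression statistics
#'
#' A self-contained rank-based DE stage: per gene, a two-sided Wilcoxon
#' rank-sum test on `log2(CPM + pseudocount)` between the two groups,
#' with `log2fc = log2((mean tumor CPM + pc) / (mean normal CPM + pc))`
#' and BH-adjusted FDR. This is a deliberately simple substitute for a
#' negative-binomial GLM DE tool; externally computed DE tables with the
#' same columns can be supplied to downstream steps instead.
#'
#' @param mat raw count matrix (genes x samples).
#' @param groups named vector of group labels over the columns of `mat`;
#'   exactly two levels, the first level in `levels` is the "case"
#'   (numerator) group.
#' @param levels character(2): case level then reference level
#'   (default `c("tumor", "normal")`).
#' @param pseudocount added to CPM before log and to the fold-change
#'   means (default 0.5).
#' @return `data.frame` with columns `gene_id`, `log2fc`, `pvalue`, `fdr`.
#' @export
deStats <- function(mat, groups, levels = c("tumor", "normal"),
                    pseudocount = 0.5) {
  g <- .checkGroups2(groups, colnames(mat), levelsExpected = levels, minPer = 2L)
  libSize <- colSums(mat)
  if (any(libSize == 0)) .stopf("samples with zero total counts: %s",
                                paste(colnames(mat)[libSize == 0], collapse = ", "))
  cpm <- sweep(mat, 2L, libSize, "/") * 1e6
  logcpm <- log2(cpm + pseudocount)
  case <- g == levels[1L]
  ref <- g == levels[2L]
  pv <- vapply(seq_len(nrow(mat)), function(i) {
    wilcoxonRankSum(logcpm[i, case], logcpm[i, ref])$p.value
  }, numeric(1))
  l2fc <- log2((rowMeans(cpm[, case, drop = FALSE]) + pseudocount) /
               (rowMeans(cpm[, ref, drop = FALSE]) + pseudocount))
  data.frame(gene_id = rownames(mat), log2fc = l2fc, pvalue = pv,
             fdr = bhAdjust(pv), row.names = NULL, stringsAsFactors = FALSE)
}

#' Call up/down-regulated genes at fixed thresholds
#'
#' Strict inequalities: `up` requires `fdr < fdrCut` and
#' `log2fc > fcCut`; `down` requires `fdr < fdrCut` and
#' `log2fc < -fcCut`; everything else is `ns`.
#'
#' @param de `data.frame` with columns `gene_id`, `log2fc`, `fdr`.
#' @param fcCut absolute log2 fold-change threshold (default 1).
#' @param fdrCut FDR threshold (default 0.05).
#' @return list with `table` (the input plus a `call` column), `up` and
#'   `down` gene-id vectors, and counts `nUp`, `nDown`.
#' @export
applyDeThresholds <- function(de, fcCut = 1, fdrCut = 0.05) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% colnames(de))) {
    .stopf("DE table needs columns: %s", paste(need, collapse = ", "))
  }
  call <- rep("ns", nrow(de))
  call[de$fdr < fdrCut & de$log2fc > fcCut] <- "up"
  call[de$fdr < fdrCut & de$log2fc < -fcCut] <- "down"
  de$call <- call
  list(table = de,
       up = de$gene_id[call == "up"],
       down = de$gene_id[call == "down"],
       nUp = sum(call == "up"),
       nDown = sum(call == "down"))
}

#' Resampling null for DE counts in random gene sets
#'
#' Draws `nReps` seeded random gene sets of size `setSize` from
#' `universe` without replacement and counts how many members of each
#' are called up- or down-regulated, giving the null distribution that
#' an observed eRRG DE count is compared against.
#'
#' @param calls list from [applyDeThresholds()] (or any list with `up`
#'   and `down` gene-id vectors).
#' @param universe character vector to draw from.
#' @param setSize number of genes per draw (at most `length(universe)`).
#' @param nReps number of draws (default 1000).
#' @param seed integer seed.
#' @return list with `meanUp`, `meanDown` and the full `upCounts`,
#'   `downCounts` vectors (length `nReps`).
#' @export
resampleDeCounts <- function(calls, universe, setSize, nReps = 1000L,
                             seed = NULL) {
  if (setSize > length(universe)) .stopf("setSize exceeds the universe size")
  upSet <- calls$up
  downSet <- calls$down
  counts <- .withSeed(seed, {
    up <- integer(nReps); down <- integer(nReps)
    for (i in seq_len(nReps)) {
      draw <- sample(universe, setSize, replace = FALSE)
      up[i] <- sum(draw %in% upSet)
      down[i] <- sum(draw %in% downSet)
    }
    list(up = up, down = down)
  })
  list(meanUp = mean(counts$up), meanDown = mean(counts$down),
       upCounts = counts$up, downCounts = counts$down)
}
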