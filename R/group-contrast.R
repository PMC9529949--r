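# High-risk vs low-risk multi-omics contrasts: differential methylation
# on beta values, per-gene differential mutation, mutation burden and
# SNV-class summaries, and pairwise co-occurrence/exclusivity.

#' Read a probe-by-sample beta-value matrix
#'
#' Tab-separated, first column probe ids; all values must lie in
#' `[0, 1]` with no missing entries (impute upstream if needed).
#'
#' @param path path to the TSV file.
#' @return numeric matrix with probe ids as row names.
#' @export
readBetaMatrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(ids)) .stopf("duplicate probe ids in %s", path)
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    .stopf("beta values must be complete and within [0, 1] in %s", path)
  }
  rownames(m) <- ids
  m
}

#' Read a probe-to-gene map
#'
#' Tab-separated with columns `probe_id`, `chrom`, `position`,
#' `gene_id` (empty string for unannotated probes).
#'
#' @param path path to the TSV file.
#' @return `data.frame` with those columns.
#' @export
readProbeMap <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("probe_id", "chrom", "position", "gene_id")
  if (!all(need %in% colnames(tab))) {
    .stopf("probe map %s needs columns: %s", path, paste(need, collapse = ", "))
  }
  tab$position <- as.integer(tab$position)
  tab
}

#' Read MAF-like somatic mutation records
#'
#' Accepts the standard MAF column names (`Tumor_Sample_Barcode`,
#' `Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Classification`, `Variant_Type`, and
#' optionally `t_alt_count`/`t_depth`) and normalizes them to the
#' internal record layout; a VAF column is derived from
#' `t_alt_count / t_depth` when the counts are present.
#'
#' @param path path to the tab-separated MAF-like file.
#' @return `data.frame` with columns `sample`, `gene_id`, `chrom`,
#'   `position`, `ref`, `alt`, `variant_class`, `variant_type`, `vaf`.
#' @export
readMaf <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, comment.char = "#")
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
            "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
            "Variant_Classification", "Variant_Type")
  missingCols <- setdiff(need, colnames(tab))
  if (length(missingCols)) {
    .stopf("MAF %s lacks columns: %s", path, paste(missingCols, collapse = ", "))
  }
  vaf <- rep(NA_real_, nrow(tab))
  if (all(c("t_alt_count", "t_depth") %in% colnames(tab))) {
    vaf <- as.numeric(tab$t_alt_count) / as.numeric(tab$t_depth)
  }
  data.frame(
    sample = tab$Tumor_Sample_Barcode,
    gene_id = tab$Hugo_Symbol,
    chrom = tab$Chromosome,
    position = as.integer(tab$Start_Position),
    ref = tab$Reference_Allele,
    alt = tab$Tumor_Seq_Allele2,
    variant_class = tab$Variant_Classification,
    variant_type = tab$Variant_Type,
    vaf = vaf,
    stringsAsFactors = FALSE
  )
}

#' Call differentially methylated probes (DMPs)
#'
#' Per probe: `dbeta = mean(high) - mean(low)` and a two-sided Welch
#' t-test on the beta values, BH-adjusted. A probe is called `hyper`
#' (hypermethylated in the high-risk group) when `dbeta > dbetaCut` and
#' `hypo` when `dbeta < -dbetaCut`, both additionally requiring
#' `fdr < fdrCut`; the magnitude inequalities are strict.
#'
#' @param beta probe-by-sample matrix of beta values in `[0, 1]`,
#'   no missing values.
#' @param groups named vector of `"high"`/`"low"` labels over the
#'   columns of `beta`; each group needs >= 2 samples.
#' @param dbetaCut absolute mean-difference threshold (default 0.15).
#' @param fdrCut FDR threshold (default 0.05).
#' @param probeMap optional `data.frame` from [readProbeMap()] used to
#'   collect the genes behind called probes.
#' @return list with `table` (`probe_id`, `dbeta`, `pvalue`, `fdr`,
#'   `call`), counts `nHyper`, `nHypo`, and (when `probeMap` is given)
#'   `hyperGenes`, `hypoGenes`.
#' @export
callDmps <- function(beta, groups, dbetaCut = 0.15, fdrCut = 0.05,
                     probeMap = NULL) {
  if (anyNA(beta) || any(beta < 0) || any(beta > 1)) {
    .stopf("beta values must be complete and within [0, 1]")
  }
  g <- .checkGroups2(groups, colnames(beta),
                     levelsExpected = c("high", "low"), minPer = 2L)
  hi <- beta[, g == "high", drop = FALSE]
  lo <- beta[, g == "low", drop = FALSE]
  n1 <- ncol(hi); n2 <- ncol(lo)
  m1 <- rowMeans(hi); m2 <- rowMeans(lo)
  v1 <- (rowSums(hi^2) - n1 * m1^2) / (n1 - 1L)
  v2 <- (rowSums(lo^2) - n2 * m2^2) / (n2 - 1L)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  se2 <- v1 / n1 + v2 / n2
  d <- m1 - m2
  tt <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tt), df)
  # degenerate zero-variance probes: identical values -> p 1, else p 0
  p[se2 == 0] <- ifelse(d[se2 == 0] == 0, 1, 0)
  fdr <- bhAdjust(p)
  call <- rep("ns", nrow(beta))
  call[fdr < fdrCut & d > dbetaCut] <- "hyper"
  call[fdr < fdrCut & d < -dbetaCut] <- "hypo"
  tab <- data.frame(probe_id = rownames(beta), dbeta = d, pvalue = p,
                    fdr = fdr, call = call, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- list(table = tab, nHyper = sum(call == "hyper"),
              nHypo = sum(call == "hypo"))
  if (!is.null(probeMap)) {
    geneOf <- setNames(probeMap$gene_id, probeMap$probe_id)
    pick <- function(k) {
      gs <- geneOf[tab$probe_id[tab$call == k]]
      sort(unique(gs[!is.na(gs) & nzchar(gs)]))
    }
    out$hyperGenes <- pick("hyper")
    out$hypoGenes <- pick("hypo")
  }
  out
}

#' Collapse an SNV to its pyrimidine-reference substitution class
#'
#' Single-nucleotide variants are reported in one of six classes with a
#' pyrimidine (C or T) reference base; purine-reference SNVs are mapped
#' to the reverse complement (e.g. `G>A` becomes `C>T`).
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return character vector of classes (`"C>A"`, ..., `"T>G"`); `NA`
#'   for non-SNV input.
#' @export
snvClass <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% names(comp) & alt %in% names(comp) & ref != alt
  out <- rep(NA_character_, length(ref))
  flip <- ok & ref %in% c("A", "G")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  out[ok] <- paste0(r[ok], ">", a[ok])
  out
}

.SNV_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.VARIANT_TYPES <- c("SNP", "INS", "DEL")

#' Binary gene-by-sample mutation matrix and per-sample summaries
#'
#' An entry is 1 iff the gene carries at least one qualifying record in
#' that sample; `Silent` records do not qualify unless
#' `includeSilent = TRUE`. Unknown variant classes are a warning and
#' qualify. Per-sample counts are tabulated over all records (including
#' silent) by variant class, variant type (`SNP`/`INS`/`DEL`) and the
#' six pyrimidine-collapsed SNV classes, together with a per-sample
#' median VAF.
#'
#' @param records `data.frame` from [readMaf()].
#' @param samples character vector of all sample ids (must cover every
#'   sample appearing in `records`); samples with no records get
#'   all-zero columns.
#' @param includeSilent should `Silent` records count toward mutation
#'   status? Default `FALSE`.
#' @param knownClasses variant classes not warned about.
#' @return list with `matrix` (binary genes x samples), `classCounts`,
#'   `typeCounts`, `snvClassCounts` (samples in rows), and `vafMedian`
#'   (named vector).
#' @export
mutationMatrix <- function(records, samples, includeSilent = FALSE,
                           knownClasses = c("Missense_Mutation",
                                            "Nonsense_Mutation", "Silent",
                                            "Frame_Shift_Del",
                                            "Frame_Shift_Ins",
                                            "In_Frame_Del", "In_Frame_Ins",
                                            "Splice_Site")) {
  extra <- setdiff(unique(records$sample), samples)
  if (length(extra)) {
    .stopf("records reference samples outside the sample list: %s",
           paste(head(extra, 5L), collapse = ", "))
  }
  unknown <- setdiff(unique(records$variant_class), knownClasses)
  if (length(unknown)) {
    .warnf("unknown variant classes treated as qualifying: %s",
           paste(unknown, collapse = ", "))
  }
  qual <- records$variant_class != "Silent" | includeSilent
  q <- records[qual, , drop = FALSE]
  genes <- sort(unique(records$gene_id))
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(q)) {
    idx <- cbind(match(q$gene_id, genes), match(q$sample, samples))
    mat[idx] <- 1L
  }
  sf <- factor(records$sample, levels = samples)
  classCounts <- table(sf, factor(records$variant_class))
  typeCounts <- table(sf, factor(records$variant_type, levels = .VARIANT_TYPES))
  snv <- snvClass(records$ref, records$alt)
  snv[records$variant_type != "SNP"] <- NA
  snvClassCounts <- table(sf, factor(snv, levels = .SNV_CLASSES))
  vafMedian <- tapply(records$vaf, sf, median, na.rm = TRUE)
  vafMedian <- setNames(as.numeric(vafMedian), samples)
  list(matrix = mat,
       classCounts = as.matrix(unclass(classCounts)),
       typeCounts = as.matrix(unclass(typeCounts)),
       snvClassCounts = as.matrix(unclass(snvClassCounts)),
       vafMedian = vafMedian)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value summing the hypergeometric probabilities of
#' every table (with the observed margins) whose probability does not
#' exceed that of the observed table (with the standard `1 + 1e-7`
#' relative tolerance for floating-point ties). The odds ratio is the
#' plain cross-product `(a*d)/(b*c)`; `Inf` and `NaN` arise from zero
#' cells and are reported as-is.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds.ratio` and `p.value`.
#' @examples
#' fisherExact(rbind(c(3, 1), c(1, 3)))$p.value  # 34/70
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) .stopf("a 2x2 table is required")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    .stopf("counts must be non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  orr <- (a * d) / (b * c)
  if (m + n == 0) return(list(odds.ratio = orr, p.value = 1))
  supp <- max(0, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  p0 <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
  list(odds.ratio = orr, p.value = p)
}

#' Per-gene differential mutation between risk groups
#'
#' For every gene with at least `minMutated` mutated samples overall, a
#' 2x2 table (mutated/not x high/low) is tested with [fisherExact()].
#' Genes are called differentially mutated at raw `p < pCut`
#' (unadjusted, as is conventional for this screen); a BH column is
#' emitted additionally for transparency.
#'
#' @param mat binary gene-by-sample matrix from [mutationMatrix()].
#' @param groups named vector of `"high"`/`"low"` labels over the
#'   columns of `mat`.
#' @param minMutated minimum number of mutated samples for a gene to be
#'   tested (default 5).
#' @param pCut raw p-value threshold (default 0.05).
#' @return `data.frame` with columns `gene_id`, `nHigh`, `nLow`,
#'   `odds.ratio`, `pvalue`, `fdr`, `call` (logical), one row per
#'   tested gene.
#' @export
differentialMutation <- function(mat, groups, minMutated = 5L, pCut = 0.05) {
  g <- .checkGroups2(groups, colnames(mat),
                     levelsExpected = c("high", "low"), minPer = 1L)
  hi <- g == "high"; lo <- g == "low"
  total <- rowSums(mat)
  test <- rownames(mat)[total >= minMutated]
  res <- lapply(test, function(gene) {
    mh <- sum(mat[gene, hi]); ml <- sum(mat[gene, lo])
    ft <- fisherExact(rbind(c(mh, ml), c(sum(hi) - mh, sum(lo) - ml)))
    data.frame(gene_id = gene, nHigh = mh, nLow = ml,
               odds.ratio = ft$odds.ratio, pvalue = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(gene_id = character(), nHigh = integer(), nLow = integer(),
               odds.ratio = numeric(), pvalue = numeric(),
               stringsAsFactors = FALSE)
  }
  out$fdr <- if (nrow(out)) bhAdjust(out$pvalue) else numeric()
  out$call <- out$pvalue < pCut
  rownames(out) <- NULL
  out
}

#' Group-level mutation burden comparisons
#'
#' Compares per-sample mutation counts between the high- and low-risk
#' groups with [wilcoxonRankSum()]: per variant class, per variant type
#' (`SNP`/`INS`/`DEL`), per pyrimidine-collapsed SNV class, and the
#' per-sample median VAF.
#'
#' @param mm list from [mutationMatrix()].
#' @param groups named vector of `"high"`/`"low"` labels.
#' @return `data.frame` with columns `metric`, `medianHigh`,
#'   `medianLow`, `pvalue`.
#' @export
mutationBurdenContrast <- function(mm, groups) {
  samples <- colnames(mm$matrix)
  g <- .checkGroups2(groups, samples, levelsExpected = c("high", "low"))
  hi <- samples[g == "high"]; lo <- samples[g == "low"]
  one <- function(metric, values) {
    x <- values[hi]; y <- values[lo]
    data.frame(metric = metric, medianHigh = median(x, na.rm = TRUE),
               medianLow = median(y, na.rm = TRUE),
               pvalue = wilcoxonRankSum(x[!is.na(x)], y[!is.na(y)])$p.value,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (cl in colnames(mm$classCounts)) {
    rows[[paste0("class:", cl)]] <- one(paste0("class:", cl),
                                        mm$classCounts[samples, cl])
  }
  for (ty in colnames(mm$typeCounts)) {
    rows[[paste0("type:", ty)]] <- one(paste0("type:", ty),
                                       mm$typeCounts[samples, ty])
  }
  for (sc in colnames(mm$snvClassCounts)) {
    rows[[paste0("snv:", sc)]] <- one(paste0("snv:", sc),
                                      mm$snvClassCounts[samples, sc])
  }
  if (any(!is.na(mm$vafMedian))) rows[["vaf"]] <- one("vaf", mm$vafMedian)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise mutation co-occurrence / mutual exclusivity
#'
#' For the `topK` most frequently mutated genes, every unordered pair
#' is tested with [fisherExact()] on the 2x2 sample table (both / only
#' i / only j / neither). A pair is labelled `co-occurring` when the
#' odds ratio exceeds 1 and `exclusive` otherwise; significance tiers
#' at `p < 0.05` and `p < 0.01` are reported.
#'
#' @param mat binary gene-by-sample matrix.
#' @param topK number of most frequently mutated genes to consider
#'   (ties broken by gene id for determinism); must be >= 2.
#' @return `data.frame` with columns `gene_i`, `gene_j`, `both`,
#'   `only_i`, `only_j`, `neither`, `odds.ratio`, `pvalue`, `label`,
#'   `tier` (`"p<0.01"`, `"p<0.05"` or `"ns"`).
#' @export
cooccurrence <- function(mat, topK = 25L) {
  if (topK < 2L) .stopf("topK must be >= 2")
  freq <- rowSums(mat)
  ord <- order(-freq, rownames(mat))
  genes <- rownames(mat)[ord][seq_len(min(topK, nrow(mat)))]
  prs <- combn(genes, 2L)
  res <- lapply(seq_len(ncol(prs)), function(k) {
    gi <- prs[1L, k]; gj <- prs[2L, k]
    xi <- mat[gi, ] > 0; xj <- mat[gj, ] > 0
    a <- sum(xi & xj); b <- sum(xi & !xj); c <- sum(!xi & xj)
    d <- sum(!xi & !xj)
    ft <- fisherExact(rbind(c(a, b), c(c, d)))
    data.frame(gene_i = gi, gene_j = gj, both = a, only_i = b, only_j = c,
               neither = d, odds.ratio = ft$odds.ratio, pvalue = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$label <- ifelse(!is.nan(out$odds.ratio) & out$odds.ratio > 1,
                      "co-occurring", "exclusive")
  out$tier <- ifelse(out$pvalue < 0.01, "p<0.01",
                     ifelse(out$pvalue < 0.05, "p<0.05", "ns"))
  rownames(out) <- NULL
  out
}
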