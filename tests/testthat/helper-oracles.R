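# Independent reference computations used to verify the package.
# Everything here works on plain data frames / vectors in 0-based
# half-open coordinates and shares no code with the implementation.

# build a GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  gr
}

# all-pairs overlap scan: indices of records overlapping the query
orc_overlap <- function(records, qchrom, qstart, qend) {
  hits <- integer()
  for (i in seq_len(nrow(records))) {
    if (records$chrom[i] == qchrom &&
        records$start[i] < qend && qstart < records$end[i]) {
      hits <- c(hits, i)
    }
  }
  hits
}

# brute-force eRRG identification over all (enhancer, gene) pairs:
# enhancers is a named list of data.frames (chrom, start, end, id),
# genes a data.frame (chrom, start, end, gene_id)
orc_identify <- function(enhancers, genes, hw = 3000, dl = 185000) {
  half <- dl %/% 2
  perResource <- list()
  pairs <- list()
  for (r in names(enhancers)) {
    e <- enhancers[[r]]
    gset <- list()
    for (i in seq_len(nrow(e))) {
      mid <- (e$start[i] + e$end[i]) %/% 2
      rs <- max(0, mid - hw); re <- mid + hw
      same <- genes$chrom == e$chrom[i]
      if (any(same & genes$start < re & rs < genes$end)) next
      ws <- max(0, mid - half); we <- mid + half
      hitg <- genes$gene_id[same & genes$start < we & ws < genes$end]
      if (length(hitg)) {
        gset[[length(gset) + 1L]] <- hitg
        pairs[[length(pairs) + 1L]] <- paste(r, e$id[i], hitg)
      }
    }
    perResource[[r]] <- sort(unique(unlist(gset)))
  }
  list(perResource = perResource,
       final = sort(Reduce(intersect, perResource)),
       pairs = sort(unique(unlist(pairs))))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# C(n, nx) rank assignments
orc_wilcox <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  idx <- utils::combn(n, nx)
  dist <- colSums(matrix(r[idx], nrow = nx))
  min(1, 2 * min(mean(dist <= w + 1e-9), mean(dist >= w - 1e-9)))
}

# two-sided Fisher p by direct hypergeometric enumeration with
# choose()-based probabilities
orc_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0, k - n2):min(k, m)
  lp <- lchoose(m, supp) + lchoose(n2, k - supp) - lchoose(m + n2, k)
  probs <- exp(lp)
  p0 <- probs[supp == a]
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

# BH step-up by definition
orc_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# product-limit estimate at each distinct time
orc_km <- function(times, events) {
  ts <- sort(unique(times))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    atRisk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# two-group log-rank chi-square accumulated per event time
orc_logrank <- function(g, times, events) {
  g <- factor(g)
  lvl <- levels(g)[1L]
  evTimes <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in evTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g == lvl)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == lvl)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p.value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# random annotation instance for equivalence testing (overlaps allowed)
random_instance <- function(nEnh, nGenes, nResources, chromLen = 5e6,
                            chroms = c("chr1", "chr2", "chr3")) {
  genes <- data.frame(
    chrom = sample(chroms, nGenes, replace = TRUE),
    start = sample.int(chromLen - 6000L, nGenes, replace = TRUE),
    gene_id = sprintf("g%04d", seq_len(nGenes)),
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + sample(500:5000, nGenes, replace = TRUE)
  genes$biotype <- sample(c("protein_coding", "lncRNA"), nGenes, replace = TRUE)
  enhancers <- lapply(seq_len(nResources), function(r) {
    e <- data.frame(
      chrom = sample(chroms, nEnh, replace = TRUE),
      start = sample.int(chromLen - 3000L, nEnh, replace = TRUE),
      stringsAsFactors = FALSE
    )
    e$end <- e$start + sample(100:2000, nEnh, replace = TRUE)
    e$id <- sprintf("e%05d", seq_len(nEnh))
    e
  })
  names(enhancers) <- paste0("res", seq_len(nResources))
  list(genes = genes, enhancers = enhancers)
}

genes_df_to_gr <- function(genes) {
  gr0(genes$chrom, genes$start, genes$end,
      gene_id = genes$gene_id,
      gene_name = genes$gene_id,
      biotype = if (is.null(genes$biotype)) rep("other", nrow(genes)) else genes$biotype)
}

enh_df_to_gr <- function(e, resource) {
  gr0(e$chrom, e$start, e$end, enhancer_id = e$id,
      resource = rep(resource, nrow(e)))
}

pairs_key <- function(asn) {
  p <- errgPairs(asn)
  sort(unique(paste(p$resource, p$erna_id, p$gene_id)))
}
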