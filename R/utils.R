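# Internal helpers shared across the package.

#' @import methods
#' @importFrom stats median pchisq pnorm pt pwilcox p.adjust rbinom rexp
#'   rlnorm rnbinom rnorm runif sd setNames qnorm dhyper complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed (if any) is restored afterwards, so no function in
# the package mutates global RNG state.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Coordinate conventions: all on-disk formats except GTF are 0-based
# half-open [start, end); in-memory containers are GRanges (1-based closed
# [start+1, end]).  The mapping is exact, so >=1 bp overlap and half-open
# adjacency semantics carry over unchanged.
.grangesFromZero <- function(chrom, start0, end0, ..., strand = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = if (is.null(strand)) rep("*", length(chrom)) else strand
  )
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  gr
}

.zeroStart <- function(gr) GenomicRanges::start(gr) - 1L
.zeroEnd <- function(gr) GenomicRanges::end(gr)

.normalizeChrom <- function(chrom, normalizeChrom = c("none", "strip", "add")) {
  normalizeChrom <- match.arg(normalizeChrom)
  switch(normalizeChrom,
    none = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

.checkGroups2 <- function(groups, samples, levelsExpected = NULL, minPer = 1L) {
  if (is.null(names(groups))) .stopf("group labels must be a named vector")
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    .stopf("samples without a group label: %s",
           paste(head(missing, 5L), collapse = ", "))
  }
  g <- factor(as.character(groups[samples]))
  if (!is.null(levelsExpected)) {
    bad <- setdiff(levels(g), levelsExpected)
    if (length(bad)) .stopf("unexpected group labels: %s", paste(bad, collapse = ", "))
    g <- factor(g, levels = levelsExpected)
  }
  if (nlevels(droplevels(g)) != 2L) .stopf("exactly two groups are required")
  tab <- table(g)
  if (any(tab < minPer)) {
    .stopf("each group needs at least %d samples (got %s)",
           minPer, paste(tab, collapse = "/"))
  }
  g
}
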