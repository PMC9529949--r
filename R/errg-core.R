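# Core eRRG identification: eRNA regions, gene-overlap filtering,
# contact-domain assignment, multi-resource intersection.

#' Build eRNA regions around enhancer midpoints
#'
#' An eRNA region is the window of `halfWidth` bp on either side of the
#' enhancer midpoint. In 0-based half-open coordinates the midpoint is
#' `floor((start + end) / 2)` and the region is
#' `[max(0, midpoint - halfWidth), midpoint + halfWidth)`; only the
#' chromosome start is clamped (chromosome sizes are not consulted).
#'
#' @param enhancers `GRanges` from [readEnhancerBed()], with
#'   `enhancer_id` and `resource` metadata columns.
#' @param halfWidth half-width of the eRNA region in bp (default 3000,
#'   i.e. a +/- 3 kb window around the enhancer midpoint).
#' @return `GRanges` of eRNA regions with metadata columns
#'   `enhancer_id`, `resource` and `midpoint` (0-based).
#' @export
ernaRegions <- function(enhancers, halfWidth = 3000L) {
  stopifnot(is(enhancers, "GRanges"))
  halfWidth <- as.integer(halfWidth)
  if (is.na(halfWidth) || halfWidth <= 0L) .stopf("halfWidth must be > 0")
  start0 <- .zeroStart(enhancers)
  end0 <- .zeroEnd(enhancers)
  mid0 <- (start0 + end0) %/% 2L
  regStart0 <- pmax(0L, mid0 - halfWidth)
  regEnd0 <- mid0 + halfWidth
  .grangesFromZero(as.character(GenomicRanges::seqnames(enhancers)),
                   regStart0, regEnd0,
                   enhancer_id = enhancers$enhancer_id,
                   resource = enhancers$resource,
                   midpoint = mid0)
}

#' Drop eRNA regions overlapping known genes
#'
#' Removes every eRNA region with >= 1 bp overlap with any annotated gene
#' of any biotype on either strand; input order is preserved for the
#' survivors. The number removed is reported with a message.
#'
#' @param regions `GRanges` of eRNA regions from [ernaRegions()].
#' @param genes non-empty `GRanges` gene annotation.
#' @return the non-overlapping subset of `regions`.
#' @export
filterGeneOverlapping <- function(regions, genes) {
  stopifnot(is(regions, "GRanges"), is(genes, "GRanges"))
  if (!length(genes)) .stopf("gene annotation is empty")
  # records on chromosomes absent from the other set simply never match
  drop <- suppressWarnings(
    IRanges::overlapsAny(regions, genes, ignore.strand = TRUE))
  message(sprintf("filtered %d of %d eRNA regions overlapping known genes",
                  sum(drop), length(regions)))
  regions[!drop]
}

#' Assign genes within the contact-domain window of eRNA regions
#'
#' For each eRNA region a contact-domain window of total length
#' `domainLength` is centred on the region midpoint:
#' `[max(0, midpoint - domainLength/2), midpoint + domainLength/2)` in
#' 0-based half-open coordinates. Every gene whose body overlaps the
#' window by >= 1 bp (any biotype, either strand) is assigned to that
#' eRNA as an eRRG.
#'
#' @param regions `GRanges` of (already filtered) eRNA regions.
#' @param genes `GRanges` gene annotation.
#' @param domainLength total window length in bp (default 185000,
#'   the median contact-domain length used as the regulatory neighbourhood).
#' @return a `data.frame` of pairs with columns `erna_id`, `resource`,
#'   `gene_id`, `biotype`, `chrom`, `region_start`, `region_end`
#'   (0-based half-open eRNA region) and `midpoint`.
#' @export
assignErrgs <- function(regions, genes, domainLength = 185000L) {
  stopifnot(is(regions, "GRanges"), is(genes, "GRanges"))
  domainLength <- as.integer(domainLength)
  if (is.na(domainLength) || domainLength <= 0L) .stopf("domainLength must be > 0")
  half <- domainLength %/% 2L
  mid0 <- regions$midpoint
  windows <- .grangesFromZero(as.character(GenomicRanges::seqnames(regions)),
                              pmax(0L, mid0 - half), mid0 + half)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(windows, genes, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(
    erna_id = regions$enhancer_id[qi],
    resource = regions$resource[qi],
    gene_id = genes$gene_id[si],
    biotype = genes$biotype[si],
    chrom = as.character(GenomicRanges::seqnames(regions))[qi],
    region_start = .zeroStart(regions)[qi],
    region_end = .zeroEnd(regions)[qi],
    midpoint = mid0[qi],
    stringsAsFactors = FALSE
  )
  pairs[order(pairs$erna_id, pairs$gene_id), , drop = FALSE]
}

#' Intersect per-resource eRRG sets
#'
#' The final eRRG set is the intersection of the gene sets obtained from
#' every enhancer resource; counts are reported split by biotype.
#'
#' @param perResource named list of character vectors of gene ids, one
#'   per enhancer resource.
#' @param genes optional `GRanges` gene annotation used to attach
#'   biotypes to the counts; without it only the total is counted.
#' @return list with `final` (sorted character vector) and `counts`
#'   (named list: `n`, `protein_coding`, `lncRNA`, `other`).
#' @export
intersectResources <- function(perResource, genes = NULL) {
  if (!length(perResource)) .stopf("at least one resource is required")
  final <- sort(Reduce(intersect, perResource))
  counts <- list(n = length(final), protein_coding = NA_integer_,
                 lncRNA = NA_integer_, other = NA_integer_)
  if (!is.null(genes)) {
    bt <- genes$biotype[match(final, genes$gene_id)]
    counts$protein_coding <- sum(bt == "protein_coding", na.rm = TRUE)
    counts$lncRNA <- sum(bt == "lncRNA", na.rm = TRUE)
    counts$other <- sum(bt == "other", na.rm = TRUE)
  }
  list(final = final, counts = counts)
}

#' Identify eRNA-regulated genes across enhancer resources
#'
#' Runs the full identification chain for each enhancer resource: build
#' eRNA regions around enhancer midpoints ([ernaRegions()]), discard
#' regions overlapping any known gene ([filterGeneOverlapping()]),
#' assign genes inside the contact-domain window ([assignErrgs()]), and
#' finally intersect the per-resource gene sets
#' ([intersectResources()]).
#'
#' @param enhancers named list; each element either a `GRanges` from
#'   [readEnhancerBed()] or a path to a BED file. Names are the resource
#'   labels.
#' @param genes `GRanges` from [readGeneTable()], or a path to a gene
#'   table (`.gtf`/`.gff` read as GTF, anything else as the TSV dialect).
#' @inheritParams ernaRegions
#' @inheritParams assignErrgs
#' @return an [ErrgAssignment-class] object.
#' @examples
#' genes <- readGeneTable(system.file("extdata", "mini_genes.tsv", package = "errg"))
#' beds <- system.file("extdata", c("mini_res1.bed", "mini_res2.bed"), package = "errg")
#' asn <- identifyErrgs(list(res1 = beds[1], res2 = beds[2]), genes)
#' errgFinal(asn)
#' @export
identifyErrgs <- function(enhancers, genes, halfWidth = 3000L,
                          domainLength = 185000L) {
  if (!length(enhancers) || is.null(names(enhancers)) ||
      any(!nzchar(names(enhancers)))) {
    .stopf("'enhancers' must be a non-empty named list (names are resource labels)")
  }
  if (is.character(genes)) {
    dialect <- if (grepl("\\.(gtf|gff3?)(\\.gz)?$", genes, ignore.case = TRUE))
      "gtf" else "tsv"
    genes <- readGeneTable(genes, dialect = dialect)
  }
  stopifnot(is(genes, "GRanges"))
  resources <- names(enhancers)
  perResource <- list()
  pairsList <- list()
  summaryPer <- list()
  for (r in resources) {
    enh <- enhancers[[r]]
    if (is.character(enh)) enh <- readEnhancerBed(enh, resource = r)
    stopifnot(is(enh, "GRanges"))
    if (anyDuplicated(enh$enhancer_id)) {
      .stopf("duplicate enhancer ids within resource '%s'", r)
    }
    enh$resource <- rep(r, length(enh))
    regions <- ernaRegions(enh, halfWidth = halfWidth)
    kept <- suppressMessages(filterGeneOverlapping(regions, genes))
    if (!length(kept)) {
      .warnf("resource '%s' contributes zero eRNA regions after gene-overlap filtering", r)
    }
    pairs <- assignErrgs(kept, genes, domainLength = domainLength)
    perResource[[r]] <- sort(unique(pairs$gene_id))
    pairsList[[r]] <- pairs
    summaryPer[[r]] <- list(nEnhancers = length(enh),
                            nRegions = length(kept),
                            nErrgs = length(perResource[[r]]))
  }
  inter <- intersectResources(perResource, genes)
  pairs <- do.call(rbind, pairsList)
  rownames(pairs) <- NULL
  methods::new("ErrgAssignment",
    perResource = perResource,
    final = inter$final,
    pairs = pairs,
    halfWidth = as.integer(halfWidth),
    domainLength = as.integer(domainLength),
    summary = list(perResource = summaryPer, final = inter$counts)
  )
}
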