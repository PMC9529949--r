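#' ErrgAssignment: eRNA-region to gene assignments across enhancer resources
#'
#' Container for the result of [identifyErrgs()]: the per-resource eRNA
#' regulated gene (eRRG) sets, the final multi-resource intersection, the
#' full (eRNA region, gene, resource) pair table, and the parameters the
#' assignment was run with.
#'
#' @slot perResource named list of character vectors; eRRG gene ids found
#'   from each enhancer resource.
#' @slot final character vector; intersection of the per-resource sets.
#' @slot pairs `data.frame` with columns `erna_id`, `resource`, `gene_id`,
#'   `biotype`, plus the eRNA region coordinates (`chrom`, `region_start`,
#'   `region_end`, 0-based half-open) and `midpoint`.
#' @slot halfWidth integer, half-width in bp of the eRNA region around the
#'   enhancer midpoint.
#' @slot domainLength integer, total length in bp of the contact-domain
#'   window centred on the eRNA midpoint.
#' @slot summary list of per-resource and final counts (enhancers read,
#'   eRNA regions kept after the gene-overlap filter, eRRGs per resource,
#'   final counts split by biotype).
#'
#' @seealso [identifyErrgs()], [errgFinal()], [errgPairs()]
#' @exportClass ErrgAssignment
setClass("ErrgAssignment",
  representation(
    perResource = "list",
    final = "character",
    pairs = "data.frame",
    halfWidth = "integer",
    domainLength = "integer",
    summary = "list"
  )
)

setValidity("ErrgAssignment", function(object) {
  msg <- character()
  if (length(object@perResource) < 1L)
    msg <- c(msg, "at least one resource is required")
  if (is.null(names(object@perResource)) ||
      anyDuplicated(names(object@perResource)))
    msg <- c(msg, "perResource must be uniquely named")
  expected <- sort(Reduce(intersect, object@perResource))
  if (!identical(sort(object@final), expected))
    msg <- c(msg, "final must equal the intersection of the per-resource sets")
  if (object@halfWidth <= 0L) msg <- c(msg, "halfWidth must be > 0")
  if (object@domainLength <= 0L) msg <- c(msg, "domainLength must be > 0")
  allGenes <- unique(unlist(object@perResource, use.names = FALSE))
  if (nrow(object@pairs) &&
      !all(object@pairs$gene_id %in% allGenes))
    msg <- c(msg, "pairs reference gene ids absent from the per-resource sets")
  if (length(msg)) msg else TRUE
})

#' @describeIn ErrgAssignment final intersected eRRG gene ids
#' @param x,object an `ErrgAssignment`
#' @export
setGeneric("errgFinal", function(x) standardGeneric("errgFinal"))

#' @rdname ErrgAssignment
#' @export
setMethod("errgFinal", "ErrgAssignment", function(x) x@final)

#' @describeIn ErrgAssignment per-resource eRRG gene-id sets
#' @export
setGeneric("errgPerResource", function(x) standardGeneric("errgPerResource"))

#' @rdname ErrgAssignment
#' @export
setMethod("errgPerResource", "ErrgAssignment", function(x) x@perResource)

#' @describeIn ErrgAssignment (eRNA region, gene, resource) pair table
#' @export
setGeneric("errgPairs", function(x) standardGeneric("errgPairs"))

#' @rdname ErrgAssignment
#' @export
setMethod("errgPairs", "ErrgAssignment", function(x) x@pairs)

#' @describeIn ErrgAssignment count summary (per resource and final)
#' @export
setGeneric("errgSummary", function(x) standardGeneric("errgSummary"))

#' @rdname ErrgAssignment
#' @export
setMethod("errgSummary", "ErrgAssignment", function(x) x@summary)

#' @rdname ErrgAssignment
#' @export
setMethod("show", "ErrgAssignment", function(object) {
  cat("ErrgAssignment\n")
  cat(sprintf("  resources: %s\n", paste(names(object@perResource), collapse = ", ")))
  cat(sprintf("  half-width: %d bp; contact domain: %d bp\n",
              object@halfWidth, object@domainLength))
  for (r in names(object@perResource)) {
    s <- object@summary$perResource[[r]]
    cat(sprintf("  %s: %d enhancers -> %d eRNA regions -> %d eRRGs\n",
                r, s$nEnhancers, s$nRegions, s$nErrgs))
  }
  fs <- object@summary$final
  cat(sprintf("  final: %d eRRGs (%d protein_coding, %d lncRNA, %d other)\n",
              fs$n, fs$protein_coding, fs$lncRNA, fs$other))
  invisible(object)
})
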