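#' Read enhancer annotations from a BED3/BED4 file
#'
#' Reads a whitespace- or tab-delimited BED file of enhancer coordinates.
#' Coordinates are taken as 0-based half-open, the BED native convention,
#' and returned as a `GRanges` (1-based closed internally, converted
#' exactly). Lines starting with `#`, `track` or `browser` are skipped.
#' When the optional 4th column is absent an id of the form
#' `resource:lineNumber` is generated.
#'
#' @param path path to the BED file.
#' @param resource label for the enhancer resource the file comes from
#'   (e.g. one of several enhancer databases); stored in `mcols()$resource`.
#' @param normalizeChrom one of `"none"` (default; chromosome names are
#'   compared as exact strings), `"strip"` (remove a leading `"chr"`) or
#'   `"add"` (prepend `"chr"` where missing).
#' @return `GRanges` with metadata columns `enhancer_id` and `resource`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("# demo", "chr1\t100\t200\te1", "chr1\t500\t900"), bed)
#' readEnhancerBed(bed, resource = "demo")
#' @export
readEnhancerBed <- function(path, resource,
                            normalizeChrom = c("none", "strip", "add")) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (missing(resource) || !nzchar(resource)) .stopf("a resource label is required")
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (!length(lines)) {
    return(.grangesFromZero(character(), integer(), integer(),
                            enhancer_id = character(),
                            resource = character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    .stopf("line %d of %s: fewer than 3 columns", lineNo[which(nf < 3L)[1L]], path)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  startTxt <- vapply(fields, `[`, "", 2L)
  endTxt <- vapply(fields, `[`, "", 3L)
  badNum <- !grepl("^[0-9]+$", startTxt) | !grepl("^[0-9]+$", endTxt)
  if (any(badNum)) {
    .stopf("line %d of %s: non-integer coordinates", lineNo[which(badNum)[1L]], path)
  }
  start0 <- as.integer(startTxt)
  end0 <- as.integer(endTxt)
  badIv <- end0 <= start0
  if (any(badIv)) {
    .stopf("line %d of %s: end <= start", lineNo[which(badIv)[1L]], path)
  }
  id <- ifelse(nf >= 4L,
               vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, ""),
               paste0(resource, ":", lineNo))
  if (anyDuplicated(id)) {
    .stopf("duplicate enhancer ids within resource '%s': %s", resource,
           paste(unique(id[duplicated(id)])[1:min(5, sum(duplicated(id)))],
                 collapse = ", "))
  }
  chrom <- .normalizeChrom(chrom, match.arg(normalizeChrom))
  .grangesFromZero(chrom, start0, end0, enhancer_id = id,
                   resource = rep(resource, length(id)))
}

.BIOTYPES <- c("protein_coding", "lncRNA")

.mapBiotype <- function(b) {
  b <- as.character(b)
  b[is.na(b) | !(b %in% .BIOTYPES)] <- "other"
  b
}

#' Read a gene annotation table
#'
#' Two dialects are supported. `"tsv"` is the package's own 7-column table
#' (`gene_id`, `gene_name`, `chrom`, `start`, `end`, `strand`, `biotype`)
#' with 0-based half-open coordinates, as written by [writeGeneTable()].
#' `"gtf"` reads only feature-type `gene` lines through
#' [rtracklayer::import()]; GTF's 1-based closed coordinates map to the
#' same internal representation without adjustment. Biotypes outside
#' `protein_coding`/`lncRNA` are mapped to `other`; duplicate gene ids are
#' an error.
#'
#' @param path path to the annotation file.
#' @param dialect `"tsv"` or `"gtf"`.
#' @inheritParams readEnhancerBed
#' @return `GRanges` with metadata columns `gene_id`, `gene_name`,
#'   `biotype` and strand set from the annotation (`.` becomes `*`).
#' @seealso [writeGeneTable()]
#' @export
readGeneTable <- function(path, dialect = c("tsv", "gtf"),
                          normalizeChrom = c("none", "strip", "add")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (dialect == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
    need <- c("gene_id", "gene_name", "chrom", "start", "end", "strand", "biotype")
    missingCols <- setdiff(need, colnames(tab))
    if (length(missingCols)) {
      .stopf("gene table %s lacks columns: %s", path,
             paste(missingCols, collapse = ", "))
    }
    start0 <- suppressWarnings(as.integer(tab$start))
    end0 <- suppressWarnings(as.integer(tab$end))
    if (anyNA(start0) || anyNA(end0)) .stopf("non-integer gene coordinates in %s", path)
    if (any(start0 < 0L) || any(end0 <= start0)) {
      .stopf("invalid gene interval (need start >= 0, end > start) in %s", path)
    }
    strand <- tab$strand
    strand[strand == "."] <- "*"
    if (!all(strand %in% c("+", "-", "*"))) .stopf("invalid strand values in %s", path)
    gr <- .grangesFromZero(.normalizeChrom(tab$chrom, match.arg(normalizeChrom)),
                           start0, end0,
                           gene_id = tab$gene_id,
                           gene_name = tab$gene_name,
                           biotype = .mapBiotype(tab$biotype),
                           strand = strand)
  } else {
    gtf <- rtracklayer::import(path, format = "gtf")
    gtf <- gtf[!is.na(gtf$type) & gtf$type == "gene"]
    if (!length(gtf)) .stopf("no feature-type 'gene' lines in %s", path)
    biotype <- if ("gene_type" %in% colnames(S4Vectors::mcols(gtf))) {
      gtf$gene_type
    } else if ("gene_biotype" %in% colnames(S4Vectors::mcols(gtf))) {
      gtf$gene_biotype
    } else {
      rep(NA_character_, length(gtf))
    }
    geneName <- if ("gene_name" %in% colnames(S4Vectors::mcols(gtf))) {
      ifelse(is.na(gtf$gene_name), gtf$gene_id, gtf$gene_name)
    } else {
      gtf$gene_id
    }
    gr <- GenomicRanges::GRanges(
      seqnames = .normalizeChrom(as.character(GenomicRanges::seqnames(gtf)),
                                 match.arg(normalizeChrom)),
      ranges = IRanges::ranges(gtf),
      strand = GenomicRanges::strand(gtf)
    )
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = gtf$gene_id,
      gene_name = geneName,
      biotype = .mapBiotype(biotype)
    )
  }
  dup <- unique(gr$gene_id[duplicated(gr$gene_id)])
  if (length(dup)) {
    .stopf("duplicate gene_id in %s: %s", path,
           paste(head(dup, 5L), collapse = ", "))
  }
  gr
}

#' Write a gene annotation in the package's TSV dialect
#'
#' Emits the 7-column tab-separated table read back by
#' `readGeneTable(dialect = "tsv")`, with 0-based half-open coordinates;
#' `*` strand is written as `.`. Round-tripping is the identity on all
#' fields.
#'
#' @param genes `GRanges` as returned by [readGeneTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  strand <- as.character(GenomicRanges::strand(genes))
  strand[strand == "*"] <- "."
  tab <- data.frame(
    gene_id = genes$gene_id,
    gene_name = genes$gene_name,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = .zeroStart(genes),
    end = .zeroEnd(genes),
    strand = strand,
    biotype = genes$biotype,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Query records overlapping an interval
#'
#' Returns the records with at least 1 bp overlap with the query under
#' half-open semantics (adjacent intervals do not overlap), strand
#' agnostic, ordered deterministically by start position and then by id.
#'
#' @param records `GRanges` of annotated records (enhancers or genes);
#'   any metadata columns are carried through.
#' @param query a length-1 `GRanges` query interval.
#' @return the overlapping subset of `records`, sorted by start then id.
#' @export
overlappingRecords <- function(records, query) {
  stopifnot(is(records, "GRanges"), is(query, "GRanges"), length(query) == 1L)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, records, ignore.strand = TRUE))
  out <- records[S4Vectors::subjectHits(hits)]
  mc <- S4Vectors::mcols(out)
  id <- if ("enhancer_id" %in% colnames(mc)) {
    out$enhancer_id
  } else if ("gene_id" %in% colnames(mc)) {
    out$gene_id
  } else {
    as.character(seq_along(out))
  }
  out[order(GenomicRanges::start(out), id)]
}
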