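# Synthetic-data generator: every input the pipeline consumes, with
# planted ground truth derived by an independent all-pairs computation
# (never by the identification code itself).

#' SimConfig: parameters of the synthetic study generator
#'
#' A validated parameter bundle for [simulateErrgStudy()] and the
#' individual generators. Generation is a pure function of the config:
#' the same config yields byte-identical outputs. See [simConfig()] for
#' the slot-by-slot description and defaults.
#'
#' @seealso [simConfig()], [simulateErrgStudy()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "numeric",
    nChromosomes = "numeric", chromLength = "numeric",
    nGenes = "numeric", pcgFraction = "numeric", geneLength = "numeric",
    nEnhancers = "numeric", resourceOverlap = "numeric",
    resources = "character",
    halfWidth = "numeric", domainLength = "numeric",
    nTumor = "numeric", nNormal = "numeric",
    exprMeanLog = "numeric", exprSdLog = "numeric",
    errgMeanFactor = "numeric",
    deFracUp = "numeric", deFracDown = "numeric", deLog2fc = "numeric",
    nbDispersion = "numeric",
    nProbes = "numeric", nDmpProbes = "numeric",
    dmpDelta = "numeric", betaSd = "numeric",
    mutBackgroundRate = "numeric", nDiffMutGenes = "numeric",
    mutRateHigh = "numeric", mutRateLow = "numeric",
    silentFraction = "numeric", indelFraction = "numeric",
    snvClassMix = "numeric",
    signatureSize = "numeric",
    survivalEffect = "numeric", baselineHazard = "numeric",
    censorFraction = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  fracs <- c(pcgFraction = object@pcgFraction,
             resourceOverlap = object@resourceOverlap,
             deFracUp = object@deFracUp, deFracDown = object@deFracDown,
             mutBackgroundRate = object@mutBackgroundRate,
             mutRateHigh = object@mutRateHigh, mutRateLow = object@mutRateLow,
             silentFraction = object@silentFraction,
             indelFraction = object@indelFraction,
             censorFraction = object@censorFraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) msg <- c(msg, paste("fractions outside [0, 1]:",
                                    paste(names(fracs)[bad], collapse = ", ")))
  pos <- c(nChromosomes = object@nChromosomes, chromLength = object@chromLength,
           nGenes = object@nGenes, geneLength = object@geneLength,
           nEnhancers = object@nEnhancers, halfWidth = object@halfWidth,
           domainLength = object@domainLength, nTumor = object@nTumor,
           nNormal = object@nNormal, nProbes = object@nProbes,
           signatureSize = object@signatureSize,
           baselineHazard = object@baselineHazard)
  if (any(pos <= 0)) msg <- c(msg, paste("non-positive counts:",
                                         paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@deFracUp + object@deFracDown > 1)
    msg <- c(msg, "deFracUp + deFracDown must be <= 1")
  if (length(object@resources) < 1L || anyDuplicated(object@resources))
    msg <- c(msg, "resources must be a non-empty set of unique labels")
  if (!setequal(names(object@snvClassMix), .SNV_CLASSES) ||
      any(object@snvClassMix < 0) || abs(sum(object@snvClassMix) - 1) > 1e-8)
    msg <- c(msg, "snvClassMix must be a probability vector over the six SNV classes")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-study configuration
#'
#' The defaults form the "demo" configuration: a desk-scale emulation
#' of a tumor/normal cohort with four enhancer resources. All
#' generation is seeded and reproducible from the config alone.
#'
#' @param seed base RNG seed; each sub-generator derives its own stream
#'   from it.
#' @param nChromosomes,chromLength genome shape (bp).
#' @param nGenes,pcgFraction,geneLength gene annotation: number of
#'   (non-overlapping) genes, fraction annotated `protein_coding`
#'   (remainder `lncRNA`), and typical gene length in bp.
#' @param nEnhancers enhancers per resource; `resourceOverlap` is the
#'   fraction shared by all resources (the planted eRRG signal), the
#'   remainder being resource-private.
#' @param resources resource labels.
#' @param halfWidth,domainLength eRNA region half-width and
#'   contact-domain window length in bp.
#' @param nTumor,nNormal sample sizes for the expression matrix.
#' @param exprMeanLog,exprSdLog log-normal distribution of baseline
#'   per-gene mean counts.
#' @param errgMeanFactor multiplicative boost of the baseline mean for
#'   planted eRRGs (drives the mean/CV contrast).
#' @param deFracUp,deFracDown,deLog2fc fraction of planted eRRGs given
#'   a tumor-vs-normal fold change of `+/- deLog2fc` (log2 units).
#' @param nbDispersion negative-binomial dispersion (1/size).
#' @param nProbes,nDmpProbes,dmpDelta,betaSd methylation array:
#'   number of probes, planted differential probes with mean beta shift
#'   `dmpDelta` between risk groups, and within-group beta SD
#'   (truncated-normal noise on `[0, 1]`).
#' @param mutBackgroundRate per-gene per-sample background mutation
#'   probability; `nDiffMutGenes` genes instead mutate at
#'   `mutRateHigh` / `mutRateLow` in the high/low-risk groups.
#' @param silentFraction,indelFraction,snvClassMix variant composition:
#'   probability of a Silent record, of an indel, and the mix over the
#'   six pyrimidine-collapsed SNV classes.
#' @param signatureSize number of genes in the planted risk signature.
#' @param survivalEffect scale of the survival linear predictor in SD
#'   units of the planted risk score (0 gives a null signature).
#' @param baselineHazard exponential baseline hazard (per day).
#' @param censorFraction expected fraction of censored samples.
#' @return a validated [SimConfig-class] object.
#' @export
simConfig <- function(seed = 1,
                      nChromosomes = 2, chromLength = 1e7,
                      nGenes = 500, pcgFraction = 0.6, geneLength = 2000,
                      nEnhancers = 90, resourceOverlap = 2 / 3,
                      resources = c("ensembl", "fantom", "roadmap", "encode"),
                      halfWidth = 3000, domainLength = 185000,
                      nTumor = 200, nNormal = 32,
                      exprMeanLog = log(8), exprSdLog = 1,
                      errgMeanFactor = 8,
                      deFracUp = 0.15, deFracDown = 0.10, deLog2fc = 2,
                      nbDispersion = 0.2,
                      nProbes = 3000, nDmpProbes = 100,
                      dmpDelta = 0.3, betaSd = 0.05,
                      mutBackgroundRate = 0.08, nDiffMutGenes = 10,
                      mutRateHigh = 0.4, mutRateLow = 0.05,
                      silentFraction = 0.2, indelFraction = 0.1,
                      snvClassMix = c("C>A" = 0.08, "C>G" = 0.06,
                                      "C>T" = 0.47, "T>A" = 0.07,
                                      "T>C" = 0.25, "T>G" = 0.07),
                      signatureSize = 12,
                      survivalEffect = 1, baselineHazard = 5e-4,
                      censorFraction = 0.2) {
  methods::new("SimConfig",
    seed = seed, nChromosomes = nChromosomes, chromLength = chromLength,
    nGenes = nGenes, pcgFraction = pcgFraction, geneLength = geneLength,
    nEnhancers = nEnhancers, resourceOverlap = resourceOverlap,
    resources = resources, halfWidth = halfWidth,
    domainLength = domainLength, nTumor = nTumor, nNormal = nNormal,
    exprMeanLog = exprMeanLog, exprSdLog = exprSdLog,
    errgMeanFactor = errgMeanFactor, deFracUp = deFracUp,
    deFracDown = deFracDown, deLog2fc = deLog2fc,
    nbDispersion = nbDispersion, nProbes = nProbes,
    nDmpProbes = nDmpProbes, dmpDelta = dmpDelta, betaSd = betaSd,
    mutBackgroundRate = mutBackgroundRate, nDiffMutGenes = nDiffMutGenes,
    mutRateHigh = mutRateHigh, mutRateLow = mutRateLow,
    silentFraction = silentFraction, indelFraction = indelFraction,
    snvClassMix = snvClassMix[.SNV_CLASSES], signatureSize = signatureSize,
    survivalEffect = survivalEffect, baselineHazard = baselineHazard,
    censorFraction = censorFraction
  )
}

#' @rdname SimConfig-class
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  genome: %d chromosomes x %g bp; %d genes (%.0f%% protein_coding)\n",
              as.integer(object@nChromosomes), object@chromLength,
              as.integer(object@nGenes), 100 * object@pcgFraction))
  cat(sprintf("  enhancers: %d per resource (%s), %.0f%% shared\n",
              as.integer(object@nEnhancers),
              paste(object@resources, collapse = ", "),
              100 * object@resourceOverlap))
  cat(sprintf("  samples: %d tumor, %d normal; probes: %d; seed: %g\n",
              as.integer(object@nTumor), as.integer(object@nNormal),
              as.integer(object@nProbes), object@seed))
  invisible(object)
})

# Independent all-pairs eRRG derivation on plain data frames (0-based
# half-open coordinates). Used only to construct ground truth; it shares
# no code with ernaRegions()/assignErrgs()/identifyErrgs().
.bruteForceErrgs <- function(enh, genes, halfWidth, domainLength) {
  half <- as.integer(domainLength) %/% 2L
  out <- character()
  for (i in seq_len(nrow(enh))) {
    mid <- (enh$start[i] + enh$end[i]) %/% 2L
    rs <- max(0L, mid - as.integer(halfWidth)); re <- mid + as.integer(halfWidth)
    onChrom <- genes$chrom == enh$chrom[i]
    if (any(onChrom & genes$start < re & rs < genes$end)) next
    ws <- max(0L, mid - half); we <- mid + half
    out <- c(out, genes$gene_id[onChrom & genes$start < we & ws < genes$end])
  }
  sort(unique(out))
}

#' Generate the gene annotation, enhancer resources and eRRG truth
#'
#' Places non-overlapping genes on a regular jittered grid, then plants
#' two kinds of enhancers: "shared" enhancers present in every resource
#' (placed inside gene-free gaps so their eRNA regions survive the
#' gene-overlap filter, with genes nearby inside the contact-domain
#' window) and "resource-private" enhancers (half placed on top of
#' genes, so they are filtered; half in gaps kept at least a domain
#' length away from other resources' private gaps, so they never
#' contribute to the all-resource intersection). The per-resource and
#' final eRRG truth sets are derived by an internal all-pairs scan that
#' shares no code with [identifyErrgs()].
#'
#' @param config a [SimConfig-class].
#' @return list with `genes` (`GRanges`), `enhancers` (named list of
#'   `GRanges`, one per resource) and `truth` (list with `perResource`
#'   and `final` gene-id sets).
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  .withSeed(config@seed + 1, {
    nChrom <- as.integer(config@nChromosomes)
    chromLen <- as.integer(config@chromLength)
    nGenes <- as.integer(config@nGenes)
    geneLen <- as.integer(config@geneLength)
    hw <- as.integer(config@halfWidth)
    perChrom <- rep(nGenes %/% nChrom, nChrom)
    if (nGenes %% nChrom) perChrom[seq_len(nGenes %% nChrom)] <-
      perChrom[seq_len(nGenes %% nChrom)] + 1L
    slot <- chromLen %/% (max(perChrom) + 1L)
    maxGeneLen <- as.integer(ceiling(geneLen * 1.5))
    if (slot < maxGeneLen + 2L * (hw + 1000L) + 400L) {
      .stopf("infeasible packing: %d genes do not fit on %d bp chromosomes with %d bp eRNA clearance",
             nGenes, chromLen, hw)
    }
    genes <- do.call(rbind, lapply(seq_len(nChrom), function(ci) {
      k <- perChrom[ci]
      slotC <- chromLen %/% (k + 1L)
      centers <- slotC * seq_len(k) +
        as.integer(round(runif(k, -slotC / 8, slotC / 8)))
      lens <- as.integer(round(geneLen * runif(k, 0.5, 1.5)))
      start <- pmax(0L, centers - lens %/% 2L)
      data.frame(chrom = paste0("chr", ci), start = start,
                 end = start + lens, stringsAsFactors = FALSE)
    }))
    ord <- order(genes$chrom, genes$start)
    genes <- genes[ord, , drop = FALSE]
    genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
    genes$gene_name <- sprintf("GENE%d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    nPcg <- round(nrow(genes) * config@pcgFraction)
    bt <- rep("lncRNA", nrow(genes))
    bt[sample(nrow(genes), nPcg)] <- "protein_coding"
    genes$biotype <- bt

    # interior gene-free gaps able to host an eRNA region entirely
    gaps <- do.call(rbind, lapply(unique(genes$chrom), function(ch) {
      g <- genes[genes$chrom == ch, ]
      if (nrow(g) < 2L) return(NULL)
      data.frame(chrom = ch, lo = g$end[-nrow(g)], hi = g$start[-1],
                 stringsAsFactors = FALSE)
    }))
    gaps <- gaps[gaps$hi - gaps$lo >= 2L * hw + 1200L, , drop = FALSE]

    nShared <- round(config@nEnhancers * config@resourceOverlap)
    nPriv <- as.integer(config@nEnhancers) - nShared
    nPrivGene <- nPriv %/% 2L
    nPrivGap <- nPriv - nPrivGene

    # a pool of gaps pairwise >= domainLength apart for private
    # enhancers, so private assignments never reach a common gene
    gapOrd <- order(gaps$chrom, gaps$lo)
    isolated <- integer()
    lastBy <- list()
    minSep <- as.integer(config@domainLength) + 2L * hw
    for (j in gapOrd) {
      ch <- gaps$chrom[j]
      if (is.null(lastBy[[ch]]) || gaps$lo[j] - lastBy[[ch]] >= minSep) {
        isolated <- c(isolated, j)
        lastBy[[ch]] <- gaps$lo[j]
      }
    }
    needPriv <- nPrivGap * length(config@resources)
    if (length(isolated) < needPriv) {
      .stopf("not enough isolated gene-free gaps for %d private enhancers (found %d)",
             needPriv, length(isolated))
    }
    sharedPool <- setdiff(seq_len(nrow(gaps)), isolated)
    if (length(sharedPool) < nShared) {
      # fall back on unused isolated gaps when few shared gaps remain
      sharedPool <- c(sharedPool, isolated[seq_len(min(length(isolated),
                                                       nShared - length(sharedPool)))])
    }
    if (length(sharedPool) < nShared) {
      .stopf("not enough gene-free gaps for %d shared enhancers", nShared)
    }

    placeInGap <- function(j, id) {
      lo <- gaps$lo[j]; hi <- gaps$hi[j]
      w <- sample(200:1000, 1L)
      slack <- (hi - lo - 2L * hw - 200L) %/% 2L
      jit <- if (slack > 0) sample(-min(slack, 2000L):min(slack, 2000L), 1L) else 0L
      mid <- (lo + hi) %/% 2L + jit
      s0 <- mid - w %/% 2L
      data.frame(chrom = gaps$chrom[j], start = s0, end = s0 + w, id = id,
                 stringsAsFactors = FALSE)
    }
    placeOnGene <- function(gi, id) {
      mid <- (genes$start[gi] + genes$end[gi]) %/% 2L
      w <- sample(200:1000, 1L)
      s0 <- max(0L, mid - w %/% 2L)
      data.frame(chrom = genes$chrom[gi], start = s0, end = s0 + w, id = id,
                 stringsAsFactors = FALSE)
    }

    sharedGaps <- sharedPool[sample.int(length(sharedPool), nShared)]
    sharedEnh <- if (nShared) do.call(rbind, lapply(seq_len(nShared), function(k)
      placeInGap(sharedGaps[k], sprintf("shared_%03d", k)))) else NULL

    privPool <- sample(isolated)
    enhancers <- list()
    truthPer <- list()
    for (ri in seq_along(config@resources)) {
      r <- config@resources[ri]
      privGaps <- privPool[seq_len(nPrivGap) + (ri - 1L) * nPrivGap]
      priv <- list()
      if (nPrivGap) priv <- c(priv, lapply(seq_len(nPrivGap), function(k)
        placeInGap(privGaps[k], sprintf("priv_%s_gap%03d", r, k))))
      if (nPrivGene) {
        onGenes <- sample(nrow(genes), nPrivGene)
        priv <- c(priv, lapply(seq_len(nPrivGene), function(k)
          placeOnGene(onGenes[k], sprintf("priv_%s_gene%03d", r, k))))
      }
      enh <- rbind(sharedEnh, if (length(priv)) do.call(rbind, priv))
      rownames(enh) <- NULL
      enhancers[[r]] <- enh
      truthPer[[r]] <- .bruteForceErrgs(enh, genes, config@halfWidth,
                                        config@domainLength)
    }
    truthFinal <- sort(Reduce(intersect, truthPer))

    genesGr <- .grangesFromZero(genes$chrom, genes$start, genes$end,
                                gene_id = genes$gene_id,
                                gene_name = genes$gene_name,
                                biotype = genes$biotype,
                                strand = genes$strand)
    enhGr <- lapply(seq_along(enhancers), function(ri) {
      e <- enhancers[[ri]]
      .grangesFromZero(e$chrom, e$start, e$end, enhancer_id = e$id,
                       resource = rep(config@resources[ri], nrow(e)))
    })
    names(enhGr) <- config@resources
    list(genes = genesGr, enhancers = enhGr,
         truth = list(perResource = truthPer, final = truthFinal))
  })
}

#' Generate negative-binomial expression counts with planted signal
#'
#' Baseline per-gene means are log-normal; planted eRRGs (the truth
#' final set) get an `errgMeanFactor`-fold higher baseline, and a
#' chosen subset of them a tumor-specific fold change of
#' `+/- deLog2fc`. Counts are negative binomial with common dispersion.
#'
#' @param config a [SimConfig-class].
#' @param annotation list from [simulateAnnotation()].
#' @return list with `counts` (matrix), `groups` (named tumor/normal
#'   vector) and `deTruth` (list `up`, `down` of planted DE gene ids).
#' @export
simulateExpression <- function(config, annotation) {
  stopifnot(is(config, "SimConfig"))
  .withSeed(config@seed + 2, {
    geneIds <- annotation$genes$gene_id
    errgs <- annotation$truth$final
    nT <- as.integer(config@nTumor); nN <- as.integer(config@nNormal)
    samples <- c(sprintf("T%03d", seq_len(nT)), sprintf("N%03d", seq_len(nN)))
    groups <- setNames(rep(c("tumor", "normal"), c(nT, nN)), samples)
    base <- rlnorm(length(geneIds), config@exprMeanLog, config@exprSdLog)
    names(base) <- geneIds
    base[errgs] <- base[errgs] * config@errgMeanFactor
    nUp <- round(length(errgs) * config@deFracUp)
    nDown <- round(length(errgs) * config@deFracDown)
    deGenes <- sample(errgs, nUp + nDown)
    up <- sort(deGenes[seq_len(nUp)])
    down <- sort(deGenes[nUp + seq_len(nDown)])
    muT <- base; muN <- base
    muT[up] <- muT[up] * 2^config@deLog2fc
    muT[down] <- muT[down] * 2^(-config@deLog2fc)
    size <- 1 / config@nbDispersion
    counts <- cbind(
      matrix(rnbinom(length(base) * nT, mu = rep(muT, nT), size = size),
             nrow = length(base)),
      matrix(rnbinom(length(base) * nN, mu = rep(muN, nN), size = size),
             nrow = length(base))
    )
    dimnames(counts) <- list(geneIds, samples)
    list(counts = counts, groups = groups, deTruth = list(up = up, down = down))
  })
}

#' Generate the planted risk signature and the truth risk groups
#'
#' Draws `signatureSize` genes from the planted eRRG set with signed
#' coefficients, scores the tumor samples on `log2(count + 1)`, and
#' splits them at the median using the generator's own order-statistic
#' computation (independent of [medianSplit()]).
#'
#' @param config a [SimConfig-class].
#' @param annotation list from [simulateAnnotation()].
#' @param expression list from [simulateExpression()].
#' @return list with `signature` (`data.frame`), `scores` (named
#'   vector over tumor samples) and `groups` (named high/low vector).
#' @export
simulateSignature <- function(config, annotation, expression) {
  stopifnot(is(config, "SimConfig"))
  .withSeed(config@seed + 3, {
    pool <- annotation$truth$final
    if (length(pool) < config@signatureSize) {
      .stopf("fewer planted eRRGs (%d) than signature genes requested (%d)",
             length(pool), as.integer(config@signatureSize))
    }
    sigGenes <- sort(sample(pool, as.integer(config@signatureSize)))
    signature <- data.frame(
      gene_id = sigGenes,
      coefficient = round(runif(length(sigGenes), 0.3, 0.9), 4) *
        sample(c(-1, 1), length(sigGenes), replace = TRUE),
      stringsAsFactors = FALSE
    )
    tumor <- names(expression$groups)[expression$groups == "tumor"]
    lexpr <- log2(expression$counts[sigGenes, tumor, drop = FALSE] + 1)
    scores <- colSums(lexpr * signature$coefficient)
    s <- sort(scores)
    n <- length(s)
    med <- if (n %% 2L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
    groups <- setNames(ifelse(scores > med, "high", "low"), names(scores))
    list(signature = signature, scores = scores, groups = groups)
  })
}

.rtruncnorm01 <- function(n, mean, sd) {
  lo <- pnorm((0 - mean) / sd)
  hi <- pnorm((1 - mean) / sd)
  mean + sd * qnorm(lo + runif(n) * (hi - lo))
}

#' Generate beta values, probe map and MAF-like mutation records
#'
#' Betas are truncated normal on `[0, 1]` around per-probe baselines;
#' `nDmpProbes` planted probes shift the high-risk group mean by
#' `+/- dmpDelta` (half hypo-, half hypermethylated in high-risk).
#' Mutation records are drawn per gene and sample at the configured
#' rates, with the configured Silent/indel/SNV-class composition and
#' `VAF ~ U(0.05, 0.9)`.
#'
#' @param config a [SimConfig-class].
#' @param annotation list from [simulateAnnotation()].
#' @param groups named high/low vector over tumor samples.
#' @return list with `beta` (matrix), `probeMap` (`data.frame`),
#'   `maf` (`data.frame` as from [readMaf()]) and `truth` (lists
#'   `dmpHypo`, `dmpHyper` probe ids and `diffMutGenes`).
#' @export
simulateMethylationMutations <- function(config, annotation, groups) {
  stopifnot(is(config, "SimConfig"))
  .withSeed(config@seed + 4, {
    samples <- names(groups)
    hi <- groups == "high"
    nP <- as.integer(config@nProbes)
    nD <- as.integer(config@nDmpProbes)
    if (nD > nP) .stopf("nDmpProbes exceeds nProbes")
    probes <- sprintf("cg%06d", seq_len(nP))
    genesDf <- data.frame(
      gene_id = annotation$genes$gene_id,
      chrom = as.character(GenomicRanges::seqnames(annotation$genes)),
      start = .zeroStart(annotation$genes),
      stringsAsFactors = FALSE
    )
    mapIdx <- sample(nrow(genesDf), nP, replace = TRUE)
    hasGene <- runif(nP) < 0.6
    probeMap <- data.frame(
      probe_id = probes,
      chrom = genesDf$chrom[mapIdx],
      position = genesDf$start[mapIdx] + sample(0:1500, nP, replace = TRUE),
      gene_id = ifelse(hasGene, genesDf$gene_id[mapIdx], ""),
      stringsAsFactors = FALSE
    )
    dmpIdx <- sample(nP, nD)
    hypoIdx <- dmpIdx[seq_len(nD %/% 2L)]                 # lower in high-risk
    hyperIdx <- setdiff(dmpIdx, hypoIdx)
    baseMean <- runif(nP, 0.05, 0.95)
    baseMean[dmpIdx] <- runif(nD, 0.35, 0.62)
    meanMat <- matrix(baseMean, nrow = nP, ncol = length(samples))
    meanMat[hypoIdx, hi] <- meanMat[hypoIdx, hi] - config@dmpDelta
    meanMat[hyperIdx, hi] <- meanMat[hyperIdx, hi] + config@dmpDelta
    beta <- matrix(.rtruncnorm01(length(meanMat), as.vector(meanMat),
                                 config@betaSd),
                   nrow = nP, dimnames = list(probes, samples))

    geneIds <- genesDf$gene_id
    diffGenes <- sort(sample(geneIds, as.integer(config@nDiffMutGenes)))
    rateMat <- matrix(config@mutBackgroundRate, nrow = length(geneIds),
                      ncol = length(samples),
                      dimnames = list(geneIds, samples))
    rateMat[diffGenes, hi] <- config@mutRateHigh
    rateMat[diffGenes, !hi] <- config@mutRateLow
    mut <- matrix(runif(length(rateMat)) < rateMat, nrow = length(geneIds))
    idx <- which(mut, arr.ind = TRUE)
    nRec <- nrow(idx)
    makeRecords <- function(gene_i, sample_i) {
      n <- length(gene_i)
      cls <- character(n); type <- character(n)
      ref <- character(n); alt <- character(n)
      u <- runif(n)
      isIndel <- u < config@indelFraction
      isSilent <- !isIndel & u < config@indelFraction + config@silentFraction
      isDel <- isIndel & runif(n) < 0.5
      type[isIndel] <- ifelse(isDel[isIndel], "DEL", "INS")
      cls[isIndel] <- ifelse(isDel[isIndel], "Frame_Shift_Del", "Frame_Shift_Ins")
      ref[isIndel] <- ifelse(isDel[isIndel], "AC", "-")
      alt[isIndel] <- ifelse(isDel[isIndel], "-", "AC")
      snp <- !isIndel
      type[snp] <- "SNP"
      cls[isSilent] <- "Silent"
      cls[snp & !isSilent] <- ifelse(runif(sum(snp & !isSilent)) < 0.85,
                                     "Missense_Mutation", "Nonsense_Mutation")
      if (any(snp)) {
        classes <- sample(.SNV_CLASSES, sum(snp), replace = TRUE,
                          prob = config@snvClassMix)
        refs <- substr(classes, 1L, 1L)
        alts <- substr(classes, 3L, 3L)
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        flip <- runif(sum(snp)) < 0.5  # represent half on the purine strand
        ref[snp] <- ifelse(flip, comp[refs], refs)
        alt[snp] <- ifelse(flip, comp[alts], alts)
      }
      gi <- match(geneIds[gene_i], genesDf$gene_id)
      data.frame(
        sample = samples[sample_i],
        gene_id = geneIds[gene_i],
        chrom = genesDf$chrom[gi],
        position = genesDf$start[gi] + sample(0:1500, n, replace = TRUE),
        ref = ref, alt = alt, variant_class = cls, variant_type = type,
        vaf = round(runif(n, 0.05, 0.9), 4),
        stringsAsFactors = FALSE
      )
    }
    maf <- makeRecords(idx[, 1L], idx[, 2L])
    # occasional second hit in the same gene/sample exercises binarization
    dupPick <- which(runif(nRec) < 0.1)
    if (length(dupPick)) {
      maf <- rbind(maf, makeRecords(idx[dupPick, 1L], idx[dupPick, 2L]))
    }
    maf <- maf[order(maf$sample, maf$gene_id, maf$position), , drop = FALSE]
    rownames(maf) <- NULL
    list(beta = beta, probeMap = probeMap, maf = maf,
         truth = list(dmpHypo = sort(probes[hypoIdx]),
                      dmpHyper = sort(probes[hyperIdx]),
                      diffMutGenes = diffGenes))
  })
}

#' Generate exponential survival times from a linear predictor
#'
#' Event times are exponential with hazard
#' `baselineHazard * exp(linearPredictor)`; a seeded
#' `Bernoulli(censorFraction)` subset of samples is censored at a
#' uniform fraction of its event time.
#'
#' @param config a [SimConfig-class].
#' @param linearPredictor named numeric vector (one value per sample).
#' @return `data.frame` with columns `sample`, `time`, `event`.
#' @export
simulateSurvival <- function(config, linearPredictor) {
  stopifnot(is(config, "SimConfig"))
  if (is.null(names(linearPredictor))) .stopf("linearPredictor must be named by sample")
  .withSeed(config@seed + 5, {
    n <- length(linearPredictor)
    rate <- config@baselineHazard * exp(linearPredictor)
    time <- rexp(n, rate)
    event <- rep(1L, n)
    cen <- runif(n) < config@censorFraction
    time[cen] <- time[cen] * runif(sum(cen))
    event[cen] <- 0L
    time <- pmax(time, 1e-3)
    data.frame(sample = names(linearPredictor), time = time, event = event,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study with ground truth
#'
#' Runs every generator in sequence (annotation, expression, planted
#' signature and risk groups, methylation and mutations, survival) and
#' optionally writes all pipeline input files plus `truth.json` to a
#' directory.
#'
#' @param config a [SimConfig-class].
#' @param outDir optional output directory; created if needed and
#'   populated via [writeSimulation()].
#' @return list with `genes`, `enhancers`, `counts`, `groups`, `beta`,
#'   `probeMap`, `maf`, `survival`, `signature`, `riskScores`,
#'   `riskGroups`, and `truth` (per-resource and final eRRG sets,
#'   planted DE genes, DMP probes, differential-mutation genes, risk
#'   groups).
#' @examples
#' \donttest{
#' sim <- simulateErrgStudy(simConfig(seed = 7, nTumor = 40, nNormal = 10,
#'                                    nProbes = 200, nGenes = 200,
#'                                    nEnhancers = 30))
#' length(sim$truth$final)
#' }
#' @export
simulateErrgStudy <- function(config, outDir = NULL) {
  stopifnot(is(config, "SimConfig"))
  ann <- simulateAnnotation(config)
  expr <- simulateExpression(config, ann)
  sig <- simulateSignature(config, ann, expr)
  mm <- simulateMethylationMutations(config, ann, sig$groups)
  lp <- if (stats::sd(sig$scores) > 0) {
    config@survivalEffect * (sig$scores - mean(sig$scores)) / stats::sd(sig$scores)
  } else {
    setNames(rep(0, length(sig$scores)), names(sig$scores))
  }
  surv <- simulateSurvival(config, lp)
  sim <- list(
    genes = ann$genes,
    enhancers = ann$enhancers,
    counts = expr$counts,
    groups = expr$groups,
    beta = mm$beta,
    probeMap = mm$probeMap,
    maf = mm$maf,
    survival = surv,
    signature = sig$signature,
    riskScores = sig$scores,
    riskGroups = sig$groups,
    truth = list(
      perResource = ann$truth$perResource,
      final = ann$truth$final,
      deUp = expr$deTruth$up,
      deDown = expr$deTruth$down,
      dmpHypo = mm$truth$dmpHypo,
      dmpHyper = mm$truth$dmpHyper,
      diffMutGenes = mm$truth$diffMutGenes,
      riskGroups = as.list(sig$groups)
    ),
    config = config
  )
  if (!is.null(outDir)) writeSimulation(sim, outDir)
  sim
}

#' Write a simulated study to pipeline input files
#'
#' Emits the gene table (TSV dialect), one BED per enhancer resource,
#' the counts, groups, beta, probe-map, MAF-like mutation, survival and
#' signature tables, and `truth.json`. Identical configs produce
#' byte-identical files.
#'
#' @param sim list from [simulateErrgStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  writeGeneTable(sim$genes, fp("genes.tsv"))
  for (r in names(sim$enhancers)) {
    e <- sim$enhancers[[r]]
    write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(e)),
                           start = .zeroStart(e), end = .zeroEnd(e),
                           id = e$enhancer_id),
                fp(paste0("enhancers_", r, ".bed")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  writeMatrix <- function(m, idCol, path) {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    colnames(df)[1L] <- idCol
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeMatrix(sim$counts, "gene_id", fp("counts.tsv"))
  write.table(data.frame(sample = names(sim$groups), group = sim$groups),
              fp("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeMatrix(round(sim$beta, 6), "probe_id", fp("beta.tsv"))
  write.table(sim$probeMap, fp("probe_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  maf <- data.frame(
    Tumor_Sample_Barcode = sim$maf$sample,
    Hugo_Symbol = sim$maf$gene_id,
    Chromosome = sim$maf$chrom,
    Start_Position = sim$maf$position,
    Reference_Allele = sim$maf$ref,
    Tumor_Seq_Allele2 = sim$maf$alt,
    Variant_Classification = sim$maf$variant_class,
    Variant_Type = sim$maf$variant_type,
    t_alt_count = round(sim$maf$vaf * 1000),
    t_depth = 1000L
  )
  write.table(maf, fp("mutations.maf.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$survival, fp("survival.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$signature, fp("signature.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated study back from files
#'
#' Inverse of [writeSimulation()]: reloads every pipeline input (and
#' `truth.json` when present) from a directory.
#'
#' @param dir directory written by [writeSimulation()].
#' @return list shaped like the output of [simulateErrgStudy()]
#'   (without `config`; `riskScores`/`riskGroups` are recovered from
#'   the truth file when present).
#' @export
readSimulation <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  beds <- list.files(dir, pattern = "^enhancers_.*\\.bed$")
  resources <- sub("^enhancers_(.*)\\.bed$", "\\1", beds)
  enhancers <- setNames(lapply(seq_along(beds), function(i)
    readEnhancerBed(fp(beds[i]), resource = resources[i])), resources)
  out <- list(
    genes = readGeneTable(fp("genes.tsv"), dialect = "tsv"),
    enhancers = enhancers,
    counts = readExpressionMatrix(fp("counts.tsv")),
    groups = readSampleGroups(fp("groups.tsv")),
    beta = readBetaMatrix(fp("beta.tsv")),
    probeMap = readProbeMap(fp("probe_map.tsv")),
    maf = readMaf(fp("mutations.maf.tsv")),
    survival = readSurvivalTable(fp("survival.tsv")),
    signature = readSignature(fp("signature.tsv"))
  )
  if (file.exists(fp("truth.json"))) {
    tr <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
    tr$riskGroups <- unlist(tr$riskGroups)
    out$truth <- tr
    out$riskGroups <- tr$riskGroups
  }
  out
}
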