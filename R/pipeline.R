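# End-to-end orchestration over a simulated (or file-based) study.

#' Run the full eRRG pipeline on a study bundle
#'
#' Chains every stage on a study as produced by [simulateErrgStudy()]
#' or reloaded with [readSimulation()]: eRRG identification across
#' resources, expression filtering, the random-gene mean/CV contrast,
#' the built-in DE stage with thresholding and the resampling null,
#' the signature risk score with median split, differential methylation
#' and mutation contrasts between the risk groups, and the
#' Kaplan-Meier / log-rank survival comparison.
#'
#' @param sim study list (`genes`, `enhancers`, `counts`, `groups`,
#'   `beta`, `probeMap`, `maf`, `survival`, `signature`; `truth`
#'   optional) — from [simulateErrgStudy()] or [readSimulation()].
#' @param halfWidth,domainLength see [identifyErrgs()].
#' @param fcCut,fdrCut DE thresholds, see [applyDeThresholds()].
#' @param dbetaCut methylation effect cutoff, see [callDmps()].
#' @param nRandomSets random sets for the mean/CV contrast.
#' @param nResampleReps draws for the DE-count resampling null.
#' @param topKCooccur genes in the co-occurrence screen.
#' @param minMutated testing floor for differential mutation.
#' @param seed seed for the two resampling stages.
#' @param outJson optional path; the summary is written there as JSON.
#' @return list with the per-stage results (`assignment`, `expression`,
#'   `de`, `risk`, `methylation`, `mutation`, `survival`) and a flat
#'   machine-readable `summary` of the headline counts.
#' @export
runErrgPipeline <- function(sim, halfWidth = 3000L, domainLength = 185000L,
                            fcCut = 1, fdrCut = 0.05, dbetaCut = 0.15,
                            nRandomSets = 100L, nResampleReps = 1000L,
                            topKCooccur = 15L, minMutated = 5L,
                            seed = 1L, outJson = NULL) {
  asn <- identifyErrgs(sim$enhancers, sim$genes,
                       halfWidth = halfWidth, domainLength = domainLength)
  errgs <- filterUnexpressed(sim$counts, errgFinal(asn))
  universe <- filterUnexpressed(sim$counts)
  cmp <- compareToRandomSets(sim$counts, errgs, universe = universe,
                             nSets = nRandomSets, seed = seed)

  de <- deStats(sim$counts, sim$groups)
  calls <- applyDeThresholds(de, fcCut = fcCut, fdrCut = fdrCut)
  errgUp <- intersect(calls$up, errgs)
  errgDown <- intersect(calls$down, errgs)
  nullDe <- resampleDeCounts(calls, universe = universe,
                             setSize = length(errgs),
                             nReps = nResampleReps, seed = seed)

  tumor <- names(sim$groups)[sim$groups == "tumor"]
  scores <- riskScore(log2(sim$counts[, tumor, drop = FALSE] + 1),
                      sim$signature)
  riskGroups <- medianSplit(scores)

  dmp <- callDmps(sim$beta, riskGroups, dbetaCut = dbetaCut,
                  fdrCut = fdrCut, probeMap = sim$probeMap)
  mm <- mutationMatrix(sim$maf, samples = tumor)
  dm <- differentialMutation(mm$matrix, riskGroups, minMutated = minMutated)
  burden <- mutationBurdenContrast(mm, riskGroups)
  co <- cooccurrence(mm$matrix, topK = topKCooccur)

  surv <- sim$survival
  stopifnot(all(surv$sample %in% names(riskGroups)))
  g <- riskGroups[surv$sample]
  lr <- logrankTest(g, surv$time, surv$event)
  km <- lapply(split(seq_len(nrow(surv)), g), function(i)
    kmCurve(surv$time[i], surv$event[i]))

  summary <- list(
    n_errgs_final = length(errgFinal(asn)),
    n_errg_pcg = errgSummary(asn)$final$protein_coding,
    n_errg_lncrna = errgSummary(asn)$final$lncRNA,
    n_errgs_expressed = length(errgs),
    errg_mean = cmp$errgMean, random_mean = cmp$randomMean,
    errg_cv = cmp$errgCv, random_cv = cmp$randomCv,
    p_mean = cmp$pMean, p_cv = cmp$pCv,
    n_errg_up = length(errgUp), n_errg_down = length(errgDown),
    random_mean_up = nullDe$meanUp, random_mean_down = nullDe$meanDown,
    n_high_risk = sum(riskGroups == "high"),
    n_low_risk = sum(riskGroups == "low"),
    n_dmp_hyper = dmp$nHyper, n_dmp_hypo = dmp$nHypo,
    n_diff_mut_genes = sum(dm$call),
    n_cooccurring_p05 = sum(co$label == "co-occurring" & co$pvalue < 0.05),
    n_exclusive_p05 = sum(co$label == "exclusive" & co$pvalue < 0.05),
    logrank_chisq = lr$chisq, logrank_p = lr$p.value
  )
  if (!is.null(outJson)) {
    jsonlite::write_json(summary, outJson, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(assignment = asn,
       expression = list(errgs = errgs, universe = universe, randomSets = cmp),
       de = list(table = calls$table, up = calls$up, down = calls$down,
                 errgUp = errgUp, errgDown = errgDown, resampleNull = nullDe),
       risk = list(scores = scores, groups = riskGroups),
       methylation = dmp,
       mutation = list(matrix = mm, differential = dm, burden = burden,
                       cooccurrence = co),
       survival = list(logrank = lr, km = km),
       summary = summary)
}
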