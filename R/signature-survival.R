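# Gene-signature risk score, median split, Kaplan-Meier and log-rank.

#' Read a gene-signature coefficient table
#'
#' Tab-separated two-column table `gene_id`, `coefficient`.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `gene_id`, `coefficient`.
#' @export
readSignature <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("gene_id", "coefficient") %in% colnames(tab))) {
    .stopf("signature %s needs columns 'gene_id' and 'coefficient'", path)
  }
  tab$gene_id <- as.character(tab$gene_id)
  tab$coefficient <- as.numeric(tab$coefficient)
  if (anyDuplicated(tab$gene_id)) .stopf("duplicate signature gene ids in %s", path)
  if (!nrow(tab)) .stopf("empty signature in %s", path)
  tab
}

#' Read a survival table
#'
#' Tab-separated with columns `sample`, `time` (> 0) and `event`
#' (0 = censored, 1 = event).
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `sample`, `time`, `event`.
#' @export
readSurvivalTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t")
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(tab))) {
    .stopf("survival table %s needs columns: %s", path, paste(need, collapse = ", "))
  }
  tab$sample <- as.character(tab$sample)
  tab$time <- as.numeric(tab$time)
  tab$event <- as.integer(tab$event)
  if (any(tab$time <= 0)) .stopf("survival times must be > 0 in %s", path)
  if (!all(tab$event %in% c(0L, 1L))) .stopf("event must be 0/1 in %s", path)
  tab[, need]
}

#' Linear risk score from a fixed gene signature
#'
#' `score_s = sum_g coefficient_g * expr[g, s]` — a plain linear
#' predictor in whatever expression unit the coefficients were trained
#' on (the caller's responsibility). Every signature gene must be
#' present in the matrix.
#'
#' @param expr expression matrix (genes x samples) or a named vector
#'   for a single sample.
#' @param signature `data.frame` with columns `gene_id`, `coefficient`.
#' @return named numeric vector of per-sample scores (or a single
#'   number for vector input).
#' @export
riskScore <- function(expr, signature) {
  if (!all(c("gene_id", "coefficient") %in% colnames(signature))) {
    .stopf("signature needs columns 'gene_id' and 'coefficient'")
  }
  vec <- is.null(dim(expr))
  if (vec) expr <- matrix(expr, ncol = 1L, dimnames = list(names(expr), "sample"))
  missing <- setdiff(signature$gene_id, rownames(expr))
  if (length(missing)) {
    .stopf("signature genes absent from the expression matrix: %s",
           paste(missing, collapse = ", "))
  }
  scores <- colSums(expr[signature$gene_id, , drop = FALSE] * signature$coefficient)
  if (vec) unname(scores) else scores
}

#' Split samples at the median risk score
#'
#' Scores strictly above the median go to the `high` group, the rest
#' (including exact ties with the median) to `low`; for an even number
#' of samples the median is the midpoint of the two central order
#' statistics.
#'
#' @param scores named numeric vector of risk scores (>= 2 samples).
#' @return named factor with levels `c("low", "high")`.
#' @export
medianSplit <- function(scores) {
  if (length(scores) < 2L) .stopf("at least 2 samples are required")
  if (anyNA(scores)) .stopf("missing risk scores are not allowed")
  if (length(unique(scores)) == 1L) {
    .stopf("all risk scores are identical; no median split is possible")
  }
  med <- median(scores)
  setNames(factor(ifelse(scores > med, "high", "low"),
                  levels = c("low", "high")),
           names(scores))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; samples censored at
#' an event time are counted at risk for that time.
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @return `data.frame` with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, one row per distinct observed time.
#' @export
kmCurve <- function(times, events) {
  if (any(times <= 0)) .stopf("times must be > 0")
  if (!all(events %in% c(0, 1))) .stopf("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic accumulated over
#' event times with the hypergeometric variance, referred to a
#' chi-square distribution with 1 df.
#'
#' @param groups two-level factor (or vector) of group labels.
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @return list with `chisq`, `df` (1), `p.value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrankTest <- function(groups, times, events) {
  g <- droplevels(factor(groups))
  if (nlevels(g) != 2L) .stopf("exactly two groups are required")
  if (any(times <= 0)) .stopf("times must be > 0")
  if (!all(events %in% c(0, 1))) .stopf("events must be 0/1")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = unname(sd$chisq), df = 1L,
       p.value = pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       observed = setNames(as.numeric(sd$obs), levels(g)),
       expected = setNames(as.numeric(sd$exp), levels(g)))
}
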