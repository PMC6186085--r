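#' Read or validate patient metadata
#'
#' Patient records carry id, TP53 status (`wt`/`mut`), chemotherapy flag,
#' survival time in days after surgery, an event flag (1 = death observed,
#' 0 = censored) and tumour stage 1-4 (may be missing). If the `event` column
#' is absent every patient is treated as an observed event, with a loud
#' warning: Pearson correlations against survival time ignore censoring
#' anyway, but Cox regression honours it, so an explicit flag is strongly
#' preferred.
#'
#' @param records data.frame with columns `id`, `p53_status`, `chemo`,
#'   `survival_days`, and optionally `event` and `stage`.
#' @return The validated data.frame (with `event` filled in if missing).
#' @export
patient_records <- function(records) {
  req <- c("id", "p53_status", "chemo", "survival_days")
  if (!all(req %in% names(records)))
    stop("patient records need columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(records$id))
    stop("duplicate patient ids")
  if (!all(records$p53_status %in% c("wt", "mut")))
    stop("p53_status must be 'wt' or 'mut'")
  records$chemo <- as.logical(records$chemo)
  if (any(records$survival_days <= 0))
    stop("survival_days must be positive")
  if (is.null(records$event)) {
    warning("no 'event' column: assuming every survival time is an ",
            "observed death (no censoring); Cox results will be biased ",
            "if any times are actually censored", call. = FALSE)
    records$event <- 1L
  }
  records$event <- as.integer(as.logical(records$event))
  if (!is.null(records$stage) &&
      !all(records$stage %in% c(1:4, NA)))
    stop("stage must be 1, 2, 3, 4 or missing")
  records
}

#' @rdname patient_records
#' @param path path to a tab-separated metadata file.
#' @export
read_patients <- function(path) {
  patient_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Stratify patients by TP53 status and chemotherapy
#'
#' Partitions a cohort into the four groups wild-type/mutant TP53 crossed
#' with treated/untreated by chemotherapy. Empty groups are allowed (real
#' cohorts can have, e.g., a single mutant treated patient) and flagged with
#' a warning.
#'
#' @param records patient metadata (see [patient_records()]).
#' @return Named list of four data.frames: `wt_chemo`, `wt_nochemo`,
#'   `mut_chemo`, `mut_nochemo`.
#' @export
stratify_patients <- function(records) {
  records <- patient_records(records)
  groups <- list(
    wt_chemo = records[records$p53_status == "wt" & records$chemo, ],
    wt_nochemo = records[records$p53_status == "wt" & !records$chemo, ],
    mut_chemo = records[records$p53_status == "mut" & records$chemo, ],
    mut_nochemo = records[records$p53_status == "mut" & !records$chemo, ])
  empty <- names(groups)[vapply(groups, nrow, 0L) == 0]
  if (length(empty))
    warning("empty patient group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  groups
}

#' Pearson correlation of gene scores with survival time
#'
#' For each gene, the Pearson correlation coefficient between its per-patient
#' score and survival time in days. Censoring is ignored here (the companion
#' Cox analysis honours it). Genes whose scores have zero variance across the
#' patients are skipped with a message. Results are ranked ascending by `r`,
#' so the strongest negative survival correlations come first.
#'
#' @param scores numeric matrix, genes x patients (column names are patient
#'   ids).
#' @param records patient metadata for the patients to use (e.g. one stratum
#'   from [stratify_patients()]); at least 3 patients.
#' @param genes optional subset of genes (default: all rows of `scores`).
#' @return data.frame with columns `gene`, `r`, sorted ascending by `r`.
#' @export
correlate_scores_with_survival <- function(scores, records, genes = NULL) {
  records <- patient_records(records)
  if (nrow(records) < 3)
    stop("need at least 3 patients for a correlation")
  missing_p <- setdiff(records$id, colnames(scores))
  if (length(missing_p))
    stop("patients without score columns: ",
         paste(missing_p, collapse = ", "))
  if (is.null(genes)) genes <- rownames(scores)
  x <- scores[genes, records$id, drop = FALSE]
  surv <- records$survival_days
  if (stats::var(surv) == 0)
    stop("survival times have zero variance")
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    message(sum(v == 0), " zero-variance gene(s) skipped")
  keep <- v > 0
  r <- apply(x[keep, , drop = FALSE], 1, stats::cor, y = surv)
  out <- data.frame(gene = genes[keep], r = as.numeric(r), row.names = NULL)
  out[order(out$r), , drop = FALSE]
}

#' Univariate Cox proportional-hazards regression for one gene
#'
#' Fits survival ~ score by Cox partial likelihood (Breslow tie handling) and
#' reports the regression coefficient beta, the hazard ratio `exp(beta)` with
#' its 95% Wald confidence interval, and the Wald-test p-value. A hazard
#' ratio above 1 means higher scores associate with worse survival.
#'
#' @param score numeric vector of per-patient gene scores, named by patient
#'   id or aligned with `records`.
#' @param records patient metadata with survival and event columns; at least
#'   two observed events.
#' @param ties tie-handling method passed to [survival::coxph()]
#'   (default `"breslow"`).
#' @return A one-row data.frame of class `cox_result`: `beta`, `hr`,
#'   `ci_low`, `ci_high`, `wald_p`.
#' @export
univariate_cox <- function(score, records, ties = "breslow") {
  records <- patient_records(records)
  if (!is.null(names(score))) score <- score[records$id]
  if (length(score) != nrow(records))
    stop("score vector does not match patient records")
  if (sum(records$event) < 2) stop("need at least 2 observed events")
  if (stats::var(score) == 0)
    stop("constant covariate carries no information")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(records$survival_days, records$event) ~
                      score, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("Cox fit did not converge (monotone likelihood / separation)",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  out <- data.frame(beta = beta, hr = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    wald_p = stats::pchisq((beta / se)^2, df = 1,
                                           lower.tail = FALSE))
  class(out) <- c("cox_result", class(out))
  out
}

#' Univariate Cox regression for a set of genes
#'
#' Applies [univariate_cox()] per gene; genes whose fit fails (constant
#' covariate, separation) are skipped with a message.
#'
#' @param scores numeric matrix, genes x patients.
#' @param records patient metadata.
#' @param genes optional subset of genes.
#' @inheritParams univariate_cox
#' @return data.frame with columns `gene`, `beta`, `hr`, `ci_low`,
#'   `ci_high`, `wald_p`, `prognosis`.
#' @export
cox_table <- function(scores, records, genes = NULL, ties = "breslow") {
  records <- patient_records(records)
  if (is.null(genes)) genes <- rownames(scores)
  rows <- lapply(genes, function(g) {
    res <- tryCatch(univariate_cox(scores[g, records$id], records,
                                   ties = ties),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(data.frame(gene = g), as.data.frame(res),
          data.frame(prognosis = interpret_hr(res$hr)))
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped) message(skipped, " gene(s) skipped (degenerate Cox fit)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prognostic interpretation of a hazard ratio
#'
#' @param hr hazard ratio (or a `cox_result`).
#' @return `"good prognostic factor"` if HR < 1 (higher score associates
#'   with better survival), `"bad prognostic factor"` if HR > 1,
#'   `"no effect"` if HR = 1.
#' @examples
#' interpret_hr(0.97)
#' interpret_hr(1.59)
#' @export
interpret_hr <- function(hr) {
  if (inherits(hr, "cox_result")) hr <- hr$hr
  vapply(hr, function(h) {
    if (h < 1) "good prognostic factor"
    else if (h > 1) "bad prognostic factor"
    else "no effect"
  }, character(1))
}
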