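#' Compare gene score distributions across tumour stages
#'
#' For each gene, per-stage median scores, a one-way ANOVA p-value across the
#' stage groups, and a direction flag comparing the stage-4 and stage-3
#' medians (`positive` when the stage-4 median is higher, `negative` when
#' lower, `none` when equal or either stage is unavailable). Stages with
#' fewer than `min_per_stage` patients are excluded from the test; genes left
#' with fewer than two eligible stage groups are skipped with a message. A
#' gene with identical scores in every stage gets p = 1 by convention (no
#' evidence of a difference) rather than an undefined statistic.
#'
#' @param scores numeric matrix, genes x patients (column names are patient
#'   ids).
#' @param records patient metadata with a `stage` column (see
#'   [patient_records()]); patients with missing stage are ignored.
#' @param genes optional subset of genes.
#' @param min_per_stage minimum patients per stage group (default 2).
#' @return data.frame with columns `gene`, `median_s1` .. `median_s4`
#'   (`NA` where a stage has no patients), `anova_p`, `direction`.
#' @export
compare_stages <- function(scores, records, genes = NULL,
                           min_per_stage = 2) {
  records <- patient_records(records)
  if (is.null(records$stage) || all(is.na(records$stage)))
    stop("patient records carry no stage information")
  records <- records[!is.na(records$stage), , drop = FALSE]
  if (is.null(genes)) genes <- rownames(scores)
  stage <- records$stage
  sizes <- table(factor(stage, levels = 1:4))
  eligible <- as.integer(names(sizes))[sizes >= min_per_stage]
  excluded <- as.integer(names(sizes))[sizes > 0 & sizes < min_per_stage]
  if (length(excluded))
    message("stage(s) excluded from the test (fewer than ", min_per_stage,
            " patients): ", paste(excluded, collapse = ", "))

  rows <- lapply(genes, function(g) {
    x <- scores[g, records$id]
    med <- vapply(1:4, function(s)
      if (any(stage == s)) stats::median(x[stage == s]) else NA_real_,
      numeric(1))
    direction <- if (is.na(med[3]) || is.na(med[4]) || med[4] == med[3])
      "none" else if (med[4] > med[3]) "positive" else "negative"
    use <- stage %in% eligible
    if (length(unique(stage[use])) < 2) return(NULL)
    p <- if (stats::var(x[use]) == 0) 1 else {
      fit <- stats::lm(x[use] ~ factor(stage[use]))
      pv <- stats::anova(fit)[["Pr(>F)"]][1]
      if (is.na(pv)) 1 else pv
    }
    data.frame(gene = g, median_s1 = med[1], median_s2 = med[2],
               median_s3 = med[3], median_s4 = med[4],
               anova_p = p, direction = direction)
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped)
    message(skipped, " gene(s) skipped (fewer than 2 eligible stage groups)")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene had 2 or more eligible stage groups")
  rownames(out) <- NULL
  out
}
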