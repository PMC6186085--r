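#' End-to-end LSSA validation run
#'
#' Orchestrates the qualitative validation pipeline: restrict the DE table
#' to model genes, compute the steady state under both scenarios, derive
#' E_mod, call E_exp (if not already present), classify the per-gene errors
#' and summarise with the exact binomial significance value. When `out_dir`
#' is given, writes `lssa_validation.tsv` / `.json` (the summary),
#' `lssa_classes.tsv` (the per-gene table) and a `manifest.json` sufficient
#' to reproduce the run.
#'
#' @param net a [p53_network()] object.
#' @param de data.frame with columns `gene`, `log2fc`, `pvalue` (and
#'   optionally `eexp`).
#' @param scenario_pair list of two [lssa_scenario()] objects
#'   (source, target).
#' @param thresholds a [de_thresholds()] object.
#' @param out_dir optional output directory (created if needed).
#' @return A [validate_predictions()] summary (invisibly carries the
#'   per-gene classes as attribute `"classes"`).
#' @export
run_lssa_validation <- function(net, de, scenario_pair,
                                thresholds = de_thresholds(),
                                out_dir = NULL) {
  de <- map_genes_to_model(de, net)
  if (is.null(de$eexp)) de <- derive_eexp(de, thresholds)
  s1 <- lssa_steady_state(net, scenario_pair[[1]])
  s2 <- lssa_steady_state(net, scenario_pair[[2]])
  emod <- derive_emod(s1, s2)[de$gene]
  classes <- classify_predictions(emod, de)
  label <- sprintf("LSSA %s vs %s", scenario_label(scenario_pair[[2]]),
                   scenario_label(scenario_pair[[1]]))
  summary <- validate_predictions(classes, comparison = label)
  attr(summary, "classes") <- classes
  if (!is.null(out_dir))
    write_validation_outputs(out_dir, "lssa", summary, classes, de, emod,
                             scenario_pair, thresholds)
  summary
}

#' End-to-end STSFA validation run
#'
#' Semi-quantitative counterpart of [run_lssa_validation()]: score-flow
#' scores are computed for the two sample groups under the two scenarios,
#' the log10 score fold change is classified against the mean +/- sd limits
#' to give E_mod, and the result is compared with the experimental calls.
#'
#' @param net a [p53_network()] object.
#' @param mat expression matrix, genes x samples.
#' @param samples_a,samples_b columns of the source and target group.
#' @param de DE table between the two groups (`gene`, `log2fc`, `pvalue`).
#' @param scenario_pair list of two [lssa_scenario()] objects.
#' @param cfg an [stsfa_config()].
#' @param thresholds a [de_thresholds()] object.
#' @param scale expression scale, `"log_intensity"` or `"counts"`.
#' @param out_dir optional output directory.
#' @return A [validate_predictions()] summary.
#' @export
run_stsfa_validation <- function(net, mat, samples_a, samples_b, de,
                                 scenario_pair, cfg = stsfa_config(),
                                 thresholds = de_thresholds(),
                                 scale = "log_intensity", out_dir = NULL) {
  de <- map_genes_to_model(de, net)
  if (is.null(de$eexp)) de <- derive_eexp(de, thresholds)
  sc1 <- stsfa_score(mat, samples_a, net, scenario_pair[[1]], cfg,
                     scale = scale)
  sc2 <- stsfa_score(mat, samples_b, net, scenario_pair[[2]], cfg,
                     scale = scale)
  pred <- stsfa_emod(sc1, sc2, de$gene)
  classes <- classify_predictions(pred$emod, de)
  label <- sprintf("STSFA %s vs %s", scenario_label(scenario_pair[[2]]),
                   scenario_label(scenario_pair[[1]]))
  summary <- validate_predictions(classes, comparison = label)
  attr(summary, "classes") <- classes
  if (!is.null(out_dir))
    write_validation_outputs(out_dir, "stsfa", summary, classes, de,
                             pred$emod, scenario_pair, thresholds)
  summary
}

#' Per-patient survival and staging analysis
#'
#' Computes score-flow scores for every patient (DNA damage ON for
#' chemotherapy-treated patients, OFF otherwise; TP53 status taken from the
#' record), then: per-stratum Pearson correlations of gene scores with
#' survival time (strata below `min_group` patients are skipped with a
#' warning), a pooled univariate Cox table over all patients, and a
#' stage-comparison table (skipped with a warning when no stage information
#' is present).
#'
#' @param net a [p53_network()] object.
#' @param mat per-patient expression matrix, genes x patients (column names
#'   are patient ids).
#' @param records patient metadata (see [patient_records()]).
#' @param cfg an [stsfa_config()].
#' @param scale expression scale (default `"counts"` for RNA-seq).
#' @param min_group minimum stratum size for the Pearson tables (default 3).
#' @param genes optional subset of genes to report.
#' @param out_dir optional output directory.
#' @return A list with `scores` (genes x patients), `pearson` (named list of
#'   per-stratum data.frames), `cox` (pooled Cox table), `stages` (stage
#'   table or `NULL`), `groups` (stratum sizes).
#' @export
run_patient_analysis <- function(net, mat, records, cfg = stsfa_config(),
                                 scale = "counts", min_group = 3,
                                 genes = NULL, out_dir = NULL) {
  records <- patient_records(records)
  if (is.null(genes)) genes <- intersect(rownames(mat), model_genes(net))
  scores <- vapply(seq_len(nrow(records)), function(i) {
    sc <- lssa_scenario(if (records$p53_status[i] == "wt") "wt" else "null",
                        if (records$chemo[i]) "ON" else "OFF")
    stsfa_score(mat, records$id[i], net, sc, cfg, scale = scale)$final[genes]
  }, numeric(length(genes)))
  dimnames(scores) <- list(genes, records$id)

  strata <- stratify_patients(records)
  sizes <- vapply(strata, nrow, 0L)
  message("patient groups: ",
          paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  pearson <- lapply(names(strata), function(nm) {
    if (nrow(strata[[nm]]) < min_group) {
      warning("group ", nm, " below minimum size (",
              nrow(strata[[nm]]), " < ", min_group, "); skipped",
              call. = FALSE)
      return(NULL)
    }
    correlate_scores_with_survival(scores, strata[[nm]], genes)
  })
  names(pearson) <- names(strata)

  cox <- cox_table(scores, records, genes)
  stages <- if (is.null(records$stage) || all(is.na(records$stage))) {
    warning("no stage information; staging analysis skipped", call. = FALSE)
    NULL
  } else {
    compare_stages(scores, records, genes)
  }

  out <- list(scores = scores, pearson = pearson, cox = cox,
              stages = stages, groups = sizes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(data.frame(gene = rownames(scores), scores,
                         check.names = FALSE),
              file.path(out_dir, "patient_scores.tsv"))
    for (nm in names(pearson))
      if (!is.null(pearson[[nm]]))
        write_tsv(pearson[[nm]],
                  file.path(out_dir, paste0("pearson_", nm, ".tsv")))
    write_tsv(cox, file.path(out_dir, "cox.tsv"))
    if (!is.null(stages)) write_tsv(stages, file.path(out_dir, "stages.tsv"))
    write_manifest(out_dir, list(analysis = "patient",
                                 n_patients = nrow(records),
                                 genes = length(genes),
                                 groups = as.list(sizes),
                                 stsfa = unclass(cfg)))
  }
  out
}

#' Static drug-target reference table
#'
#' Approved drugs directly targeting genes flagged as negative survival
#' correlates (a packaged join table; no live database queries).
#'
#' @return data.frame with columns `gene`, `drug`.
#' @export
drug_targets <- function() {
  utils::read.delim(system.file("extdata", "drug_targets.tsv",
                                package = "p53flow"),
                    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, extra) {
  manifest <- c(list(
    package = "p53flow",
    version = as.character(utils::packageVersion("p53flow")),
    r_version = R.version.string,
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_validation_outputs <- function(out_dir, prefix, summary, classes, de,
                                     emod, scenario_pair, thresholds) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(summary),
            file.path(out_dir, paste0(prefix, "_validation.tsv")))
  jsonlite::write_json(unclass(as.data.frame(summary)),
                       file.path(out_dir, paste0(prefix, "_validation.json")),
                       auto_unbox = TRUE, digits = NA)
  genes <- names(classes)
  eexp <- stats::setNames(de$eexp, de$gene)
  write_tsv(data.frame(gene = genes, emod = as.integer(emod[genes]),
                       eexp = as.integer(eexp[genes]),
                       error_class = as.integer(classes)),
            file.path(out_dir, paste0(prefix, "_classes.tsv")))
  write_manifest(out_dir, list(
    analysis = prefix,
    scenarios = lapply(scenario_pair, unclass),
    thresholds = unclass(thresholds),
    n_genes = summary$n_genes))
}
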