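#' Specification of a synthetic two-condition expression experiment
#'
#' Describes a simulated two-condition experiment over the genes of a
#' network, emulating a cell line assayed untreated vs. treated with a
#' DNA-damaging drug. The generator first computes the model prediction
#' E_mod for every gene between the two scenarios, then draws group means so
#' that the differential-expression pipeline is expected to reproduce E_mod
#' for a controlled fraction of genes (`concordance`); each discordant gene
#' is assigned uniformly one of the two wrong calls. Defaults reflect a
#' typical small microarray experiment: triplicate arrays, within-group sd
#' of 0.25 on the log2 scale, a 2-fold effect for truly changed genes, and a
#' concordance of 0.75 in line with prediction rates typically observed for
#' this kind of network superimposition.
#'
#' @param network a [p53_network()] object.
#' @param scenario_pair list of two [lssa_scenario()] objects (source,
#'   target).
#' @param concordance fraction of genes whose intended call equals E_mod.
#' @param n_replicates samples per condition.
#' @param noise_sd within-group standard deviation on the log2 scale.
#' @param effect_size log2 fold-change magnitude of non-null genes; must
#'   exceed `log2(1.5)` for the calls to be recoverable.
#' @param seed integer seed.
#' @return A list of class `synth_experiment_spec`.
#' @export
synth_experiment_spec <- function(network,
                                  scenario_pair = list(
                                    lssa_scenario("wt", "OFF"),
                                    lssa_scenario("wt", "ON")),
                                  concordance = 0.75, n_replicates = 3,
                                  noise_sd = 0.25, effect_size = 1,
                                  seed = 1) {
  stopifnot(inherits(network, "p53net"),
            length(scenario_pair) == 2,
            inherits(scenario_pair[[1]], "lssa_scenario"),
            inherits(scenario_pair[[2]], "lssa_scenario"))
  if (concordance < 0 || concordance > 1)
    stop("concordance must be in [0, 1]")
  if (effect_size <= log2(1.5))
    stop("effect_size must exceed log2(1.5) for calls to be recoverable")
  structure(list(network = network, scenario_pair = scenario_pair,
                 concordance = concordance, n_replicates = n_replicates,
                 noise_sd = noise_sd, effect_size = effect_size,
                 seed = seed),
            class = "synth_experiment_spec")
}

#' Generate a synthetic two-condition expression experiment
#'
#' @param spec a [synth_experiment_spec()].
#' @return A list with elements `matrix` (genes x samples, log2 scale),
#'   `groups` (named sample-to-group vector with labels `"control"` and
#'   `"treated"`), `truth` (data.frame gene / emod / intended call) and
#'   `scenario_pair`.
#' @export
generate_expression_experiment <- function(spec) {
  stopifnot(inherits(spec, "synth_experiment_spec"))
  net <- spec$network
  genes <- model_genes(net)
  if (!length(genes)) stop("network has no gene nodes")
  s1 <- lssa_steady_state(net, spec$scenario_pair[[1]])
  s2 <- lssa_steady_state(net, spec$scenario_pair[[2]])
  emod <- derive_emod(s1, s2)[genes]

  set.seed(spec$seed)
  concordant <- stats::runif(length(genes)) < spec$concordance
  intended <- ifelse(concordant, emod, NA_integer_)
  for (i in which(!concordant))
    intended[i] <- sample(setdiff(c(-1L, 0L, 1L), emod[i]), 1)

  n <- spec$n_replicates
  base <- stats::runif(length(genes), 6, 10)
  mu_a <- base
  mu_b <- base + intended * spec$effect_size
  mat <- cbind(
    matrix(stats::rnorm(length(genes) * n, mu_a, spec$noise_sd),
           ncol = n),
    matrix(stats::rnorm(length(genes) * n, mu_b, spec$noise_sd),
           ncol = n))
  rownames(mat) <- genes
  colnames(mat) <- c(paste0("ctrl_", seq_len(n)), paste0("trt_", seq_len(n)))
  groups <- stats::setNames(rep(c("control", "treated"), each = n),
                            colnames(mat))
  list(matrix = mat, groups = groups,
       truth = data.frame(gene = genes, emod = as.integer(emod),
                          intended = as.integer(intended),
                          row.names = NULL),
       scenario_pair = spec$scenario_pair)
}

#' Specification of a synthetic patient cohort
#'
#' Describes a simulated cohort with per-patient expression, TP53 status,
#' chemotherapy, tumour stage and survival. Defaults mirror a 71-patient
#' mesothelioma surgical cohort: 27 wild-type treated, 26 wild-type
#' untreated, 1 mutant treated and 17 mutant untreated patients. Survival
#' times are exponential with per-patient hazard
#' `base_hazard * exp(sum(beta_g * z_g))` over the driver genes, where `z_g`
#' is the patient's score-flow score for gene g standardised across the
#' cohort (so beta is a log-hazard per score standard deviation and
#' comparable across genes). A requested fraction of patients is censored
#' uniformly over their survival time. Designated stage-effect genes have
#' their log2 expression shifted in stage-4 patients.
#'
#' @param n_patients cohort size (>= 8).
#' @param group_fractions numeric of length 4 summing to 1, named
#'   `wt_chemo`, `wt_nochemo`, `mut_chemo`, `mut_nochemo`.
#' @param driver_genes named numeric vector: true beta (log-hazard per score
#'   sd) for each survival driver gene; may be empty.
#' @param censoring_fraction fraction of patients censored, in [0, 1).
#' @param stage_effect_genes named numeric vector: shift (in units of the
#'   expression sd) applied to each gene's log2 expression in stage-4
#'   patients; may be empty.
#' @param base_hazard baseline hazard per day (default 1/700, a median
#'   survival of about 485 days for a null patient).
#' @param expr_sd per-gene between-patient sd of log2 expression
#'   (default 1).
#' @param seed integer seed.
#' @return A list of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_patients = 71,
                              group_fractions = c(wt_chemo = 27,
                                                  wt_nochemo = 26,
                                                  mut_chemo = 1,
                                                  mut_nochemo = 17) / 71,
                              driver_genes = numeric(0),
                              censoring_fraction = 0.3,
                              stage_effect_genes = numeric(0),
                              base_hazard = 1 / 700, expr_sd = 1,
                              seed = 1) {
  if (n_patients < 8) stop("n_patients must be at least 8")
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stop("group_fractions must sum to 1")
  if (!setequal(names(group_fractions),
                c("wt_chemo", "wt_nochemo", "mut_chemo", "mut_nochemo")))
    stop("group_fractions must be named wt_chemo, wt_nochemo, mut_chemo, ",
         "mut_nochemo")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0, 1)")
  structure(list(n_patients = n_patients,
                 group_fractions = group_fractions[
                   c("wt_chemo", "wt_nochemo", "mut_chemo", "mut_nochemo")],
                 driver_genes = driver_genes,
                 censoring_fraction = censoring_fraction,
                 stage_effect_genes = stage_effect_genes,
                 base_hazard = base_hazard, expr_sd = expr_sd, seed = seed),
            class = "synth_cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient expression counts over the network's genes, computes
#' each patient's score-flow scores with the package's own machinery
#' (DNA damage ON for chemotherapy-treated patients, OFF otherwise), and
#' simulates survival from the scores as described in
#' [synth_cohort_spec()].
#'
#' @param spec a [synth_cohort_spec()].
#' @param net a [p53_network()] object containing all driver and
#'   stage-effect genes.
#' @param cfg an [stsfa_config()] used for the per-patient scoring.
#' @return A list with elements `expression` (genes x patients count
#'   matrix), `records` (patient metadata data.frame), `scores` (genes x
#'   patients score-flow score matrix used to build the hazards) and `truth`
#'   (the spec plus the standardised driver scores).
#' @export
generate_cohort <- function(spec, net, cfg = stsfa_config()) {
  stopifnot(inherits(spec, "synth_cohort_spec"), inherits(net, "p53net"))
  genes <- model_genes(net)
  bad <- setdiff(c(names(spec$driver_genes), names(spec$stage_effect_genes)),
                 genes)
  if (length(bad))
    stop("genes absent from network: ", paste(bad, collapse = ", "))
  set.seed(spec$seed)
  n <- spec$n_patients

  sizes <- round(spec$group_fractions * n)
  sizes[1] <- n - sum(sizes[-1])  # absorb rounding in the first group
  grp <- rep(names(sizes), times = sizes)
  records <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    p53_status = ifelse(grepl("^wt", grp), "wt", "mut"),
    chemo = grepl("chemo$", grp) & !grepl("nochemo$", grp),
    stage = sample(1:4, n, replace = TRUE,
                   prob = c(0.15, 0.25, 0.30, 0.30)))

  # log2 expression: per-gene baseline + patient-level variation
  base <- stats::runif(length(genes), 5, 12)
  logx <- matrix(stats::rnorm(length(genes) * n, mean = base,
                              sd = spec$expr_sd),
                 nrow = length(genes),
                 dimnames = list(genes, records$id))
  for (g in names(spec$stage_effect_genes))
    logx[g, records$stage == 4] <- logx[g, records$stage == 4] +
      spec$stage_effect_genes[[g]] * spec$expr_sd
  counts <- round(pmax(2^logx - 1, 0))

  scores <- vapply(seq_len(n), function(i) {
    sc <- lssa_scenario(if (records$p53_status[i] == "wt") "wt" else "null",
                        if (records$chemo[i]) "ON" else "OFF")
    res <- stsfa_score(counts, records$id[i], net, sc, cfg,
                       scale = "counts")
    res$final[genes]
  }, numeric(length(genes)))
  dimnames(scores) <- list(genes, records$id)

  lp <- rep(0, n)
  z <- NULL
  if (length(spec$driver_genes)) {
    z <- t(apply(scores[names(spec$driver_genes), , drop = FALSE], 1,
                 function(x) (x - mean(x)) / stats::sd(x)))
    lp <- as.numeric(crossprod(z, spec$driver_genes))
  }
  time <- stats::rexp(n, rate = spec$base_hazard * exp(lp))
  event <- rep(1L, n)
  cens <- sample(n, round(spec$censoring_fraction * n))
  event[cens] <- 0L
  time[cens] <- stats::runif(length(cens), 0, time[cens])
  records$survival_days <- pmax(time, 0.5)
  records$event <- event

  list(expression = counts, records = patient_records(records),
       scores = scores,
       truth = list(spec = spec, linear_predictor = lp,
                    standardized_driver_scores = z))
}
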