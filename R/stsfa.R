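#' Score-flow configuration
#'
#' Tunable parameters of the score-flow computation. `scale_factor`
#' multiplies log2 expression to form initial node scores (the conventional
#' factor is 100, turning a log2 intensity of 8 into a score of 800).
#' The three reconstruction choices of the flow heuristic are exposed:
#' out-degree normalisation of a node's outgoing contribution, clamping of
#' negative scores to zero, and the damping of the fixed-point iteration used
#' on cyclic networks.
#'
#' @param scale_factor positive multiplier for log2 expression (default 100).
#' @param tolerance convergence threshold on the maximum relative score
#'   change per iteration (default 1e-9).
#' @param max_iterations iteration cap; default `NULL` means
#'   `max(100, 10 * n_nodes)`.
#' @param clamp_negative clamp negative scores to 0 (default `TRUE`).
#' @param damping damping factor in (0, 1] for the fixed-point iteration
#'   (default 0.5; 1 = undamped).
#' @param normalization `"outdegree"` (each node's score is split equally
#'   over its outgoing edges; default) or `"none"` (full score sent along
#'   every edge).
#' @return A list of class `stsfa_config`.
#' @export
stsfa_config <- function(scale_factor = 100, tolerance = 1e-9,
                         max_iterations = NULL, clamp_negative = TRUE,
                         damping = 0.5,
                         normalization = c("outdegree", "none")) {
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]")
  structure(list(scale_factor = scale_factor, tolerance = tolerance,
                 max_iterations = max_iterations,
                 clamp_negative = clamp_negative, damping = damping,
                 normalization = match.arg(normalization)),
            class = "stsfa_config")
}

#' Initial node scores from expression data
#'
#' Maps expression values onto network nodes. A mapped gene's score is
#' `log2(value) * scale_factor` (counts are `log2(x + 1)`-transformed). The
#' DNA-damage input node receives the arithmetic mean of the mapped gene
#' scores when the scenario has damage ON, and their minimum when OFF; every
#' unmapped model node also receives the minimum mapped score. When several
#' sample columns are given their per-gene median is used.
#'
#' @param mat numeric matrix, genes x samples.
#' @param samples column name(s) of the sample or group to score.
#' @param net a [p53_network()] object.
#' @param scenario an [lssa_scenario()]; only the damage flag is used here.
#' @param cfg an [stsfa_config()].
#' @param scale `"log_intensity"` (values are positive intensities to be
#'   log2-ed) or `"counts"`.
#' @return Named numeric vector of initial scores over all nodes.
#' @examples
#' net <- toy_p53_network()
#' m <- matrix(c(4, 16), 2, 1, dimnames = list(c("TP53", "MDM2"), "s1"))
#' ini <- stsfa_init_scores(m, "s1", net, lssa_scenario("wt", "ON"))
#' ini[c("TP53", "MDM2", "DNA_damage")]  # 200, 400, 300
#' @export
stsfa_init_scores <- function(mat, samples, net, scenario,
                              cfg = stsfa_config(),
                              scale = c("log_intensity", "counts")) {
  scale <- match.arg(scale)
  stopifnot(inherits(net, "p53net"), inherits(scenario, "lssa_scenario"))
  vals <- mat[, samples, drop = FALSE]
  v <- apply(vals, 1, stats::median)
  if (scale == "counts") {
    v <- log2(v + 1)
  } else {
    if (any(v <= 0)) stop("log-intensity scoring needs positive values")
    v <- log2(v)
  }
  ids <- node_ids(net)
  mapped <- intersect(names(v), setdiff(ids, net$input_node))
  if (!length(mapped)) stop("no expression rows map to model nodes")
  score <- v[mapped] * cfg$scale_factor
  init <- stats::setNames(rep(min(score), length(ids)), ids)
  init[mapped] <- score
  init[net$input_node] <- if (scenario$damage == "ON") mean(score)
                          else min(score)
  attr(init, "mapped") <- mapped
  init
}

#' Propagate scores along signed edges
#'
#' Solves the score-flow fixpoint
#' `final(v) = clamp0(init(v) + sum over incoming edges u->v of
#' sign(u->v) * final(u) / outdegree(u))`
#' (out-degree normalisation and clamping per the configuration). On acyclic
#' networks the solution is computed exactly in one pass over a topological
#' order; on cyclic networks (or with `method = "iterative"`) a damped
#' fixed-point iteration from `final = init` runs until the maximum relative
#' change drops below the tolerance.
#'
#' @param net a [p53_network()] object.
#' @param init named numeric vector of initial scores covering all nodes,
#'   e.g. from [stsfa_init_scores()].
#' @param cfg an [stsfa_config()].
#' @param method `"auto"` (topological if acyclic, else iterative),
#'   `"topological"`, or `"iterative"`.
#' @param scenario optional [lssa_scenario()] recorded on the result.
#' @return An object of class `stsfa_scores`: list with `init`, `final`,
#'   `iterations`, `scenario`.
#' @examples
#' net <- p53_network(
#'   nodes = data.frame(id = c("DNA_damage", "TP53", "B"),
#'                      kind = c("stimulus", "gene", "gene")),
#'   edges = data.frame(source = c("DNA_damage", "TP53"),
#'                      target = c("TP53", "B"), sign = 1))
#' sf <- stsfa_flow(net, c(DNA_damage = 100, TP53 = 50, B = 10))
#' sf$final  # 100, 150, 160
#' @export
stsfa_flow <- function(net, init, cfg = stsfa_config(),
                       method = c("auto", "topological", "iterative"),
                       scenario = NULL) {
  method <- match.arg(method)
  ids <- node_ids(net)
  if (!all(ids %in% names(init)))
    stop("`init` must cover every network node")
  init <- init[ids]
  g <- as_igraph(net)
  acyclic <- igraph::is_dag(g)
  if (method == "auto") method <- if (acyclic) "topological" else "iterative"
  if (method == "topological" && !acyclic)
    stop("topological evaluation requires an acyclic network")

  outdeg <- table(factor(net$edges$source, levels = ids))
  w <- if (cfg$normalization == "outdegree")
    net$edges$sign / pmax(1, as.numeric(outdeg[net$edges$source]))
  else net$edges$sign
  clamp <- function(x) if (cfg$clamp_negative) pmax(x, 0) else x
  incoming <- split(seq_len(nrow(net$edges)), net$edges$target)

  node_update <- function(v, final) {
    ix <- incoming[[v]]
    if (is.null(ix)) return(clamp(init[[v]]))
    clamp(init[[v]] + sum(w[ix] * final[net$edges$source[ix]]))
  }

  if (method == "topological") {
    ord <- ids[as.integer(igraph::topo_sort(g))]
    final <- clamp(init)
    for (v in ord) final[[v]] <- node_update(v, final)
    iterations <- 1L
  } else {
    max_iter <- if (is.null(cfg$max_iterations)) max(100L, 10L * length(ids))
                else cfg$max_iterations
    final <- clamp(init)
    iterations <- NA_integer_
    polish <- 0L
    for (k in seq_len(max_iter)) {
      prop <- vapply(ids, node_update, numeric(1), final = final)
      new <- (1 - cfg$damping) * final + cfg$damping * prop
      resid <- max(abs(new - final) / pmax(1, abs(final)))
      final <- new
      # once the step change is below tolerance, a few polish iterations
      # push the remaining geometric tail well below the step size
      if (resid < cfg$tolerance) polish <- polish + 1L else polish <- 0L
      if (polish >= 10L) { iterations <- k; break }
    }
    if (is.na(iterations))
      stop(sprintf(
        "score flow did not converge in %d iterations (residual %.3g)",
        max_iter, resid))
  }
  structure(list(init = init, final = final, iterations = iterations,
                 scenario = scenario),
            class = "stsfa_scores")
}

#' @export
print.stsfa_scores <- function(x, ...) {
  cat(sprintf("Score flow over %d nodes (%d iteration%s)\n",
              length(x$final), x$iterations,
              if (x$iterations == 1) "" else "s"))
  if (!is.null(x$scenario))
    cat(sprintf("  scenario: TP53 %s, DNA damage %s\n",
                x$scenario$p53, x$scenario$damage))
  cat(sprintf("  final scores: min %.4g, median %.4g, max %.4g\n",
              min(x$final), stats::median(x$final), max(x$final)))
  invisible(x)
}

#' @export
as.data.frame.stsfa_scores <- function(x, ...) {
  data.frame(node = names(x$final), init = as.numeric(x$init),
             final = as.numeric(x$final), row.names = NULL)
}

#' Expression-to-scores convenience wrapper
#'
#' Runs [stsfa_init_scores()] then [stsfa_flow()] for one sample (or group of
#' samples) under one scenario.
#'
#' @inheritParams stsfa_init_scores
#' @inheritParams stsfa_flow
#' @return An `stsfa_scores` object.
#' @export
stsfa_score <- function(mat, samples, net, scenario, cfg = stsfa_config(),
                        scale = c("log_intensity", "counts"),
                        method = c("auto", "topological", "iterative")) {
  init <- stsfa_init_scores(mat, samples, net, scenario, cfg,
                            scale = match.arg(scale))
  stsfa_flow(net, init, cfg, method = match.arg(method), scenario = scenario)
}

#' Score-based model prediction between two scenarios
#'
#' For every gene in the supplied set, the log10 fold change of the final
#' score between scenario 2 and scenario 1 is computed with a pseudocount of
#' 1 (`log10((final2 + 1) / (final1 + 1))`, so clamped zero scores never
#' produce infinities). A gene is predicted up (E_mod = +1) when its log10
#' fold change strictly exceeds the upper limit mean + sd of the fold-change
#' distribution over the gene set, down (-1) when strictly below mean - sd,
#' and unchanged (0) in between.
#'
#' @param scores1,scores2 `stsfa_scores` for the source and target scenario
#'   over the same nodes.
#' @param genes character vector of at least two gene ids to classify.
#' @return A list of class `stsfa_emod`: `emod` (named integer vector),
#'   `table` (data.frame gene/log10fc/call), `mean_fc`, `sd_fc`, `upper`,
#'   `lower`.
#' @export
stsfa_emod <- function(scores1, scores2, genes) {
  f1 <- scores1$final; f2 <- scores2$final
  if (!setequal(names(f1), names(f2)))
    stop("score maps must cover the same node set")
  missing_g <- setdiff(genes, names(f1))
  if (length(missing_g))
    stop("genes not in score maps: ", paste(missing_g, collapse = ", "))
  if (length(genes) < 2)
    stop("need at least 2 genes to form mean +/- sd limits")
  log10fc <- log10((f2[genes] + 1) / (f1[genes] + 1))
  m <- mean(log10fc); s <- stats::sd(log10fc)
  upper <- m + s; lower <- m - s
  call <- ifelse(log10fc > upper, 1L, ifelse(log10fc < lower, -1L, 0L))
  structure(list(
    emod = stats::setNames(as.integer(call), genes),
    table = data.frame(gene = genes, log10fc = as.numeric(log10fc),
                       call = as.integer(call), row.names = NULL),
    mean_fc = m, sd_fc = s, upper = upper, lower = lower),
    class = "stsfa_emod")
}

#' @export
print.stsfa_emod <- function(x, ...) {
  cat(sprintf(
    "Score-flow prediction over %d genes: %d up, %d down, %d unchanged\n",
    length(x$emod), sum(x$emod == 1), sum(x$emod == -1), sum(x$emod == 0)))
  cat(sprintf("  log10 fold-change limits: %.4g (lower) .. %.4g (upper)\n",
              x$lower, x$upper))
  invisible(x)
}
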