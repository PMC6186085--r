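#' Classify model predictions against experimental calls
#'
#' Per-gene absolute difference `|E_mod - E_exp|`: 0 is a correct prediction,
#' 1 a small error (e.g. the model predicts upregulation but the gene is
#' unchanged), 2 a large error (the model predicts the opposite of what
#' occurred). Genes with an undefined experimental call (`NA`) are excluded
#' and counted in a message.
#'
#' @param emod named integer vector of model predictions in `{-1, 0, 1}`
#'   (from [derive_emod()] or [stsfa_emod()]).
#' @param eexp experimental calls: a named vector in `{-1, 0, 1}` or a
#'   data.frame with columns `gene` and `eexp` (from [derive_eexp()]).
#' @return Named integer vector of error classes in `{0, 1, 2}`.
#' @export
classify_predictions <- function(emod, eexp) {
  if (is.data.frame(eexp))
    eexp <- stats::setNames(eexp$eexp, eexp$gene)
  if (!setequal(names(emod), names(eexp)))
    stop("E_mod and E_exp must cover the same gene set; ",
         "intersect with map_genes_to_model() first")
  eexp <- eexp[names(emod)]
  drop <- is.na(eexp)
  if (any(drop)) {
    message(sum(drop), " gene(s) with undefined E_exp excluded")
    emod <- emod[!drop]; eexp <- eexp[!drop]
  }
  stats::setNames(as.integer(abs(emod - eexp)), names(emod))
}

#' Exact binomial probability of a prediction count
#'
#' Significance of observing `k` correct predictions out of `n` genes when
#' each gene independently falls in one of three equiprobable classes
#' (success probability 1/3 by default). The default is the exact binomial
#' point probability `C(n,k) p^k (1-p)^(n-k)`, evaluated in log space; the
#' upper-tail variant `P(X >= k)` is available via `tail = "upper"`.
#'
#' @param n number of genes (trials).
#' @param k number of correct predictions (successes), `0 <= k <= n`.
#' @param p null success probability (default 1/3).
#' @param tail `"point"` (default) or `"upper"`.
#' @return A probability.
#' @examples
#' binom_point_prob(4, 2)          # 8/27
#' binom_point_prob(199, 149)      # ~4.33e-33
#' @export
binom_point_prob <- function(n, k, p = 1 / 3, tail = c("point", "upper")) {
  tail <- match.arg(tail)
  if (length(n) != 1 || length(k) != 1 || n < 0 || k < 0 || k > n)
    stop("need scalar 0 <= k <= n")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (tail == "point") exp(stats::dbinom(k, n, p, log = TRUE))
  else stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Summarise a prediction-error classification
#'
#' Counts and percentages of correct predictions, small errors and large
#' errors, with the exact binomial point probability of the correct count
#' under a null success probability of 1/3 as the significance value.
#'
#' @param classes integer vector of per-gene error classes from
#'   [classify_predictions()].
#' @param comparison optional free-text label of the scenario comparison.
#' @param tail passed to [binom_point_prob()].
#' @return An object of class `validation_summary` with fields `n_genes`,
#'   `n_correct`, `n_small`, `n_large`, `pct_correct`, `pct_small`,
#'   `pct_large` (percentages, 2 decimal places in print), `significance`.
#' @examples
#' validate_counts(149, 48, 2)   # 74.87% correct, p ~ 4.33e-33
#' @export
validate_predictions <- function(classes, comparison = NULL,
                                 tail = c("point", "upper")) {
  if (!all(classes %in% 0:2)) stop("error classes must be 0, 1 or 2")
  validate_counts(sum(classes == 0), sum(classes == 1), sum(classes == 2),
                  comparison = comparison, tail = tail)
}

#' @rdname validate_predictions
#' @param n_correct,n_small,n_large pre-tabulated class counts.
#' @export
validate_counts <- function(n_correct, n_small, n_large, comparison = NULL,
                            tail = c("point", "upper")) {
  counts <- as.integer(c(n_correct, n_small, n_large))
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("empty classification")
  structure(list(
    comparison = comparison,
    n_genes = n, n_correct = counts[1], n_small = counts[2],
    n_large = counts[3],
    pct_correct = 100 * counts[1] / n,
    pct_small = 100 * counts[2] / n,
    pct_large = 100 * counts[3] / n,
    significance = binom_point_prob(n, counts[1], 1 / 3,
                                    tail = match.arg(tail))),
    class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  if (!is.null(x$comparison)) cat(x$comparison, "\n")
  cat(sprintf("Model validation over %d genes:\n", x$n_genes))
  cat(sprintf("  correct:     %4d (%.2f%%), significance %.3g\n",
              x$n_correct, x$pct_correct, x$significance))
  cat(sprintf("  small error: %4d (%.2f%%)\n", x$n_small, x$pct_small))
  cat(sprintf("  large error: %4d (%.2f%%)\n", x$n_large, x$pct_large))
  invisible(x)
}

#' @export
as.data.frame.validation_summary <- function(x, ...) {
  data.frame(comparison = if (is.null(x$comparison)) NA_character_
                          else x$comparison,
             n_genes = x$n_genes, n_correct = x$n_correct,
             n_small = x$n_small, n_large = x$n_large,
             pct_correct = round(x$pct_correct, 2),
             pct_small = round(x$pct_small, 2),
             pct_large = round(x$pct_large, 2),
             significance = x$significance)
}
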