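#' Differential-expression thresholds
#'
#' Filtering thresholds for calling a gene differentially expressed: an
#' absolute log2 fold change of at least `fc_threshold` (default
#' `log2(1.5)`, i.e. a 1.5-fold change) and a raw p-value strictly below
#' `alpha` (default 0.05). No multiple-testing correction is applied; calls
#' are made on raw p-values. The fold-change comparison is inclusive
#' (`|log2fc| >= fc_threshold`), the p-value strict.
#'
#' @param fc_threshold positive log2 fold-change threshold.
#' @param alpha significance level in (0, 1).
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(fc_threshold = log2(1.5), alpha = 0.05) {
  if (fc_threshold <= 0) stop("fc_threshold must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(fc_threshold = fc_threshold, alpha = alpha),
            class = "de_thresholds")
}

#' Collapse probe-level expression to gene level
#'
#' Multiple array probes annotated to the same gene symbol are merged by
#' taking, for each sample, the median expression value across the gene's
#' probes. Probes without a gene mapping are dropped and counted.
#'
#' @param mat numeric matrix, probes x samples, with probe ids as rownames.
#' @param probe_map mapping of probes to genes: either a named character
#'   vector (names = probe ids) or a data.frame with columns `probe`, `gene`.
#'   Each probe maps to at most one gene.
#' @return Numeric matrix, genes x samples.
#' @examples
#' m <- matrix(c(2, 4, 9), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
#' collapse_by_gene(m, c(p1 = "g", p2 = "g", p3 = "g"))  # median 4
#' @export
collapse_by_gene <- function(mat, probe_map) {
  if (is.data.frame(probe_map))
    probe_map <- stats::setNames(as.character(probe_map$gene),
                                 as.character(probe_map$probe))
  if (length(probe_map) == 0) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(probe_map)))
    stop("a probe maps to more than one gene")
  mapped <- rownames(mat) %in% names(probe_map)
  if (sum(!mapped))
    message(sum(!mapped), " unmapped probe(s) dropped")
  if (!any(mapped)) stop("no probes map to any gene")
  mat <- mat[mapped, , drop = FALSE]
  gene <- probe_map[rownames(mat)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(mat)), gene), function(ix)
    apply(mat[ix, , drop = FALSE], 2, stats::median)))
  out
}

#' Two-group differential expression on a gene-level matrix
#'
#' A Welch (unequal-variance) two-sample t-test per gene on log2-scale values,
#' with `log2fc = mean(group_b) - mean(group_a)`. Count-scale matrices are
#' transformed `log2(x + 1)` first. Degenerate cases: with a single sample in
#' a group the fold change is still computed but the p-value is `NaN` (the
#' gene is later excluded from calling); a gene with zero variance in both
#' groups gets p = 1 when the means are equal and p = 0 otherwise.
#'
#' @param mat numeric matrix, genes x samples.
#' @param groups named character vector mapping sample (column) names to group
#'   labels, or an unnamed vector aligned with the columns.
#' @param group_a,group_b labels of the reference and treated group.
#' @param scale `"log_intensity"` (default) or `"counts"`.
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`.
#' @export
differential_expression <- function(mat, groups, group_a, group_b,
                                    scale = c("log_intensity", "counts")) {
  scale <- match.arg(scale)
  if (!is.null(names(groups))) {
    if (length(setdiff(colnames(mat), names(groups))))
      stop("`groups` must label every column of `mat`")
    groups <- groups[colnames(mat)]
  } else if (length(groups) != ncol(mat)) {
    stop("`groups` must label every column of `mat`")
  }
  for (g in c(group_a, group_b))
    if (!g %in% groups) stop("group label '", g, "' not present")
  if (scale == "counts") {
    if (any(mat < 0)) stop("count-scale matrix has negative values")
    mat <- log2(mat + 1)
  }
  a <- mat[, groups == group_a, drop = FALSE]
  b <- mat[, groups == group_b, drop = FALSE]
  res <- t(vapply(seq_len(nrow(mat)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    fc <- mean(xb) - mean(xa)
    if (length(xa) < 2 || length(xb) < 2) return(c(fc, NaN))
    if (stats::var(xa) == 0 && stats::var(xb) == 0)
      return(c(fc, if (fc == 0) 1 else 0))
    c(fc, stats::t.test(xb, xa, var.equal = FALSE)$p.value)
  }, numeric(2)))
  data.frame(gene = rownames(mat), log2fc = res[, 1], pvalue = res[, 2],
             row.names = NULL)
}

#' Experimental differential-expression call E_exp
#'
#' Converts fold changes and p-values into the three-valued experimental call
#' E_exp: +1 (up) when `log2fc >= fc_threshold` and `pvalue < alpha`, -1
#' (down) when `log2fc <= -fc_threshold` and `pvalue < alpha`, else 0.
#' Genes with an undefined p-value get 0.
#'
#' @param de data.frame with columns `gene`, `log2fc`, `pvalue`.
#' @param thresholds a [de_thresholds()] object.
#' @return `de` with an integer `eexp` column added.
#' @examples
#' derive_eexp(data.frame(gene = "g", log2fc = 1, pvalue = 0.01))
#' @export
derive_eexp <- function(de, thresholds = de_thresholds()) {
  stopifnot(all(c("gene", "log2fc", "pvalue") %in% names(de)))
  sig <- !is.na(de$pvalue) & de$pvalue < thresholds$alpha
  de$eexp <- ifelse(sig & de$log2fc >= thresholds$fc_threshold, 1L,
             ifelse(sig & de$log2fc <= -thresholds$fc_threshold, -1L, 0L))
  de
}

#' Restrict a DE table to the genes of a network model
#'
#' Intersects a differential-expression table with the network's gene nodes
#' by exact, case-sensitive id match (no symbol normalisation), reporting how
#' many genes mapped.
#'
#' @param de data.frame with a `gene` column (one row per gene).
#' @param net a [p53_network()] object.
#' @return The subset of `de` whose genes are model genes.
#' @export
map_genes_to_model <- function(de, net) {
  if (anyDuplicated(de$gene))
    stop("duplicate gene rows; collapse probes to genes first")
  genes <- model_genes(net)
  keep <- de$gene %in% genes
  if (!any(keep))
    stop("no DE genes map to the model; check gene id conventions ",
         "(matching is exact and case-sensitive)")
  message(sum(keep), " of ", nrow(de), " DE genes mapped to model genes")
  de[keep, , drop = FALSE]
}
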