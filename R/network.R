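#' Signed directed interaction networks
#'
#' A `p53net` object represents a signed, directed interaction network of the
#' kind used for qualitative p53-pathway modelling: genes/proteins, stimuli and
#' output processes are nodes, activating (+1) or inhibiting (-1) interactions
#' are edges, one stimulus node is the designated DNA-damage input, and one
#' node is the p53 gene whose loss of function can be simulated.
#'
#' @param nodes data.frame with columns `id` (unique, non-empty character),
#'   `kind` (one of `"gene"`, `"stimulus"`, `"phenotype"`) and optionally
#'   `label` (free text; defaults to `id`).
#' @param edges data.frame with columns `source`, `target` (node ids) and
#'   `sign` (+1 or -1). Duplicate identical edges are collapsed with a warning;
#'   parallel edges with opposite signs are retained.
#' @param input_node id of the DNA-damage stimulus node.
#' @param p53_node id of the p53 node.
#' @return An object of class `p53net`: a list with elements `nodes`, `edges`,
#'   `input_node`, `p53_node`.
#' @examples
#' net <- p53_network(
#'   nodes = data.frame(id = c("DNA_damage", "TP53", "MDM2"),
#'                      kind = c("stimulus", "gene", "gene")),
#'   edges = data.frame(source = c("DNA_damage", "TP53", "MDM2"),
#'                      target = c("TP53", "MDM2", "TP53"),
#'                      sign = c(1, 1, -1)))
#' net
#' @export
p53_network <- function(nodes, edges,
                        input_node = "DNA_damage", p53_node = "TP53") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "kind") %in% names(nodes)))
    stop("`nodes` must have columns 'id' and 'kind'")
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes <- nodes[, c("id", "kind", "label")]
  if (nrow(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer())
  }
  if (!all(c("source", "target", "sign") %in% names(edges)))
    stop("`edges` must have columns 'source', 'target' and 'sign'")
  edges <- edges[, c("source", "target", "sign")]
  edges$sign <- as.integer(edges$sign)

  if (any(!nzchar(nodes$id))) stop("node ids must be non-empty")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids: ",
    paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (!all(nodes$kind %in% c("gene", "stimulus", "phenotype")))
    stop("node kind must be one of 'gene', 'stimulus', 'phenotype'")
  missing_ep <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(missing_ep))
    stop("edge endpoints not in node table: ",
         paste(missing_ep, collapse = ", "))
  if (!all(edges$sign %in% c(-1L, 1L)))
    stop("edge sign must be +1 or -1")
  for (nd in c(input_node, p53_node))
    if (!nd %in% nodes$id)
      stop("designated node '", nd, "' not present in network")

  key <- paste(edges$source, edges$target, edges$sign)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate identical edge(s) collapsed")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 input_node = input_node, p53_node = p53_node),
            class = "p53net")
}

#' @export
print.p53net <- function(x, ...) {
  cat(sprintf("Signed interaction network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  input node: %s   p53 node: %s\n", x$input_node, x$p53_node))
  cat(sprintf("  %d activating / %d inhibiting edges\n",
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  invisible(x)
}

node_ids <- function(net) net$nodes$id

#' Gene nodes of a network
#'
#' Node ids of kind `"gene"`, the nodes that expression data can map onto.
#'
#' @param net a `p53net` object.
#' @return Character vector of gene node ids.
#' @export
model_genes <- function(net) net$nodes$id[net$nodes$kind == "gene"]

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Read a network from a SIF-like file
#'
#' The dialect is tab- or whitespace-separated records
#' `source relation target` where relation is `activates` or `inhibits`;
#' a line holding a single token declares an isolated node; lines starting
#' with `#` are comments. A JSON sidecar `<path>.json` may name `input_node`
#' and `p53_node`; otherwise the defaults are used.
#'
#' @param path path to the SIF file.
#' @param input_node,p53_node designated node ids (overridden by the sidecar
#'   if one is present).
#' @return A [p53_network()] object.
#' @export
read_sif <- function(path, input_node = "DNA_damage", p53_node = "TP53") {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$input_node)) input_node <- meta$input_node
    if (!is.null(meta$p53_node)) p53_node <- meta$p53_node
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  src <- tgt <- character(0)
  sgn <- integer(0)
  solo <- character(0)
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 1) {
      solo <- c(solo, tok)
    } else if (length(tok) == 3) {
      s <- switch(tok[2], activates = 1L, inhibits = -1L,
                  stop("line ", i, ": unknown relation token '", tok[2], "'"))
      src <- c(src, tok[1]); tgt <- c(tgt, tok[3]); sgn <- c(sgn, s)
    } else {
      stop("line ", i, ": malformed record (expected 1 or 3 fields)")
    }
  }
  ids <- unique(c(src, tgt, solo))
  if (!input_node %in% ids)
    stop("designated input node '", input_node, "' absent from ", path)
  if (!p53_node %in% ids)
    stop("designated p53 node '", p53_node, "' absent from ", path)
  kind <- ifelse(ids == input_node, "stimulus", "gene")
  p53_network(nodes = data.frame(id = ids, kind = kind),
              edges = data.frame(source = src, target = tgt, sign = sgn),
              input_node = input_node, p53_node = p53_node)
}

#' Write a network to a SIF-like file
#'
#' Inverse of [read_sif()] up to node/edge ordering; isolated nodes are
#' written as single-token lines and designated nodes go to the JSON sidecar.
#'
#' @param net a `p53net` object.
#' @param path output path.
#' @param sidecar write the `<path>.json` sidecar naming the designated nodes
#'   (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_sif <- function(net, path, sidecar = TRUE) {
  rel <- ifelse(net$edges$sign == 1, "activates", "inhibits")
  rec <- sprintf("%s\t%s\t%s", net$edges$source, rel, net$edges$target)
  isolated <- setdiff(node_ids(net), c(net$edges$source, net$edges$target))
  writeLines(c(rec, isolated), path)
  if (sidecar)
    jsonlite::write_json(list(input_node = net$input_node,
                              p53_node = net$p53_node),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Toy p53 network fixture
#'
#' A small (~20 node) documented stand-in for a genome-scale p53 interactome.
#' DNA damage activates ATM, which activates TP53; TP53 sits in its canonical
#' negative feedback loop with MDM2 (the only cycle), drives the apoptotic arm
#' (BAX, APAF1, SIAH1, SFN, ZMAT3 and the apoptosis phenotype), induces the
#' cell-cycle brake CDKN1A, and represses a proliferative arm (E2F1 and its
#' targets FEN1, FOXM1, AURKA, plus MMP2, PDRG1, and the proliferation
#' phenotype). The gene set includes survival-relevant genes commonly reported
#' in mesothelioma score analyses (FEN1, MMP2, SIAH1, E2F1, FOXM1, AURKA,
#' APAF1). Signs are fixed by this documentation; the fixture makes no claim
#' to reproduce any published genome-scale edge list.
#'
#' @return A [p53_network()] object with input node `DNA_damage` and p53 node
#'   `TP53`.
#' @examples
#' toy_p53_network()
#' @export
toy_p53_network <- function() {
  nodes <- data.frame(
    id = c("DNA_damage", "ATM", "TP53", "MDM2", "CDKN1A", "BAX", "APAF1",
           "SIAH1", "SFN", "ZMAT3", "PDRG1", "E2F1", "FEN1", "FOXM1",
           "AURKA", "MMP2", "CCNB1", "apoptosis", "proliferation"),
    kind = c("stimulus", rep("gene", 16), "phenotype", "phenotype"))
  edges <- rbind(
    data.frame(source = "DNA_damage", target = "ATM",    sign =  1),
    data.frame(source = "ATM",       target = "TP53",    sign =  1),
    data.frame(source = "TP53",      target = "MDM2",    sign =  1),
    data.frame(source = "MDM2",      target = "TP53",    sign = -1),
    data.frame(source = "TP53",      target = "CDKN1A",  sign =  1),
    data.frame(source = "TP53",      target = "BAX",     sign =  1),
    data.frame(source = "TP53",      target = "APAF1",   sign =  1),
    data.frame(source = "TP53",      target = "SIAH1",   sign =  1),
    data.frame(source = "TP53",      target = "SFN",     sign =  1),
    data.frame(source = "TP53",      target = "ZMAT3",   sign =  1),
    data.frame(source = "TP53",      target = "PDRG1",   sign = -1),
    data.frame(source = "TP53",      target = "E2F1",    sign = -1),
    data.frame(source = "TP53",      target = "MMP2",    sign = -1),
    data.frame(source = "CDKN1A",    target = "E2F1",    sign = -1),
    data.frame(source = "CDKN1A",    target = "CCNB1",   sign = -1),
    data.frame(source = "E2F1",      target = "FEN1",    sign =  1),
    data.frame(source = "E2F1",      target = "FOXM1",   sign =  1),
    data.frame(source = "FOXM1",     target = "AURKA",   sign =  1),
    data.frame(source = "FOXM1",     target = "CCNB1",   sign =  1),
    data.frame(source = "BAX",       target = "apoptosis", sign = 1),
    data.frame(source = "APAF1",     target = "apoptosis", sign = 1),
    data.frame(source = "SIAH1",     target = "apoptosis", sign = 1),
    data.frame(source = "CCNB1",     target = "proliferation", sign = 1),
    data.frame(source = "MMP2",      target = "proliferation", sign = 1),
    data.frame(source = "FEN1",      target = "proliferation", sign = 1))
  p53_network(nodes, edges)
}

#' Random signed network generator
#'
#' Generates a reproducible signed directed network for testing. The input
#' node has out-edges only, every node is guaranteed reachable from it
#' (missing nodes are re-wired), and each edge is inhibitory with the given
#' probability. With `acyclic = TRUE` edges only run forward along a fixed
#' node ordering, producing a DAG.
#'
#' @param n_nodes number of nodes (>= 3). Nodes are named `DNA_damage`,
#'   `TP53`, `G3`, ..., `G<n>`; `TP53` serves as the p53 node.
#' @param edge_density probability of each admissible ordered node pair being
#'   an edge (0 < density <= 1).
#' @param inhibition_fraction probability that an edge is inhibitory.
#' @param seed integer seed; identical arguments give identical networks.
#' @param acyclic if `TRUE`, restrict to forward edges so the result is a DAG.
#' @return A [p53_network()] object.
#' @export
random_network <- function(n_nodes, edge_density, inhibition_fraction, seed,
                           acyclic = FALSE) {
  if (n_nodes < 3) stop("n_nodes must be at least 3")
  if (edge_density <= 0 || edge_density > 1)
    stop("edge_density must be in (0, 1]")
  if (inhibition_fraction < 0 || inhibition_fraction > 1)
    stop("inhibition_fraction must be in [0, 1]")
  ids <- c("DNA_damage", "TP53", if (n_nodes > 2) paste0("G", 3:n_nodes))
  set.seed(seed)
  pairs <- expand.grid(source = seq_len(n_nodes), target = seq_len(n_nodes))
  pairs <- pairs[pairs$source != pairs$target & pairs$target != 1L, ]
  if (acyclic) pairs <- pairs[pairs$source < pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < edge_density
  edges <- pairs[keep, , drop = FALSE]

  # re-wire until every node is reachable from the input
  repeat {
    reach <- reachable_from(n_nodes, edges, 1L)
    missing <- setdiff(seq_len(n_nodes), reach)
    if (!length(missing)) break
    v <- missing[1]
    from_pool <- if (acyclic) intersect(reach, seq_len(v - 1L)) else reach
    if (!length(from_pool)) from_pool <- 1L
    u <- from_pool[sample.int(length(from_pool), 1)]
    edges <- rbind(edges, data.frame(source = u, target = v))
  }
  edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
  sign <- ifelse(stats::runif(nrow(edges)) < inhibition_fraction, -1L, 1L)
  p53_network(
    nodes = data.frame(id = ids,
                       kind = ifelse(ids == "DNA_damage", "stimulus", "gene")),
    edges = data.frame(source = ids[edges$source], target = ids[edges$target],
                       sign = sign))
}

# breadth-first reachability over an integer edge list
reachable_from <- function(n, edges, start) {
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges$target[edges$source %in% frontier])
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}
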