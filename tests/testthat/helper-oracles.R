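# Independent oracles, deliberately written as naive recursive/enumerative
# implementations so they share no code path with the package internals.

# Recursive evaluation of the three-valued steady state on an acyclic
# network: memoized top-down recursion, one node at a time.
oracle_lssa_recursive <- function(net, scenario) {
  ids <- net$nodes$id
  memo <- new.env(parent = emptyenv())
  kor <- function(v) {
    if (any(v == 1, na.rm = TRUE)) return(1)
    if (length(v) == 0 || (!anyNA(v) && all(v == 0))) return(0)
    NaN
  }
  eval_node <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    val <- if (v == net$input_node) {
      if (scenario$damage == "ON") 1 else 0
    } else if (scenario$p53 == "null" && v == net$p53_node) {
      0
    } else {
      ein <- net$edges[net$edges$target == v, , drop = FALSE]
      if (nrow(ein) == 0) NaN else {
        a <- kor(vapply(ein$source[ein$sign == 1], eval_node, numeric(1)))
        i <- kor(vapply(ein$source[ein$sign == -1], eval_node, numeric(1)))
        if (identical(a, 0) || identical(i, 1)) 0
        else if (identical(a, 1) && identical(i, 0)) 1
        else NaN
      }
    }
    memo[[v]] <- val
    val
  }
  stats::setNames(vapply(ids, eval_node, numeric(1)), ids)
}

# Recursive memoized score-flow evaluation on an acyclic network.
oracle_stsfa_recursive <- function(net, init, clamp_negative = TRUE,
                                   normalization = "outdegree") {
  memo <- new.env(parent = emptyenv())
  outdeg <- table(factor(net$edges$source, levels = net$nodes$id))
  clamp <- function(x) if (clamp_negative) max(x, 0) else x
  eval_node <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    ein <- net$edges[net$edges$target == v, , drop = FALSE]
    flow <- 0
    if (nrow(ein)) {
      for (j in seq_len(nrow(ein))) {
        u <- ein$source[j]
        w <- if (normalization == "outdegree") 1 / outdeg[[u]] else 1
        flow <- flow + ein$sign[j] * w * eval_node(u)
      }
    }
    memo[[v]] <- clamp(init[[v]] + flow)
    memo[[v]]
  }
  stats::setNames(vapply(net$nodes$id, eval_node, numeric(1)), net$nodes$id)
}

# Brute-force maximization of the Cox partial likelihood (Breslow) over a
# fine beta grid; assumes no tied event times unless breslow sums handle it.
oracle_cox_grid <- function(score, time, event,
                            grid = seq(-5, 5, by = 1e-3)) {
  logpl <- vapply(grid, function(b) {
    eta <- b * score
    sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      eta[i] - log(sum(exp(eta[risk])))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(logpl)]
}

# Binomial point mass by enumerating all 2^n weighted outcomes.
oracle_binom_enum <- function(n, k, p) {
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) == k)
      total <- total + p^k * (1 - p)^(n - k)
  }
  total
}

# Tiny deterministic DE table aligned with the toy network's gene ids.
make_de <- function(genes, log2fc, pvalue) {
  data.frame(gene = genes, log2fc = log2fc, pvalue = pvalue)
}
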