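test_that("probe collapsing takes the per-gene median and drops unmapped probes", {
  m <- matrix(c(2, 4, 9, 3, 5, 7, 1, 1, 1), nrow = 3, byrow = FALSE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2", "s3")))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gA")
  out <- collapse_by_gene(m, map)
  expect_equal(unname(out["gA", ]), c(4, 5, 1))

  # single-probe gene is unchanged; even probe count averages the middle pair
  m2 <- matrix(c(3, 5, 8), 3, 1, dimnames = list(c("q1", "q2", "q3"), "s"))
  out2 <- collapse_by_gene(m2, c(q1 = "gA", q2 = "gA", q3 = "gB"))
  expect_equal(unname(out2["gA", ]), 4)
  expect_equal(unname(out2["gB", ]), 8)

  # unmapped probes dropped with a count; probe order irrelevant
  expect_message(collapse_by_gene(m2, c(q1 = "gA", q2 = "gA")), "1 unmapped")
  shuf <- m2[c(3, 1, 2), , drop = FALSE]
  expect_equal(collapse_by_gene(shuf, c(q1 = "gA", q2 = "gA", q3 = "gB")),
               out2)
  expect_error(collapse_by_gene(m2, character(0)), "empty")
})

test_that("Welch DE recovers known effects and handles degenerate variance", {
  set.seed(42)
  n <- 5
  mat <- rbind(
    shifted = c(rnorm(n, 8, 0.1), rnorm(n, 9, 0.1)),
    null = c(rnorm(n, 8, 0.1), rnorm(n, 8, 0.1)),
    flat = rep(5, 2 * n),
    jump = rep(c(1, 3), each = n))
  colnames(mat) <- paste0("s", 1:(2 * n))
  groups <- rep(c("a", "b"), each = n)
  de <- differential_expression(mat, groups, "a", "b")
  expect_equal(de$log2fc[de$gene == "shifted"], 1.0, tolerance = 0.15)
  expect_lt(de$pvalue[de$gene == "shifted"], 0.01)
  expect_equal(de$log2fc[de$gene == "null"], 0, tolerance = 0.15)
  expect_gt(de$pvalue[de$gene == "null"], 0.05)
  # zero variance in both groups: p = 1 when means equal, 0 otherwise
  expect_equal(de$pvalue[de$gene == "flat"], 1)
  expect_equal(de$pvalue[de$gene == "jump"], 0)
  expect_error(differential_expression(mat, groups, "a", "zzz"),
               "not present")
})

test_that("identical groups give zero fold change and p near 1", {
  m <- matrix(rep(c(7, 8, 9), 2), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  de <- differential_expression(m, rep(c("a", "b"), each = 3), "a", "b")
  expect_equal(de$log2fc, 0)
  expect_equal(de$pvalue, 1)
})

test_that("single-sample groups yield a fold change but no p-value", {
  m <- matrix(c(4, 6), 1, dimnames = list("g", c("s1", "s2")))
  de <- differential_expression(m, c("a", "b"), "a", "b")
  expect_equal(de$log2fc, 2)
  expect_true(is.nan(de$pvalue))
  # and such genes are called 0 downstream
  expect_identical(derive_eexp(de)$eexp, 0L)
})

test_that("E_exp calls follow the inclusive fold-change / strict p rule", {
  de <- make_de(paste0("g", 1:6),
                log2fc = c(1.0, -0.30, 2.0, log2(1.5), -log2(1.5), -1),
                pvalue = c(0.01, 0.001, 0.20, 0.049, 0.05, 0.002))
  out <- derive_eexp(de)
  # boundary: |fc| = log2(1.5) counts, p = alpha does not
  expect_identical(out$eexp, c(1L, 0L, 0L, 1L, 0L, -1L))
})

test_that("E_exp is monotone in |fold change| and in p-value", {
  fcs <- seq(-2, 2, by = 0.05)
  calls_lowp <- derive_eexp(make_de("g", fcs, rep(0.01, length(fcs))))$eexp
  expect_true(all(diff(calls_lowp) >= 0))  # monotone non-decreasing in fc
  ps <- seq(0.001, 0.999, by = 0.001)
  calls_fixed_fc <- derive_eexp(make_de("g", rep(1, length(ps)), ps))$eexp
  expect_true(all(diff(calls_fixed_fc) <= 0))  # calls only vanish as p grows
})

test_that("model-gene mapping intersects exactly and enforces its contract", {
  net <- toy_p53_network()
  de <- make_de(c("TP53", "MDM2", "NOT_A_GENE"), c(1, -1, 0),
                c(0.01, 0.01, 0.5))
  expect_message(mapped <- map_genes_to_model(de, net), "2 of 3")
  expect_setequal(mapped$gene, c("TP53", "MDM2"))
  expect_error(map_genes_to_model(make_de("ZZZ", 0, 1), net), "no DE genes")
  dup <- make_de(c("TP53", "TP53"), c(1, 1), c(0.1, 0.1))
  expect_error(map_genes_to_model(dup, net), "duplicate")
})

test_that("counts are log2(x+1)-transformed before testing", {
  m <- matrix(c(15, 15, 15, 63, 63, 63), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  de <- differential_expression(m, rep(c("a", "b"), each = 3), "a", "b",
                                scale = "counts")
  expect_equal(de$log2fc, log2(64) - log2(16))  # exactly 2 on log2 scale
})
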