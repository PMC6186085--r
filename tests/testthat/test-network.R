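test_that("SIF reading transcribes records and materializes nodes", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("# comment line",
               "A\tactivates\tB",
               "B inhibits C",
               "DNA_damage activates A",
               "TP53"), path)
  net <- read_sif(path)
  expect_s3_class(net, "p53net")
  expect_setequal(net$nodes$id, c("A", "B", "C", "DNA_damage", "TP53"))
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$sign[net$edges$source == "B"], -1)
})

test_that("SIF reader rejects malformed input and missing designated nodes", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines("A phosphorylates B", path)
  expect_error(read_sif(path), "unknown relation")
  writeLines("A activates B C D", path)
  expect_error(read_sif(path), "malformed")
  writeLines(c("A activates B"), path)
  expect_error(read_sif(path), "DNA_damage")
  writeLines(character(0), path)
  expect_error(read_sif(path), "DNA_damage")
})

test_that("duplicate identical edges collapse with a warning, opposite signs survive", {
  nodes <- data.frame(id = c("DNA_damage", "TP53"),
                      kind = c("stimulus", "gene"))
  expect_warning(
    net <- p53_network(nodes, data.frame(
      source = c("DNA_damage", "DNA_damage"), target = "TP53", sign = 1)),
    "collapsed")
  expect_equal(nrow(net$edges), 1)
  mixed <- p53_network(nodes, data.frame(
    source = "DNA_damage", target = c("TP53", "TP53"), sign = c(1, -1)))
  expect_equal(nrow(mixed$edges), 2)
})

test_that("write/read round trip is identity up to ordering", {
  for (net in list(toy_p53_network(),
                   random_network(12, 0.25, 0.4, seed = 3),
                   p53_network(data.frame(id = c("DNA_damage", "TP53", "X"),
                                          kind = c("stimulus", "gene", "gene")),
                               data.frame(source = character(),
                                          target = character(),
                                          sign = integer())))) {
    path <- withr::local_tempfile(fileext = ".sif")
    write_sif(net, path)
    back <- read_sif(path)
    expect_setequal(back$nodes$id, net$nodes$id)
    key <- function(n) sort(paste(n$edges$source, n$edges$target,
                                  n$edges$sign))
    expect_equal(key(back), key(net))
    expect_equal(back$input_node, net$input_node)
    expect_equal(back$p53_node, net$p53_node)
  }
})

test_that("toy fixture satisfies network invariants and TP53 is the apoptotic bottleneck", {
  net <- toy_p53_network()
  expect_true("TP53" %in% net$nodes$id)
  expect_true(all(net$edges$sign %in% c(-1, 1)))
  expect_false(anyDuplicated(net$nodes$id) > 0)
  g <- igraph::graph_from_data_frame(net$edges, vertices = net$nodes)
  # full network: apoptosis reachable from the input
  expect_true(igraph::distances(g, "DNA_damage", "apoptosis",
                                mode = "out") < Inf)
  # deleting TP53 disconnects the input from the apoptotic arm
  g2 <- igraph::delete_vertices(g, "TP53")
  for (v in c("APAF1", "BAX", "SIAH1", "apoptosis"))
    expect_true(is.infinite(igraph::distances(g2, "DNA_damage", v,
                                              mode = "out")))
})

test_that("random networks are seed-deterministic and reachable from the input", {
  a <- random_network(10, 0.2, 0.3, seed = 1)
  b <- random_network(10, 0.2, 0.3, seed = 1)
  expect_identical(a, b)
  expect_true(all(random_network(10, 0.2, 0, seed = 2)$edges$sign == 1))
  expect_error(random_network(2, 0.5, 0.5, seed = 1), "at least 3")

  for (seed in 1:10) {
    net <- random_network(30, 0.08, 0.3, seed = seed)
    g <- igraph::graph_from_data_frame(net$edges, vertices = net$nodes)
    d <- igraph::distances(g, "DNA_damage", mode = "out")
    expect_true(all(is.finite(d)), label = paste("seed", seed))
    expect_false(any(net$edges$target == "DNA_damage"))
  }
})

test_that("inhibitory edge fraction lands in the binomial 99% interval", {
  net <- random_network(50, 0.1, 0.3, seed = 7)
  m <- nrow(net$edges)
  k <- sum(net$edges$sign == -1)
  ci <- qbinom(c(0.005, 0.995), m, 0.3)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})
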