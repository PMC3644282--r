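# Readers, writers and quantization rules.

test_that("trinary expression tables round-trip exactly", {
  x <- trinary_matrix(matrix(c("UP", "down", "NoChange", "DOWN", "UP", "UP"),
                             nrow = 3,
                             dimnames = list(c("g1", "g2", "g3"),
                                             c("s1", "s2"))))
  expect_equal(unclass(x)[, 1], c(g1 = 1L, g2 = -1L, g3 = 0L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  expect_identical(read_expression(f, "trinary"), x)
})

test_that("malformed expression tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "g1\tUP\tDOWN", "g1\tUP\tUP"), f)
  expect_error(read_expression(f, "trinary"), "duplicate row.*g1")
  writeLines(c("id\ts1\ts2", "g1\tUP\tSIDEWAYS"), f)
  expect_error(read_expression(f, "trinary"), "SIDEWAYS.*row 'g1', column 's2'")
  writeLines(c("id\ts1\ts2", "g1\t0.5\tNA"), f)
  expect_error(read_expression(f, "continuous"), "row 'g1', column 's2'")
  writeLines(c("id\ts1", "g1\t1.5", "g2\t0.25"), f)
  m <- read_expression(f, "continuous")
  expect_equal(m["g2", "s1"], 0.25)
})

test_that("fold-change quantization thresholds are inclusive and symmetric", {
  m <- matrix(c(4, 1, 0.25, 2, 0.5, 1.01), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  q <- quantize_log_ratio(m, fold = 2)
  expect_equal(as.integer(q), c(1L, 0L, -1L, 1L, -1L, 0L))
  expect_error(quantize_log_ratio(matrix(-1, 1, 1,
                                         dimnames = list("g", "s"))),
               "positive")
  # ratio symmetry: x called DOWN iff 1/x called UP
  withr::with_seed(42, {
    r <- matrix(exp(rnorm(200)), 10,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:20)))
  })
  q1 <- quantize_log_ratio(r)
  q2 <- quantize_log_ratio(1 / r)
  expect_identical(unclass(q1) == -1L, unclass(q2) == 1L)
  expect_identical(unclass(q1) == 1L, unclass(q2) == -1L)
})

test_that("z-score quantization is exclusive at the boundary and affine-invariant", {
  s <- sqrt(2)
  m <- matrix(c(1, 3, 2 + 1.5 * s, 2 - 0.5 * s, 2 - 1.2 * s, 2 + s), nrow = 1,
              dimnames = list("g1", sprintf("s%d", 1:6)))
  q <- quantize_zscore(m, reference_samples = c("s1", "s2"))
  # reference mean 2, sd sqrt(2); z = 1.5, -0.5, -1.2, exactly 1
  expect_equal(as.integer(q[1, 3:6]), c(1L, 0L, -1L, 0L))
  # affine rescaling of a gene's values and its references leaves calls fixed
  q2 <- quantize_zscore(m * 7 - 3, reference_samples = c("s1", "s2"))
  expect_identical(unclass(q), unclass(q2))
  # zero reference SD: gene forced to NOCHANGE with a warning
  flat <- matrix(c(1, 1, 5), nrow = 1, dimnames = list("g1", c("s1", "s2", "s3")))
  expect_warning(qf <- quantize_zscore(flat, c("s1", "s2")), "zero reference SD")
  expect_true(all(unclass(qf) == 0L))
})

test_that("GMT files parse with set semantics", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tC", "S2\tother\tB\tD"), f)
  gs <- read_gmt(f)
  expect_equal(gs[["S1"]], c("A", "B", "C"))
  expect_equal(length(gs), 2L)
  writeLines(c("S1\td\tA", "S1\td\tB"), f)
  expect_error(read_gmt(f), "duplicate set name")
  writeLines(c("S1\td\tA\tA\tB"), f)
  expect_warning(gs <- read_gmt(f), "duplicated members")
  expect_equal(gs[["S1"]], c("A", "B"))
  writeLines(c("S1\tdesc"), f)
  expect_error(read_gmt(f), "fewer than 3")
  # write/read round trip
  gs <- gene_set_collection(list(S1 = c("A", "B"), S2 = "C"))
  write_gmt(gs, f)
  expect_equal(read_gmt(f)$sets, gs$sets)
})

test_that("condition tables enforce proper subsets and allow overlap", {
  u <- sprintf("s%d", 1:6)
  ct <- condition_table(list(a = u[1:2], b = u[2:4]), u)
  expect_equal(ct$assignments$b, u[2:4])
  expect_error(condition_table(list(a = "zzz"), u), "outside the universe")
  expect_error(condition_table(list(a = u), u), "fewer than all")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_conditions(ct, f)
  ct2 <- read_conditions(f, universe = u)
  expect_equal(ct2$assignments, ct$assignments)
})

test_that("network export writes called edges only and round-trips d exactly", {
  d <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d["x", "y"] <- d["y", "x"] <- 0.7
  d["y", "z"] <- d["z", "y"] <- 0.5   # exactly at threshold: not called
  net <- consensus_network(d, R = 10, d_theta = 0.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  spec <- data.frame(set_i = "x", set_j = "y", condition = "c1",
                     d_all = 0.7, d_without = 0.1, gamma = 7, H = 0L,
                     M = 10L, p = 0, specific = TRUE)
  write_network(net, spec, f, "tsv")
  tab <- read.delim(f)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$d, 0.7)
  expect_equal(tab$gamma_c1, 7)
  expect_true(tab$specific_c1)
  net2 <- read_network(f, R = 10, node_ids = net$node_ids)
  expect_identical(net2$d["x", "y"], 0.7)
  # all-subthreshold network -> header-only file
  write_network(consensus_network(d * 0, R = 10), NULL, f, "tsv")
  expect_equal(nrow(read.delim(f)), 0L)
  # unknown node in the specificity table is rejected
  bad <- spec; bad$set_j <- "nope"
  expect_error(write_network(net, bad, f, "tsv"), "unknown node")
  # GraphML output parses and carries the attributes
  fg <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, spec, fg, "graphml")
  g <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::edge_attr(g, "d"), 0.7)
})
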