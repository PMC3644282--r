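# Condition-effect ratio, permutation test, and gene-set classification.

test_that("gamma ratio follows the leave-out formula with the zero floor", {
  expect_equal(gamma_ratio(0.6, 0.6, 1024), 1)
  expect_equal(gamma_ratio(0.8, 0.2, 1024), 4)
  expect_equal(gamma_ratio(0.9, 0, 1024), 0.9 * 1025)
  expect_true(is.finite(gamma_ratio(1, 0, 10)))
})

test_that("specificity results are deterministic and consistent between
           single-edge and batch calls", {
  sim <- generate_planted(6, 120, list(c1 = sprintf("s%03d", 1:60),
                                       c2 = sprintf("s%03d", 61:120)),
                          data.frame(i = 1, j = 2, condition = "c1",
                                     strength = 1),
                          noise = 0, seed = 10)
  cfg <- search_config(R = 32, base_seed = 6)
  net <- consensus(sim$data, cfg)
  pars <- specificity_params(M = 20, R_perm = 32)
  r1 <- test_all(sim$data, net, sim$conditions, pars, cfg, seed = 9)
  r2 <- test_all(sim$data, net, sim$conditions, pars, cfg, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$p == r1$H / r1$M))
  expect_true(all(r1$H >= 0 & r1$H <= r1$M))
  expect_identical(r1$specific,
                   r1$gamma > pars$gamma_theta & r1$p < pars$p_theta)
  edge <- c(r1$set_i[1], r1$set_j[1])
  single <- specificity_test(sim$data, edge, r1$condition[1], net,
                             sim$conditions, pars, cfg, seed = 9)
  expect_equal(single, r1[1, ], ignore_attr = TRUE)
})

test_that("edges and conditions are validated before testing", {
  sim <- generate_planted(4, 60, list(c1 = sprintf("s%03d", 1:30),
                                      c2 = sprintf("s%03d", 31:60)),
                          data.frame(i = 1, j = 2, condition = "c1",
                                     strength = 1),
                          noise = 0, seed = 2)
  cfg <- search_config(R = 16, base_seed = 3)
  net <- consensus(sim$data, cfg)
  pars <- specificity_params(M = 5, R_perm = 16)
  expect_error(specificity_test(sim$data, c("S03", "S04"), "c1", net,
                                sim$conditions, pars, cfg),
               "not called")
  expect_error(
    specificity_test(sim$data, c("S01", "S02"),
                     list(label = "all", samples = colnames(sim$data)),
                     net, NULL, pars, cfg),
    "leave-out set empty")
  # a network with no called edges yields an empty result table
  flat <- make_tri(3, 50, seed = 4)
  net0 <- consensus(flat, cfg)
  ct <- condition_table(list(c1 = sprintf("s%03d", 1:25)),
                        colnames(flat))
  expect_equal(nrow(test_all(flat, net0, ct, pars, cfg)), 0L)
})

test_that("an exchangeable condition is not declared specific", {
  # the A-B dependency holds across ALL samples; removing any condition
  # leaves it intact, so gamma stays near 1 and p is large
  withr::with_seed(31, {
    z <- sample(tri_states, 160, replace = TRUE)
    m <- rbind(A = z, B = z,
               C = sample(tri_states, 160, replace = TRUE),
               D = sample(tri_states, 160, replace = TRUE))
    colnames(m) <- sprintf("s%03d", 1:160)
  })
  x <- trinary_matrix(m)
  ct <- condition_table(list(c1 = colnames(x)[1:40]), colnames(x))
  cfg <- search_config(R = 64, base_seed = 13)
  net <- consensus(x, cfg)
  res <- test_all(x, net, ct, specificity_params(M = 20, R_perm = 64), cfg,
                  seed = 5)
  row <- res[res$set_i == "A" & res$set_j == "B", ]
  expect_equal(nrow(row), 1L)
  expect_gte(row$p, 0.5)
  expect_lt(abs(row$gamma - 1), 0.5)
  expect_false(any(res$specific))
})

test_that("a dependency confined to one condition is recovered as specific", {
  conds <- list(c1 = sprintf("s%03d", 1:100), c2 = sprintf("s%03d", 101:200))
  hits <- 0
  for (r in 1:3) {
    sim <- generate_planted(8, 200, conds,
                            data.frame(i = 1, j = 2, condition = "c1",
                                       strength = 1),
                            noise = 0, seed = 300 + r)
    cfg <- search_config(R = 64, base_seed = 400 + r)
    net <- consensus(sim$data, cfg)
    res <- test_all(sim$data, net, sim$conditions,
                    specificity_params(M = 40, R_perm = 64), cfg,
                    seed = 500 + r)
    row <- res[res$set_i == "S01" & res$set_j == "S02" &
                 res$condition == "c1", ]
    hits <- hits + (nrow(row) == 1 && row$specific)
  }
  expect_gte(hits, 2)
})

test_that("test_edges evaluates explicitly supplied pairs, called or not", {
  sim <- generate_planted(5, 80, list(c1 = sprintf("s%03d", 1:40),
                                      c2 = sprintf("s%03d", 41:80)),
                          data.frame(i = 1, j = 2, condition = "c1",
                                     strength = 1),
                          noise = 0, seed = 6)
  cfg <- search_config(R = 16, base_seed = 2)
  net <- consensus(sim$data, cfg)
  res <- test_edges(sim$data,
                    data.frame(set_i = c("S01", "S03"),
                               set_j = c("S02", "S04")),
                    net, sim$conditions,
                    specificity_params(M = 10, R_perm = 16), cfg, seed = 3)
  expect_equal(nrow(res), 4L)  # 2 edges x 2 conditions
  expect_equal(res$d_all[res$set_i == "S03" & res$condition == "c1"],
               net$d["S03", "S04"])
  expect_error(test_edges(sim$data,
                          data.frame(set_i = "S01", set_j = "NOPE"),
                          net, sim$conditions), "unknown node")
})

test_that("gene sets classify as generic, centric or mixed by their edges", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.9
  d["b", "c"] <- d["c", "b"] <- 0.8
  d["c", "d"] <- d["d", "c"] <- 0.7
  net <- consensus_network(d, R = 10)
  spec <- data.frame(
    set_i = c("a", "b", "c"), set_j = c("b", "c", "d"),
    condition = "melanoma",
    d_all = c(0.9, 0.8, 0.7), d_without = 0.1,
    gamma = c(9, 8, 1), H = 0L, M = 10L, p = c(0, 0, 0.9),
    specific = c(TRUE, TRUE, FALSE))
  out <- classify_centricity(net, spec)
  expect_equal(out$class[out$set == "a"], "centric")
  expect_equal(out$condition[out$set == "a"], "melanoma")
  expect_equal(out$class[out$set == "b"], "centric")
  expect_equal(out$class[out$set == "c"], "mixed")
  expect_equal(out$class[out$set == "d"], "generic")
  bad <- spec; bad$set_j[1] <- "d"
  expect_error(classify_centricity(net, bad), "not called")
})
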