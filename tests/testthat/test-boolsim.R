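# Synchronous boolean simulation, the cholesterol model, and the planted
# generator.

test_that("synchronous update applies rules simultaneously with clamp
           precedence", {
  net <- boolean_network(c(S = "S", X = "NOT S AND Y", Y = "Y"))
  st <- c(S = 1, X = 1, Y = 1)
  out <- bn_step(net, st)
  expect_equal(out[["X"]], FALSE)    # statins-like input wins over Y
  # fixed point maps to itself
  net2 <- boolean_network(c(A = "A", B = "A"))
  fp <- c(A = TRUE, B = TRUE)
  expect_equal(bn_step(net2, fp), fp)
  # a clamped node ignores a rule that would set it to 1
  net3 <- clamp(boolean_network(c(A = "A", B = "A")), c(B = 0))
  expect_false(bn_step(net3, c(A = TRUE, B = TRUE))[["B"]])
})

test_that("rule parsing validates node references and operators", {
  expect_error(boolean_network(c(A = "B AND C")), "undeclared")
  expect_error(boolean_network(c(A = "A + A")), "unsupported")
  expect_error(boolean_network(c(A = "A", A = "A")), "duplicate")
  f <- withr::local_tempfile(fileext = ".bn")
  writeLines(c("# comment", "A = NOT B", "B = A"), f)
  net <- read_boolean_network(f)
  expect_equal(sort(net$nodes), c("A", "B"))
})

test_that("the cholesterol model matches the published pathway logic", {
  net <- cholesterol_network()
  edges <- bn_edges(net)
  # statins inhibits HMG-CoA reductase
  row <- edges[edges$from == "Statins" & edges$to == "HMG_CoA_reductase", ]
  expect_equal(nrow(row), 1L)
  expect_true(row$negated)
  # cholesterol integrates its synthesis branches with OR logic
  expect_match(net$rules[["Cholesterol"]], "OR")
  # every other node with two or more distinct (non-self) inputs is an AND
  multi <- vapply(net$nodes, function(v) {
    length(setdiff(all.vars(net$exprs[[v]]), v)) >= 2
  }, logical(1))
  for (v in setdiff(net$nodes[multi], "Cholesterol")) {
    expect_false(grepl("\\bOR\\b", net$rules[[v]]), label = v)
  }
  # feedback from cholesterol to SREBP-SCAP is present and inhibitory
  fb <- edges[edges$from == "Cholesterol" & edges$to == "SREBP_SCAP", ]
  expect_equal(nrow(fb), 1L)
  expect_true(fb$negated)
})

test_that("with statins clamped on, every reachable steady state has the
           mevalonate branch off", {
  net <- cholesterol_network()
  n <- length(net$nodes)
  # exhaustive: all 2^n initial states, statins clamped to 1
  bits <- matrix(FALSE, 2^n, n, dimnames = list(NULL, net$nodes))
  for (j in seq_len(n)) {
    bits[, j] <- rep(rep(c(FALSE, TRUE), each = 2^(j - 1)),
                     length.out = 2^n)
  }
  cnet <- clamp(net, c(Statins = 1))
  bits[, "Statins"] <- TRUE
  states <- bits
  for (t in 1:40) states <- bn_step(cnet, states)
  # all trajectories have converged to fixed points
  expect_identical(bn_step(cnet, states), states)
  expect_true(all(!states[, "HMG_CoA_reductase"]))
  expect_true(all(!states[, "Mevalonic_acid"]))
  downstream <- c("Mevalonate_PP", "Isopentenyl_PP", "Farnesyl_PP",
                  "Squalene", "Lanosterol", "Desmosterol",
                  "Dehydrocholesterol_7", "Cholesterol")
  expect_true(all(!states[, downstream]))
})

test_that("attractor sampling emits fixed points and cycle states
           deterministically", {
  net <- cholesterol_network()
  des <- simulation_design(50, list(statins_off = c(Statins = 0),
                                    statins_on = c(Statins = 1)),
                           seed = 3)
  sim1 <- sample_steady_states(net, des)
  sim2 <- sample_steady_states(net, des)
  expect_identical(sim1$data, sim2$data)
  expect_equal(dim(sim1$data), c(length(net$nodes), 100L))
  expect_equal(sort(names(sim1$conditions$assignments)),
               c("statins_off", "statins_on"))
  on <- sim1$conditions$assignments$statins_on
  expect_true(all(unclass(sim1$data)["HMG_CoA_reductase", on] == -1L))
  expect_true(all(unclass(sim1$data)["Mevalonic_acid", on] == -1L))
  # period-2 toggle: emitted states are valid cycle states
  tg <- toggle_net()
  simt <- sample_steady_states(tg, simulation_design(
    40, list(base = c()), seed = 9))
  a <- unclass(simt$data)["A", ]
  b <- unclass(simt$data)["B", ]
  expect_true(all(a %in% c(-1L, 1L) & b %in% c(-1L, 1L)))
  expect_gt(length(unique(a)), 1L)   # both cycle phases get emitted
  # max_steps exhaustion falls back to the last state with a warning
  expect_warning(
    sample_steady_states(tg, simulation_design(5, list(base = c()),
                                               max_steps = 1, seed = 2)),
    "max_steps")
})

test_that("the planted generator honours strengths, noise, seeds and
           marginals", {
  conds <- list(c1 = sprintf("s%03d", 1:50), c2 = sprintf("s%03d", 51:100))
  pe <- data.frame(i = 1, j = 2, condition = "c1", strength = 1)
  sim <- generate_planted(6, 100, conds, pe, noise = 0, seed = 4)
  expect_identical(unclass(sim$data)["S02", conds$c1],
                   unclass(sim$data)["S01", conds$c1])
  expect_identical(sim$data, generate_planted(6, 100, conds, pe, noise = 0,
                                              seed = 4)$data)
  # strength 0 leaves the pair independent within the condition block
  sim0 <- generate_planted(6, 200,
                           list(c1 = sprintf("s%03d", 1:100),
                                c2 = sprintf("s%03d", 101:200)),
                           data.frame(i = 1, j = 2, condition = "c1",
                                      strength = 0),
                           noise = 0, seed = 8)
  tab <- table(unclass(sim0$data)["S01", 1:100],
               unclass(sim0$data)["S02", 1:100])
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
  # configured marginals are matched within 3 standard errors at n = 1000
  marg <- c(0.2, 0.5, 0.3)
  simm <- generate_planted(2, 1000, list(c1 = sprintf("s%03d", 1:500),
                                         c2 = sprintf("s%03d", 501:1000)),
                           pe[0, ], noise = 0, seed = 12, marginals = marg)
  for (s in 1:3) {
    frac <- mean(unclass(simm$data) == c(-1L, 0L, 1L)[s])
    se <- sqrt(marg[s] * (1 - marg[s]) / length(simm$data))
    expect_lt(abs(frac - marg[s]), 3 * se + 1e-9)
  }
  expect_error(generate_planted(6, 100, conds,
                                data.frame(i = 1, j = 2,
                                           condition = "nope",
                                           strength = 1), seed = 1),
               "condition block unknown")
  expect_error(generate_planted(6, 100, conds,
                                rbind(pe, pe), seed = 1), "distinct")
})
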