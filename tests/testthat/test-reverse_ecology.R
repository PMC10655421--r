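test_that("compound graph construction follows the reaction structure", {
  g <- build_compound_graph(toy_s1())
  expect_setequal(paste(g$edges[, "from"], g$edges[, "to"]),
                  c("A C", "B C", "C D"))

  rv <- metabolic_network("RV", list(reaction("R1", "X", "Y", TRUE),
                                     reaction("R2", "Y", "Z")))
  g2 <- build_compound_graph(rv)
  expect_setequal(paste(g2$edges[, "from"], g2$edges[, "to"]),
                  c("X Y", "Y X", "Y Z"))

  # excluding a compound removes it and its incident edges
  g3 <- build_compound_graph(toy_s1(), exclude = "C")
  expect_setequal(g3$nodes, c("A", "B", "D"))
  expect_equal(nrow(g3$edges), 0L)

  # exclusion never adds edges
  set.seed(5)
  for (i in 1:20) {
    net <- random_network("R", n_reactions = 15L)
    full <- build_compound_graph(net)
    excl <- build_compound_graph(net,
                                 exclude = sample(net$compounds, 3))
    expect_true(all(paste(excl$edges[, 1], excl$edges[, 2]) %in%
                      paste(full$edges[, 1], full$edges[, 2])))
  }
})

test_that("seed sets are the source SCCs with 1/|component| confidence", {
  ss <- compute_seed_set(build_compound_graph(toy_s1()))
  expect_equal(ss$entries, c(A = 1, B = 1))

  rv <- metabolic_network("RV", list(reaction("R1", "X", "Y", TRUE),
                                     reaction("R2", "Y", "Z")))
  ss2 <- compute_seed_set(build_compound_graph(rv))
  expect_equal(ss2$entries, c(X = 0.5, Y = 0.5))
  expect_false("Z" %in% names(ss2$entries))

  # an isolated compound is its own source component
  iso <- structure(list(owner = "I", nodes = "L",
                        edges = cbind(from = character(0),
                                      to = character(0))),
                   class = "compound_graph")
  expect_equal(compute_seed_set(iso)$entries, c(L = 1))

  # empty graph: empty seed set
  empty <- build_compound_graph(metabolic_network("E"))
  expect_length(compute_seed_set(empty)$entries, 0L)
})

test_that("source-SCC detection matches brute-force reachability", {
  set.seed(41)
  for (i in 1:110) {
    net <- random_network("R", n_reactions = sample(3:25, 1),
                          n_compounds = sample(4:15, 1),
                          p_reversible = 0.3)
    g <- build_compound_graph(net)
    ss <- compute_seed_set(g)
    expect_identical(sort(names(ss$entries)), brute_seed_compounds(g))
    # per-component confidences sum to exactly 1
    for (comp in ss$components) {
      expect_equal(sum(ss$entries[comp]), 1)
    }
  }
})

test_that("competition and complementarity follow the weighted overlap", {
  f <- list(entries = c(A = 1, B = 1), components = list("A", "B"),
            owner = "F")
  class(f) <- "seed_set"
  p <- list(entries = c(B = 1, C = 1), components = list("B", "C"),
            owner = "P")
  class(p) <- "seed_set"
  expect_equal(competition_index(f, p), 0.5)
  expect_equal(competition_index(f, f), 1)
  disj <- list(entries = c(Q = 1), components = list("Q"), owner = "D")
  class(disj) <- "seed_set"
  expect_equal(competition_index(f, disj), 0)

  partner <- metabolic_network("P", list(reaction("r", "Q", "A")))
  pseeds <- network_seed_set(partner)  # seeds {Q}
  expect_equal(complementarity_index(f, partner, pseeds), 0.5)

  # against itself every own seed is excluded: complementarity 0
  own <- toy_s1()
  own_ss <- network_seed_set(own)
  expect_equal(complementarity_index(own_ss, own, own_ss), 0)

  # partner sharing no compounds with the focal seeds
  far <- metabolic_network("Z", list(reaction("r", "u", "v")))
  expect_equal(complementarity_index(f, far, network_seed_set(far)), 0)

  empty <- list(entries = stats::setNames(numeric(0), character(0)),
                components = list(), owner = "E")
  class(empty) <- "seed_set"
  expect_error(competition_index(empty, f), "empty")
})

test_that("BSS counts any supporter compound, seeds included", {
  consumer <- list(entries = c(A = 1, B = 1),
                   components = list("A", "B"), owner = "C")
  class(consumer) <- "seed_set"
  supp <- metabolic_network("S", list(reaction("r", "A", "Q")))
  expect_equal(biosynthetic_support_score(consumer, supp), 0.5)
  all_in <- metabolic_network("S2", list(reaction("r", "A", "B")))
  expect_equal(biosynthetic_support_score(consumer, all_in), 1)
  none <- metabolic_network("S3", list(reaction("r", "u", "v")))
  expect_equal(biosynthetic_support_score(consumer, none), 0)

  # a species always fully supports itself
  net <- toy_s2()
  expect_equal(biosynthetic_support_score(network_seed_set(net), net), 1)
})

test_that("pairwise matrices have the right algebra on all metrics", {
  n1 <- toy_s1()
  n1b <- metabolic_network("S1b", unname(toy_s1()$reactions))
  m <- pairwise_matrix(list(n1, n1b), "competition")
  expect_equal(unname(m["S1", "S1b"]), 1)
  expect_equal(unname(m["S1b", "S1"]), 1)
  expect_equal(unname(diag(m)), c(1, 1))

  nets <- list(toy_s1(), toy_s2(), toy_s3())
  for (metric in c("competition", "complementarity", "bss", "mci")) {
    mm <- pairwise_matrix(nets, metric)
    expect_true(all(mm >= 0 & mm <= 1))
  }
  comp <- pairwise_matrix(nets, "complementarity")
  expect_equal(unname(diag(comp)), c(0, 0, 0))
  # mci is the complementarity formula under the host-microbe name
  expect_identical(pairwise_matrix(nets, "mci"), comp)
  expect_equal(unname(diag(pairwise_matrix(nets, "bss"))), c(1, 1, 1))

  # hand computation: seeds S1={A,B}, S2={A,D}, S3={A,B}
  ss1 <- network_seed_set(toy_s1())
  ss2 <- network_seed_set(toy_s2())
  expect_equal(ss2$entries, c(A = 1, D = 1))
  cm <- pairwise_matrix(nets, "competition")
  expect_equal(unname(cm["S1", "S2"]), 0.5)  # A shared, B not
  expect_equal(unname(cm["S2", "S1"]), 0.5)
  expect_equal(unname(cm["S1", "S3"]), 1)    # identical seed sets
  # S2's seed D is produced (non-seed) in S1: complementarity 0.5
  expect_equal(unname(comp["S2", "S1"]), 0.5)
})

test_that("the unweighted variant uses plain set fractions", {
  # source SCC {X, Y} of size 2 plus singleton {W}
  net <- metabolic_network("M", list(reaction("r1", "X", "Y", TRUE),
                                     reaction("r2", c("Y", "W"), "Z")))
  ss <- network_seed_set(net)
  expect_equal(ss$entries, c(W = 1, X = 0.5, Y = 0.5))
  partner <- list(entries = c(X = 1, Y = 1),
                  components = list("X", "Y"), owner = "P")
  class(partner) <- "seed_set"
  expect_equal(competition_index(ss, partner, weighted = TRUE), 0.5)
  expect_equal(competition_index(ss, partner, weighted = FALSE), 2 / 3)
})
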