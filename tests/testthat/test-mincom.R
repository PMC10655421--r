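test_that("minimal communities match the hand-checked toy cases", {
  # a species holding both pathways alone beats the two-species split
  inst <- community_instance(list(toy_s1(), toy_s2(), toy_s3()),
                             c("A", "B"), "F")
  res <- solve_minimal_community(inst)
  expect_equal(res$optimum_size, 1L)
  expect_identical(res$one_solution, "S3")

  # without the fused species, both halves are required
  inst2 <- community_instance(list(toy_s1(), toy_s2()), c("A", "B"), "F")
  res2 <- solve_minimal_community(inst2)
  expect_equal(res2$optimum_size, 2L)
  expect_identical(res2$one_solution, c("S1", "S2"))

  # host reactions support coverage but the host is not selectable
  h <- metabolic_network("H", list(reaction("Rh", "B", "D")))
  inst3 <- community_instance(list(toy_s2()), c("A", "B"), "F", host = h)
  res3 <- solve_minimal_community(inst3)
  expect_equal(res3$optimum_size, 1L)
  expect_identical(res3$one_solution, "S2")
  expect_true(res3$host_included)
})

test_that("enumeration finds all optima and classifies symbionts", {
  s3a <- metabolic_network("S3a", unname(toy_s3()$reactions))
  s3b <- metabolic_network("S3b", unname(toy_s3()$reactions))
  inst <- community_instance(list(s3a, s3b, toy_s1()), c("A", "B"), "F")
  res <- enumerate_minimal_communities(inst)
  expect_equal(res$optimum_size, 1L)
  expect_identical(sorted_solution_key(res$all_solutions),
                   c("S3a", "S3b"))
  expect_identical(res$essential, character(0))
  expect_identical(res$alternative, c("S3a", "S3b"))
  expect_false(res$truncated)

  # unique optimum: the sole solution is essential
  inst_u <- community_instance(list(toy_s1(), toy_s2(), toy_s3()),
                               c("A", "B"), "F")
  res_u <- enumerate_minimal_communities(inst_u)
  expect_identical(res_u$essential, "S3")
  expect_identical(res_u$alternative, character(0))

  # cap below the number of optima flags truncation
  res_t <- enumerate_minimal_communities(inst, cap = 1L)
  expect_true(res_t$truncated)
  expect_error(classify_symbionts(res_t), "truncated")
})

test_that("classify_symbionts is intersection/union set algebra", {
  mk <- function(sols) {
    structure(list(all_solutions = sols, truncated = FALSE),
              class = "mincom_result")
  }
  cl <- classify_symbionts(mk(list(c("a", "b"), c("a", "c"))))
  expect_identical(cl$essential, "a")
  expect_identical(cl$alternative, c("b", "c"))

  cl2 <- classify_symbionts(mk(list("a")))
  expect_identical(cl2$essential, "a")
  expect_identical(cl2$alternative, character(0))

  cl3 <- classify_symbionts(mk(list(c("a", "b"), c("c", "d"))))
  expect_identical(cl3$essential, character(0))
  expect_identical(cl3$alternative, c("a", "b", "c", "d"))
})

test_that("degenerate inputs are handled as specified", {
  # no producible target at all: size-0 result, all targets unproducible
  inert <- metabolic_network("D", list(reaction("r", "ghost", "p")))
  inst <- suppressWarnings(community_instance(list(inert), "A", "F"))
  expect_warning(res <- solve_minimal_community(inst), "unproducible")
  expect_equal(res$optimum_size, 0L)
  expect_identical(res$one_solution, character(0))
  expect_identical(res$unproducible_targets, "F")

  # a target already in the seeds is covered by the empty community
  inst2 <- community_instance(list(toy_s1()), c("A", "B"),
                              target_set("A"))
  res2 <- solve_minimal_community(inst2)
  expect_equal(res2$optimum_size, 0L)

  expect_error(
    suppressWarnings(community_instance(list(), "A", "F")) |>
      solve_minimal_community(),
    "member")
})

test_that("solver agrees with exhaustive subset search on random instances", {
  set.seed(91)
  for (i in 1:8) {
    n_sp <- pick(7:10)
    cfg <- generator_config(
      n_species = n_sp, n_targets = pick(1:2),
      chain_length = 4L, n_hub = pick(2:min(3L, n_sp - 4L)),
      n_decoys = 2L,
      plant_competitor_pair = sample(c(TRUE, FALSE), 1),
      rng_seed = 1000L + i)
    si <- generate_instance(cfg)
    oracle <- exhaustive_mincom(si$instance)
    res <- enumerate_minimal_communities(si$instance)
    expect_equal(res$optimum_size, oracle$optimum_size)
    expect_identical(sorted_solution_key(res$all_solutions),
                     sorted_solution_key(oracle$optima))
    expect_identical(res$essential, sort(Reduce(intersect, oracle$optima)))
  }
})

test_that("returned solutions are feasible and irreducible", {
  si <- generate_instance(generator_config(
    n_species = 8L, n_hub = 3L, n_decoys = 2L, rng_seed = 77L))
  inst <- si$instance
  res <- enumerate_minimal_communities(inst)
  producible <- res$producible_targets
  for (sol in res$all_solutions) {
    sc <- community_scope(unname(inst$members[sol]), inst$seeds)
    expect_true(all(producible %in% sc$full_scope))
    for (drop in sol) {
      rest <- setdiff(sol, drop)
      sc_rest <- if (length(rest)) {
        community_scope(unname(inst$members[rest]), inst$seeds)$full_scope
      } else {
        inst$seeds
      }
      expect_false(all(producible %in% sc_rest))
    }
  }
})

test_that("adding a host never increases the optimum size", {
  set.seed(55)
  for (i in 1:5) {
    si <- generate_instance(generator_config(
      n_species = 7L, n_hub = 3L, n_decoys = 2L,
      plant_host_support = TRUE, rng_seed = 300L + i))
    with_host <- solve_minimal_community(si$instance)$optimum_size
    no_host <- solve_minimal_community(community_instance(
      unname(si$instance$members), si$instance$seeds,
      si$instance$targets))$optimum_size
    expect_lte(with_host, no_host)
  }
})
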