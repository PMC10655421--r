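# Small species with controllable seed sets: a chain consuming `inputs`
# and producing `outputs` gives a species whose reverse-ecology seed set
# is exactly `inputs`.
chain_species <- function(id, inputs, outputs) {
  rxs <- lapply(seq_along(outputs), function(j)
    reaction(sprintf("%s_r%d", id, j),
             if (j == 1L) inputs else outputs[j - 1L], outputs[j]))
  metabolic_network(id, rxs)
}

test_that("competitor pruning removes the fewest, most violating species", {
  # all pairwise competition at or below threshold: nothing removed
  calm <- list(chain_species("a", c("u1", "u2"), "p1"),
               chain_species("b", c("v1", "v2"), "p2"),
               chain_species("c", c("w1", "w2"), "p3"))
  pr <- prune_competitors(calm, threshold = 0.6)
  expect_identical(pr$kept, c("a", "b", "c"))
  expect_equal(nrow(pr$excluded), 0L)
  expect_true(all(pr$matrix_after[upper.tri(pr$matrix_after)] <= 0.6))

  # two identical species: exactly one removed, lexicographically last
  twin1 <- chain_species("t1", c("u1", "u2"), "p1")
  twin2 <- metabolic_network("t2", unname(twin1$reactions))
  pr2 <- prune_competitors(list(twin1, twin2), threshold = 0.6)
  expect_identical(pr2$kept, "t1")
  expect_identical(pr2$excluded$species_id, "t2")
  expect_equal(pr2$excluded$index_value, 1)

  # one high-competition pair among three: one of the pair goes, by the
  # tie rules (equal violation counts -> higher mean -> last id)
  x <- chain_species("x", c("s1", "s2", "s3", "s4"), "px")
  y <- chain_species("y", c("s1", "s2", "s3", "z9"), "py")
  w <- chain_species("w", c("q1", "q2", "q3", "q4"), "pw")
  # comp(x,y) = comp(y,x) = 3/4 > 0.6; w uncontested
  pr3 <- prune_competitors(list(x, y, w), threshold = 0.6)
  expect_identical(pr3$excluded$species_id, "y")
  expect_identical(pr3$kept, c("w", "x"))
  off <- pr3$matrix_after
  diag(off) <- NA
  expect_true(all(off <= 0.6, na.rm = TRUE))
})

test_that("pruning is recorded in order and errors if nothing survives", {
  # asymmetric violations: u competes with both v1 and v2, which do not
  # compete with each other -> removing u alone must suffice
  u <- chain_species("u", c("m1", "m2"), "pu")
  v1 <- chain_species("v1", c("m1", "n1"), "pv1")
  v2 <- chain_species("v2", c("m2", "n2"), "pv2")
  # comp(u, v1) = 1/2, not a violation at 0.6; build stronger overlap
  u2 <- chain_species("U", c("m1", "m2", "m3", "m4"), "pU")
  w1 <- chain_species("W1", c("m1", "m2", "m3", "k1"), "pW1")
  w2 <- chain_species("W2", c("m2", "m3", "m4", "k2"), "pW2")
  # comp(U,W1)=comp(U,W2)=3/4; comp(W1,W2)=2/4 -> U has 4 violating
  # pairs, W1/W2 two each: U is removed first and no violation remains
  pr <- prune_competitors(list(u2, w1, w2), threshold = 0.6)
  expect_identical(pr$excluded$species_id, "U")
  expect_identical(pr$kept, c("W1", "W2"))

  # a single member is trivially kept
  pr1 <- prune_competitors(list(u), threshold = 0.6)
  expect_identical(pr1$kept, "u")
})

test_that("host support summary scores both directions per pair", {
  m1 <- chain_species("m1", c("aa1", "aa2"), c("x1", "x2"))
  m2 <- chain_species("m2", c("bb1", "bb2"), "x3")
  # host produces m1's required compounds but none of m2's
  host <- chain_species("plantA", c("hs1", "hs2"), c("aa1", "aa2"))
  hs <- host_support_summary(list(m1, m2), list(host))
  pairs <- hs$pairs
  bss_m1 <- pairs$bss[pairs$consumer == "m1" & pairs$supporter == "plantA"]
  expect_equal(bss_m1, 1)
  bss_m2 <- pairs$bss[pairs$consumer == "m2" & pairs$supporter == "plantA"]
  expect_equal(bss_m2, 0)
  # community -> host direction exists for every pair
  expect_setequal(unique(pairs$direction),
                  c("host_to_community", "community_to_host"))
  expect_equal(nrow(pairs), 4L)
  expect_setequal(hs$supported_compounds$host_to_community$compound,
                  c("aa1", "aa2"))

  # brute-force agreement on a 2-member, 2-host toy
  host2 <- chain_species("plantB", c("ht1", "ht2"), c("bb1", "x9"))
  hs2 <- host_support_summary(list(m1, m2), list(host, host2))
  p <- hs2$pairs
  expect_equal(p$bss[p$consumer == "m2" & p$supporter == "plantB"], 0.5)
  for (r in seq_len(nrow(p))) {
    cons <- p$consumer[r]
    supp <- p$supporter[r]
    nets <- list(m1 = m1, m2 = m2, plantA = host, plantB = host2)
    expect_equal(p$bss[r], biosynthetic_support_score(
      network_seed_set(nets[[cons]]), nets[[supp]]))
    expect_equal(p$mci[r], complementarity_index(
      network_seed_set(nets[[cons]]), nets[[supp]]))
  }
})

test_that("design_syncom keeps essential species when competition is low", {
  si <- generate_instance(generator_config(
    n_species = 8L, n_hub = 3L, n_decoys = 2L, rng_seed = 12L))
  rep <- design_syncom(si$instance)
  expect_identical(rep$essential_symbionts, si$truth$planted_essential)
  expect_identical(rep$final_members, rep$essential_symbionts)
  expect_equal(nrow(rep$excluded), 0L)
})

test_that("design_syncom drops one member of a planted competitor trio", {
  si <- generate_instance(generator_config(
    n_species = 10L, n_hub = 4L, plant_competitor_pair = TRUE,
    rng_seed = 42L))
  rep <- design_syncom(si$instance, threshold = 0.6)
  dup <- si$truth$duplicated_hub_member
  expect_identical(rep$final_members, setdiff(si$truth$planted_hub, dup))
  expect_true(dup %in% si$truth$planted_competitor_pairs$focal)
  # after-matrix honours the threshold
  off <- rep$competition_matrix_after
  diag(off) <- NA
  expect_true(all(off <= 0.6, na.rm = TRUE))
})

test_that("empty essentiality yields an explicit empty selection", {
  # two interchangeable all-in-one species: no essential symbiont at all
  a <- metabolic_network("S3a", unname(toy_s3()$reactions))
  b <- metabolic_network("S3b", unname(toy_s3()$reactions))
  inst <- community_instance(list(a, b), c("A", "B"), "F")
  expect_warning(rep <- design_syncom(inst), "empty")
  expect_identical(rep$final_members, character(0))
  expect_identical(rep$essential_symbionts, character(0))
})

test_that("reports attach PGPT profiles and host support for final members", {
  si <- generate_instance(generator_config(
    n_species = 8L, n_hub = 3L, n_decoys = 2L,
    plant_host_support = TRUE, rng_seed = 9L))
  ann <- generate_annotations(si, per_category_presence = 0.3,
                              rng_seed = 5L)
  rep <- design_syncom(si$instance, annotations = ann)
  expect_identical(sort(names(rep$pgpt_summary)), rep$final_members)
  expect_true(all(rep$host_support$bss >= 0 & rep$host_support$bss <= 1))
  expect_identical(names(rep$per_run), c("none", "host_plant"))
  # host run needs one fewer species than the hostless run
  expect_lt(rep$per_run$host_plant$optimum_size,
            rep$per_run$none$optimum_size)
})

test_that("identical inputs produce byte-identical reports", {
  si <- generate_instance(generator_config(
    n_species = 9L, n_hub = 3L, plant_competitor_pair = TRUE,
    rng_seed = 21L))
  ann <- generate_annotations(si, rng_seed = 2L)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_syncom_report(design_syncom(si$instance, annotations = ann), p1)
  write_syncom_report(design_syncom(si$instance, annotations = ann), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
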