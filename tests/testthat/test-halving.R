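test_that("distance formula evaluates hand-checked censuses", {
  # fully doubled: n = 2, two even cycles
  cen0 <- dcjhalving:::component_census(n = 2, c_even = 2)
  expect_equal(halving_distance_census(cen0)$distance, 0L)
  # one matched pair around an even pontoon
  cen1 <- dcjhalving:::component_census(n = 1, pontoons_even = 1)
  expect_equal(halving_distance_census(cen1)$distance, 1L)
  # the delta edge case: odd pontoon with balanced piers
  cen2 <- dcjhalving:::component_census(n = 1, piers_even = 1, piers_odd = 1,
                                        pontoons_odd = 1)
  b2 <- halving_distance_census(cen2)
  expect_equal(b2$delta, 1L)
  expect_equal(b2$q, 2L)
  expect_equal(b2$distance, 3L)
  expect_error(halving_distance_census(dcjhalving:::component_census(n = -1)),
               "negative")
})

test_that("halving distance matches worked examples", {
  h <- homology(list(c("1", "3"), c("2", "4")))
  g0 <- new_genome(list(c("1", "2"), c("3", "4")), circular = c(TRUE, TRUE))
  expect_equal(halving_distance(g0, h)$distance, 0L)
  g1 <- new_genome(list(c("1", "2", "4", "3")), circular = TRUE)
  expect_equal(halving_distance(g1, h)$distance, 1L)
  g2 <- new_genome(list(c("2", "1", "3", "4")))
  expect_equal(halving_distance(g2, homology(list(c("1", "3"))))$distance, 2L)
  # circular singletons add one deletion each
  g3 <- parse_genomes(">A\n1 2 |\n5 6 )\n7 )")[[1]]
  h3 <- homology(list(c("1", "2")))
  b3 <- halving_distance(g3, h3)
  expect_equal(b3$circular_singletons, 2L)
  # unresolved homology is rejected with a pointer to the ILP
  g4 <- new_genome(list(c("1", "1", "1")))
  expect_error(halving_distance(g4), "ILP")
})

test_that("singular-free genomes reduce to the DCJ halving formula", {
  set.seed(9)
  for (s in 1:30) {
    f <- make_fixture("sd", sample(4:30, 1), seed = s)
    g <- f$genome
    # rearrange without touching content: no singular markers appear
    for (k in seq_len(sample(0:6, 1))) {
      op <- random_dcj(g)
      if (!is.null(op)) g <- apply_operation(g, op)
    }
    b <- halving_distance(g)
    cen <- b$census
    expect_equal(cen$pontoons_odd + cen$pontoons_even +
                   cen$piers_odd + cen$piers_even, 0L)
    expect_equal(b$distance,
                 cen$n - cen$c_even - floor(cen$viaducts_odd / 2))
  }
})

test_that("distance is zero exactly on structurally doubled genomes", {
  set.seed(10)
  for (s in 1:30) {
    f <- make_fixture("sd", sample(2:20, 1), seed = s)
    expect_true(is_sd(f$genome))
    expect_equal(halving_distance(f$genome)$distance, 0L)
    f2 <- make_fixture("resolved", sample(4:20, 1), seed = s)
    expect_equal(halving_distance(f2$genome)$distance == 0L, is_sd(f2$genome))
  }
})

test_that("single operations change the distance by at most one", {
  set.seed(12)
  for (s in 1:30) {
    f <- make_fixture("resolved", sample(5:18, 1), seed = s)
    g <- f$genome
    d0 <- halving_distance(g)$distance
    op <- random_dcj(g)
    if (!is.null(op)) {
      d1 <- halving_distance(apply_operation(g, op))$distance
      expect_lte(abs(d1 - d0), 1L)
    }
    # restricted deletion of one singular marker
    idx <- dcjhalving:::genome_index(g)
    partner <- dcjhalving:::matching_partner(idx, matching_from_homology(g))
    sing <- which(partner == 0L)
    if (length(sing)) {
      lab <- idx$label[sample(sing, 1)]
      d2 <- halving_distance(apply_operation(g, op_deletion(lab)))$distance
      expect_lte(abs(d2 - d0), 1L)
    }
  }
})

test_that("sorting reaches the structurally doubled ancestor optimally", {
  # worked examples
  h <- homology(list(c("1", "3"), c("2", "4")))
  g0 <- new_genome(list(c("1", "2"), c("3", "4")), circular = c(TRUE, TRUE))
  expect_length(sort_halving(g0, h)$operations, 0)
  g1 <- new_genome(list(c("1", "2", "4", "3")), circular = TRUE)
  s1 <- sort_halving(g1, h)
  expect_equal(s1$distance, 1L)
  expect_equal(s1$operations[[1]]$kind, "dcj")
  expect_true(is_sd(s1$final, hom = h))
  g2 <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  h2 <- homology(list(c("1", "3")))
  s2 <- sort_halving(g2, h2)
  expect_equal(s2$distance, 1L)
  expect_equal(s2$operations[[1]]$kind, "deletion")
  # random fixtures: scenario length equals the formula, final genome SD
  set.seed(13)
  for (s in 1:40) {
    f <- make_fixture("resolved", sample(4:22, 1), seed = s + 40)
    sc <- sort_halving(f$genome)
    expect_equal(sc$distance, halving_distance(f$genome)$distance)
    expect_true(isTRUE(verify_scenario(f$genome, sc)))
  }
})

test_that("scenario verification flags illegal and incomplete scenarios", {
  g <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  h <- homology(list(c("1", "3")))
  # deleting a matched marker is not restricted-legal
  bad <- list(op_deletion("1.1"))
  v <- verify_scenario(g, bad, hom = h)
  expect_false(isTRUE(v))
  expect_match(attr(v, "log"), "matched")
  # truncated scenario: final genome not SD
  v2 <- verify_scenario(g, list(), hom = h)
  expect_false(isTRUE(v2))
  # a legal one-step scenario passes
  v3 <- verify_scenario(g, list(op_deletion("2.1")), hom = h)
  expect_true(isTRUE(v3))
  # insertion of a homolog of a singular marker is legal and pairs up
  glin <- new_genome(list("1"))
  v4 <- verify_scenario(glin, list(op_insertion("1")), marker_matching())
  expect_true(isTRUE(v4))
})
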