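test_that("brute-force search reproduces hand-verified distances", {
  g1 <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  expect_equal(bruteforce_halving(g1, hom = homology(list(c("1", "3"))),
                                  max_depth = 4), 1L)
  g2 <- new_genome(list(c("1", "-2", "3")))
  expect_equal(bruteforce_halving(g2, hom = homology(list(c("1", "2"))),
                                  max_depth = 4), 2L)
  g3 <- new_genome(list(c("1", "2", "3", "4")))
  expect_equal(bruteforce_halving(g3, hom = homology(list(c("2", "4"))),
                                  max_depth = 4), 3L)
  # already doubled: zero
  g0 <- new_genome(list(c("1", "1")), circular = TRUE)
  expect_equal(bruteforce_halving(g0, max_depth = 2), 0L)
  # depth cap reached
  expect_true(is.na(bruteforce_halving(g3, hom = homology(list(c("2", "4"))),
                                       max_depth = 1)))
  expect_error(bruteforce_halving(make_fixture("resolved", 20, 1)$genome),
               "too large")
})

test_that("oracle distance is invariant under genome symmetries", {
  h <- homology(list(c("2", "4")))
  variants <- list(
    new_genome(list(c("1", "2", "3", "4"))),
    new_genome(list(c("-4", "-3", "-2", "-1")))       # reflection
  )
  d <- vapply(variants, function(g)
    bruteforce_halving(g, hom = h, max_depth = 4), integer(1))
  expect_equal(d[1], d[2])
  # rotation of a circular chromosome
  c1 <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  c2 <- new_genome(list(c("2", "3", "1")), circular = TRUE)
  hh <- homology(list(c("1", "3")))
  expect_equal(bruteforce_halving(c1, hom = hh, max_depth = 3),
               bruteforce_halving(c2, hom = hh, max_depth = 3))
})

test_that("maximum matchings are enumerated with the right counts", {
  g2 <- new_genome(list(c("1", "1")))
  expect_length(enumerate_maximum_matchings(g2), 1)
  g3 <- new_genome(list(c("1", "1", "1")))
  expect_length(enumerate_maximum_matchings(g3), 3)
  g4 <- new_genome(list(c("1", "1", "1", "1")))
  expect_length(enumerate_maximum_matchings(g4), 3)
  # combination across families: 3 x 1
  g5 <- new_genome(list(c("1", "1", "1", "2", "2")))
  expect_length(enumerate_maximum_matchings(g5), 3)
  # every matching leaves at most one singular marker per family
  for (m in enumerate_maximum_matchings(g4)) {
    expect_equal(nrow(m$pairs), 2)
  }
})

test_that("matching minimization agrees with direct evaluation", {
  # resolved: single matching
  f <- make_fixture("resolved", 8, seed = 3)
  expect_equal(min_over_matchings(f$genome),
               halving_distance(f$genome)$distance)
  # doubled genome: zero under some matching
  base <- make_fixture("natural", 5, seed = 4)$genome
  expect_equal(min_over_matchings(dcjhalving:::wgd(base), family_guard = 8L), 0L)
})

test_that("formula is a lower bound attained by the oracle on small genomes", {
  set.seed(77)
  gs <- enumerate_small_genomes(3)
  picks <- sample(seq_along(gs), 40)
  for (i in picks) {
    d <- halving_distance(gs[[i]])$distance
    expect_equal(bruteforce_halving(gs[[i]], max_depth = d), d)
  }
})
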