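test_that("model structure follows the construction rules", {
  g <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  m <- build_halving_ilp(g, homology(list(c("1", "3"))))
  expect_equal(m$caps, 0L)            # no telomeres
  expect_equal(nrow(m$pairs), 1L)     # one candidate sibling pair
  expect_length(m$var$d, 3L)
  expect_equal(m$nV, 6L)
  # maximum matching: d2 forced to 1, family {1,3} fully matched
  sol <- solve_halving_ilp(m)
  dv <- sol$assignment[m$var$d]
  expect_equal(unname(round(dv)), c(0, 1, 0))
  expect_equal(sol$distance, 1L)
})

test_that("LP export is deterministic and complete", {
  f <- make_fixture("natural", 8, seed = 2)
  m <- build_halving_ilp(f$genome)
  p1 <- tempfile(); p2 <- tempfile()
  write_lp(m, p1)
  write_lp(build_halving_ilp(f$genome), p2)
  expect_identical(readLines(p1), readLines(p2))
  txt <- readLines(p1)
  expect_true(any(grepl("^Minimize", txt)))
  # every variable appears in the bounds section
  expect_equal(sum(grepl("<=", txt[(which(txt == "Bounds") + 1):length(txt)],
                         fixed = TRUE)),
               length(m$builder$vn))
  # empty genome: trivial model
  m0 <- build_halving_ilp(new_genome(list()))
  expect_true(m0$empty)
  expect_equal(solve_halving_ilp(m0)$distance, 0L)
})

test_that("model size grows linearly with the genome", {
  sizes <- c(10, 20, 40)
  counts <- vapply(sizes, function(s) {
    f <- make_fixture("resolved", s, seed = 7)
    m <- build_halving_ilp(f$genome)
    c(length(m$builder$vn), m$builder$nrow)
  }, numeric(2))
  # doubling the markers at most ~doubles variables and constraints
  expect_lt(counts[1, 3], 5 * counts[1, 1])
  expect_lt(counts[2, 3], 5 * counts[2, 1])
})

test_that("ILP reproduces the closed form on resolved genomes", {
  set.seed(21)
  for (s in 1:10) {
    f <- make_fixture("resolved", sample(8:30, 1), seed = s + 200)
    d1 <- halving_distance(f$genome)$distance
    sol <- solve_halving_ilp(build_halving_ilp(f$genome))
    expect_equal(sol$distance, d1)
    # the decoded matching reproduces the same distance via the census
    expect_equal(sol$breakdown$distance, d1)
  }
})

test_that("ILP minimizes over maximum matchings on natural genomes", {
  set.seed(22)
  for (s in 1:10) {
    f <- make_fixture("natural", sample(5:9, 1), seed = s + 300)
    d1 <- min_over_matchings(f$genome)
    sol <- solve_halving_ilp(build_halving_ilp(f$genome))
    expect_equal(sol$distance, d1)
    # decoded matching is a maximum matching: at most one singular per family
    keys <- dcjhalving:::family_keys(f$genome)
    idx <- dcjhalving:::genome_index(f$genome)
    partner <- dcjhalving:::matching_partner(idx, sol$matching)
    for (fam in split(seq_along(keys), keys)) {
      expect_lte(sum(partner[fam] == 0L), 1L)
    }
    # decoded census satisfies the parity invariants
    cen <- sol$breakdown$census
    expect_equal((cen$piers_even + cen$piers_odd) %% 2L, 0L)
    expect_equal((cen$c_odd + cen$viaducts_odd + cen$piers_odd +
                    cen$pontoons_odd) %% 2L, 0L)
  }
})

test_that("doubled natural genomes have ILP distance zero", {
  set.seed(23)
  for (s in 1:5) {
    base <- make_fixture("natural", sample(4:7, 1), seed = s)$genome
    doubled <- dcjhalving:::wgd(base)
    sol <- solve_halving_ilp(build_halving_ilp(doubled))
    expect_equal(sol$distance, 0L)
  }
})

test_that("all-singular circular chromosome is priced as one deletion", {
  g <- new_genome(list(c("1", "2", "3", "4", "5")), circular = TRUE)
  sol <- solve_halving_ilp(build_halving_ilp(g))
  expect_equal(sol$distance, 1L)
  sv <- sol$assignment[grep("^s_D", names(sol$assignment))]
  expect_equal(unname(round(sv)), 1)
})

test_that("halve_natural composes solving and sorting", {
  f <- make_fixture("natural", 8, seed = 31)
  res <- halve_natural(f$genome)
  expect_equal(res$scenario$distance, res$solution$distance)
  expect_true(is_sd(res$scenario$final, res$scenario$matching))
  expect_true(isTRUE(verify_scenario(f$genome, res$scenario,
                                     matching = res$matching)))
})
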