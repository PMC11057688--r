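test_that("Zipf sampler follows the stated density", {
  set.seed(31)
  x <- zipf_length(1e5, 4)
  p1 <- pi^4 / 90            # zeta(4)
  expected <- 1 / p1
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(mean(x == 1) - expected), 3 * se)
  # large shape degenerates to length 1
  expect_gt(mean(zipf_length(1e4, 50) == 1), 0.999)
  # reproducibility
  set.seed(99); a <- zipf_length(100, 4)
  set.seed(99); b <- zipf_length(100, 4)
  expect_identical(a, b)
  expect_error(zipf_length(1, 1), "shape")
})

test_that("lineage trees with unary nodes parse correctly", {
  tr <- dcjhalving:::parse_lineage_tree("(((G)D)S)R;")
  expect_equal(tr$root, "R")
  expect_setequal(paste(tr$edges[, 1], tr$edges[, 2]), c("R S", "S D", "D G"))
  tr2 <- dcjhalving:::parse_lineage_tree("((A,B)X)R;")
  expect_setequal(paste(tr2$edges[, 1], tr2$edges[, 2]),
                  c("R X", "X A", "X B"))
  expect_error(sim_params(tree = "(G)R;", wgd_branch = "Z"), "wgd_branch")
})

test_that("evolution respects the requested operation counts and bookkeeping", {
  p <- sim_params(root_markers = 40, ops_per_branch = 10, seed = 5)
  r <- evolve(p)
  tr <- r$truth
  # WGD branch does exactly the duplication
  expect_true(tr$wgd[tr$child == "D"])
  expect_equal(tr$markers_end[tr$child == "D"], 2 * tr$markers_start[tr$child == "D"])
  # non-WGD branches perform the requested counts (rates relative to DCJs)
  for (ch in c("S", "G")) {
    row <- tr[tr$child == ch, ]
    expect_equal(row$dcj, 10L)
    expect_equal(row$insertions, round(0.2 * 10))
    expect_equal(row$duplications, round(0.3 * 10))
    expect_equal(row$deletions, if (ch == "G") round(1.0 * 10) else 0L)
    # marker-count identity per branch
    expect_equal(row$markers_end,
                 row$markers_start + row$inserted_markers +
                   row$duplicated_markers - row$deleted_markers)
  }
  # reproducibility
  r2 <- evolve(p)
  expect_identical(write_genomes(r$genomes[["G"]]), write_genomes(r2$genomes[["G"]]))
})

test_that("degenerate protocols behave as identities", {
  # no operations, no WGD branch reached: leaf equals root
  p0 <- sim_params(root_markers = 12, ops_per_branch = 0, tree = "(G)R;",
                   wgd_branch = "R", seed = 2)
  r0 <- evolve(p0)
  expect_true(genomes_equal(r0$genomes[["G"]], r0$genomes[["R"]]))
  # WGD only: leaf is structurally doubled
  p1 <- sim_params(root_markers = 12, ops_per_branch = 0, seed = 3)
  r1 <- evolve(p1)
  expect_true(is_sd(r1$genomes[["G"]]))
  expect_equal(halving_distance(r1$genomes[["G"]])$distance, 0L)
})

test_that("fixture generator delivers the advertised genome classes", {
  for (s in 1:5) {
    fs <- make_fixture("sd", 14, seed = s)
    expect_true(is_sd(fs$genome))
    fr <- make_fixture("resolved", 15, seed = s)
    expect_true(is_resolved(fr$genome))
    expect_equal(dcjhalving:::n_markers(fr$genome), 15L)
    fn <- make_fixture("natural", 11, seed = s)
    expect_gte(max(table(dcjhalving:::family_keys(fn$genome))), 3L)
  }
})
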