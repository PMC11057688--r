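library(igraph)

ecount_type <- function(g, type) sum(E(g)$etype == type)

test_that("supernatural graph has the prescribed vertices and edges", {
  g <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  sng <- build_sng(g, homology(list(c("1", "3"))))
  expect_equal(vcount(sng), 6)
  expect_equal(ecount_type(sng, "adjacency"), 3)
  expect_equal(ecount_type(sng, "extremity"), 2)
  ext <- as_edgelist(sng)[E(sng)$etype == "extremity", , drop = FALSE]
  expect_setequal(apply(ext, 1, paste, collapse = "-"),
                  c("t1.1-t3.1", "h1.1-h3.1"))

  # all-singular genome: no extremity edges
  s <- build_sng(new_genome(list(c("1", "2"))))
  expect_equal(ecount_type(s, "extremity"), 0)

  # family of size 3: complete graph on equivalent extremities
  t3 <- build_sng(new_genome(list(c("1", "1", "1"))))
  expect_equal(ecount_type(t3, "extremity"), 6)
})

test_that("pseudo-caps complete the adjacency matching", {
  g <- new_genome(list(c("1", "2"), c("3")))
  sng <- add_pseudo_caps(build_sng(g))
  expect_equal(sum(V(sng)$cap), 4)
  deg <- dcjhalving:::adjacency_degree(sng)
  expect_true(all(deg == 1))
  # pseudo-caps indexed before regular vertices
  expect_true(max(V(sng)$ix[V(sng)$cap]) < min(V(sng)$ix[!V(sng)$cap]))
  # all-circular genome unchanged
  c1 <- build_sng(new_genome(list(c("1", "2")), circular = TRUE))
  expect_equal(vcount(add_pseudo_caps(c1)), vcount(c1))
})

test_that("decomposition keeps exactly the matched sibling edges", {
  g <- new_genome(list(c("1", "1", "1", "2")), circular = TRUE)
  sng <- build_sng(g)
  m <- marker_matching(rbind(c("1.1", "1.2")))
  simple <- decompose(sng, m)
  expect_equal(ecount_type(simple, "extremity"), 2)
  expect_equal(ecount_type(simple, "adjacency"), ecount_type(sng, "adjacency"))
  # empty matching: adjacency edges only
  s0 <- decompose(sng, marker_matching())
  expect_equal(ecount_type(s0, "extremity"), 0)
  # resolved homology: decomposition equals the graph itself
  gr <- new_genome(list(c("1", "2", "1")), circular = TRUE)
  sng2 <- build_sng(gr)
  s2 <- decompose(sng2, matching_from_homology(gr))
  expect_equal(ecount(s2), ecount(sng2))
})

test_that("component classification matches hand-traced censuses", {
  # circular (1 2 3), 1 == 3: one even pontoon
  g1 <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  h1 <- homology(list(c("1", "3")))
  m1 <- matching_from_homology(g1, h1)
  c1 <- classify_components(decompose(build_sng(g1, h1), m1), m1)
  expect_equal(c1$n, 1L)
  expect_equal(c1$pontoons_even, 1L)
  expect_equal(c1$c_even + c1$c_odd + c1$viaducts_even + c1$viaducts_odd +
                 c1$piers_even + c1$piers_odd + c1$pontoons_odd, 0L)

  # linear [2 1 3 4], 1 == 3: two isolated telomere-lava piers + even pontoon
  g2 <- new_genome(list(c("2", "1", "3", "4")))
  h2 <- homology(list(c("1", "3")))
  m2 <- matching_from_homology(g2, h2)
  c2 <- classify_components(decompose(build_sng(g2, h2), m2), m2)
  expect_equal(c2$n, 1L)
  expect_equal(c2$piers_even, 2L)
  expect_equal(c2$pontoons_even, 1L)
  expect_equal(c2$piers_odd + c2$pontoons_odd + c2$viaducts_odd, 0L)

  # linear [1 2 3 4], 2 == 4: even pier, odd pier, odd pontoon
  g3 <- new_genome(list(c("1", "2", "3", "4")))
  h3 <- homology(list(c("2", "4")))
  m3 <- matching_from_homology(g3, h3)
  c3 <- classify_components(decompose(build_sng(g3, h3), m3), m3)
  expect_equal(c3$n, 1L)
  expect_equal(c3$piers_even, 1L)
  expect_equal(c3$piers_odd, 1L)
  expect_equal(c3$pontoons_odd, 1L)
})

test_that("census is identical with and without pseudo-caps and matches the
           fast traversal", {
  set.seed(5)
  for (s in 1:25) {
    f <- make_fixture(sample(c("resolved", "sd"), 1), sample(4:18, 1), seed = s)
    g <- f$genome
    m <- matching_from_homology(g)
    sng <- build_sng(g)
    c_plain <- classify_components(decompose(sng, m), m)
    c_caps <- classify_components(decompose(add_pseudo_caps(sng), m), m)
    expect_identical(unclass(c_plain), unclass(c_caps))
    idx <- dcjhalving:::genome_index(g)
    c_fast <- dcjhalving:::census_from_partner(
      idx, dcjhalving:::matching_partner(idx, m))
    expect_identical(unclass(c_plain), unclass(c_fast))
  }
})

test_that("census invariants hold on random fixtures", {
  set.seed(6)
  for (s in 1:40) {
    f <- make_fixture("resolved", sample(4:25, 1), seed = s + 500)
    g <- f$genome
    m <- matching_from_homology(g)
    idx <- dcjhalving:::genome_index(g)
    cen <- dcjhalving:::census_from_partner(
      idx, dcjhalving:::matching_partner(idx, m))
    # total pier count is even
    expect_equal((cen$piers_even + cen$piers_odd) %% 2L, 0L)
    # odd components pair up: total extremity edges are even
    expect_equal((cen$c_odd + cen$viaducts_odd + cen$piers_odd +
                    cen$pontoons_odd) %% 2L, 0L)
    # every extremity is covered: counted via the graph classification too
    sng <- build_sng(g)
    simple <- decompose(sng, m)
    comp <- igraph::components(simple)
    expect_equal(sum(comp$csize), 2L * idx$M)
  }
})

test_that("parallel adjacency and extremity edges form a valid 2-edge odd cycle", {
  g <- new_genome(list(c("-1", "2")))  # adjacency {t1, t2} with 1 == 2
  h <- homology(list(c("1", "2")))
  m <- matching_from_homology(g, h)
  cen <- classify_components(decompose(build_sng(g, h), m), m)
  expect_equal(cen$c_odd, 1L)
})

test_that("DOT export lists every edge", {
  g <- new_genome(list(c("1", "2")), circular = TRUE)
  path <- tempfile(fileext = ".dot")
  sng_to_dot(build_sng(g), path)
  txt <- readLines(path)
  expect_equal(sum(grepl("--", txt, fixed = TRUE)), ecount(build_sng(g)))
})
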