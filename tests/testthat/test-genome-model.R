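test_that("parsing derives chromosomes, occurrences and adjacencies", {
  gs <- parse_genomes(">A\n1 -2 |\n3 )")
  expect_length(gs, 1)
  g <- gs[[1]]
  expect_equal(g$name, "A")
  expect_length(g$chromosomes, 2)
  expect_false(g$chromosomes[[1]]$circular)
  expect_true(g$chromosomes[[2]]$circular)
  idx <- dcjhalving:::genome_index(g)
  # linear [1, -2]: adjacency head(1)-head(2); circular [3]: head(3)-tail(3)
  expect_equal(idx$adj[2], 4L)
  expect_equal(idx$adj[6], 5L)
  expect_equal(sum(idx$adj == 0), 2)  # telomeres t1, t2

  # empty genome
  e <- parse_genomes(">A\n")[[1]]
  expect_length(e$chromosomes, 0)

  # occurrence numbering in reading order
  g2 <- parse_genomes(">A\n1 2 3 1 |")[[1]]
  idx2 <- dcjhalving:::genome_index(g2)
  expect_equal(idx2$label, c("1.1", "2.1", "3.1", "1.2"))
  expect_equal(sum(idx2$fam == "1"), 2)
})

test_that("parser rejects malformed input", {
  expect_error(parse_genomes(">A\n1 2\n>B\n3 |"), "not terminated")
  expect_error(parse_genomes(">A\n1 |\n>A\n2 |"), "duplicate genome name")
  expect_error(parse_genomes(">A\n|"), "empty chromosome")
  expect_error(parse_genomes("1 2 |"), "before any")
})

test_that("writing canonicalizes and round-trips", {
  expect_equal(write_genomes(list()), "")
  g <- new_genome(list(c("3", "1", "2")), circular = TRUE, name = "A")
  expect_match(write_genomes(g), "1 2 3 )", fixed = TRUE)
  # round trip equals canonical form, including comments and glued terminators
  txt <- ">X\n# comment\n1 -2 3|\n-4 5 )\n>Y\n7 |"
  gs <- parse_genomes(txt)
  gs2 <- parse_genomes(write_genomes(gs))
  expect_length(gs2, 2)
  for (i in 1:2) expect_true(genomes_equal(gs[[i]], gs2[[i]]))
})

test_that("DCJ application follows the cut-and-join bookkeeping", {
  g <- new_genome(list(c("1", "2", "4", "3")), circular = TRUE)
  op <- op_dcj(list(c("h1.1", "t2.1"), c("h4.1", "t3.1")),
               list(c("h1.1", "t3.1"), c("t2.1", "h4.1")))
  g2 <- apply_operation(g, op)
  expect_true(genomes_equal(
    g2, new_genome(list(c("1", "3"), c("2", "4")), circular = c(TRUE, TRUE))))
  # inverse DCJ restores the genome
  inv <- op_dcj(list(c("h1.1", "t3.1"), c("t2.1", "h4.1")),
                list(c("h1.1", "t2.1"), c("h4.1", "t3.1")))
  expect_true(genomes_equal(apply_operation(g2, inv), g))
  # operand errors
  expect_error(apply_operation(g, op_dcj(list(c("h1.1", "t3.1")), list())),
               "adjacency not present")
  expect_error(apply_operation(g, op_dcj(list("h1.1"), list())),
               "not a telomere")
})

test_that("deletions and insertions edit segments", {
  g <- new_genome(list(c("1", "2", "3")), circular = TRUE)
  g2 <- apply_operation(g, op_deletion("2.1"))
  expect_true(genomes_equal(g2, new_genome(list(c("1", "3")), circular = TRUE)))
  idx2 <- dcjhalving:::genome_index(g2)
  expect_equal(idx2$M, 2L)

  lin <- new_genome(list("1"))
  ins <- apply_operation(lin, op_insertion("1"))
  expect_length(ins$chromosomes, 2)
  expect_equal(dcjhalving:::genome_index(ins)$label, c("1.1", "1.2"))

  # insertion into an adjacency
  g3 <- apply_operation(g, op_insertion("9", list(adjacency = c("h1.1", "t2.1"))))
  expect_true(genomes_equal(g3, new_genome(list(c("1", "9", "2", "3")),
                                           circular = TRUE)))
  # non-contiguous deletion segment
  g4 <- new_genome(list(c("1", "2", "3", "4")))
  expect_error(apply_operation(g4, op_deletion(c("1.1", "3.1"))),
               "not contiguous")
})

test_that("operations preserve the adjacency matching and marker counts", {
  set.seed(11)
  for (rep in 1:20) {
    f <- make_fixture("resolved", sample(6:15, 1), seed = rep)
    g <- f$genome
    op <- random_dcj(g)
    if (is.null(op)) next
    g2 <- apply_operation(g, op)
    idx <- dcjhalving:::genome_index(g2)
    # adjacency set is a matching: symmetric, no extremity twice
    has <- which(idx$adj > 0)
    expect_true(all(idx$adj[idx$adj[has]] == has))
    expect_equal(dcjhalving:::n_markers(g2), dcjhalving:::n_markers(g))
  }
})

test_that("structural doubling test follows the adjacency pairing rule", {
  h <- homology(list(c("1", "3"), c("2", "4")))
  expect_true(is_sd(new_genome(list(c("1", "2", "3", "4")), circular = TRUE), hom = h))
  expect_false(is_sd(new_genome(list(c("1", "2", "4", "3")), circular = TRUE), hom = h))
  expect_true(is_sd(new_genome(list()), marker_matching()))
  # unmatched marker forbids SD
  expect_false(is_sd(new_genome(list(c("1", "2", "3", "4", "5")), circular = TRUE), hom = h))
})

test_that("circular singletons are detected", {
  g <- parse_genomes(">A\n1 2 |\n3 )")[[1]]
  h <- homology(list(c("1", "2")))
  cs <- find_circular_singletons(g, hom = h)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$family, "3")
  expect_length(find_circular_singletons(new_genome(list(c("1", "2"))),
                                         marker_matching()), 0)
  # circular chromosome with one matched marker is not a singleton
  g2 <- parse_genomes(">A\n1 |\n3 4 )")[[1]]
  expect_length(find_circular_singletons(g2, hom = homology(list(c("1", "4")))), 0)
})

test_that("scenario files round-trip through the grammar", {
  ops <- list(
    op_dcj(list(c("h1.1", "t2.1"), "t3.1"), list(c("h1.1", "t3.1"))),
    op_deletion(c("2.1", "4.1")),
    op_insertion(c("5", "-6"), list(adjacency = c("h1.1", "t3.1"))),
    op_insertion("7"),
    op_insertion("8", "circular")
  )
  lines <- write_scenario(ops)
  back <- parse_scenario(lines)
  expect_equal(length(back), length(ops))
  for (i in seq_along(ops)) expect_equal(back[[i]]$kind, ops[[i]]$kind)
  expect_equal(back[[2]]$segment, c("2.1", "4.1"))
  expect_equal(back[[3]]$attach$adjacency, c("h1.1", "t3.1"))
})
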