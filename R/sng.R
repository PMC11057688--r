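# ---------------------------------------------------------------------------
# Supernatural graph (SNG): vertices are marker extremities, adjacency edges
# are the genome adjacencies, extremity edges connect equivalent extremities
# (tail-tail and head-head within a family).  Pseudo-caps are artificial
# vertices attached to telomeres so that every component contains at least
# one adjacency edge.  Built on igraph; multi-edges (parallel adjacency +
# extremity edge) are valid and kept.
# ---------------------------------------------------------------------------

#' Build the supernatural graph of a genome
#'
#' @param genome A `genome`.
#' @param hom A `homology` or `NULL` (families by marker name).
#' @return An igraph object with vertex attributes `name` (extremity label),
#'   `marker` (instance label), `side` (`"t"`/`"h"`), `chrom`, `cap`
#'   (pseudo-cap flag) and `ix` (vertex index used by the ILP), and edge
#'   attribute `etype` (`"adjacency"` or `"extremity"`).
#' @export
build_sng <- function(genome, hom = NULL) {
  idx <- genome_index(genome)
  M <- idx$M
  labs <- if (M) ext_label(idx, seq_len(2L * M)) else character(0)
  g <- igraph::make_empty_graph(n = 2L * M, directed = FALSE)
  igraph::V(g)$name <- labs
  igraph::V(g)$marker <- if (M) idx$label[(seq_len(2L * M) + 1L) %/% 2L] else character(0)
  igraph::V(g)$side <- if (M) ifelse(seq_len(2L * M) %% 2L == 1L, "t", "h") else character(0)
  igraph::V(g)$chrom <- if (M) idx$chrom[(seq_len(2L * M) + 1L) %/% 2L] else integer(0)
  igraph::V(g)$circular <- if (M) idx$circular[igraph::V(g)$chrom] else logical(0)
  igraph::V(g)$cap <- rep(FALSE, 2L * M)
  igraph::V(g)$ix <- seq_len(2L * M)
  # adjacency edges
  ea <- which(idx$adj > seq_len(2L * M))
  if (length(ea)) {
    g <- igraph::add_edges(g, rbind(idx$adj[ea], ea), etype = "adjacency")
  }
  # extremity edges: all same-side pairs within a family
  keys <- family_keys(genome, hom)
  for (ii in split(seq_len(M), keys)) {
    if (length(ii) < 2) next
    prs <- utils::combn(ii, 2)
    tails <- rbind(2L * prs[1, ] - 1L, 2L * prs[2, ] - 1L)
    heads <- rbind(2L * prs[1, ], 2L * prs[2, ])
    g <- igraph::add_edges(g, cbind(tails, heads), etype = "extremity")
  }
  g
}

#' Add pseudo-caps to a supernatural graph
#'
#' One new vertex and one adjacency edge per telomere. Pseudo-caps receive
#' indices lower than every regular vertex and never carry extremity edges.
#' @param sng An SNG from [build_sng()].
#' @return The augmented igraph.
#' @export
add_pseudo_caps <- function(sng) {
  adj_deg <- adjacency_degree(sng)
  telo <- which(adj_deg == 0L & !igraph::V(sng)$cap)
  if (length(telo) == 0) return(sng)
  nv <- igraph::vcount(sng)
  g <- igraph::add_vertices(sng, length(telo),
                            name = paste0("cap.", seq_along(telo)),
                            marker = NA_character_, side = "cap",
                            chrom = NA_integer_, circular = NA,
                            cap = TRUE, ix = NA_integer_)
  g <- igraph::add_edges(g, rbind(nv + seq_along(telo), telo), etype = "adjacency")
  # pseudo-caps get the lowest indices
  caps <- igraph::V(g)$cap
  igraph::V(g)$ix[caps] <- seq_len(sum(caps))
  igraph::V(g)$ix[!caps] <- sum(caps) + seq_len(sum(!caps))
  g
}

adjacency_degree <- function(sng) {
  el <- igraph::as_edgelist(sng, names = FALSE)
  et <- igraph::E(sng)$etype
  deg <- integer(igraph::vcount(sng))
  if (length(et)) {
    tab <- tabulate(c(el[et == "adjacency", 1], el[et == "adjacency", 2]),
                    nbins = igraph::vcount(sng))
    deg <- tab
  }
  deg
}

#' Restrict a supernatural graph to the extremity edges of a matching
#'
#' Keeps the extremity edges `{t_m, t_n}` and `{h_m, h_n}` for each matched
#' pair and drops all others; the result is simple (at most one extremity
#' edge per vertex), so every component is a simple path or cycle.
#'
#' @param sng An SNG (with or without pseudo-caps).
#' @param matching A `marker_matching` on the homology used to build the SNG.
#' @return The simple igraph decomposition.
#' @export
decompose <- function(sng, matching) {
  et <- igraph::E(sng)$etype
  el <- igraph::as_edgelist(sng, names = FALSE)
  mk <- igraph::V(sng)$marker
  keep <- et == "adjacency"
  if (any(et == "extremity")) {
    pk <- paste0(pmin(matching$pairs[, 1], matching$pairs[, 2]), "|",
                 pmax(matching$pairs[, 1], matching$pairs[, 2]))
    m1 <- mk[el[, 1]]; m2 <- mk[el[, 2]]
    ek <- paste0(pmin(m1, m2), "|", pmax(m1, m2))
    keep <- keep | (et == "extremity" & ek %in% pk)
  }
  g <- igraph::subgraph_from_edges(sng, which(keep), delete.vertices = FALSE)
  # simplicity check
  el2 <- igraph::as_edgelist(g, names = FALSE)
  ext2 <- igraph::E(g)$etype == "extremity"
  if (any(ext2)) {
    cnt <- tabulate(c(el2[ext2, 1], el2[ext2, 2]), nbins = igraph::vcount(g))
    if (any(cnt > 1)) stop("matching does not induce a simple decomposition")
  }
  g
}

#' Classify the components of a simple supernatural graph
#'
#' Walks every component of the decomposition and tallies cycles, viaducts,
#' piers and pontoons by parity of their extremity-edge count. Pseudo-cap
#' endpoints count as the telomere side; an isolated vertex that is both
#' telomere and lava counts as one even pier. Components of circular
#' singletons (circular chromosomes of only singular markers) are excluded
#' and reported in `circular_singletons`.
#'
#' @param simple A simple SNG from [decompose()].
#' @param matching The `marker_matching` that induced the decomposition.
#' @return A `component_census`.
#' @export
classify_components <- function(simple, matching) {
  nv <- igraph::vcount(simple)
  mk <- igraph::V(simple)$marker
  cap <- igraph::V(simple)$cap
  matched <- mk %in% as.vector(matching$pairs)
  # circular singleton chromosomes
  chrom <- igraph::V(simple)$chrom
  circ <- igraph::V(simple)$circular
  excl <- rep(FALSE, nv)
  l <- 0L
  for (k in unique(chrom[!is.na(chrom)])) {
    vk <- which(!is.na(chrom) & chrom == k)
    if (isTRUE(circ[vk[1]]) && !any(matched[vk])) { excl[vk] <- TRUE; l <- l + 1L }
  }
  el <- igraph::as_edgelist(simple, names = FALSE)
  et <- igraph::E(simple)$etype
  comp <- igraph::components(simple)$membership
  cnt <- c(c_even = 0L, c_odd = 0L, v_even = 0L, v_odd = 0L,
           p_even = 0L, p_odd = 0L, g_even = 0L, g_odd = 0L)
  deg <- igraph::degree(simple)
  has_ext <- rep(FALSE, nv)
  if (any(et == "extremity")) {
    has_ext[unique(c(el[et == "extremity", 1], el[et == "extremity", 2]))] <- TRUE
  }
  ecomp <- comp[el[, 1]]
  next_cnt <- tapply(et == "extremity", ecomp, sum)
  for (cid in seq_len(max(comp))) {
    vs <- which(comp == cid)
    if (any(excl[vs])) next
    nx <- if (as.character(cid) %in% names(next_cnt)) next_cnt[[as.character(cid)]] else 0L
    odd <- nx %% 2L == 1L
    ends <- vs[deg[vs] <= 1L]
    if (length(ends) == 0L) {            # cycle
      key <- if (odd) "c_odd" else "c_even"
    } else if (length(ends) == 1L && deg[ends] == 0L) {
      key <- "p_even"                    # isolated telomere-lava vertex
    } else {
      safe <- cap[ends] | has_ext[ends]  # telomere side: pseudo-cap or safe telomere
      lava <- sum(!safe)
      key <- if (lava == 2L) if (odd) "g_odd" else "g_even"
             else if (lava == 1L) if (odd) "p_odd" else "p_even"
             else if (odd) "v_odd" else "v_even"
    }
    cnt[key] <- cnt[key] + 1L
  }
  # a component must be a simple path or cycle
  if (any(deg > 2L)) stop("component is neither a simple path nor a simple cycle")
  present <- matching$pairs[, 1] %in% mk & matching$pairs[, 2] %in% mk
  component_census(n = sum(present),
                   c_even = cnt["c_even"], c_odd = cnt["c_odd"],
                   viaducts_even = cnt["v_even"], viaducts_odd = cnt["v_odd"],
                   piers_even = cnt["p_even"], piers_odd = cnt["p_odd"],
                   pontoons_even = cnt["g_even"], pontoons_odd = cnt["g_odd"],
                   circular_singletons = l)
}

#' Export a supernatural graph in DOT format
#' @param sng An SNG.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
sng_to_dot <- function(sng, path) {
  el <- igraph::as_edgelist(sng, names = TRUE)
  et <- igraph::E(sng)$etype
  lines <- c("graph sng {",
             paste0("  \"", igraph::V(sng)$name, "\";"),
             paste0("  \"", el[, 1], "\" -- \"", el[, 2], "\" [kind=", et,
                    ifelse(et == "extremity", ", style=dashed", ""), "];"),
             "}")
  writeLines(lines, path)
  invisible(path)
}
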