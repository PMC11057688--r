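# ---------------------------------------------------------------------------
# Fast component census on the simple supernatural graph induced by a
# resolved matching.  Vertices are extremities; adjacency edges come from the
# genome, extremity edges pair the same-side extremities of matched markers.
# Components of the simple graph are simple paths and cycles; the census
# classifies them into cycles (by parity of extremity-edge count), viaducts
# (paths ending in two telomeres), piers (telomere + lava vertex) and
# pontoons (two lava vertices).  Circular singletons are stripped first.
# ---------------------------------------------------------------------------

component_census <- function(n = 0L, c_even = 0L, c_odd = 0L,
                             viaducts_even = 0L, viaducts_odd = 0L,
                             piers_even = 0L, piers_odd = 0L,
                             pontoons_even = 0L, pontoons_odd = 0L,
                             circular_singletons = 0L) {
  cen <- list(n = as.integer(n), c_even = as.integer(c_even), c_odd = as.integer(c_odd),
              viaducts_even = as.integer(viaducts_even), viaducts_odd = as.integer(viaducts_odd),
              piers_even = as.integer(piers_even), piers_odd = as.integer(piers_odd),
              pontoons_even = as.integer(pontoons_even), pontoons_odd = as.integer(pontoons_odd),
              circular_singletons = as.integer(circular_singletons))
  if (any(unlist(cen) < 0)) stop("negative component counts")
  structure(cen, class = "component_census")
}

#' @export
print.component_census <- function(x, ...) {
  cat("Component census (n =", x$n, ", circular singletons =", x$circular_singletons, ")\n")
  cat(sprintf("  cycles     even %3d  odd %3d\n", x$c_even, x$c_odd))
  cat(sprintf("  viaducts   even %3d  odd %3d\n", x$viaducts_even, x$viaducts_odd))
  cat(sprintf("  piers      even %3d  odd %3d\n", x$piers_even, x$piers_odd))
  cat(sprintf("  pontoons   even %3d  odd %3d\n", x$pontoons_even, x$pontoons_odd))
  invisible(x)
}

# Census from a genome index and an instance partner vector (0 = singular).
census_from_partner <- function(idx, partner) {
  M <- idx$M
  if (M == 0) return(component_census())
  excl <- rep(FALSE, M)
  l <- 0L
  for (k in seq_along(idx$circular)) {
    if (!idx$circular[k]) next
    ii <- which(idx$chrom == k)
    if (length(ii) && all(partner[ii] == 0L)) { excl[ii] <- TRUE; l <- l + 1L }
  }
  nE <- 2L * M
  extP <- integer(nE)
  m <- which(partner > 0L)
  extP[2L * m - 1L] <- 2L * partner[m] - 1L
  extP[2L * m] <- 2L * partner[m]
  adj <- idx$adj
  visited <- logical(nE)
  if (any(excl)) visited[c(2L * which(excl) - 1L, 2L * which(excl))] <- TRUE
  cnt <- c(c_even = 0L, c_odd = 0L, v_even = 0L, v_odd = 0L,
           p_even = 0L, p_odd = 0L, g_even = 0L, g_odd = 0L)
  deg <- (adj > 0L) + (extP > 0L)
  endpoints <- which(!visited & deg <= 1L)
  for (s in endpoints) {
    if (visited[s]) next
    visited[s] <- TRUE
    if (deg[s] == 0L) {           # isolated telomere-lava vertex: one even pier
      cnt["p_even"] <- cnt["p_even"] + 1L
      next
    }
    nx <- 0L
    use_ext <- extP[s] > 0L
    v <- s
    repeat {
      nxt <- if (use_ext) extP[v] else adj[v]
      if (nxt == 0L) break
      if (use_ext) nx <- nx + 1L
      v <- nxt
      visited[v] <- TRUE
      use_ext <- !use_ext
    }
    lava <- (extP[s] == 0L) + (extP[v] == 0L)
    odd <- nx %% 2L == 1L
    key <- if (lava == 2L) if (odd) "g_odd" else "g_even"
           else if (lava == 1L) if (odd) "p_odd" else "p_even"
           else if (odd) "v_odd" else "v_even"
    cnt[key] <- cnt[key] + 1L
  }
  for (s in which(!visited)) {    # remaining components are cycles
    if (visited[s]) next
    nx <- 0L
    v <- s
    use_ext <- TRUE
    repeat {
      visited[v] <- TRUE
      nxt <- if (use_ext) extP[v] else adj[v]
      if (use_ext) nx <- nx + 1L
      use_ext <- !use_ext
      v <- nxt
      if (v == s && use_ext) break
    }
    if (nx %% 2L == 1L) cnt["c_odd"] <- cnt["c_odd"] + 1L else cnt["c_even"] <- cnt["c_even"] + 1L
  }
  component_census(n = sum(partner > 0L) / 2L,
                   c_even = cnt["c_even"], c_odd = cnt["c_odd"],
                   viaducts_even = cnt["v_even"], viaducts_odd = cnt["v_odd"],
                   piers_even = cnt["p_even"], piers_odd = cnt["p_odd"],
                   pontoons_even = cnt["g_even"], pontoons_odd = cnt["g_odd"],
                   circular_singletons = l)
}
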