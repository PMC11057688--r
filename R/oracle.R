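# ---------------------------------------------------------------------------
# Brute-force reference implementations used to validate the closed-form
# distance and the ILP on toy instances.
# ---------------------------------------------------------------------------

#' Brute-force restricted halving distance
#'
#' Breadth-first search over all genomes reachable by DCJ operations,
#' deletions of contiguous singular segments, and insertions of the single
#' missing homolog of a singular marker, until a structurally doubled genome
#' is reached. Exponential; intended for instances with at most about six
#' markers.
#'
#' @param genome A `genome`.
#' @param matching A `marker_matching`, or `NULL` to use the matching of the
#'   (resolved) homology `hom`.
#' @param hom Optional `homology`.
#' @param max_depth Search depth limit.
#' @param allow_insertions Include insertion moves (single-marker segments;
#'   longer insertions are compositions within the depth bound).
#' @param size_guard Error out above this many markers.
#' @return The minimum scenario length, or `NA` if above `max_depth`.
#' @export
bruteforce_halving <- function(genome, matching = NULL, hom = NULL,
                               max_depth = 6L, allow_insertions = TRUE,
                               size_guard = 8L) {
  idx <- genome_index(genome)
  if (idx$M > size_guard) stop("instance too large for the brute-force oracle")
  if (is.null(matching)) matching <- matching_from_homology(genome, hom)
  partner <- matching_partner(idx, matching)
  chroms <- lapply(seq_along(idx$circular), function(k) {
    ii <- which(idx$chrom == k)
    as.integer(ii * idx$sign[ii])
  })
  res <- oracle_bfs_cpp(chroms, idx$circular, as.integer(partner),
                        as.integer(max_depth), isTRUE(allow_insertions))
  if (res < 0) NA_integer_ else as.integer(res)
}

# all perfect pairings of a vector (used per family)
perfect_pairings <- function(v) {
  if (length(v) == 0) return(list(list()))
  out <- list()
  a <- v[1]
  for (j in 2:length(v)) {
    rest <- v[-c(1, j)]
    for (p in perfect_pairings(rest)) {
      out[[length(out) + 1L]] <- c(list(c(a, v[j])), p)
    }
  }
  out
}

#' Enumerate all maximum matchings of a homology
#'
#' Every family of size f contributes its pairings with at most one singular
#' marker: (f-1)!! pairings for even f and f times (f-2)!! for odd f;
#' matchings combine across families.
#'
#' @inheritParams is_resolved
#' @param family_guard Error out if any family is larger than this.
#' @return List of `marker_matching` objects.
#' @export
enumerate_maximum_matchings <- function(genome, hom = NULL, family_guard = 6L) {
  idx <- genome_index(genome)
  keys <- family_keys(genome, hom)
  fams <- split(seq_len(idx$M), keys)
  if (any(lengths(fams) > family_guard)) stop("family too large for enumeration")
  per_family <- lapply(fams, function(ii) {
    if (length(ii) < 2) return(list(list()))
    if (length(ii) %% 2L == 0L) return(perfect_pairings(ii))
    out <- list()
    for (s in seq_along(ii)) {
      for (p in perfect_pairings(ii[-s])) out[[length(out) + 1L]] <- p
    }
    out
  })
  combos <- list(list())
  for (pf in per_family) {
    combos <- unlist(lapply(combos, function(acc) {
      lapply(pf, function(p) c(acc, p))
    }), recursive = FALSE)
  }
  lapply(combos, function(prs) {
    if (length(prs) == 0) return(marker_matching())
    marker_matching(t(vapply(prs, function(p) idx$label[p], character(2))))
  })
}

#' Minimum halving distance over all maximum matchings
#'
#' Exhaustive counterpart of the ILP for small natural genomes: evaluates the
#' closed-form distance under every maximum matching and returns the minimum.
#'
#' @inheritParams enumerate_maximum_matchings
#' @return Integer distance.
#' @export
min_over_matchings <- function(genome, hom = NULL, family_guard = 6L) {
  ms <- enumerate_maximum_matchings(genome, hom, family_guard)
  min(vapply(ms, function(m) halving_distance(genome, matching = m)$distance,
             integer(1)))
}
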