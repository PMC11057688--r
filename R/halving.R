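# ---------------------------------------------------------------------------
# Restricted DCJ-indel halving distance for resolved homologies.
#
#   d = l + n - c_even + ceil((q + delta) / 2)
#
# with l the number of circular singletons (each costs one deletion and is
# stripped in preprocessing), n the number of matched marker pairs, c_even
# the even cycles of the simple supernatural graph,
#   q = pontoons_odd + max(piers_even, piers_odd) - viaducts_odd,
# and delta = 1 exactly when pontoons_odd is odd and the two pier counts are
# equal.  The half-sum is taken as a ceiling so the distance is always an
# integer; in the singular-free limit this reduces to
# n - c_even - floor(viaducts_odd / 2), the classical DCJ halving formula.
# ---------------------------------------------------------------------------

#' Halving distance from a component census
#'
#' @param census A `component_census` (from [classify_components()] or
#'   internally from [halving_distance()]).
#' @return A `halving_breakdown` with fields `n`, `c_even`, `q`, `delta`,
#'   `circular_singletons` and `distance`.
#' @export
halving_distance_census <- function(census) {
  stopifnot(inherits(census, "component_census"))
  q <- census$pontoons_odd + max(census$piers_even, census$piers_odd) -
    census$viaducts_odd
  delta <- as.integer(census$pontoons_odd %% 2L == 1L &&
                        census$piers_even == census$piers_odd)
  d <- census$circular_singletons + census$n - census$c_even +
    as.integer(ceiling((q + delta) / 2))
  structure(list(n = census$n, c_even = census$c_even, q = q, delta = delta,
                 circular_singletons = census$circular_singletons,
                 distance = as.integer(d), census = census),
            class = "halving_breakdown")
}

#' @export
print.halving_breakdown <- function(x, ...) {
  cat("DCJ-indel halving distance:", x$distance, "\n")
  cat(sprintf("  n = %d, even cycles = %d, q = %d, delta = %d, circular singletons = %d\n",
              x$n, x$c_even, x$q, x$delta, x$circular_singletons))
  invisible(x)
}

#' Restricted DCJ-indel halving distance of a genome
#'
#' Computes the exact halving distance for a genome with resolved homology
#' (every family of size at most two) in time near-linear in the marker
#' count. For unresolved homologies use [halve_natural()].
#'
#' @param genome A `genome`.
#' @param hom A `homology` or `NULL` (families by marker name).
#' @param matching Optionally an explicit `marker_matching`; overrides `hom`.
#' @return A `halving_breakdown`.
#' @examples
#' g <- new_genome(list(c("1", "2", "4", "3")), circular = TRUE)
#' halving_distance(g, homology(list(c("1", "3"), c("2", "4"))))$distance
#' @export
halving_distance <- function(genome, hom = NULL, matching = NULL) {
  idx <- genome_index(genome)
  if (is.null(matching)) matching <- matching_from_homology(genome, hom)
  partner <- matching_partner(idx, matching)
  halving_distance_census(census_from_partner(idx, partner))
}

# partner extremity under a matching partner vector
partner_ext <- function(partner, e) {
  i <- (e + 1L) %/% 2L
  p <- partner[i]
  if (p == 0L) 0L else 2L * p - (e %% 2L)
}

# ---------------------------------------------------------------------------
# Sorting: produce an optimal scenario of DCJs and singular-segment deletions
# transforming the genome into a structurally doubled one.  Each accepted
# step lowers the distance by exactly one (checked at run time); candidate
# operations are generated from the component structure in the order that
# mirrors how they pay into the formula (circular-singleton deletions, even
# cycle extraction, lava-end merges, singular-run deletions, pier cuts), with
# a full enumeration fallback guaranteeing totality.
# ---------------------------------------------------------------------------

# maximal runs of singular markers per chromosome (instance index vectors)
singular_runs <- function(idx, partner) {
  runs <- list()
  for (k in seq_along(idx$circular)) {
    ii <- which(idx$chrom == k)
    sing <- partner[ii] == 0L
    if (!any(sing)) next
    if (all(sing)) { runs[[length(runs) + 1L]] <- ii; next }
    r <- rle(sing)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- lapply(which(r$values), function(j) ii[starts[j]:ends[j]])
    if (idx$circular[k] && length(segs) > 1 && r$values[1] && r$values[length(r$values)]) {
      # wrap-around run on a circular chromosome
      segs[[1]] <- c(segs[[length(segs)]], segs[[1]])
      segs[[length(segs)]] <- NULL
    }
    runs <- c(runs, segs)
  }
  runs
}

# DCJ candidate doubling adjacency (a,b): cut the adjacencies/telomeres at
# the partner extremities and join them, extracting an even 2-cycle.
extract_cycle_op <- function(idx, partner, a, b) {
  ap <- partner_ext(partner, a); bp <- partner_ext(partner, b)
  if (ap == 0L || bp == 0L) return(NULL)
  if (idx$adj[ap] == bp) return(NULL)          # already doubled
  x <- idx$adj[ap]; y <- idx$adj[bp]
  site1 <- if (x == 0L) ap else c(ap, x)
  site2 <- if (y == 0L) bp else c(bp, y)
  if (length(intersect(site1, site2)) > 0) return(NULL)
  join <- list(ext_label(idx, c(ap, bp)))
  if (x != 0L && y != 0L) join <- c(join, list(ext_label(idx, c(x, y))))
  op_dcj(list(ext_label(idx, site1), ext_label(idx, site2)), join)
}

# lava path endpoints: extremities without extremity edge, outside circular
# singletons
lava_ends <- function(idx, partner) {
  sing <- which(partner == 0L)
  if (length(sing) == 0) return(integer(0))
  excl <- rep(FALSE, idx$M)
  for (k in seq_along(idx$circular)) {
    if (!idx$circular[k]) next
    ii <- which(idx$chrom == k)
    if (length(ii) && all(partner[ii] == 0L)) excl[ii] <- TRUE
  }
  sing <- sing[!excl[sing]]
  c(2L * sing - 1L, 2L * sing)
}

sort_candidates <- function(genome, idx, partner) {
  ops <- list()
  # 1. circular singleton deletions
  for (k in seq_along(idx$circular)) {
    if (!idx$circular[k]) next
    ii <- which(idx$chrom == k)
    if (length(ii) && all(partner[ii] == 0L)) {
      ops[[length(ops) + 1L]] <- op_deletion(idx$label[ii])
    }
  }
  # 2. even-cycle extraction from every adjacency with two safe ends
  aa <- which(idx$adj > seq_along(idx$adj))
  for (a in aa) {
    op <- extract_cycle_op(idx, partner, a, idx$adj[a])
    if (!is.null(op)) ops[[length(ops) + 1L]] <- op
  }
  # doubling of telomeres: free the partner extremity of a telomere so the
  # two form an odd viaduct
  telo <- which(idx$adj == 0L & seq_along(idx$adj) <= 2L * idx$M)
  for (s in telo) {
    sp <- partner_ext(partner, s)
    if (sp == 0L || idx$adj[sp] == 0L) next
    ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, c(sp, idx$adj[sp]))), list())
  }
  # 3. merges / closures of lava ends
  le <- lava_ends(idx, partner)
  if (length(le) >= 2) {
    prs <- utils::combn(le, 2)
    for (j in seq_len(ncol(prs))) {
      u <- prs[1, j]; w <- prs[2, j]
      if ((u + 1L) %/% 2L == (w + 1L) %/% 2L) next   # two ends of one marker
      x <- idx$adj[u]; y <- idx$adj[w]
      if (x == w || y == u) next                     # u,w already adjacent
      s1 <- if (x == 0L) u else c(u, x)
      s2 <- if (y == 0L) w else c(w, y)
      if (length(intersect(s1, s2)) > 0) next
      jset <- list(list(c(u, w)))
      if (x != 0L && y != 0L) {
        jset[[1]] <- list(c(u, w), c(x, y))
        jset[[2]] <- list(c(u, y), c(x, w))
      } else if (x == 0L && y != 0L) {
        jset[[2]] <- list(c(u, y))
      } else if (x != 0L && y == 0L) {
        jset[[2]] <- list(c(x, w))
      }
      for (jn in jset) {
        ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, s1), ext_label(idx, s2)),
                                          lapply(jn, function(p) ext_label(idx, p)))
      }
    }
  }
  # 4. deletions of maximal singular runs
  for (run in singular_runs(idx, partner)) {
    ops[[length(ops) + 1L]] <- op_deletion(idx$label[run])
  }
  # 5. pier cuts: split off a lava end
  for (u in le) {
    if (idx$adj[u] != 0L) {
      ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, c(u, idx$adj[u]))), list())
    }
  }
  ops
}

# exhaustive operation enumeration (fallback; guarantees a decreasing step
# exists whenever the distance is positive)
all_operations <- function(genome, idx, partner) {
  ops <- list()
  sites <- list()
  aa <- which(idx$adj > seq_along(idx$adj))
  for (a in aa) sites[[length(sites) + 1L]] <- c(a, idx$adj[a])
  for (s in which(idx$adj == 0L)) sites[[length(sites) + 1L]] <- s
  ns <- length(sites)
  if (ns >= 2) {
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      s1 <- sites[[i]]; s2 <- sites[[j]]
      ends1 <- s1; ends2 <- s2
      # all rejoin matchings between freed ends
      if (length(ends1) == 2 && length(ends2) == 2) {
        ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, s1), ext_label(idx, s2)),
          list(ext_label(idx, c(ends1[1], ends2[1])), ext_label(idx, c(ends1[2], ends2[2]))))
        ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, s1), ext_label(idx, s2)),
          list(ext_label(idx, c(ends1[1], ends2[2])), ext_label(idx, c(ends1[2], ends2[1]))))
      } else if (length(ends1) + length(ends2) == 3) {
        two <- if (length(ends1) == 2) ends1 else ends2
        one <- if (length(ends1) == 1) ends1 else ends2
        ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, s1), ext_label(idx, s2)),
          list(ext_label(idx, c(two[1], one))))
        ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, s1), ext_label(idx, s2)),
          list(ext_label(idx, c(two[2], one))))
      } else {
        ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, s1), ext_label(idx, s2)),
          list(ext_label(idx, c(ends1, ends2))))
      }
    }
  }
  for (i in seq_len(ns)) {
    if (length(sites[[i]]) == 2) {
      ops[[length(ops) + 1L]] <- op_dcj(list(ext_label(idx, sites[[i]])), list())
    }
  }
  # deletions: all contiguous singular sub-runs
  for (run in singular_runs(idx, partner)) {
    nr <- length(run)
    for (i in seq_len(nr)) for (j in i:nr) {
      ops[[length(ops) + 1L]] <- op_deletion(idx$label[run[i:j]])
    }
  }
  ops
}

#' Optimally sort a genome to a structurally doubled ancestor
#'
#' Produces a scenario of DCJ operations and singular-segment deletions whose
#' length equals the halving distance, together with the reconstructed
#' structurally doubled genome.
#'
#' @inheritParams halving_distance
#' @return A list of class `halving_scenario` with elements `operations`,
#'   `final` (the SD genome), `matching` and `distance`.
#' @export
sort_halving <- function(genome, hom = NULL, matching = NULL) {
  if (is.null(matching)) matching <- matching_from_homology(genome, hom)
  g <- genome
  scenario <- list()
  repeat {
    idx <- genome_index(g)
    partner <- matching_partner(idx, matching)
    d <- halving_distance_census(census_from_partner(idx, partner))$distance
    if (d == 0L) break
    found <- FALSE
    for (stage in 1:2) {
      cands <- if (stage == 1) sort_candidates(g, idx, partner)
               else all_operations(g, idx, partner)
      for (op in cands) {
        g2 <- tryCatch(apply_operation(g, op), error = function(e) NULL)
        if (is.null(g2)) next
        idx2 <- genome_index(g2)
        d2 <- halving_distance_census(
          census_from_partner(idx2, matching_partner(idx2, matching)))$distance
        if (d2 == d - 1L) {
          scenario[[length(scenario) + 1L]] <- op
          g <- g2
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-decreasing operation found")
  }
  structure(list(operations = scenario, final = g, matching = matching,
                 distance = length(scenario)),
            class = "halving_scenario")
}

#' @export
print.halving_scenario <- function(x, ...) {
  cat("Halving scenario with", x$distance, "operations\n")
  for (ln in write_scenario(x$operations)) cat(" ", ln, "\n")
  invisible(x)
}

#' Verify a halving scenario
#'
#' Checks that every operation applies cleanly, that indels respect the
#' restricted model (only singular markers deleted; an inserted marker is the
#' homolog of a singular marker, at most one per singular marker), and that
#' the final genome is structurally doubled.
#'
#' @param genome Starting `genome`.
#' @param scenario A `halving_scenario` or plain list of operations.
#' @param matching A `marker_matching` on the starting genome, or `NULL` for
#'   the matching of the (resolved) `hom`.
#' @param hom Optional `homology` (used to pair inserted homologs).
#' @return Logical; on failure the attribute `"log"` carries a diagnostic.
#' @export
verify_scenario <- function(genome, scenario, matching = NULL, hom = NULL) {
  ops <- if (inherits(scenario, "halving_scenario")) scenario$operations else scenario
  if (is.null(matching)) matching <- matching_from_homology(genome, hom)
  fail <- function(msg) structure(FALSE, log = msg)
  pairs <- matching$pairs
  g <- genome
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    idx <- genome_index(g)
    partner <- matching_partner(idx, marker_matching(pairs))
    if (op$kind == "deletion") {
      seg <- match(op$segment, idx$label)
      if (anyNA(seg)) return(fail(paste("step", k, ": deletion of unknown instance")))
      if (any(partner[seg] != 0L)) {
        return(fail(paste("step", k, ": deletion of a matched marker")))
      }
    } else if (op$kind == "insertion") {
      keys_cur <- family_keys(g, hom)
      sgn_fams <- sub("^-", "", op$segment)
      hkey <- function(f) {
        m <- if (!is.null(hom)) hom$map[f] else NA
        ifelse(is.na(m), f, unname(m))
      }
      for (f in sgn_fams) {
        cand <- which(keys_cur == hkey(f) & partner == 0L)
        if (length(cand) == 0) {
          return(fail(paste("step", k, ": inserted marker", f,
                            "has no singular homolog")))
        }
      }
    }
    g2 <- tryCatch(apply_operation(g, op), error = function(e) e)
    if (inherits(g2, "error")) {
      return(fail(paste("step", k, ":", conditionMessage(g2))))
    }
    if (op$kind == "insertion") {
      # pair each inserted instance with a singular homolog
      idx_old <- idx
      idx2 <- genome_index(g2)
      new_lab <- setdiff(idx2$label, idx_old$label)
      keys2 <- family_keys(g2, hom)
      partner2 <- matching_partner(idx2, marker_matching(pairs))
      for (lab in new_lab) {
        i <- match(lab, idx2$label)
        cand <- which(keys2 == keys2[i] & partner2 == 0L & seq_along(keys2) != i &
                        !(idx2$label %in% new_lab))
        if (length(cand) == 0) {
          return(fail(paste("step", k, ": inserted marker", lab,
                            "has no singular homolog")))
        }
        j <- cand[1]
        pairs <- rbind(pairs, c(idx2$label[j], lab))
        partner2 <- matching_partner(idx2, marker_matching(pairs))
      }
    }
    g <- g2
  }
  if (!is_sd(g, marker_matching(pairs))) {
    return(fail("final genome is not structurally doubled"))
  }
  TRUE
}
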