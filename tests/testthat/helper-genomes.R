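# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files.

# all permutations of a multiset (small vectors only)
multiset_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    for (p in multiset_perms(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  out
}

# Exhaustive set of genomes with <= max_markers markers over the family
# patterns {all singular; one pair (+ singletons); two pairs} and all
# chromosome structures (1-2 chromosomes, each linear or circular), all sign
# patterns, deduplicated up to chromosome order / rotation / reflection and
# family relabeling.
enumerate_small_genomes <- function(max_markers = 4L) {
  patterns <- list()
  for (k in 1:max_markers) {
    patterns[[length(patterns) + 1L]] <- paste0("s", seq_len(k))
    if (k >= 2) {
      patterns[[length(patterns) + 1L]] <-
        c("a", "a", if (k > 2) paste0("s", seq_len(k - 2L)))
    }
    if (k == 4) patterns[[length(patterns) + 1L]] <- c("a", "a", "b", "b")
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (pat in patterns) {
    k <- length(pat)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
    for (p in multiset_perms(pat)) {
      splits <- list(list(seq_len(k)))
      if (k >= 2) {
        for (cut in seq_len(k - 1L)) {
          splits[[length(splits) + 1L]] <- list(seq_len(cut), (cut + 1L):k)
        }
      }
      for (sp in splits) {
        circs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(sp))))
        for (si in seq_len(nrow(signs))) {
          toks_all <- ifelse(signs[si, ] < 0, paste0("-", p), p)
          for (ci in seq_len(nrow(circs))) {
            g <- new_genome(lapply(sp, function(ii) toks_all[ii]), circs[ci, ],
                            name = "e")
            key <- write_genomes(g)
            # relabel families by first appearance (pair status kept) so
            # isomorphic labelings collapse to one key
            toks <- strsplit(gsub("[>|)\n]", " ", key), "[[:space:]]+")[[1]]
            toks <- toks[toks != "" & toks != "e"]
            fam <- sub("^-", "", toks)
            uf <- unique(fam)
            stat <- ifelse(uf %in% c("a", "b"), "p", "q")
            map2 <- stats::setNames(paste0(stat, seq_along(uf)), uf)
            key2 <- paste(ifelse(startsWith(toks, "-"),
                                 paste0("-", map2[fam]), map2[fam]),
                          collapse = " ")
            key2 <- paste(key2, paste(circs[ci, ], collapse = ""),
                          paste(lengths(sp), collapse = ","))
            if (exists(key2, envir = seen, inherits = FALSE)) next
            assign(key2, TRUE, envir = seen)
            out[[length(out) + 1L]] <- g
          }
        }
      }
    }
  }
  out
}

# post-WGD true operation count of a simulation result (WGD itself excluded)
true_post_wgd_ops <- function(res) {
  tr <- res$truth
  sum(tr$dcj[tr$post_wgd & !tr$wgd] + tr$insertions[tr$post_wgd & !tr$wgd] +
        tr$deletions[tr$post_wgd & !tr$wgd] + tr$duplications[tr$post_wgd & !tr$wgd])
}
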