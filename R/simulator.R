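# ---------------------------------------------------------------------------
# Tree-guided genome evolution simulator with a whole-genome duplication,
# DCJ rearrangements, Zipf-length segmental indels and tandem duplications.
# Emits the genomes at every tree node and an exact truth log per branch.
# ---------------------------------------------------------------------------

# Minimal recursive newick reader supporting unary internal nodes (the
# simulation trees are lineages like (((G)D)S)R; which general-purpose
# phylogenetics readers refuse or mis-number).  Returns an edge list of
# (parent label, child label) plus the root label.
parse_lineage_tree <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  s <- sub(";$", "", s)
  pos <- 1L
  nanon <- 0L
  read_label <- function() {
    start <- pos
    while (pos <= nchar(s) && !substr(s, pos, pos) %in% c("(", ")", ",", ";")) {
      pos <<- pos + 1L
    }
    lab <- substr(s, start, pos - 1L)
    lab <- sub(":[0-9.eE+-]*$", "", lab)   # drop branch length
    if (lab == "") { nanon <<- nanon + 1L; lab <- paste0("node", nanon) }
    lab
  }
  edges <- list()
  read_subtree <- function() {
    if (substr(s, pos, pos) == "(") {
      pos <<- pos + 1L
      children <- character(0)
      repeat {
        children <- c(children, read_subtree())
        ch <- substr(s, pos, pos)
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        stop("malformed newick string")
      }
      lab <- read_label()
      for (c in children) edges[[length(edges) + 1L]] <<- c(lab, c)
      lab
    } else {
      read_label()
    }
  }
  root <- read_subtree()
  list(root = root,
       edges = if (length(edges)) do.call(rbind, edges) else matrix(character(0), ncol = 2))
}

zipf_cache <- new.env(parent = emptyenv())

#' Sample segment lengths from a Zipf distribution
#'
#' Lengths l are drawn with probability l^(-a) / zeta(a) by inverse CDF on
#' precomputed tail sums, truncated where the remaining mass drops below
#' 1e-12 (renormalized).
#'
#' @param n Number of draws.
#' @param shape Shape parameter a > 1.
#' @return Integer vector of lengths.
#' @export
zipf_length <- function(n, shape) {
  if (shape <= 1) stop("Zipf shape must be > 1")
  key <- format(shape, digits = 15)
  if (!exists(key, envir = zipf_cache, inherits = FALSE)) {
    # truncation point: tail sum beyond L is below L^(1-a)/(a-1)
    L <- ceiling(((shape - 1) * 1e-12)^(1 / (1 - shape)))
    L <- min(max(L, 10), 1e6)
    p <- seq_len(L)^(-shape)
    assign(key, cumsum(p) / sum(p), envir = zipf_cache)
  }
  cdf <- get(key, envir = zipf_cache)
  findInterval(stats::runif(n), cdf) + 1L
}

#' Simulation parameters
#'
#' Defaults reproduce the reference protocol: 5000 markers on one linear
#' chromosome at the root of the lineage `(((G)D)S)R;`, a single WGD on the
#' branch into `D`, insertion/duplication rates 0.2/0.3 relative to the DCJ
#' count, deletion rate 1.0 after the WGD and 0 before it, and Zipf shape
#' parameters 6 (duplications) and 4 (indels).
#'
#' @param root_markers Markers at the root (one linear chromosome).
#' @param tree Newick lineage (unary nodes allowed).
#' @param ops_per_branch Number of DCJ operations per non-WGD branch.
#' @param ins_rate,dup_rate,del_rate Rates relative to the DCJ count.
#' @param pre_wgd_del_rate Deletion rate on branches before the WGD.
#' @param zipf_dup,zipf_indel Zipf shape parameters.
#' @param wgd_branch Child node label of the branch carrying the WGD.
#' @param seed Random seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(root_markers = 5000L, tree = "(((G)D)S)R;",
                       ops_per_branch = 2500L, ins_rate = 0.2, dup_rate = 0.3,
                       del_rate = 1.0, pre_wgd_del_rate = 0,
                       zipf_dup = 6, zipf_indel = 4,
                       wgd_branch = "D", seed = NULL) {
  stopifnot(root_markers >= 1, ops_per_branch >= 0,
            ins_rate >= 0, dup_rate >= 0, del_rate >= 0,
            zipf_dup > 1, zipf_indel > 1)
  tr <- parse_lineage_tree(tree)
  labs <- unique(c(tr$root, as.vector(tr$edges)))
  if (!wgd_branch %in% labs) stop("wgd_branch not found in tree")
  structure(list(root_markers = as.integer(root_markers), tree = tree,
                 parsed_tree = tr, ops_per_branch = as.integer(ops_per_branch),
                 ins_rate = ins_rate, dup_rate = dup_rate, del_rate = del_rate,
                 pre_wgd_del_rate = pre_wgd_del_rate,
                 zipf_dup = zipf_dup, zipf_indel = zipf_indel,
                 wgd_branch = wgd_branch, seed = seed),
            class = "sim_params")
}

# uniformly sample one DCJ on the genome: two distinct cut sites among
# adjacencies and telomeres, rejoined uniformly among the legal outcomes
#' Sample a random DCJ operation on a genome
#' @param genome A `genome`.
#' @return A `dcj_op`, or `NULL` if the genome has fewer than two cut sites.
#' @export
random_dcj <- function(genome) {
  idx <- genome_index(genome)
  if (idx$M == 0) return(NULL)
  sites <- list()
  for (a in which(idx$adj > seq_along(idx$adj))) sites[[length(sites) + 1L]] <- c(a, idx$adj[a])
  for (t in which(idx$adj == 0L)) sites[[length(sites) + 1L]] <- t
  if (length(sites) < 2) return(NULL)
  ij <- sample.int(length(sites), 2)
  s1 <- sites[[ij[1]]]; s2 <- sites[[ij[2]]]
  if (length(s1) == 2 && length(s2) == 2) {
    join <- if (stats::runif(1) < 0.5) {
      list(c(s1[1], s2[1]), c(s1[2], s2[2]))
    } else {
      list(c(s1[1], s2[2]), c(s1[2], s2[1]))
    }
  } else if (length(s1) + length(s2) == 3) {
    two <- if (length(s1) == 2) s1 else s2
    one <- if (length(s1) == 1) s1 else s2
    keep <- sample(two, 1)
    join <- list(c(keep, one))
  } else {
    join <- list(c(s1, s2))
  }
  op_dcj(lapply(list(s1, s2), function(s) ext_label(idx, s)),
         lapply(join, function(j) ext_label(idx, j)))
}

# segment choice helpers ----------------------------------------------------

pick_segment <- function(idx, len) {
  # chromosome weighted by marker count, uniform start, length truncated
  sizes <- tabulate(idx$chrom, nbins = length(idx$circular))
  k <- sample.int(length(sizes), 1, prob = sizes)
  ii <- which(idx$chrom == k)
  nk <- length(ii)
  start <- sample.int(nk, 1)
  if (idx$circular[k]) {
    len <- min(len, nk)
    sel <- ii[((start - 1L + seq_len(len) - 1L) %% nk) + 1L]
  } else {
    len <- min(len, nk - start + 1L)
    sel <- ii[start:(start + len - 1L)]
  }
  sel
}

sim_delete <- function(genome, idx, len) {
  total <- idx$M
  sel <- pick_segment(idx, len)
  if (length(sel) >= total) {
    if (total <= 1L) stop("deletion would empty the genome")
    sel <- sel[seq_len(total - 1L)]
  }
  # deleting a whole chromosome is allowed as long as the genome stays
  # non-empty; otherwise the segment is contiguous by construction
  apply_operation(genome, op_deletion(idx$label[sel]))
}

sim_duplicate <- function(genome, idx, len) {
  sel <- pick_segment(idx, len)
  k <- idx$chrom[sel[1]]
  ch <- genome$chromosomes[[k]]
  pos <- match(sel, which(idx$chrom == k))
  # tandem: copy of the segment inserted right after it (reading order)
  fams <- idx$fam[sel]; sgn <- idx$sign[sel]
  after <- pos[length(pos)]
  occ_used <- lapply(fams, function(f) idx$occ[idx$fam == f])
  new_occ <- integer(length(fams))
  seen <- list()
  for (j in seq_along(fams)) {
    prev <- c(occ_used[[j]], seen[[fams[j]]])
    new_occ[j] <- max(prev) + 1L
    seen[[fams[j]]] <- c(seen[[fams[j]]], new_occ[j])
  }
  ins_at <- after
  ch$family <- append(ch$family, fams, ins_at)
  ch$occ <- append(ch$occ, new_occ, ins_at)
  ch$sign <- append(ch$sign, sgn, ins_at)
  genome$chromosomes[[k]] <- ch
  genome
}

sim_insert <- function(genome, idx, len, counter) {
  fams <- paste0("n", counter + seq_len(len))
  sgn <- sample(c(-1L, 1L), len, replace = TRUE)
  toks <- ifelse(sgn < 0, paste0("-", fams), fams)
  if (idx$M == 0) {
    return(list(genome = apply_operation(genome, op_insertion(toks)),
                counter = counter + len))
  }
  sites <- list()
  for (a in which(idx$adj > seq_along(idx$adj))) sites[[length(sites) + 1L]] <- c(a, idx$adj[a])
  for (t in which(idx$adj == 0L)) sites[[length(sites) + 1L]] <- t
  s <- sites[[sample.int(length(sites), 1)]]
  at <- if (length(s) == 2) list(adjacency = ext_label(idx, s)) else list(telomere = ext_label(idx, s))
  list(genome = apply_operation(genome, op_insertion(toks, at)),
       counter = counter + len)
}

wgd <- function(genome) {
  idx <- genome_index(genome)
  occ_max <- new.env(parent = emptyenv())
  for (j in seq_len(idx$M)) {
    f <- idx$fam[j]
    cur <- if (exists(f, envir = occ_max, inherits = FALSE)) get(f, envir = occ_max) else 0L
    assign(f, max(cur, idx$occ[j]), envir = occ_max)
  }
  dup <- lapply(genome$chromosomes, function(ch) {
    occ <- integer(length(ch$family))
    for (j in seq_along(ch$family)) {
      f <- ch$family[j]
      cur <- get(f, envir = occ_max)
      occ[j] <- cur + 1L
      assign(f, occ[j], envir = occ_max)
    }
    list(family = ch$family, occ = occ, sign = ch$sign, circular = ch$circular)
  })
  structure(list(name = genome$name,
                 chromosomes = c(genome$chromosomes, dup)),
            class = "genome")
}

evolve_branch <- function(genome, params, post_wgd, counter) {
  nops <- params$ops_per_branch
  del_rate <- if (post_wgd) params$del_rate else params$pre_wgd_del_rate
  kinds <- c(rep("dcj", nops),
             rep("ins", round(params$ins_rate * nops)),
             rep("dup", round(params$dup_rate * nops)),
             rep("del", round(del_rate * nops)))
  kinds <- sample(kinds)
  log <- c(dcj = 0L, ins = 0L, del = 0L, dup = 0L)
  mlog <- c(ins = 0L, del = 0L, dup = 0L)   # marker-count bookkeeping
  for (kind in kinds) {
    idx <- genome_index(genome)
    m_before <- idx$M
    if (kind == "dcj") {
      op <- random_dcj(genome)
      if (is.null(op)) next
      genome <- apply_operation(genome, op)
    } else if (kind == "del") {
      genome <- sim_delete(genome, idx, zipf_length(1, params$zipf_indel))
    } else if (kind == "dup") {
      genome <- sim_duplicate(genome, idx, zipf_length(1, params$zipf_dup))
    } else {
      r <- sim_insert(genome, idx, zipf_length(1, params$zipf_indel), counter)
      genome <- r$genome; counter <- r$counter
    }
    log[kind] <- log[kind] + 1L
    if (kind != "dcj") mlog[kind] <- mlog[kind] + abs(n_markers(genome) - m_before)
  }
  list(genome = genome, log = log, mlog = mlog, counter = counter)
}

#' Simulate genome evolution with a whole-genome duplication
#'
#' Evolves a root genome of singular markers along the lineage tree. Each
#' non-WGD branch performs `ops_per_branch` DCJs plus rate-proportional
#' numbers of insertions, tandem duplications and deletions, interleaved
#' uniformly at random; the WGD branch duplicates every chromosome. The leaf
#' genome (node `G` in the default tree) is the halving input.
#'
#' @param params A `sim_params`.
#' @return A list of class `sim_result` with `genomes` (one per tree node)
#'   and `truth` (a data frame with per-branch operation counts).
#' @export
evolve <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  tr <- params$parsed_tree
  root_g <- new_genome(list(as.character(seq_len(params$root_markers))),
                       circular = FALSE, name = tr$root)
  genomes <- list()
  genomes[[tr$root]] <- root_g
  truth <- list()
  counter <- 0L
  recurse <- function(node, post_wgd) {
    kids <- tr$edges[tr$edges[, 1] == node, 2]
    for (child in kids) {
      g <- genomes[[node]]
      m_start <- n_markers(g)
      if (child == params$wgd_branch) {
        g <- wgd(g)
        lg <- c(dcj = 0L, ins = 0L, del = 0L, dup = 0L)
        ml <- c(ins = 0L, del = 0L, dup = 0L)
        is_wgd <- TRUE
        post <- TRUE
      } else {
        r <- evolve_branch(g, params, post_wgd, counter)
        g <- r$genome; lg <- r$log; ml <- r$mlog; counter <<- r$counter
        is_wgd <- FALSE
        post <- post_wgd
      }
      g$name <- child
      genomes[[child]] <<- g
      truth[[length(truth) + 1L]] <<- data.frame(
        parent = node, child = child, dcj = lg["dcj"], insertions = lg["ins"],
        deletions = lg["del"], duplications = lg["dup"], wgd = is_wgd,
        post_wgd = post, markers_start = m_start, markers_end = n_markers(g),
        inserted_markers = ml["ins"], deleted_markers = ml["del"],
        duplicated_markers = ml["dup"], row.names = NULL)
      recurse(child, post)
    }
  }
  recurse(tr$root, FALSE)
  truth <- do.call(rbind, truth)
  truth$total_ops <- truth$dcj + truth$insertions + truth$deletions + truth$duplications
  structure(list(genomes = genomes, truth = truth, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation over", length(x$genomes), "tree nodes\n")
  print(x$truth)
  invisible(x)
}

#' Generate a test fixture genome
#'
#' `"sd"` doubles a random genome (halving distance 0 by construction),
#' `"resolved"` caps family sizes at two, `"natural"` draws family sizes up
#' to four.
#'
#' @param kind One of `"sd"`, `"resolved"`, `"natural"`.
#' @param size Approximate number of markers.
#' @param seed Random seed.
#' @param singular_frac For `"resolved"`: fraction of markers that stay
#'   singular.
#' @return A list with elements `genome` and `hom` (`NULL`: by-name
#'   homology).
#' @export
make_fixture <- function(kind = c("resolved", "natural", "sd"), size = 20L,
                         seed = 1L, singular_frac = 0.3) {
  kind <- match.arg(kind)
  set.seed(seed)
  arrange <- function(names) {
    names <- sample(names)
    sgn <- sample(c("", "-"), length(names), replace = TRUE)
    toks <- paste0(sgn, names)
    nchrom <- sample(1:min(3, max(1, length(toks) %/% 2)), 1)
    splits <- sort(sample(seq_len(length(toks) - 1L),
                          min(nchrom - 1L, length(toks) - 1L)))
    parts <- split(toks, cumsum(seq_along(toks) %in% (splits + 1L)))
    circ <- sample(c(TRUE, FALSE), length(parts), replace = TRUE)
    new_genome(unname(parts), circ, name = paste0(kind, seed))
  }
  if (kind == "sd") {
    half <- max(1L, size %/% 2L)
    g <- arrange(as.character(seq_len(half)))
    list(genome = wgd(g), hom = NULL)
  } else if (kind == "resolved") {
    nsing <- round(size * singular_frac)
    npair <- max(0L, (size - nsing) %/% 2L)
    nsing <- size - 2L * npair
    names <- c(rep(as.character(seq_len(npair)), 2),
               if (nsing > 0) paste0("s", seq_len(nsing)))
    list(genome = arrange(names), hom = NULL)
  } else {
    names <- character(0); f <- 0L
    while (length(names) < size) {
      f <- f + 1L
      sz <- if (f == 1L) sample(3:4, 1) else sample(1:4, 1)  # ensure an ambiguous family
      names <- c(names, rep(as.character(f), sz))
    }
    names <- names[seq_len(size)]
    list(genome = arrange(names), hom = NULL)
  }
}
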