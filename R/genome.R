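#' @useDynLib dcjhalving, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Genome data model
#
# A genome is a set of chromosomes; each chromosome is an ordered list of
# signed marker instances, flagged linear or circular.  A marker instance is
# identified by its family name (a string) and an occurrence number that
# distinguishes copies of the same family within one genome.  Every instance
# has two extremities, a tail and a head.  Internally extremities are coded
# as integers: instance i has tail 2i-1 and head 2i.
# ---------------------------------------------------------------------------

#' Construct a genome from chromosome marker lists
#'
#' @param chromosomes A list of chromosomes. Each chromosome is a character
#'   vector of signed marker tokens (e.g. `c("1", "-2")`) or a numeric vector
#'   of signed integers. Marker names are family names; occurrence numbers
#'   are assigned in reading order, so the second appearance of family `"1"`
#'   becomes instance `1.2`.
#' @param circular Logical vector (recycled) flagging each chromosome as
#'   circular (`TRUE`) or linear (`FALSE`).
#' @param name Genome name.
#' @return An object of class `genome`.
#' @examples
#' g <- new_genome(list(c("1", "-2"), "3"), circular = c(FALSE, TRUE), name = "A")
#' @export
new_genome <- function(chromosomes = list(), circular = FALSE, name = "genome") {
  if (length(chromosomes) > 0) {
    circular <- rep_len(as.logical(circular), length(chromosomes))
  } else {
    circular <- logical(0)
  }
  occ_count <- new.env(parent = emptyenv())
  chrs <- vector("list", length(chromosomes))
  for (k in seq_along(chromosomes)) {
    toks <- chromosomes[[k]]
    if (is.numeric(toks)) toks <- ifelse(toks < 0, paste0("-", abs(toks)), as.character(toks))
    toks <- as.character(toks)
    if (length(toks) == 0) stop("empty chromosome")
    sign <- ifelse(startsWith(toks, "-"), -1L, 1L)
    fam <- sub("^[-+]", "", toks)
    if (any(fam == "")) stop("invalid marker token")
    occ <- integer(length(fam))
    for (j in seq_along(fam)) {
      prev <- if (exists(fam[j], envir = occ_count, inherits = FALSE)) get(fam[j], envir = occ_count) else 0L
      occ[j] <- prev + 1L
      assign(fam[j], occ[j], envir = occ_count)
    }
    chrs[[k]] <- list(family = fam, occ = occ, sign = sign, circular = circular[k])
  }
  structure(list(name = name, chromosomes = chrs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(">", x$name, "\n", sep = "")
  for (ch in x$chromosomes) {
    toks <- ifelse(ch$sign < 0, paste0("-", ch$family), ch$family)
    cat(paste(toks, collapse = " "), if (ch$circular) ")" else "|", "\n")
  }
  invisible(x)
}

n_markers <- function(genome) {
  sum(vapply(genome$chromosomes, function(ch) length(ch$family), integer(1)))
}

# ---------------------------------------------------------------------------
# Homology: an equivalence relation on marker families.  By default families
# are given by marker names; explicit groups may merge names (e.g. 1 == 3).
# ---------------------------------------------------------------------------

#' Define a homology relation on marker names
#'
#' By default every marker name is its own family. Explicit groups merge
#' names into one family, e.g. `homology(list(c("1", "3")))` declares markers
#' named 1 and 3 homologous.
#'
#' @param groups List of character vectors; each vector is one family of
#'   marker names. Names not listed remain singleton name-families.
#' @return Object of class `homology`.
#' @export
homology <- function(groups = list()) {
  map <- character(0)
  for (i in seq_along(groups)) {
    g <- as.character(groups[[i]])
    if (any(g %in% names(map))) stop("marker name in more than one homology group")
    map[g] <- paste0("grp", i)
  }
  structure(list(map = map), class = "homology")
}

family_keys <- function(genome, hom = NULL) {
  fams <- unlist(lapply(genome$chromosomes, `[[`, "family"))
  if (is.null(fams)) fams <- character(0)
  if (is.null(hom)) return(fams)
  stopifnot(inherits(hom, "homology"))
  mapped <- hom$map[fams]
  ifelse(is.na(mapped), fams, unname(mapped))
}

#' Test whether a homology is resolved on a genome
#'
#' A homology is resolved if every family has at most two member markers in
#' the genome.
#' @param genome A `genome`.
#' @param hom A `homology` or `NULL` (families given by marker names).
#' @return Logical.
#' @export
is_resolved <- function(genome, hom = NULL) {
  keys <- family_keys(genome, hom)
  length(keys) == 0 || max(table(keys)) <= 2
}

# ---------------------------------------------------------------------------
# Matching: a resolved sub-homology given as explicit pairs of instances.
# Instances are referred to by label "family.occ".
# ---------------------------------------------------------------------------

#' Construct a marker matching
#'
#' @param pairs A two-column character matrix (or list of length-2 vectors) of
#'   instance labels `"family.occ"`; each row pairs two marker instances.
#' @return Object of class `marker_matching`.
#' @export
marker_matching <- function(pairs = NULL) {
  if (is.null(pairs)) pairs <- matrix(character(0), ncol = 2)
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.character))
  if (length(pairs) == 0) pairs <- matrix(character(0), ncol = 2)
  stopifnot(is.matrix(pairs), ncol(pairs) == 2)
  if (anyDuplicated(as.vector(pairs))) stop("marker in more than one matching pair")
  structure(list(pairs = pairs), class = "marker_matching")
}

#' Derive the unique matching of a resolved homology
#'
#' For a resolved homology (all family sizes at most 2) the matching is
#' unique: each size-2 family forms one pair.
#' @inheritParams is_resolved
#' @return A `marker_matching`.
#' @export
matching_from_homology <- function(genome, hom = NULL) {
  idx <- genome_index(genome)
  keys <- family_keys(genome, hom)
  tab <- split(seq_along(keys), keys)
  sizes <- lengths(tab)
  if (any(sizes > 2)) {
    stop("homology is not resolved (family of size ", max(sizes),
         "); use the ILP solver for natural genomes")
  }
  prs <- tab[sizes == 2]
  pairs <- if (length(prs)) {
    t(vapply(prs, function(ii) idx$label[ii], character(2)))
  } else matrix(character(0), ncol = 2)
  marker_matching(pairs)
}

# Map a matching to a partner vector over instance indices (0 = singular).
matching_partner <- function(idx, matching) {
  partner <- integer(idx$M)
  if (nrow(matching$pairs) == 0) return(partner)
  a <- match(matching$pairs[, 1], idx$label)
  b <- match(matching$pairs[, 2], idx$label)
  bad <- is.na(a) | is.na(b)
  a <- a[!bad]; b <- b[!bad]
  partner[a] <- b
  partner[b] <- a
  partner
}

# ---------------------------------------------------------------------------
# Flat index of a genome: one row per marker instance, extremity coding and
# the derived adjacency matching on extremities.
# ---------------------------------------------------------------------------

genome_index <- function(genome) {
  chrs <- genome$chromosomes
  fam <- unlist(lapply(chrs, `[[`, "family")); if (is.null(fam)) fam <- character(0)
  occ <- unlist(lapply(chrs, `[[`, "occ"));    if (is.null(occ)) occ <- integer(0)
  sgn <- unlist(lapply(chrs, `[[`, "sign"));   if (is.null(sgn)) sgn <- integer(0)
  M <- length(fam)
  chrom <- rep(seq_along(chrs), vapply(chrs, function(ch) length(ch$family), integer(1)))
  label <- if (M) paste0(fam, ".", occ) else character(0)
  # extremities: tail = 2i-1, head = 2i; reading direction depends on sign
  left  <- ifelse(sgn > 0, 2L * seq_len(M) - 1L, 2L * seq_len(M))
  right <- ifelse(sgn > 0, 2L * seq_len(M), 2L * seq_len(M) - 1L)
  adj <- integer(2L * M)
  off <- 0L
  for (k in seq_along(chrs)) {
    nk <- length(chrs[[k]]$family)
    ii <- off + seq_len(nk)
    if (nk > 1) {
      r <- right[ii[-nk]]; l <- left[ii[-1]]
      adj[r] <- l; adj[l] <- r
    }
    if (chrs[[k]]$circular) {
      r <- right[ii[nk]]; l <- left[ii[1]]
      if (adj[r] != 0L || adj[l] != 0L) stop("inconsistent circular chromosome")
      adj[r] <- l; adj[l] <- r
    }
    off <- off + nk
  }
  list(M = M, fam = fam, occ = occ, sign = sgn, chrom = chrom, label = label,
       left = left, right = right, adj = adj,
       circular = vapply(chrs, `[[`, logical(1), "circular"))
}

ext_label <- function(idx, e) {
  i <- (e + 1L) %/% 2L
  paste0(ifelse(e %% 2L == 1L, "t", "h"), idx$fam[i], ".", idx$occ[i])
}

ext_from_label <- function(idx, lab) {
  side <- substr(lab, 1, 1)
  if (!all(side %in% c("t", "h"))) stop("invalid extremity label: ", paste(lab, collapse = " "))
  inst <- substring(lab, 2)
  i <- match(inst, idx$label)
  if (anyNA(i)) stop("unknown marker instance: ", paste(inst[is.na(i)], collapse = " "))
  ifelse(side == "t", 2L * i - 1L, 2L * i)
}

# Rebuild a genome object from an instance table and an adjacency matching
# on extremities.  `keep` is a logical vector over instances.
rebuild_genome <- function(idx, adj, keep = NULL, name = "genome") {
  M <- idx$M
  if (is.null(keep)) keep <- rep(TRUE, M)
  inst <- which(keep)
  if (length(inst) == 0) return(new_genome(list(), name = name))
  other <- function(e) e + ifelse(e %% 2L == 1L, 1L, -1L)
  visited <- rep(FALSE, 2L * M)
  visited[c(2L * which(!keep), 2L * which(!keep) - 1L)] <- TRUE
  chrs <- list(); circs <- logical(0)
  walk <- function(start, circular) {
    fams <- character(0); signs <- integer(0); occs <- integer(0)
    e <- start
    repeat {
      i <- (e + 1L) %/% 2L
      s <- if (e %% 2L == 1L) 1L else -1L   # entered at tail => forward
      fams <- c(fams, idx$fam[i]); occs <- c(occs, idx$occ[i]); signs <- c(signs, s)
      visited[e] <<- TRUE
      e2 <- other(e)
      visited[e2] <<- TRUE
      nxt <- adj[e2]
      if (nxt == 0L || visited[nxt]) break
      e <- nxt
    }
    list(family = fams, occ = occs, sign = signs, circular = circular)
  }
  # linear chromosomes first: start at telomeres (smallest extremity id)
  telo <- which(adj == 0L & !visited)
  for (e in telo) {
    if (visited[e]) next
    chrs[[length(chrs) + 1L]] <- walk(e, FALSE)
  }
  # remaining extremities lie on circular chromosomes
  repeat {
    rest <- which(!visited)
    if (length(rest) == 0) break
    chrs[[length(chrs) + 1L]] <- walk(rest[1], TRUE)
  }
  # occurrence numbers are retained so that instance identity survives rebuilds
  structure(list(name = name, chromosomes = chrs), class = "genome")
}

# ---------------------------------------------------------------------------
# UniMoG-dialect parsing and writing
# ---------------------------------------------------------------------------

#' Parse genomes from UniMoG-dialect text
#'
#' Lines starting with `>` open a genome; whitespace-separated signed marker
#' tokens form chromosomes; `|` ends a linear chromosome and `)` a circular
#' one; `#` starts a comment line. Marker tokens with the same name receive
#' consecutive occurrence numbers in reading order.
#'
#' @param text Character scalar (or vector of lines) with file content.
#' @return List of `genome` objects.
#' @examples
#' gs <- parse_genomes(">A\n1 -2 |\n3 )")
#' @export
parse_genomes <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  genomes <- list()
  cur_name <- NULL; cur_chroms <- list(); cur_circ <- logical(0); cur_toks <- character(0)
  flush_genome <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_toks) > 0) stop("chromosome not terminated by '|' or ')' in genome ", cur_name)
    if (cur_name %in% vapply(genomes, `[[`, character(1), "name")) {
      stop("duplicate genome name: ", cur_name)
    }
    genomes[[length(genomes) + 1L]] <<- new_genome(cur_chroms, cur_circ, name = cur_name)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, ">")) {
      flush_genome()
      cur_name <- trimws(substring(ln, 2))
      cur_chroms <- list(); cur_circ <- logical(0); cur_toks <- character(0)
      next
    }
    if (is.null(cur_name)) stop("marker data before any '>' genome header")
    # allow terminators glued to the last token, e.g. "3)"
    ln <- gsub("([|)])", " \\1 ", ln)
    toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    for (tk in toks) {
      if (tk %in% c("|", ")")) {
        if (length(cur_toks) == 0) stop("empty chromosome in genome ", cur_name)
        cur_chroms[[length(cur_chroms) + 1L]] <- cur_toks
        cur_circ <- c(cur_circ, tk == ")")
        cur_toks <- character(0)
      } else if (tk != "") {
        cur_toks <- c(cur_toks, tk)
      }
    }
  }
  flush_genome()
  genomes
}

#' Read genomes from a file
#' @param path File path.
#' @return List of `genome` objects.
#' @export
read_genomes <- function(path) {
  parse_genomes(readLines(path, warn = FALSE))
}

chromosome_tokens <- function(ch) {
  ifelse(ch$sign < 0, paste0("-", ch$family), ch$family)
}

# canonical token sequence of one chromosome; token order compares by family
# name first, with a positive sign ranking before a negative one, so e.g.
# the circular chromosome [3, 1, 2] is emitted as "1 2 3"
canonical_chromosome_tokens <- function(ch) {
  toks <- chromosome_tokens(ch)
  flip <- function(tk) rev(ifelse(startsWith(tk, "-"), substring(tk, 2), paste0("-", tk)))
  tok_key <- function(tk) {
    paste(paste0(sub("^-", "", tk), ifelse(startsWith(tk, "-"), "-", "+")),
          collapse = " ")
  }
  if (!ch$circular) {
    cand <- list(toks, flip(toks))
  } else {
    n <- length(toks)
    cand <- list()
    for (base in list(toks, flip(toks))) {
      for (r in seq_len(n)) cand[[length(cand) + 1L]] <- base[c(r:n, seq_len(r - 1L))]
    }
  }
  keys <- vapply(cand, tok_key, character(1))
  # radix order is locale-independent (C collation)
  cand[[order(keys, method = "radix")[1]]]
}

#' Canonicalize a genome
#'
#' Circular chromosomes are rotated/reflected to their lexicographically
#' smallest token sequence, linear chromosomes oriented from the smaller end,
#' chromosomes sorted, and occurrence numbers re-assigned in reading order.
#' @param genome A `genome`.
#' @return A `genome` in canonical form.
#' @export
canonical_genome <- function(genome) {
  toklists <- lapply(genome$chromosomes, canonical_chromosome_tokens)
  circ <- vapply(genome$chromosomes, `[[`, logical(1), "circular")
  keys <- paste0(ifelse(circ, "c:", "l:"), vapply(toklists, paste, character(1), collapse = " "))
  o <- order(keys, method = "radix")
  new_genome(toklists[o], circ[o], name = genome$name)
}

#' Test two genomes for structural equality
#'
#' Equality up to chromosome order, rotation and reflection of circular
#' chromosomes, orientation of linear chromosomes, and occurrence relabeling.
#' @param a,b Genomes.
#' @return Logical.
#' @export
genomes_equal <- function(a, b) {
  ca <- canonical_genome(a); cb <- canonical_genome(b)
  fmt <- function(g) paste(vapply(seq_along(g$chromosomes), function(k) {
    ch <- g$chromosomes[[k]]
    paste(c(chromosome_tokens(ch), if (ch$circular) ")" else "|"), collapse = " ")
  }, character(1)), collapse = " / ")
  fmt(ca) == fmt(cb)
}

#' Write genomes in UniMoG-dialect text
#'
#' Genomes are emitted in canonical form so that writing is deterministic and
#' `parse_genomes(write_genomes(g))` reproduces `g` up to canonicalization.
#' @param genomes List of `genome` objects (or a single genome).
#' @param path Optional output file path.
#' @return The text, invisibly if `path` is given.
#' @export
write_genomes <- function(genomes, path = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  out <- character(0)
  for (g in genomes) {
    gc <- canonical_genome(g)
    out <- c(out, paste0(">", gc$name))
    for (ch in gc$chromosomes) {
      out <- c(out, paste(c(chromosome_tokens(ch), if (ch$circular) ")" else "|"),
                          collapse = " "))
    }
  }
  text <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

# ---------------------------------------------------------------------------
# Operations: DCJ, deletion, insertion
# ---------------------------------------------------------------------------

#' Construct a DCJ operation
#'
#' A DCJ cuts at one or two sites (adjacencies or telomeres) and rejoins the
#' freed extremities. Extremities are written `t<name>.<occ>` / `h<name>.<occ>`.
#'
#' @param cut List of one or two sites; a site is a character vector of two
#'   extremity labels (an adjacency) or one label (a telomere).
#' @param join List of zero, one or two new adjacencies (length-2 character
#'   vectors); freed extremities not joined become telomeres.
#' @return Object of class `dcj_op`.
#' @export
op_dcj <- function(cut, join = list()) {
  if (!is.list(cut)) cut <- list(cut)
  if (!is.list(join)) join <- list(join)
  structure(list(kind = "dcj", cut = cut, join = join), class = c("dcj_op", "genome_op"))
}

#' Construct a deletion operation
#' @param segment Character vector of instance labels `"family.occ"` forming a
#'   contiguous chromosome segment (or a whole chromosome).
#' @return Object of class `deletion_op`.
#' @export
op_deletion <- function(segment) {
  structure(list(kind = "deletion", segment = as.character(segment)),
            class = c("deletion_op", "genome_op"))
}

#' Construct an insertion operation
#' @param segment Character vector of signed family tokens for the inserted
#'   markers (occurrence numbers are assigned automatically).
#' @param attach `NULL` for a new linear chromosome, `"circular"` for a new
#'   circular chromosome, `list(adjacency = c(a, b))` to insert into an
#'   adjacency, or `list(telomere = x)` to extend at a telomere.
#' @return Object of class `insertion_op`.
#' @export
op_insertion <- function(segment, attach = NULL) {
  structure(list(kind = "insertion", segment = as.character(segment), attach = attach),
            class = c("insertion_op", "genome_op"))
}

site_extremities <- function(idx, site) {
  e <- ext_from_label(idx, site)
  if (length(e) == 2) {
    if (idx$adj[e[1]] != e[2]) {
      stop("adjacency not present: {", paste(site, collapse = ","), "}")
    }
  } else if (length(e) == 1) {
    if (idx$adj[e] != 0L) stop("extremity is not a telomere: ", site)
  } else stop("a cut site has one or two extremities")
  e
}

#' Apply an operation to a genome
#'
#' @param genome A `genome`.
#' @param op An operation created by [op_dcj()], [op_deletion()] or
#'   [op_insertion()].
#' @return The transformed `genome`.
#' @export
apply_operation <- function(genome, op) {
  idx <- genome_index(genome)
  if (op$kind == "dcj") {
    if (length(op$cut) < 1 || length(op$cut) > 2) stop("DCJ cuts one or two sites")
    freed <- integer(0)
    adj <- idx$adj
    sites <- lapply(op$cut, function(s) site_extremities(idx, s))
    if (length(sites) == 2 && length(intersect(sites[[1]], sites[[2]])) > 0) {
      stop("DCJ cut sites overlap")
    }
    for (e in sites) {
      if (length(e) == 2) { adj[e[1]] <- 0L; adj[e[2]] <- 0L }
      freed <- c(freed, e)
    }
    used <- integer(0)
    for (j in op$join) {
      e <- ext_from_label(idx, j)
      if (length(e) != 2) stop("a join must have two extremities")
      if (!all(e %in% freed)) stop("join extremity was not freed by the cuts")
      if (any(e %in% used)) stop("extremity used in two joins")
      if (e[1] == e[2]) stop("cannot join an extremity to itself")
      adj[e[1]] <- e[2]; adj[e[2]] <- e[1]
      used <- c(used, e)
    }
    return(rebuild_genome(idx, adj, name = genome$name))
  }
  if (op$kind == "deletion") {
    seg <- match(op$segment, idx$label)
    if (anyNA(seg)) stop("deletion segment contains unknown instance")
    del <- rep(FALSE, idx$M); del[seg] <- TRUE
    # contiguity: within one chromosome, consecutive positions (circular wrap ok)
    ch <- unique(idx$chrom[seg])
    if (length(ch) != 1) stop("deletion segment spans chromosomes")
    ii <- which(idx$chrom == ch)
    inseg <- del[ii]
    if (!all(inseg)) {
      runs <- rle(inseg)
      nseg <- sum(runs$values)
      if (nseg > 1) {
        wrap <- idx$circular[ch] && inseg[1] && inseg[length(inseg)]
        if (!(wrap && nseg == 2)) stop("deletion segment is not contiguous")
      }
    }
    adj <- idx$adj
    segext <- c(2L * seg - 1L, 2L * seg)
    ends <- setdiff(adj[segext], c(segext, 0L))  # flank extremities outside segment
    adj[segext] <- 0L
    adj[ends] <- 0L
    if (length(ends) == 2) { adj[ends[1]] <- ends[2]; adj[ends[2]] <- ends[1] }
    return(rebuild_genome(idx, adj, keep = !del, name = genome$name))
  }
  if (op$kind == "insertion") {
    toks <- op$segment
    sgn <- ifelse(startsWith(toks, "-"), -1L, 1L)
    fams <- sub("^-", "", toks)
    # next free occurrence per family
    occ <- integer(length(fams))
    for (j in seq_along(fams)) {
      used <- idx$occ[idx$fam == fams[j]]
      used <- c(used, occ[seq_len(j - 1L)][fams[seq_len(j - 1L)] == fams[j]])
      occ[j] <- if (length(used)) max(used) + 1L else 1L
    }
    ins_chr <- list(family = fams, occ = occ, sign = sgn, circular = FALSE)
    at <- op$attach
    if (is.null(at)) {
      chrs <- c(genome$chromosomes, list(ins_chr))
      return(structure(list(name = genome$name, chromosomes = chrs), class = "genome"))
    }
    if (identical(at, "circular")) {
      ins_chr$circular <- TRUE
      chrs <- c(genome$chromosomes, list(ins_chr))
      return(structure(list(name = genome$name, chromosomes = chrs), class = "genome"))
    }
    # grow the index with the new instances, then edit adjacencies
    g2 <- structure(list(name = genome$name,
                         chromosomes = c(genome$chromosomes, list(ins_chr))),
                    class = "genome")
    idx2 <- genome_index(g2)
    newi <- idx$M + seq_along(fams)
    adj <- idx2$adj
    p_first <- idx2$left[newi[1]]
    p_last <- idx2$right[newi[length(newi)]]
    if (!is.null(at$adjacency)) {
      e <- ext_from_label(idx2, at$adjacency)
      if (length(e) != 2 || adj[e[1]] != e[2]) stop("insertion attachment adjacency absent")
      adj[e[1]] <- p_first; adj[p_first] <- e[1]
      adj[e[2]] <- p_last; adj[p_last] <- e[2]
    } else if (!is.null(at$telomere)) {
      e <- ext_from_label(idx2, at$telomere)
      if (length(e) != 1 || adj[e] != 0L) stop("insertion attachment telomere absent")
      adj[e] <- p_first; adj[p_first] <- e
    } else stop("unknown insertion attachment")
    return(rebuild_genome(idx2, adj, name = genome$name))
  }
  stop("unknown operation kind: ", op$kind)
}

# ---------------------------------------------------------------------------
# SD test and singleton detection
# ---------------------------------------------------------------------------

#' Test whether a genome is structurally doubled (SD)
#'
#' A genome is SD under a matching if every marker is paired and the induced
#' equivalence partitions the adjacencies into classes of size exactly two.
#' The empty genome is SD.
#'
#' @param genome A `genome`.
#' @param matching A `marker_matching`, or `NULL` to derive the unique
#'   matching of the (resolved) by-name homology.
#' @param hom Optional `homology` used when `matching` is `NULL`.
#' @return Logical.
#' @export
is_sd <- function(genome, matching = NULL, hom = NULL) {
  idx <- genome_index(genome)
  if (idx$M == 0) return(TRUE)
  if (is.null(matching)) matching <- matching_from_homology(genome, hom)
  partner <- matching_partner(idx, matching)
  if (any(partner == 0L)) return(FALSE)
  # partner extremity: same side of the partner instance
  pext <- function(e) {
    i <- (e + 1L) %/% 2L
    2L * partner[i] - (e %% 2L)
  }
  adj <- idx$adj
  for (e in seq_len(2L * idx$M)) {
    a <- adj[e]
    if (a == 0L) next
    pe <- pext(e); pa <- pext(a)
    if (adj[pe] != pa) return(FALSE)
    if (pe == e && pa == a) return(FALSE)     # self-equivalent adjacency
    if (pe == a && pa == e) return(FALSE)     # adjacency equivalent to itself
  }
  TRUE
}

#' Find circular singletons
#'
#' Circular chromosomes consisting only of singular (unmatched) markers.
#' @inheritParams is_sd
#' @return List of chromosomes (each a list with `family`, `occ`, `sign`,
#'   `circular`).
#' @export
find_circular_singletons <- function(genome, matching = NULL, hom = NULL) {
  idx <- genome_index(genome)
  if (idx$M == 0) return(list())
  if (is.null(matching)) matching <- matching_from_homology(genome, hom)
  partner <- matching_partner(idx, matching)
  out <- list()
  for (k in seq_along(genome$chromosomes)) {
    ch <- genome$chromosomes[[k]]
    if (!ch$circular) next
    ii <- which(idx$chrom == k)
    if (all(partner[ii] == 0L)) out[[length(out) + 1L]] <- ch
  }
  out
}

# ---------------------------------------------------------------------------
# Scenario files
# ---------------------------------------------------------------------------

format_operation <- function(op) {
  fmt_set <- function(x) paste0("{", paste(x, collapse = ","), "}")
  if (op$kind == "dcj") {
    paste("DCJ cut", paste(vapply(op$cut, fmt_set, character(1)), collapse = " "),
          "join", if (length(op$join)) paste(vapply(op$join, fmt_set, character(1)), collapse = " ") else "-")
  } else if (op$kind == "deletion") {
    paste("DEL", paste(op$segment, collapse = " "))
  } else {
    at <- op$attach
    tail <- if (is.null(at)) "new"
      else if (identical(at, "circular")) "circular"
      else if (!is.null(at$adjacency)) paste("at", fmt_set(at$adjacency))
      else paste("telomere", at$telomere)
    paste("INS", paste(op$segment, collapse = " "), tail)
  }
}

#' Write a scenario (list of operations) to text
#' @param scenario List of operations.
#' @param path Optional file path.
#' @return Character vector of lines (invisibly if `path` given).
#' @export
write_scenario <- function(scenario, path = NULL) {
  lines <- vapply(scenario, format_operation, character(1))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Parse a scenario from text lines
#' @param lines Character vector, one operation per line.
#' @return List of operations.
#' @export
parse_scenario <- function(lines) {
  parse_set <- function(s) strsplit(gsub("[{}]", "", s), ",")[[1]]
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (toks[1] == "DCJ") {
      jpos <- match("join", toks)
      cuts <- lapply(toks[3:(jpos - 1L)], parse_set)
      jtoks <- toks[(jpos + 1L):length(toks)]
      joins <- if (identical(jtoks, "-")) list() else lapply(jtoks, parse_set)
      out[[length(out) + 1L]] <- op_dcj(cuts, joins)
    } else if (toks[1] == "DEL") {
      out[[length(out) + 1L]] <- op_deletion(toks[-1])
    } else if (toks[1] == "INS") {
      n <- length(toks)
      if (toks[n] == "new") {
        out[[length(out) + 1L]] <- op_insertion(toks[2:(n - 1L)])
      } else if (toks[n] == "circular") {
        out[[length(out) + 1L]] <- op_insertion(toks[2:(n - 1L)], "circular")
      } else if (toks[n - 1L] == "at") {
        out[[length(out) + 1L]] <- op_insertion(toks[2:(n - 2L)],
                                                list(adjacency = parse_set(toks[n])))
      } else if (toks[n - 1L] == "telomere") {
        out[[length(out) + 1L]] <- op_insertion(toks[2:(n - 2L)],
                                                list(telomere = toks[n]))
      } else stop("cannot parse insertion line: ", ln)
    } else stop("cannot parse scenario line: ", ln)
  }
  out
}
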