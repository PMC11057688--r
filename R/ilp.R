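# ---------------------------------------------------------------------------
# Capping-free ILP for halving natural genomes.
#
# The model searches over consistent decompositions of the supernatural
# graph (equivalently, over maximum matchings of the homology) for the one
# minimizing the halving distance.  Pseudo-caps are attached to telomeres so
# every component contains an adjacency edge; the number of extra vertices
# is linear in the number of linear chromosomes (no pairwise capping).
#
# Variables per vertex v (pseudo-caps first in the index order ix):
#   y_v in [0, ix(v)]  component label, constant on a component
#   z_v binary         reporting vertex (y_v = ix(v), the component minimum)
#   a_v binary         telomere/lava side marker: 0 at pseudo-caps, 1 at
#                      lava vertices, changes only across an adjacency edge
#                      reporting a pier
#   b_v binary         parity: 0 at pseudo-caps and lava vertices, flips
#                      across every active extremity edge, flips across an
#                      adjacency edge only when an odd type is reported
# plus x_p per candidate sibling pair (consistent decomposition), d_m per
# marker (1 = singular/deleted), six report variables per adjacency edge,
# s_D per circular chromosome (circular singleton), and the census tallies.
# ---------------------------------------------------------------------------

new_lp_builder <- function() {
  env <- new.env(parent = emptyenv())
  cap <- 256L
  env$vn <- character(cap); env$lb <- numeric(cap); env$ub <- numeric(cap)
  env$vtype <- character(cap); env$obj <- numeric(cap)
  env$nvar <- 0L
  env$ri <- vector("list", cap); env$ci <- vector("list", cap); env$vv <- vector("list", cap)
  env$sense <- character(cap); env$rhs <- numeric(cap)
  env$nrow <- 0L
  grow_vars <- function() {
    n <- length(env$vn)
    env$vn <- c(env$vn, character(n)); env$lb <- c(env$lb, numeric(n))
    env$ub <- c(env$ub, numeric(n)); env$vtype <- c(env$vtype, character(n))
    env$obj <- c(env$obj, numeric(n))
  }
  grow_cons <- function() {
    n <- length(env$sense)
    env$ri <- c(env$ri, vector("list", n)); env$ci <- c(env$ci, vector("list", n))
    env$vv <- c(env$vv, vector("list", n))
    env$sense <- c(env$sense, character(n)); env$rhs <- c(env$rhs, numeric(n))
  }
  env$add_var <- function(name, lb = 0, ub = 1, type = "B", obj = 0) {
    if (env$nvar == length(env$vn)) grow_vars()
    k <- env$nvar + 1L
    env$vn[k] <- name; env$lb[k] <- lb; env$ub[k] <- ub
    env$vtype[k] <- type; env$obj[k] <- obj
    env$nvar <- k
    k
  }
  env$add_con <- function(cols, vals, sense, rhs) {
    if (env$nrow == length(env$sense)) grow_cons()
    k <- env$nrow + 1L
    env$ri[[k]] <- rep(k, length(cols))
    env$ci[[k]] <- cols
    env$vv[[k]] <- vals
    env$sense[k] <- sense; env$rhs[k] <- rhs
    env$nrow <- k
    k
  }
  env$finalize <- function() {
    env$vn <- env$vn[seq_len(env$nvar)]; env$lb <- env$lb[seq_len(env$nvar)]
    env$ub <- env$ub[seq_len(env$nvar)]; env$vtype <- env$vtype[seq_len(env$nvar)]
    env$obj <- env$obj[seq_len(env$nvar)]
    env$ri <- env$ri[seq_len(env$nrow)]; env$ci <- env$ci[seq_len(env$nrow)]
    env$vv <- env$vv[seq_len(env$nrow)]
    env$sense <- env$sense[seq_len(env$nrow)]; env$rhs <- env$rhs[seq_len(env$nrow)]
    invisible(env)
  }
  env
}

#' Build the halving ILP for a natural genome
#'
#' @param genome A `genome`.
#' @param hom A `homology` or `NULL` (families by marker name).
#' @return An object of class `halving_ilp` holding the variables, the
#'   constraint matrix in triplet form, the objective, and the bookkeeping
#'   needed to decode a solution.
#' @export
build_halving_ilp <- function(genome, hom = NULL) {
  idx <- genome_index(genome)
  M <- idx$M
  keys <- family_keys(genome, hom)
  B <- new_lp_builder()
  telo <- if (M) which(idx$adj == 0L) else integer(0)
  P <- length(telo)                      # pseudo-caps, ix 1..P
  nV <- P + 2L * M
  vx <- function(e) P + e                # regular extremity e -> vertex ix
  marker_of <- function(v) if (v > P) (v - P + 1L) %/% 2L else 0L

  # adjacency edges: cap edges first, then genome adjacencies
  eu <- c(seq_len(P), if (M) vx(which(idx$adj > seq_len(2L * M))) else integer(0))
  ew <- c(vx(telo), if (M) vx(idx$adj[which(idx$adj > seq_len(2L * M))]) else integer(0))
  cap_edge <- c(rep(TRUE, P), rep(FALSE, length(eu) - P))
  nA <- length(eu)

  # candidate sibling pairs
  fams <- split(seq_len(M), keys)
  pair_m <- integer(0); pair_n <- integer(0)
  for (ii in fams) {
    if (length(ii) < 2) next
    prs <- utils::combn(ii, 2)
    pair_m <- c(pair_m, prs[1, ]); pair_n <- c(pair_n, prs[2, ])
  }
  nP <- length(pair_m)

  if (M == 0) {
    model <- structure(list(builder = B, idx = idx, keys = keys, nV = 0L,
                            caps = 0L, pairs = cbind(pair_m, pair_n),
                            var = list(), empty = TRUE),
                       class = "halving_ilp")
    return(model)
  }

  # --- variables (fixed order for deterministic LP export) ---
  v_x <- vapply(seq_len(nP), function(p)
    B$add_var(sprintf("x_p%d", p)), integer(1))
  v_d <- vapply(seq_len(M), function(m)
    B$add_var(sprintf("d_m%d", m)), integer(1))
  v_y <- vapply(seq_len(nV), function(v)
    B$add_var(sprintf("y_v%d", v), lb = 0, ub = v, type = "C"), integer(1))
  v_z <- vapply(seq_len(nV), function(v) B$add_var(sprintf("z_v%d", v)), integer(1))
  v_a <- vapply(seq_len(nV), function(v)
    B$add_var(sprintf("a_v%d", v), ub = if (v <= P) 0 else 1), integer(1))
  v_b <- vapply(seq_len(nV), function(v)
    B$add_var(sprintf("b_v%d", v), ub = if (v <= P) 0 else 1), integer(1))
  rclass <- c("GGl", "Gge", "Ggl", "ggl", "ce", "cl")
  v_r <- sapply(rclass, function(cl) vapply(seq_len(nA), function(e) {
    ub <- 1
    if (cl %in% c("ce", "cl") && cap_edge[e]) ub <- 0          # C.17
    if (cl %in% c("GGl", "Gge", "Ggl") && !cap_edge[e]) ub <- 0 # C.19
    B$add_var(sprintf("r%s_e%d", cl, e), ub = ub)
  }, integer(1)), simplify = FALSE)
  circ_chroms <- which(idx$circular)
  v_s <- vapply(seq_along(circ_chroms), function(j)
    B$add_var(sprintf("s_D%d", j), obj = 1), integer(1))
  v_n <- B$add_var("n", ub = M, type = "C", obj = 1)
  v_c <- B$add_var("c", ub = nA, type = "C", obj = -1)
  v_pggl <- B$add_var("p_ggl", ub = nA, type = "C", obj = 0.5)
  v_pGge <- B$add_var("p_Gge", ub = nA, type = "C")
  v_pGgl <- B$add_var("p_Ggl", ub = nA, type = "C")
  v_pGGl <- B$add_var("p_GGl", ub = nA, type = "C", obj = -0.5)
  v_T <- B$add_var("T", ub = nA, type = "C", obj = 0.5)
  v_k <- B$add_var("k", ub = nA, type = "I")
  v_O <- B$add_var("O")
  v_NE <- B$add_var("NE")
  v_w <- B$add_var("w_dir")
  v_delta <- B$add_var("delta", obj = 0.5)

  # --- constraints ---
  # C.01-C.05: consistent decomposition; sibling edges share one x variable
  for (m in seq_len(M)) {
    ps <- which(pair_m == m | pair_n == m)
    B$add_con(c(v_x[ps], v_d[m]), rep(1, length(ps) + 1L), "=", 1)
  }
  # C.06: maximum matching (exactly |F| mod 2 singular markers per family)
  for (ii in fams) {
    B$add_con(v_d[ii], rep(1, length(ii)), "=", length(ii) %% 2L)
  }
  # y constant across adjacency edges
  for (e in seq_len(nA)) {
    B$add_con(c(v_y[eu[e]], v_y[ew[e]]), c(1, -1), "=", 0)
  }
  # y constant across active extremity edges (big-M on x)
  Mx <- nV
  for (p in seq_len(nP)) {
    for (side in 0:1) {  # 0 = tails, 1 = heads
      u <- vx(2L * pair_m[p] - 1L + side); w <- vx(2L * pair_n[p] - 1L + side)
      B$add_con(c(v_y[u], v_y[w], v_x[p]), c(1, -1, Mx), "<=", Mx)
      B$add_con(c(v_y[w], v_y[u], v_x[p]), c(1, -1, Mx), "<=", Mx)
    }
  }
  # C.18: lava vertices force y = 0 on their component
  for (e2 in seq_len(2L * M)) {
    v <- vx(e2); m <- marker_of(v)
    B$add_con(c(v_y[v], v_d[m]), c(1, v), "<=", v)
  }
  # reporting vertex: z_v = 1 only if y_v = ix(v)
  for (v in seq_len(nV)) {
    B$add_con(c(v_z[v], v_y[v]), c(v, -1), "<=", 0)
  }
  # C.07/C.08: a is 0 at pseudo-caps (bound) and 1 at lava vertices
  for (e2 in seq_len(2L * M)) {
    v <- vx(e2); m <- marker_of(v)
    B$add_con(c(v_a[v], v_d[m]), c(1, -1), ">=", 0)
  }
  # C.09: a equal across active extremity edges
  for (p in seq_len(nP)) {
    for (side in 0:1) {
      u <- vx(2L * pair_m[p] - 1L + side); w <- vx(2L * pair_n[p] - 1L + side)
      B$add_con(c(v_a[u], v_a[w], v_x[p]), c(1, -1, 1), "<=", 1)
      B$add_con(c(v_a[w], v_a[u], v_x[p]), c(1, -1, 1), "<=", 1)
    }
  }
  # C.10: a changes across an adjacency edge exactly when reporting a pier
  # (the report forces the flip; otherwise a path ending in two telomeres
  # could pose as a pier at one end and an odd viaduct at the other)
  for (e in seq_len(nA)) {
    piers <- c(v_r$Gge[e], v_r$Ggl[e])
    B$add_con(c(v_a[eu[e]], v_a[ew[e]], piers), c(1, -1, -1, -1), "<=", 0)
    B$add_con(c(v_a[ew[e]], v_a[eu[e]], piers), c(1, -1, -1, -1), "<=", 0)
    B$add_con(c(v_a[eu[e]], v_a[ew[e]], piers), c(1, 1, -1, -1), ">=", 0)
    B$add_con(c(v_a[eu[e]], v_a[ew[e]], piers), c(1, 1, 1, 1), "<=", 2)
  }
  # C.11/C.12: b = 0 at pseudo-caps (bound) and at lava vertices
  for (e2 in seq_len(2L * M)) {
    v <- vx(e2); m <- marker_of(v)
    B$add_con(c(v_b[v], v_d[m]), c(1, 1), "<=", 1)
  }
  # C.13: b flips across active extremity edges
  for (p in seq_len(nP)) {
    for (side in 0:1) {
      u <- vx(2L * pair_m[p] - 1L + side); w <- vx(2L * pair_n[p] - 1L + side)
      B$add_con(c(v_b[u], v_b[w], v_x[p]), c(1, 1, -1), ">=", 0)
      B$add_con(c(v_b[u], v_b[w], v_x[p]), c(1, 1, 1), "<=", 2)
    }
  }
  # C.14/C.16: b equal across adjacency edges, different exactly when an odd
  # type is reported there
  for (e in seq_len(nA)) {
    odd <- c(v_r$cl[e], v_r$GGl[e], v_r$Ggl[e], v_r$ggl[e])
    B$add_con(c(v_b[eu[e]], v_b[ew[e]], odd), c(1, -1, rep(-1, 4)), "<=", 0)
    B$add_con(c(v_b[ew[e]], v_b[eu[e]], odd), c(1, -1, rep(-1, 4)), "<=", 0)
    B$add_con(c(v_b[eu[e]], v_b[ew[e]], odd), c(1, 1, rep(-1, 4)), ">=", 0)
    B$add_con(c(v_b[eu[e]], v_b[ew[e]], odd), c(1, 1, rep(1, 4)), "<=", 2)
  }
  # at most one report per adjacency edge
  for (e in seq_len(nA)) {
    B$add_con(vapply(rclass, function(cl) v_r[[cl]][e], integer(1)),
              rep(1, 6), "<=", 1)
  }
  # C.15: negative/neutral reports only at a reporting vertex
  for (e in seq_len(nA)) {
    for (cl in c("ce", "cl", "GGl")) {
      B$add_con(c(v_r[[cl]][e], v_z[eu[e]], v_z[ew[e]]), c(1, -1, -1), "<=", 0)
    }
  }
  # C.20: pontoons reported at a lava end
  for (e in seq_len(nA)) {
    cols <- v_r$ggl[e]; vals <- 1
    mu <- marker_of(eu[e]); mw <- marker_of(ew[e])
    if (mu > 0L) { cols <- c(cols, v_d[mu]); vals <- c(vals, -1) }
    if (mw > 0L) { cols <- c(cols, v_d[mw]); vals <- c(vals, -1) }
    B$add_con(cols, vals, "<=", 0)
  }
  # C.21-C.29: census tallies
  B$add_con(c(v_pggl, v_r$ggl), c(1, rep(-1, nA)), "=", 0)
  B$add_con(c(v_pGge, v_r$Gge), c(1, rep(-1, nA)), "=", 0)
  B$add_con(c(v_pGgl, v_r$Ggl), c(1, rep(-1, nA)), "=", 0)
  B$add_con(c(v_pGGl, v_r$GGl), c(1, rep(-1, nA)), "=", 0)
  B$add_con(c(v_c, v_r$ce), c(1, rep(-1, nA)), "=", 0)
  B$add_con(c(v_n, v_d), c(2, rep(1, M)), "=", M)
  B$add_con(c(v_T, v_pGge), c(1, -1), ">=", 0)
  B$add_con(c(v_T, v_pGgl), c(1, -1), ">=", 0)
  # C.30: parity of the odd-pontoon count
  B$add_con(c(v_pggl, v_k, v_O), c(1, -2, -1), "=", 0)
  # C.31: NE = 1 only if the two pier counts differ
  Mb <- nV
  B$add_con(c(v_NE, v_pGge, v_pGgl, v_w), c(1, -1, 1, Mb), "<=", Mb)
  B$add_con(c(v_NE, v_pGgl, v_pGge, v_w), c(1, -1, 1, -Mb), "<=", 0)
  # C.32: delta
  B$add_con(c(v_O, v_NE, v_delta), c(1, -1, -1), "<=", 0)
  # C.33/C.34: circular singletons
  for (j in seq_along(circ_chroms)) {
    ii <- which(idx$chrom == circ_chroms[j])
    B$add_con(c(v_d[ii], v_s[j]), c(rep(1, length(ii)), -1), "<=", length(ii) - 1L)
  }

  B$finalize()
  structure(list(builder = B, idx = idx, keys = keys, nV = nV, caps = P,
                 pairs = cbind(pair_m, pair_n), empty = FALSE,
                 var = list(x = v_x, d = v_d, y = v_y, z = v_z, a = v_a,
                            b = v_b, r = v_r, s = v_s, n = v_n, c = v_c,
                            pggl = v_pggl, pGge = v_pGge, pGgl = v_pGgl,
                            pGGl = v_pGGl, T = v_T, k = v_k, O = v_O,
                            NE = v_NE, w = v_w, delta = v_delta)),
            class = "halving_ilp")
}

#' @export
print.halving_ilp <- function(x, ...) {
  if (x$empty) {
    cat("Halving ILP (empty genome): objective 0\n")
  } else {
    cat("Halving ILP:", length(x$builder$vn), "variables,",
        x$builder$nrow, "constraints,", nrow(x$pairs), "candidate pairs,",
        x$caps, "pseudo-caps\n")
  }
  invisible(x)
}

#' Write an ILP model in CPLEX LP format
#'
#' Output is deterministic: two builds of the same instance are identical.
#' @param model A `halving_ilp`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  B <- model$builder
  lines <- c("\\ dcjhalving halving ILP", "Minimize")
  if (model$empty) {
    lines <- c(lines, " obj: 0 zero", "Subject To", "Bounds", " 0 <= zero <= 0", "End")
    writeLines(lines, path)
    return(invisible(path))
  }
  term <- function(v, i) sprintf("%+.12g %s", v, B$vn[i])
  nz <- which(B$obj != 0)
  lines <- c(lines, paste(" obj:", paste(term(B$obj[nz], nz), collapse = " ")))
  lines <- c(lines, "Subject To")
  ri <- unlist(B$ri); ci <- unlist(B$ci); vv <- unlist(B$vv)
  ord <- order(ri)
  ri <- ri[ord]; ci <- ci[ord]; vv <- vv[ord]
  starts <- c(1L, which(diff(ri) > 0) + 1L, length(ri) + 1L)
  sense_op <- c("<=" = "<=", ">=" = ">=", "=" = "=")
  con_lines <- vapply(seq_len(B$nrow), function(r) {
    jj <- starts[r]:(starts[r + 1L] - 1L)
    sprintf(" c%d: %s %s %.12g", r,
            paste(term(vv[jj], ci[jj]), collapse = " "),
            sense_op[B$sense[r]], B$rhs[r])
  }, character(1))
  lines <- c(lines, con_lines, "Bounds")
  lines <- c(lines, sprintf(" %.12g <= %s <= %.12g", B$lb, B$vn, B$ub))
  bin <- B$vtype == "B"; gen <- B$vtype == "I"
  if (any(bin)) lines <- c(lines, "Binaries", paste("", paste(B$vn[bin], collapse = " ")))
  if (any(gen)) lines <- c(lines, "Generals", paste("", paste(B$vn[gen], collapse = " ")))
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}

find_python <- function() {
  p <- Sys.getenv("DCJHALVING_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python3")
  if (nzchar(p)) return(unname(p))
  unname(Sys.which("python"))
}

#' Solve a halving ILP
#'
#' Solves the model with the HiGHS mixed-integer solver (through the
#' scientific Python stack's `scipy.optimize.milp`), or only exports the LP
#' file with `backend = "lp-only"`.
#'
#' @param model A `halving_ilp` from [build_halving_ilp()].
#' @param backend `"auto"`/`"highs"` to solve, `"lp-only"` to refuse solving
#'   (useful when only the LP export is wanted).
#' @param time_limit Time limit in seconds.
#' @param threads Ignored by the HiGHS backend (single-threaded); kept for
#'   interface stability.
#' @param seed Forwarded where supported; HiGHS via scipy is deterministic.
#' @param gap Relative MIP gap tolerance.
#' @return An object of class `halving_ilp_solution` with the objective, the
#'   integerized `distance`, the decoded `matching`, the decoded census and
#'   breakdown, solver `status` and `gap`.
#' @export
solve_halving_ilp <- function(model, backend = c("auto", "highs", "lp-only"),
                              time_limit = 3600, threads = 1L, seed = NULL,
                              gap = 0) {
  backend <- match.arg(backend)
  if (backend == "lp-only") stop("backend 'lp-only' cannot solve; use write_lp()")
  if (model$empty) {
    emptym <- marker_matching()
    return(structure(list(objective = 0, distance = 0L, matching = emptym,
                          status = "optimal", gap = 0,
                          breakdown = halving_distance_census(component_census()),
                          assignment = numeric(0)),
                     class = "halving_ilp_solution"))
  }
  B <- model$builder
  python <- find_python()
  if (!nzchar(python)) stop("no python interpreter found for the HiGHS backend")
  runner <- system.file("python", "highs_solve.py", package = "dcjhalving")
  if (runner == "") stop("solver runner script not found")
  # non-finite bounds travel as JSON null
  clb <- ifelse(B$sense == "<=", NA_real_, B$rhs)
  cub <- ifelse(B$sense == ">=", NA_real_, B$rhs)
  spec <- list(
    obj = B$obj, lb = B$lb, ub = B$ub,
    integrality = as.integer(B$vtype != "C"),
    nrow = B$nrow, ncol = length(B$vn),
    ai = unlist(B$ri), aj = unlist(B$ci), av = unlist(B$vv),
    clb = clb, cub = cub,
    time_limit = time_limit, mip_rel_gap = gap
  )
  infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(spec, infile, auto_unbox = TRUE, digits = NA, na = "null")
  st <- system2(python, c(runner, infile, outfile), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("MILP backend failed: ", paste(st, collapse = "\n"))
  }
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  if (is.null(res$x) || length(res$x) == 0) {
    stop("MILP backend returned no solution (status ", res$status, "); the ",
         "model is always feasible, so this indicates a resource limit")
  }
  xv <- as.numeric(res$x)
  names(xv) <- B$vn
  # decode the matching
  on <- xv[model$var$x] > 0.5
  idx <- model$idx
  pairs <- model$pairs[on, , drop = FALSE]
  matching <- if (nrow(pairs)) {
    marker_matching(cbind(idx$label[pairs[, 1]], idx$label[pairs[, 2]]))
  } else marker_matching()
  partner <- matching_partner(idx, matching)
  breakdown <- halving_distance_census(census_from_partner(idx, partner))
  distance <- as.integer(ceiling(res$objective - 1e-6))
  structure(list(objective = res$objective, distance = distance,
                 matching = matching, breakdown = breakdown,
                 status = if (isTRUE(res$success)) "optimal" else paste0("status_", res$status),
                 gap = if (!is.null(res$mip_gap)) res$mip_gap else NA_real_,
                 assignment = xv),
            class = "halving_ilp_solution")
}

#' @export
print.halving_ilp_solution <- function(x, ...) {
  cat("Halving ILP solution: objective", format(x$objective),
      "-> distance", x$distance, "(", x$status, ")\n")
  cat("Decoded matching pairs:", nrow(x$matching$pairs), "\n")
  invisible(x)
}

#' Halve a natural genome
#'
#' Solves the halving ILP for a genome with arbitrary family sizes, decodes
#' the optimal maximum matching, and sorts the genome to a structurally
#' doubled ancestor under that matching.
#'
#' @inheritParams build_halving_ilp
#' @param ... Passed to [solve_halving_ilp()].
#' @return A list with `matching`, `breakdown` (a `halving_breakdown`),
#'   `scenario` (a `halving_scenario`) and the ILP `solution`.
#' @export
halve_natural <- function(genome, hom = NULL, ...) {
  model <- build_halving_ilp(genome, hom)
  sol <- solve_halving_ilp(model, ...)
  scen <- sort_halving(genome, matching = sol$matching)
  if (scen$distance != sol$distance) {
    warning("scenario length ", scen$distance,
            " differs from ILP distance ", sol$distance)
  }
  list(matching = sol$matching, breakdown = sol$breakdown,
       scenario = scen, solution = sol)
}
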