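#' Enumerate extreme solutions (vertices) at a fixed growth rate
#'
#' Exhaustive active-set enumeration of the vertices of the flux polytope
#' at a fixed growth rate: the equality rows are always active; every
#' combination of inequality rows and non-negativity bounds that completes
#' a square, non-singular active set is solved, and solutions feasible for
#' the full system are collected and deduplicated. At the scale of this
#' model (at most 13 fluxes) the enumeration is exact; the vertices are the
#' elementary growth vectors of the growth-rate-parameterized system.
#'
#' @param params an `rba_params` object.
#' @param x_rP ribosomal protein mass fraction.
#' @param mu growth rate, per hour (must be feasible).
#' @param variant `"base"` or `"extended"`.
#' @param tol feasibility/dedup tolerance on scaled coordinates.
#' @return an object of class `rba_vertices`: list with `mu`, `vertices`
#'   (list of named flux vectors), `active_sets` (list of character vectors,
#'   rows and bounds active at each vertex), `witness_check` (record of the
#'   convex-combination test: the solver's independent feasibility witness
#'   expressed as a convex combination of the vertices, with its residual),
#'   and `variant`.
#' @export
enumerate_extreme_solutions <- function(params, x_rP, mu,
                                        variant = c("base", "extended"),
                                        tol = 1e-9) {
  variant <- match.arg(variant)
  comp <- derive_composition(params, x_rP)
  sys <- build_constraints(params, comp, mu, variant)
  feas <- is_feasible(sys)
  if (!feas$feasible)
    stop("enumerate_extreme_solutions: system infeasible at mu = ", mu)
  s <- .scaled_system(sys)
  n <- ncol(s$A)
  eq <- which(s$sign == "eq")
  ge <- which(s$sign != "eq")
  # candidate active constraints: inequality rows then bounds x_j >= 0
  M <- rbind(s$A[ge, , drop = FALSE], diag(n))
  cand_names <- c(rownames(s$A)[ge], paste0("bound ", colnames(s$A)))
  rhs_cand <- c(s$rhs[ge], rep(0, n))
  A_eq <- s$A[eq, , drop = FALSE]
  rhs_eq <- s$rhs[eq]
  k <- n - length(eq)  # additional active constraints needed for a vertex
  if (k < 0) stop("enumerate_extreme_solutions: over-determined equalities")
  combos <- utils::combn(nrow(M), k)
  verts <- list()
  acts <- list()
  keys <- character()
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    Asq <- rbind(A_eq, M[idx, , drop = FALSE])
    bsq <- c(rhs_eq, rhs_cand[idx])
    qrA <- qr(Asq)
    if (qrA$rank < n) next
    y <- qr.coef(qrA, bsq)
    if (anyNA(y)) next
    # feasibility of the full system at the candidate vertex
    if (any(y < -1e-7)) next
    resid <- drop(s$A %*% y) - s$rhs
    if (any(abs(resid[eq]) > 1e-7) || any(resid[ge] < -1e-7)) next
    key <- paste(sprintf("%.9g", round(y / max(abs(y), 1), 9)), collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    active <- c(rownames(s$A)[eq],
                cand_names[which(abs(c(drop(M %*% y) - rhs_cand)) <= 1e-7)])
    verts[[length(verts) + 1L]] <-
      stats::setNames(as.numeric(y / s$col_scale), colnames(sys$A))
    acts[[length(acts) + 1L]] <- active
  }
  if (length(verts) == 0L)
    stop("enumerate_extreme_solutions: no vertex found (unbounded or ",
         "numerically degenerate polytope)")
  # completeness audit: the independent min-norm feasibility witness must
  # be a convex combination of the enumerated vertices
  resid <- convex_hull_residual(verts, feas$witness)
  structure(list(mu = mu, vertices = verts, active_sets = acts,
                 witness_check = list(residual = resid,
                                      ok = resid < 1e-6),
                 variant = variant, x_rP = x_rP),
            class = "rba_vertices")
}

#' Residual of expressing a point as a convex combination of vertices
#'
#' Solves the non-negative least-squares problem `min || V lambda - x ||`
#' over the simplex (`lambda >= 0`, `sum(lambda) = 1`) in per-flux scaled
#' coordinates, and returns the maximum absolute residual. A point of the
#' polytope lies in the convex hull of its vertex set, so a small residual
#' for independently computed feasible points is evidence that the vertex
#' enumeration is complete.
#'
#' @param vertices list of named flux vectors (the candidate hull).
#' @param x a flux vector to test.
#' @return maximum absolute residual in scaled coordinates.
#' @export
convex_hull_residual <- function(vertices, x) {
  V <- do.call(cbind, vertices)
  sc <- pmax(apply(abs(V), 1, max), abs(x), 1e-300)
  V <- V / sc
  xs <- x / sc
  k <- ncol(V)
  D <- crossprod(V) + diag(1e-10, k)
  ans <- quadprog::solve.QP(
    Dmat = D, dvec = crossprod(V, xs),
    Amat = cbind(rep(1, k), diag(k)), bvec = c(1, rep(0, k)), meq = 1)
  max(abs(V %*% ans$solution - xs))
}

#' @export
print.rba_vertices <- function(x, ...) {
  cat(sprintf("<rba_vertices> %s model at mu = %.6g/h: %d vertices\n",
              x$variant, x$mu, length(x$vertices)))
  invisible(x)
}

#' Tabulate vertices as a tidy data frame
#'
#' @param vx an `rba_vertices` object.
#' @return data frame, one row per vertex, with flux columns, the RNAP flux
#'   branch classification (see [classify_branch()]) and the active set.
#' @export
vertices_as_table <- function(vx) {
  stopifnot(inherits(vx, "rba_vertices"))
  fluxes <- do.call(rbind, vx$vertices)
  df <- data.frame(mu = vx$mu, vertex = seq_along(vx$vertices), fluxes,
                   check.names = FALSE)
  df$branch <- vapply(vx$active_sets, classify_branch, character(1))
  df$active_rows <- vapply(vx$active_sets, paste, character(1), collapse = ";")
  df
}

#' Classify a vertex into an accumulation branch
#'
#' Below the maximum growth rate, the extreme solutions fall into branches
#' according to which accumulation-related constraints have slack: free
#' rRNA piling up (`"excess rRNA"`, rRNA row slack), idle ribosome capacity
#' (`"excess ribosome"`, cap R slack), both at once, or the no-accumulation
#' solution where both are tight.
#'
#' @param active_rows character vector of active row labels for a vertex.
#' @return one of `"no accumulation"`, `"excess rRNA"`,
#'   `"excess ribosome"`, `"excess both"`.
#' @export
classify_branch <- function(active_rows) {
  rrna <- "rRNA" %in% active_rows
  capr <- "cap R" %in% active_rows
  if (rrna && capr) "no accumulation"
  else if (!rrna && capr) "excess rRNA"
  else if (rrna && !capr) "excess ribosome"
  else "excess both"
}
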