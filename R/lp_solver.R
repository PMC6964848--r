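# ---------------------------------------------------------------------------
# Dense two-phase primal simplex for box-constrained flux LPs:
#
#     optimize  c'v   s.t.  S v = d,  lb <= v <= ub
#
# Sized for envelope-wrapped toy and mid-sized networks (tens to a few
# hundred variables). Variables are shifted to x = v - lb >= 0; upper bounds
# become slack rows, equality rows get artificial variables in phase 1.
# Bland's rule (smallest-index entering, smallest-basis-index leaving) is
# used throughout, which guarantees termination under degeneracy at the cost
# of some extra pivots -- the right trade for reproducibility.
# ---------------------------------------------------------------------------

LP_PIVOT_TOL <- 1e-9
LP_FEAS_TOL <- 1e-7

# One simplex run on an explicit tableau. Maximizes cc'z over {A z = b, z>=0}
# starting from the given feasible basis. Returns the updated tableau.
simplex_core <- function(A, b, cc, basis, tol = LP_PIVOT_TOL,
                         max_iter = 50000L) {
  for (iter in seq_len(max_iter)) {
    cb <- cc[basis]
    red <- cc - as.numeric(crossprod(A, cb)) # reduced costs
    red[basis] <- 0
    enter <- which(red > tol)
    if (!length(enter)) {
      return(list(A = A, b = b, basis = basis, status = "optimal"))
    }
    j <- min(enter) # Bland
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(A = A, b = b, basis = basis, status = "unbounded"))
    }
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])] # Bland
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    f <- A[, j]
    f[i] <- 0
    nz <- which(abs(f) > 0)
    if (length(nz)) {
      A[nz, ] <- A[nz, , drop = FALSE] - outer(f[nz], A[i, ])
      b[nz] <- b[nz] - f[nz] * b[i]
    }
    b[b < 0 & b > -tol] <- 0
    basis[i] <- j
  }
  stop("simplex iteration limit reached (", max_iter, ")")
}

#' Solve a box-constrained linear program
#'
#' Optimizes `obj' v` subject to `S v = rhs` and `lb <= v <= ub` with the
#' built-in two-phase simplex. Infinite bounds are clamped to +/- 1e6.
#'
#' @param obj objective coefficients (length n).
#' @param S constraint matrix (m x n), may be NULL for pure box problems.
#' @param rhs right-hand side (length m), defaults to zeros.
#' @param lb,ub variable bounds.
#' @param maximize direction; TRUE maximizes.
#' @return list with `status` ("optimal"/"infeasible"/"unbounded"),
#'   `objective`, and `solution` (named after `colnames(S)` when present).
#' @export
lp_solve_box <- function(obj, S = NULL, rhs = NULL, lb, ub, maximize = TRUE) {
  n <- length(obj)
  if (is.null(S)) S <- matrix(0, 0, n)
  S <- as.matrix(S)
  m <- nrow(S)
  if (is.null(rhs)) rhs <- numeric(m)
  clamp <- 1e6
  lb2 <- pmax(as.numeric(lb), -clamp)
  ub2 <- pmin(as.numeric(ub), clamp)
  bad <- list(status = "infeasible", objective = NA_real_, solution = NULL)
  if (any(lb2 > ub2 + LP_PIVOT_TOL)) return(bad)
  ub2 <- pmax(ub2, lb2)
  u <- ub2 - lb2
  d <- rhs - if (m) as.numeric(S %*% lb2) else numeric(0)
  act <- which(u > LP_PIVOT_TOL)
  na <- length(act)
  mkres <- function(x_act) {
    v <- lb2
    if (na) v[act] <- v[act] + x_act
    names(v) <- colnames(S)
    list(status = "optimal", objective = sum(obj * v), solution = v)
  }
  if (na == 0) {
    if (m && any(abs(d) > LP_FEAS_TOL)) return(bad)
    return(mkres(numeric(0)))
  }
  Sa <- S[, act, drop = FALSE]
  sgn <- ifelse(d < 0, -1, 1)
  nrow_t <- m + na
  ncol_t <- 2L * na + m
  A <- matrix(0, nrow_t, ncol_t)
  b <- numeric(nrow_t)
  if (m) {
    A[seq_len(m), seq_len(na)] <- Sa * sgn
    b[seq_len(m)] <- abs(d)
    A[cbind(seq_len(m), 2L * na + seq_len(m))] <- 1
  }
  A[cbind(m + seq_len(na), seq_len(na))] <- 1
  A[cbind(m + seq_len(na), na + seq_len(na))] <- 1
  b[m + seq_len(na)] <- u[act]
  basis <- c(if (m) 2L * na + seq_len(m) else integer(0), na + seq_len(na))

  if (m) { # phase 1: drive artificials to zero
    cc1 <- c(rep(0, 2L * na), rep(-1, m))
    r1 <- simplex_core(A, b, cc1, basis)
    if (r1$status != "optimal") return(bad)
    art_val <- sum(r1$b[r1$basis > 2L * na])
    if (art_val > LP_FEAS_TOL) return(bad)
    A <- r1$A; b <- r1$b; basis <- r1$basis
    # pivot leftover zero-level artificials out; drop redundant rows
    drop_rows <- integer(0)
    for (i in which(basis > 2L * na)) {
      row <- A[i, seq_len(2L * na)]
      j <- which(abs(row) > LP_PIVOT_TOL)
      j <- setdiff(j, basis)
      if (length(j)) {
        j <- j[1]
        piv <- A[i, j]
        A[i, ] <- A[i, ] / piv; b[i] <- b[i] / piv
        f <- A[, j]; f[i] <- 0
        nz <- which(abs(f) > 0)
        if (length(nz)) {
          A[nz, ] <- A[nz, , drop = FALSE] - outer(f[nz], A[i, ])
          b[nz] <- b[nz] - f[nz] * b[i]
        }
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
    if (length(drop_rows)) {
      A <- A[-drop_rows, , drop = FALSE]
      b <- b[-drop_rows]
      basis <- basis[-drop_rows]
    }
    A <- A[, seq_len(2L * na), drop = FALSE]
  }

  sense <- if (maximize) 1 else -1
  cc2 <- c(sense * obj[act], rep(0, na))
  r2 <- simplex_core(A, b, cc2, basis)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, solution = NULL))
  }
  x <- numeric(na)
  isx <- r2$basis <= na
  x[r2$basis[isx]] <- r2$b[isx]
  x <- pmin(pmax(x, 0), u[act])
  mkres(x)
}
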