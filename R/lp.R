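#' @keywords internal
"_PACKAGE"

## Dense bounded-variable two-phase simplex.
##
## All flux-balance and flux-variability problems in this package are small
## (tens to a few hundred variables), dense, and solved many times with the
## same constraint set but different objectives.  The solver therefore keeps
## an explicit tableau that can be re-optimized in place after an objective
## swap (warm start), which is what makes per-reaction FVA cheap.
##
## Problem form:
##   min / max  obj' x
##   s.t.       A_eq x  = b_eq
##              A_ub x <= b_ub
##              lb <= x <= ub        (all bounds finite; Inf clamped to BIG)
##
## Internals: every row is turned into an equality; "<=" rows get a slack in
## [0, BIG]; every row gets a signed artificial column so the initial basis
## is feasible by construction.  Phase 1 minimizes the artificial sum, phase
## 2 the true objective.  Dantzig pricing with a Bland fallback guards
## against cycling.

LP_BIG <- 1e10
LP_TOL <- 1e-9

#' Build a reusable LP tableau
#'
#' Constructs the internal simplex state for a linear program. The returned
#' environment can be optimized repeatedly with different objectives via
#' [lp_optimize()], which is how flux variability analysis reuses one
#' feasibility phase across many objective vectors.
#'
#' @param A_eq numeric matrix of equality rows (may have 0 rows).
#' @param b_eq right-hand side of the equality rows.
#' @param A_ub numeric matrix of `<=` rows (may be `NULL`).
#' @param b_ub right-hand side of the `<=` rows.
#' @param lb,ub variable bounds; infinite entries are clamped to `1e10`.
#' @return an opaque LP state object for [lp_optimize()].
#' @keywords internal
lp_build <- function(A_eq, b_eq, A_ub = NULL, b_ub = NULL, lb, ub) {
  A_eq <- as.matrix(A_eq)
  n <- ncol(A_eq)
  if (is.null(A_ub)) {
    A_ub <- matrix(0, 0L, n)
    b_ub <- numeric(0)
  }
  A_ub <- as.matrix(A_ub)
  stopifnot(ncol(A_ub) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + LP_TOL)) {
    return(structure(list(status = "infeasible"), class = "gutflux_lp_dead"))
  }
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)

  m_eq <- nrow(A_eq)
  m_ub <- nrow(A_ub)
  m <- m_eq + m_ub
  A <- rbind(A_eq, A_ub)
  b <- c(b_eq, b_ub)

  ## slack columns for inequality rows
  n_slack <- m_ub
  if (n_slack > 0L) {
    S <- matrix(0, m, n_slack)
    for (i in seq_len(m_ub)) S[m_eq + i, i] <- 1
    A <- cbind(A, S)
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(LP_BIG, n_slack))
  }
  n_real <- n + n_slack

  ## nonbasic start: each variable at the bound nearest zero
  at_upper <- abs(ub) < abs(lb)
  x_nb <- ifelse(at_upper, ub, lb)
  r <- b - as.vector(A %*% x_nb)

  ## signed artificial columns -> identity-like feasible basis
  sig <- ifelse(r >= 0, 1, -1)
  Art <- diag(sig, m, m)
  A <- cbind(A, Art)
  lb <- c(lb, rep(0, m))
  ub <- c(ub, rep(LP_BIG, m))

  ntot <- n_real + m
  status <- ifelse(at_upper, 1L, 0L)           # 0 at lb, 1 at ub, 2 basic
  status <- c(status, rep(2L, m))
  basis <- n_real + seq_len(m)

  st <- new.env(parent = emptyenv())
  st$n <- n; st$n_real <- n_real; st$m <- m; st$ntot <- ntot
  st$lb <- lb; st$ub <- ub
  st$T <- sig * A                              # B^{-1} A with B = diag(sig)
  st$x <- c(ifelse(at_upper, ub[seq_len(n_real)], lb[seq_len(n_real)]),
            abs(r))                            # artificials close the gap
  st$status <- status
  st$artificial <- c(rep(FALSE, n_real), rep(TRUE, m))
  st$basis <- basis
  st$phase1_done <- FALSE
  class(st) <- "gutflux_lp"
  st
}

## One simplex run on state `st` with full-length cost vector `cvec`.
## Mutates st; returns "optimal", "unbounded" or "iteration_limit".
lp_iterate <- function(st, cvec, max_iter = 20000L, exclude = NULL) {
  Tm <- st$T
  lb <- st$lb; ub <- st$ub
  status <- st$status; basis <- st$basis
  x <- st$x
  m <- st$m; ntot <- st$ntot
  bland_after <- 4L * (m + ntot)
  iter <- 0L
  res <- "iteration_limit"

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    cB <- cvec[basis]
    z <- cvec - as.vector(crossprod(cB, Tm))   # reduced costs
    nb <- which(status != 2L)
    if (!is.null(exclude)) nb <- nb[!exclude[nb]]
    viol <- numeric(length(nb))
    at_lb <- status[nb] == 0L
    viol[at_lb] <- -z[nb[at_lb]]
    viol[!at_lb] <- z[nb[!at_lb]]
    elig <- nb[viol > LP_TOL * 10]
    if (length(elig) == 0L) { res <- "optimal"; break }
    q <- if (iter > bland_after) min(elig) else
      elig[which.max(viol[viol > LP_TOL * 10])]
    dir <- if (status[q] == 0L) 1 else -1
    d <- Tm[, q] * dir                          # x_B moves by -d * t
    xB <- x[basis]
    lo <- lb[basis]; hi <- ub[basis]
    tvec <- rep(Inf, m)
    pos <- d > LP_TOL
    neg <- d < -LP_TOL
    tvec[pos] <- (xB[pos] - lo[pos]) / d[pos]
    tvec[neg] <- (xB[neg] - hi[neg]) / d[neg]
    tvec[tvec < 0] <- 0
    t_bound <- ub[q] - lb[q]
    t_star <- min(tvec, t_bound)
    if (!is.finite(t_star)) { res <- "unbounded"; break }

    if (t_bound <= t_star + LP_TOL) {
      ## bound flip, basis unchanged
      x[basis] <- xB - d * t_bound
      x[q] <- if (status[q] == 0L) ub[q] else lb[q]
      status[q] <- 1L - status[q]
      next
    }
    cand <- which(tvec <= t_star + LP_TOL)
    p <- if (iter > bland_after) cand[which.min(basis[cand])] else cand[which.max(abs(d[cand]))]
    leave <- basis[p]
    x[basis] <- xB - d * t_star
    x[q] <- (if (status[q] == 0L) lb[q] else ub[q]) + dir * t_star
    status[leave] <- if (d[p] > 0) 0L else 1L
    x[leave] <- if (d[p] > 0) lb[leave] else ub[leave]
    status[q] <- 2L
    basis[p] <- q
    piv <- Tm[p, q]
    prow <- Tm[p, ] / piv
    col <- Tm[, q]
    Tm <- Tm - tcrossprod(col, prow)
    Tm[p, ] <- prow
    ## exact zero on the pivot column keeps the tableau clean
    Tm[, q] <- 0; Tm[p, q] <- 1
  }

  st$T <- Tm; st$status <- status; st$basis <- basis; st$x <- x
  res
}

#' Re-optimize a built LP with a fresh objective
#'
#' @param st state from [lp_build()].
#' @param obj objective coefficients over the structural variables.
#' @param maximize logical.
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "iteration_limit"), `objective`, and `x` (structural solution).
#' @keywords internal
lp_optimize <- function(st, obj, maximize = FALSE) {
  if (inherits(st, "gutflux_lp_dead")) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  stopifnot(length(obj) == st$n)
  if (!st$phase1_done) {
    c1 <- c(rep(0, st$n_real), rep(1, st$m))
    r1 <- lp_iterate(st, c1)
    art <- st$n_real + seq_len(st$m)
    infeas <- sum(st$x[art][st$status[art] == 2L])
    if (r1 != "optimal" || infeas > 1e-6) {
      st$phase1_done <- TRUE
      st$infeasible <- TRUE
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    ## freeze artificials at zero; a degenerate basic artificial may remain
    st$lb[art] <- 0
    st$ub[art] <- 0
    st$x[art] <- 0
    st$phase1_done <- TRUE
    st$infeasible <- FALSE
  }
  if (isTRUE(st$infeasible)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  sgn <- if (maximize) -1 else 1
  c2 <- c(sgn * obj, rep(0, st$ntot - st$n))
  r2 <- lp_iterate(st, c2, exclude = st$artificial)
  xs <- st$x[seq_len(st$n)]
  val <- sum(obj * xs)
  ## a solution leaning on the clamped "infinity" is an unbounded direction
  if (r2 == "optimal" && abs(val) > 0.99 * LP_BIG) r2 <- "unbounded"
  list(status = r2, objective = if (r2 == "optimal") val else NA_real_, x = xs)
}

#' Solve one dense linear program
#'
#' Thin convenience wrapper over [lp_build()] + [lp_optimize()] for callers
#' that need a single solve.
#'
#' @inheritParams lp_build
#' @inheritParams lp_optimize
#' @keywords internal
lp_solve_dense <- function(obj, A_eq, b_eq, A_ub = NULL, b_ub = NULL,
                           lb, ub, maximize = FALSE) {
  st <- lp_build(A_eq, b_eq, A_ub, b_ub, lb, ub)
  lp_optimize(st, obj, maximize = maximize)
}
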