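# Independent flux-variability oracle: exhaustive vertex enumeration of the
# flux polytope. Builds its own constraint matrices from the model object
# (straightforward loops, no shared code with the solver path) and takes
# min/max over all vertices. Only usable on tiny models.

oracle_matrices <- function(model) {
  rxn <- model$reactions
  mets <- model$metabolites$id
  n <- nrow(rxn)
  S <- matrix(0, length(mets), n, dimnames = list(mets, rxn$id))
  for (j in seq_len(n)) {
    for (m in names(rxn$stoichiometry[[j]])) {
      S[m, j] <- S[m, j] + rxn$stoichiometry[[j]][[m]]
    }
  }
  A <- NULL
  b <- numeric(0)
  cp <- model$coupling
  if (!is.null(cp) && nrow(cp) > 0) {
    for (i in seq_len(nrow(cp))) {
      r1 <- numeric(n); r2 <- numeric(n)
      jr <- which(rxn$id == cp$reaction_id[i])
      jb <- which(rxn$id == cp$biomass_reaction_id[i])
      r1[jr] <- 1;  r1[jb] <- -cp$c[i]
      r2[jr] <- -1; r2[jb] <- -cp$c[i]
      A <- rbind(A, r1, r2)
      b <- c(b, cp$u[i], cp$u[i])
    }
  }
  list(S = S, A = A, b = b, lb = rxn$lower_bound, ub = rxn$upper_bound,
       ids = rxn$id)
}

# vertices of {S v = 0, A v <= b, lb <= v <= ub}; inequality rows become
# equalities with slack variables in [0, 1e12] (never binding above)
oracle_vertices <- function(model, tol = 1e-7) {
  mm <- oracle_matrices(model)
  n <- ncol(mm$S)
  m_ub <- if (is.null(mm$A)) 0L else nrow(mm$A)
  Aall <- rbind(cbind(mm$S, matrix(0, nrow(mm$S), m_ub)),
                if (m_ub > 0) cbind(mm$A, diag(m_ub)))
  ball <- c(rep(0, nrow(mm$S)), mm$b)
  lb <- c(mm$lb, rep(0, m_ub))
  ub <- c(mm$ub, rep(1e12, m_ub))
  ntot <- n + m_ub
  r <- qr(Aall)$rank
  free <- ntot - r
  stopifnot(free >= 0)
  verts <- list()
  combos <- utils::combn(ntot, free, simplify = FALSE)
  for (fixed in combos) {
    rest <- setdiff(seq_len(ntot), fixed)
    Ar <- Aall[, rest, drop = FALSE]
    qr_r <- qr(Ar)
    if (qr_r$rank < length(rest)) next
    for (mask in seq_len(2^free) - 1L) {
      vals <- ifelse(bitwAnd(mask, 2^(seq_len(free) - 1L)) > 0,
                     ub[fixed], lb[fixed])
      rhs <- ball - if (free > 0) as.vector(Aall[, fixed, drop = FALSE] %*%
                                              vals) else 0
      x_rest <- tryCatch(qr.coef(qr_r, rhs), error = function(e) NULL)
      if (is.null(x_rest) || anyNA(x_rest)) next
      if (max(abs(Ar %*% x_rest - rhs)) > tol) next
      v <- numeric(ntot)
      v[fixed] <- vals
      v[rest] <- x_rest
      if (any(v < lb - tol) || any(v > ub + tol)) next
      verts[[length(verts) + 1L]] <- v[seq_len(n)]
    }
  }
  stopifnot(length(verts) > 0)
  out <- do.call(rbind, verts)
  colnames(out) <- mm$ids
  out
}

oracle_fva <- function(model, reactions = NULL) {
  V <- oracle_vertices(model)
  if (is.null(reactions)) reactions <- colnames(V)
  tibble::tibble(reaction = reactions,
                 minimum = unname(apply(V[, reactions, drop = FALSE], 2, min)),
                 maximum = unname(apply(V[, reactions, drop = FALSE], 2, max)))
}
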