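## Internal linear-programming solver.
##
## Minimizes c'x subject to A x <= b, x >= 0, by the classic two-phase
## dense-tableau primal simplex with Bland's pivoting rule (guaranteed
## finite termination, including on the degenerate systems that
## preference-derivation programs produce).  Problems here are small
## (tens of variables, a few hundred rows), so a dense tableau is fine.

lp_min_leq <- function(cc, A, b, tol = 1e-9, max_iter = 100000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m)

  # equality form: rows with negative rhs are flipped, so slack columns on
  # those rows come in with -1 and an artificial variable is needed
  flip <- b < 0
  Aeq <- A
  Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
  beq <- abs(b)
  Sl <- diag(m)
  diag(Sl)[flip] <- -1
  n_art <- sum(flip)
  Art <- matrix(0, m, n_art)
  if (n_art > 0L) Art[cbind(which(flip), seq_len(n_art))] <- 1

  Tb <- cbind(Aeq, Sl, Art, beq)
  N <- n + m + n_art
  basis <- integer(m)
  basis[!flip] <- n + which(!flip)
  basis[flip] <- n + m + seq_len(n_art)

  pivot <- function(Tb, basis, cost) {
    it <- 0L
    repeat {
      red <- cost - as.vector(cost[basis] %*% Tb[, seq_len(N), drop = FALSE])
      ent <- which(red < -tol)
      if (length(ent) == 0L) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- ent[1L]                           # Bland: lowest entering index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[pos, N + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]      # Bland: lowest leaving basic var
      Tb[r, ] <- Tb[r, ] / Tb[r, j]
      oth <- setdiff(seq_len(m), r)
      Tb[oth, ] <- Tb[oth, ] - outer(Tb[oth, j], Tb[r, ])
      basis[r] <- j
      it <- it + 1L
      if (it > max_iter) return(list(Tb = Tb, basis = basis, status = "maxiter"))
    }
  }

  if (n_art > 0L) {
    cost1 <- c(rep(0, n + m), rep(1, n_art))
    ph1 <- pivot(Tb, basis, cost1)
    if (ph1$status != "optimal")
      return(list(x = NULL, status = ph1$status))
    obj1 <- sum(cost1[ph1$basis] * ph1$Tb[, N + 1L])
    if (obj1 > 1e-7)
      return(list(x = NULL, status = "infeasible"))
    Tb <- ph1$Tb; basis <- ph1$basis
    # drive any zero-valued artificial out of the basis; a row with no
    # usable pivot is redundant and can stay (its artificial is 0)
    for (r in which(basis > n + m)) {
      piv <- which(abs(Tb[r, seq_len(n + m)]) > tol)
      if (length(piv) > 0L) {
        j <- piv[1L]
        Tb[r, ] <- Tb[r, ] / Tb[r, j]
        oth <- setdiff(seq_len(m), r)
        Tb[oth, ] <- Tb[oth, ] - outer(Tb[oth, j], Tb[r, ])
        basis[r] <- j
      }
    }
    # forbid artificials from re-entering
    Tb[, n + m + seq_len(n_art)] <- 0
  }

  cost2 <- c(cc, rep(0, m + n_art))
  ph2 <- pivot(Tb, basis, cost2)
  if (ph2$status != "optimal")
    return(list(x = NULL, status = ph2$status))
  x <- numeric(N)
  x[ph2$basis] <- ph2$Tb[, N + 1L]
  list(x = x[seq_len(n)], value = sum(cc * x[seq_len(n)]), status = "optimal")
}
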