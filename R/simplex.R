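# Internal dense two-phase simplex solver.
#
# Solves   min/max  obj' x   s.t.  A x (<=, >=, =) b,  x >= 0
# with Bland's anti-cycling rule, so the solve is deterministic and
# terminates on the degenerate problems that flux-balance LPs routinely
# produce. Problem sizes here are tiny (on the order of 100 variables and
# rows), so a dense tableau is appropriate.

simplexLP <- function(obj, A, b, ctype, maximize = TRUE, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(ctype) == m, length(obj) == n)
  # normalize to b >= 0
  for (i in seq_len(m)) {
    if (b[i] < 0) {
      A[i, ] <- -A[i, ]
      b[i] <- -b[i]
      ctype[i] <- switch(ctype[i], "<=" = ">=", ">=" = "<=", "=" = "=")
    }
  }
  le <- which(ctype == "<="); ge <- which(ctype == ">="); eq <- which(ctype == "=")
  n_slack <- length(le) + length(ge)      # slack/surplus
  n_art <- length(ge) + length(eq)
  ncols <- n + n_slack + n_art
  T_A <- matrix(0, m, ncols)
  T_A[, seq_len(n)] <- A
  basis <- integer(m)
  sc <- n                                  # next slack/surplus column
  ac <- n + n_slack                        # next artificial column
  for (i in le) { sc <- sc + 1L; T_A[i, sc] <- 1;  basis[i] <- sc }
  for (i in ge) { sc <- sc + 1L; T_A[i, sc] <- -1 }
  for (i in c(ge, eq)) { ac <- ac + 1L; T_A[i, ac] <- 1; basis[i] <- ac }
  art_cols <- seq.int(n + n_slack + 1L, length.out = n_art)

  # bring into canonical form for the initial basis (identity in basis cols)
  # rows with artificial or slack basis are already canonical

  pivot <- function(T_A, b, basis, prow, pcol) {
    pv <- T_A[prow, pcol]
    T_A[prow, ] <- T_A[prow, ] / pv
    b[prow] <- b[prow] / pv
    for (r in seq_len(nrow(T_A))) {
      if (r == prow) next
      f <- T_A[r, pcol]
      if (f != 0) {
        T_A[r, ] <- T_A[r, ] - f * T_A[prow, ]
        b[r] <- b[r] - f * b[prow]
      }
    }
    list(T_A = T_A, b = b)
  }

  run_phase <- function(T_A, b, basis, cost, allowed) {
    it_max <- 500L * (m + ncols)
    for (it in seq_len(it_max)) {
      cB <- cost[basis]
      red <- cost - as.vector(cB %*% T_A)
      red[!allowed] <- Inf
      enter <- which(red < -tol)
      if (!length(enter))
        return(list(T_A = T_A, b = b, basis = basis, status = "optimal"))
      j <- enter[1]                        # Bland: lowest index enters
      col <- T_A[, j]
      cand <- which(col > tol)
      if (!length(cand))
        return(list(T_A = T_A, b = b, basis = basis, status = "unbounded"))
      ratio <- b[cand] / col[cand]
      best <- min(ratio)
      ties <- cand[ratio <= best + tol * (1 + abs(best))]
      i <- ties[which.min(basis[ties])]    # Bland: lowest basic index leaves
      res <- pivot(T_A, b, basis, i, j)
      T_A <- res$T_A; b <- res$b
      basis[i] <- j
    }
    list(T_A = T_A, b = b, basis = basis, status = "maxit")
  }

  # phase 1: drive artificials to zero
  if (n_art > 0L) {
    cost1 <- numeric(ncols)
    cost1[art_cols] <- 1
    allowed <- rep(TRUE, ncols)
    ph1 <- run_phase(T_A, b, basis, cost1, allowed)
    if (ph1$status != "optimal")
      return(list(status = "infeasible"))
    T_A <- ph1$T_A; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible"))
    # pivot remaining (zero-valued) artificials out of the basis
    drop_rows <- integer(0)
    for (i in which(basis %in% art_cols)) {
      row <- T_A[i, seq_len(n + n_slack)]
      j <- which(abs(row) > tol)
      if (!length(j)) { drop_rows <- c(drop_rows, i); next }
      res <- pivot(T_A, b, basis, i, j[1])
      T_A <- res$T_A; b <- res$b
      basis[i] <- j[1]
    }
    if (length(drop_rows)) {
      T_A <- T_A[-drop_rows, , drop = FALSE]
      b <- b[-drop_rows]
      basis <- basis[-drop_rows]
      m <- nrow(T_A)
    }
  }

  # phase 2
  cost2 <- numeric(ncols)
  cost2[seq_len(n)] <- if (maximize) -obj else obj
  allowed <- rep(TRUE, ncols)
  allowed[art_cols] <- FALSE
  ph2 <- run_phase(T_A, b, basis, cost2, allowed)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status != "optimal") return(list(status = "maxit"))
  x <- numeric(ncols)
  x[ph2$basis] <- ph2$b
  sol <- x[seq_len(n)]
  list(status = "optimal", soln = sol, value = sum(obj * sol))
}
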