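# Internal LP/QP backend.
#
# No LP package is installed in the target environment, so linear subproblems
# (objective maximization, FVA ranges) are solved by a dense Mehrotra
# predictor-corrector primal-dual interior-point method written here --
# robust to the mixed constraint scales these models produce (bounds of
# +-1000 against objective-fixing bands of 1e-9). Infeasibility is certified
# with an elastic phase-1 solve. The strictly convex norm-2 step goes through
# quadprog (Goldfarb-Idnani) on a null-space parametrization, with the
# interior-point method (diagonal Q) as fallback when the active-set solver
# loses conditioning. Problems are small (tens of reactions), so dense
# algebra suffices.

BIG_BOUND <- 1e6

# Mehrotra predictor-corrector for
#   min c'x + (1/2) x' diag(qdiag) x   s.t.  A x = b,  lb < ub (finite).
# A must have full row rank. Returns list(x, converged).
solve_ip <- function(cvec, qdiag, A, b, lb, ub, max_iter = 200) {
  n <- length(cvec)
  m <- nrow(A)
  # interior start
  w <- ub - lb
  x <- (lb + ub) / 2
  y <- rep(0, m)
  zl <- rep(1, n); zu <- rep(1, n)
  bscale <- 1 + max(abs(b), 0)
  cscale <- 1 + max(abs(cvec))
  for (it in seq_len(max_iter)) {
    sl <- x - lb; su <- ub - x
    rp <- b - as.numeric(A %*% x)
    rd <- cvec + qdiag * x - (if (m) as.numeric(crossprod(A, y)) else 0) - zl + zu
    mu <- (sum(sl * zl) + sum(su * zu)) / (2 * n)
    feas <- max(abs(rp)) < 1e-10 * bscale && max(abs(rd)) < 1e-10 * cscale
    if (feas && mu < 1e-11 * cscale)
      return(list(x = x, converged = TRUE))
    if (mu <= 0 || !is.finite(mu))
      return(list(x = x, converged = feas))
    d <- zl / pmax(sl, 1e-300) + zu / pmax(su, 1e-300) + qdiag
    newton <- function(vl, vu) {
      # zl*dx + sl*dzl = vl ; -zu*dx + su*dzu = vu
      # eliminating dzl, dzu leaves  A'dy - D dx = rhat,  A dx = rp; solved
      # as the augmented quasi-definite system (stable under the extreme
      # diagonal spread that degenerate bound intervals produce)
      rhat <- rd - vl / sl + vu / su
      if (m) {
        K <- rbind(cbind(diag(-d, n), t(A)), cbind(A, matrix(0, m, m)))
        sol <- tryCatch(solve(K, c(rhat, rp), tol = 1e-300),
                        error = function(e) NULL)
        if (is.null(sol)) return(NULL)
        dx <- sol[seq_len(n)]
        dy <- sol[n + seq_len(m)]
      } else {
        dy <- numeric(0)
        dx <- -rhat / d
      }
      dzl <- (vl - zl * dx) / sl
      dzu <- (vu + zu * dx) / su
      list(dx = dx, dy = dy, dzl = dzl, dzu = dzu)
    }
    steplen <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) 1 else min(1, 0.9995 * min(-v[neg] / dv[neg]))
    }
    # predictor
    aff <- newton(-sl * zl, -su * zu)
    if (is.null(aff) || any(!is.finite(c(aff$dx, aff$dy, aff$dzl, aff$dzu))))
      return(list(x = x, converged = feas))
    ap <- min(steplen(sl, aff$dx), steplen(su, -aff$dx))
    ad <- min(steplen(zl, aff$dzl), steplen(zu, aff$dzu))
    mu_aff <- (sum((sl + ap * aff$dx) * (zl + ad * aff$dzl)) +
               sum((su - ap * aff$dx) * (zu + ad * aff$dzu))) / (2 * n)
    sigma <- (mu_aff / mu)^3
    if (!is.finite(sigma)) sigma <- 0.1
    # corrector
    dir <- newton(sigma * mu - sl * zl - aff$dx * aff$dzl,
                  sigma * mu - su * zu + aff$dx * aff$dzu)
    if (is.null(dir) || any(!is.finite(c(dir$dx, dir$dy, dir$dzl, dir$dzu))))
      return(list(x = x, converged = feas))
    ap <- min(steplen(sl, dir$dx), steplen(su, -dir$dx))
    ad <- min(steplen(zl, dir$dzl), steplen(zu, dir$dzu))
    x <- x + ap * dir$dx
    if (m) y <- y + ad * dir$dy
    zl <- pmax(zl + ad * dir$dzl, 1e-300)
    zu <- pmax(zu + ad * dir$dzu, 1e-300)
  }
  list(x = x, converged = FALSE)
}

# elastic phase-1: min 1's  s.t.  A x + P s = b, box, 0 <= s <= BIG;
# returns the minimal total constraint violation (0 => feasible)
phase1_violation <- function(A, b, lb, ub) {
  m <- nrow(A)
  if (!m) return(0)
  P <- cbind(diag(m), -diag(m))
  A2 <- cbind(A, P)
  n <- ncol(A)
  res <- solve_ip(c(rep(0, n), rep(1, 2 * m)), rep(0, n + 2 * m), A2, b,
                  c(lb, rep(0, 2 * m)), c(ub, rep(BIG_BOUND, 2 * m)))
  sum(res$x[(n + 1):(n + 2 * m)])
}

# Solve  min c'x (+ 1/2 x'x if quadratic)  s.t.  Aeq x = beq, Ain x >= bin,
# lb <= x <= ub.  Returns list(status, x, obj).
solve_constrained <- function(cvec, Aeq, beq, lb, ub,
                              Ain = NULL, bin = NULL,
                              quadratic = FALSE, maximize = FALSE,
                              tol = 1e-6) {
  n <- length(cvec)
  if (maximize) cvec <- -cvec
  if (any(lb > ub + tol)) return(list(status = "infeasible", x = NULL, obj = NA_real_))
  ub <- pmax(ub, lb)   # guard tiny inversions from roundoff
  inf_lb <- !is.finite(lb); inf_ub <- !is.finite(ub)
  lb[inf_lb] <- -BIG_BOUND; ub[inf_ub] <- BIG_BOUND

  # inequality rows enter as slack variables: Ain x - s = bin, s in [0, BIG]
  nslack <- if (is.null(Ain)) 0L else nrow(Ain)
  A <- if (nslack) rbind(cbind(Aeq, matrix(0, nrow(Aeq), nslack)),
                         cbind(Ain, -diag(nslack)))
       else Aeq
  b <- c(beq, if (nslack) bin)
  lbx <- c(lb, rep(0, nslack)); ubx <- c(ub, rep(BIG_BOUND, nslack))
  cx <- c(cvec, rep(0, nslack))
  qx <- c(rep(as.numeric(quadratic), n), rep(0, nslack))
  N <- n + nslack

  # full row rank for the interior-point normal equations
  qrA <- qr(t(A))
  r <- qrA$rank
  keep <- qrA$pivot[seq_len(r)]
  Ak <- A[keep, , drop = FALSE]
  bk <- b[keep]

  # interior-point iterates need lb < ub strictly
  degen <- (ubx - lbx) < 1e-10
  mid <- (lbx + ubx) / 2
  lbx[degen] <- mid[degen] - 5e-11
  ubx[degen] <- mid[degen] + 5e-11

  finish <- function(x) {
    x <- as.numeric(x)[seq_len(n)]
    resid <- max(abs(Aeq %*% x - beq), 0)
    iresid <- if (nslack) min(Ain %*% x - bin, 0) else 0
    bresid <- max(c(lb - x, x - ub, 0))
    if (resid > 1e-6 || iresid < -1e-6 || bresid > 1e-6)
      return(NULL)
    # variables parked at an artificial cap of a formerly infinite bound with
    # objective pressure on them indicate an unbounded linear program
    at_cap <- (inf_lb & x < -BIG_BOUND * 0.999) | (inf_ub & x > BIG_BOUND * 0.999)
    if (!quadratic && any(at_cap & abs(cvec) > 0))
      return(list(status = "unbounded", x = NULL, obj = NA_real_))
    obj <- sum(cvec * x) + if (quadratic) 0.5 * sum(x^2) else 0
    if (maximize) obj <- -obj
    list(status = "optimal", x = x, obj = obj)
  }

  if (quadratic) {
    out <- qp_nullspace(cx[seq_len(n)], Aeq, beq, lb, ub, Ain, bin)
    if (!is.null(out)) {
      res <- finish(out)
      if (!is.null(res)) return(res)
    }
  }
  ipm <- solve_ip(cx, qx, Ak, bk, lbx, ubx)
  res <- finish(ipm$x)
  if (!is.null(res)) return(res)
  viol <- phase1_violation(Ak, bk, lbx, ubx)
  if (viol > 1e-6) return(list(status = "infeasible", x = NULL, obj = NA_real_))
  list(status = "numerical_failure", x = NULL, obj = NA_real_)
}

# quadprog route for the strictly convex step: equalities eliminated through
# an orthonormal null-space basis so Goldfarb-Idnani sees only inequalities
qp_nullspace <- function(cvec, Aeq, beq, lb, ub, Ain = NULL, bin = NULL) {
  n <- length(cvec)
  qrA <- qr(t(Aeq))
  r <- qrA$rank
  keep <- qrA$pivot[seq_len(r)]
  Ak <- Aeq[keep, , drop = FALSE]
  x0 <- if (r > 0) as.numeric(crossprod(Ak, solve(tcrossprod(Ak), beq[keep])))
        else rep(0, n)
  if (r == n) return(x0)
  Q <- qr.Q(qrA, complete = TRUE)
  Z <- Q[, seq.int(r + 1L, n), drop = FALSE]
  nz <- ncol(Z)
  G <- rbind(Z, -Z, if (!is.null(Ain)) Ain %*% Z)
  h <- c(lb - x0, x0 - ub, if (!is.null(Ain)) bin - as.numeric(Ain %*% x0))
  y <- tryCatch(
    quadprog::solve.QP(diag(nz), -as.numeric(crossprod(Z, cvec + x0)),
                       t(G), h, meq = 0)$solution,
    error = function(e) NULL)
  if (is.null(y)) return(NULL)
  x0 + as.numeric(Z %*% y)
}

# FBA-flavoured wrapper: steady state S v = 0 plus optional fixed objective
# fluxes and inequality rows, minimizing/maximizing a single flux or the
# squared norm. Objective fixing (the lexicographic step) is enforced as
# v_j >= val - tol with relative tolerance 1e-9: the optimal value is only
# attained on a boundary face whose relative interior is empty in the bound
# box, so a one-sided tolerance keeps the problem interior-point friendly --
# and val is an upper bound by optimality, so the constraint is two-sided in
# effect.
fba_solve <- function(model, objective_index = NULL, maximize = TRUE,
                      fixed = NULL, min_norm = FALSE,
                      Ain = NULL, bin = NULL) {
  n <- ncol(model$S)
  cvec <- numeric(n)
  if (!is.null(objective_index)) cvec[objective_index] <- 1
  if (!is.null(fixed) && length(fixed)) {
    rows <- matrix(0, length(fixed), n)
    cuts <- numeric(length(fixed))
    for (i in seq_along(fixed)) {
      val <- as.numeric(fixed[i])
      rows[i, as.integer(names(fixed)[i])] <- 1
      cuts[i] <- val - 1e-9 * max(1, abs(val))
    }
    Ain <- rbind(Ain, rows)
    bin <- c(bin, cuts)
  }
  solve_constrained(cvec, model$S, rep(0, nrow(model$S)), model$lb, model$ub,
                    Ain = Ain, bin = bin,
                    quadratic = min_norm, maximize = maximize && !min_norm)
}
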