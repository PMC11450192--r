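# Linear programming layer.
#
# All flux analyses reduce to
#     min/max  c'x   s.t.  A x {<=,>=,=} rhs,  lb <= x <= ub
# solved by a dense bounded-variable two-phase simplex. Nonbasic variables
# rest at a bound; phase 1 drives signed artificial variables to zero; the
# ratio test allows bound flips. Problem sizes here are small (tens to a few
# hundred variables), so the basis is refactorised by a dense solve at every
# iteration — slow but numerically transparent. Properties downstream are
# written against objective values, not vertex identity: no tie-breaking
# behaviour of this solver is relied upon.

# min c'x s.t. A x = b, lb <= x <= ub (lb finite; ub may be +Inf)
lp_simplex <- function(c_, A, b, lb, ub, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  tol <- 1e-9
  piv_tol <- 1e-9

  # artificials: signed so their initial value is nonnegative
  x <- ifelse(is.finite(ub) & abs(ub) < abs(lb), ub, lb)
  at_ub <- is.finite(ub) & abs(ub) < abs(lb)
  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lb_f <- c(lb, rep(0, m))
  ub_f <- c(ub, rep(Inf, m))
  x_f <- c(x, abs(r))
  basis <- n + seq_len(m)
  status <- ifelse(at_ub, 2L, 1L)          # structural: 1 at lb, 2 at ub
  status <- c(status, rep(0L, m))          # 0 = basic
  status[basis] <- 0L

  run_phase <- function(cost, x_f, basis, status, lb_f, ub_f) {
    degen <- 0L
    for (it in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(ok = FALSE))
      nonbasic <- which(status > 0L)
      d <- cost[nonbasic] - as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))
      can_in <- (status[nonbasic] == 1L & d < -tol) |
                (status[nonbasic] == 2L & d > tol)
      if (!any(can_in)) {
        return(list(ok = TRUE, x = x_f, basis = basis, status = status,
                    obj = sum(cost * x_f)))
      }
      cand <- nonbasic[can_in]
      j <- if (degen > 60L) min(cand) else cand[which.max(abs(d[can_in]))]
      delta <- if (status[j] == 1L) 1 else -1
      w <- tryCatch(solve(B, Afull[, j]), error = function(e) NULL)
      if (is.null(w)) return(list(ok = FALSE))
      # ratio test, including a bound flip of the entering variable
      t_max <- ub_f[j] - lb_f[j]
      leave <- 0L
      dw <- delta * w
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (dw[i] > piv_tol) {
          lim <- (x_f[bi] - lb_f[bi]) / dw[i]
          if (lim < t_max - 1e-12) { t_max <- lim; leave <- i }
        } else if (dw[i] < -piv_tol) {
          if (is.finite(ub_f[bi])) {
            lim <- (ub_f[bi] - x_f[bi]) / (-dw[i])
            if (lim < t_max - 1e-12) { t_max <- lim; leave <- i }
          }
        }
      }
      if (!is.finite(t_max)) return(list(ok = TRUE, unbounded = TRUE))
      t_max <- max(t_max, 0)
      degen <- if (t_max < 1e-11) degen + 1L else 0L
      # update values
      x_f[j] <- x_f[j] + delta * t_max
      x_f[basis] <- x_f[basis] - dw * t_max
      if (leave == 0L) {
        status[j] <- if (status[j] == 1L) 2L else 1L  # bound flip
      } else {
        out_var <- basis[leave]
        # leaving variable rests at the bound it reached
        hit_lb <- dw[leave] > 0
        x_f[out_var] <- if (hit_lb) lb_f[out_var] else ub_f[out_var]
        status[out_var] <- if (hit_lb) 1L else 2L
        basis[leave] <- j
        status[j] <- 0L
      }
    }
    list(ok = FALSE) # iteration limit
  }

  # phase 1: minimise the artificial mass
  p1 <- run_phase(c(rep(0, n), rep(1, m)), x_f, basis, status, lb_f, ub_f)
  if (!p1$ok) return(list(status = "failed"))
  if (isTRUE(p1$unbounded) || p1$obj > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible"))
  }
  # phase 2: artificials pinned to zero, true costs
  lb_f[n + seq_len(m)] <- 0
  ub_f[n + seq_len(m)] <- 0
  x2 <- p1$x; x2[n + seq_len(m)] <- pmax(pmin(x2[n + seq_len(m)], 0), 0)
  p2 <- run_phase(c(c_, rep(0, m)), x2, p1$basis, p1$status, lb_f, ub_f)
  if (!p2$ok) return(list(status = "failed"))
  if (isTRUE(p2$unbounded)) return(list(status = "unbounded"))
  list(status = "optimal", x = p2$x[seq_len(n)], objective = sum(c_ * p2$x[seq_len(n)]))
}

# general interface: direction vector of "<=", ">=", "=" rows; inequalities
# get slack variables internally
solve_lp <- function(obj, A = NULL, dir = character(0), rhs = numeric(0),
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  if (is.null(A)) A <- matrix(0, 0, n)
  A <- as.matrix(A)
  n_le <- sum(dir == "<="); n_ge <- sum(dir == ">=")
  n_slack <- n_le + n_ge
  S <- matrix(0, nrow(A), n_slack)
  k <- 0L
  for (i in seq_along(dir)) {
    if (dir[i] == "<=") { k <- k + 1L; S[i, k] <- 1 }
    else if (dir[i] == ">=") { k <- k + 1L; S[i, k] <- -1 }
  }
  cc <- c(if (maximize) -obj else obj, rep(0, n_slack))
  res <- lp_simplex(cc, cbind(A, S), rhs,
                    lb = c(lb, rep(0, n_slack)),
                    ub = c(ub, rep(Inf, n_slack)))
  if (res$status != "optimal") {
    return(list(status = if (res$status == "failed") "infeasible" else res$status,
                x = NULL, objective = NA_real_))
  }
  x <- res$x[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(obj * x))
}
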