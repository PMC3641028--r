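# Bounded-variable two-phase simplex for flux balance problems:
#   max/min c'x  s.t.  A x = b,  l <= x <= u.
#
# The basis is refactorized at every pivot (dense solve); for the model sizes
# this package targets (tens to a few hundred reactions) that is far cheaper
# than robustness problems are expensive. Phase 1 minimizes the sum of
# artificial residual variables; after phase 1 the artificials are pinned to
# zero and phase 2 optimizes the user objective. Dantzig pricing with a
# Bland's-rule fallback guards against cycling.

#' Solve a bounded linear program
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Equality constraint matrix (m x n).
#' @param b Equality right-hand side (length m).
#' @param lb,ub Variable bounds (length n); infinities allowed, but every
#'   variable needs at least one finite bound.
#' @param maximize Maximize (default) or minimize.
#' @param tol Feasibility / optimality tolerance.
#' @return List with `x` (solution), `objective_value` and `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`).
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A),
            length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(x = NULL, objective_value = NA_real_, status = "infeasible"))
  }
  if (any(is.infinite(lb) & is.infinite(ub))) {
    stop("every LP variable needs at least one finite bound")
  }
  m <- nrow(A)
  cc <- if (maximize) obj else -obj

  # variables n+1 .. n+m are phase-1 artificials
  start <- ifelse(is.finite(lb) & (abs(lb) <= abs(ub) | !is.finite(ub)),
                  lb, ub)
  r0 <- b - as.vector(A %*% start)
  Afull <- cbind(A, diag(ifelse(r0 >= 0, 1, -1), m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  # status: 1 = nonbasic at lower, 2 = nonbasic at upper, 0 = basic
  stat <- c(ifelse(start == lb, 1L, 2L), rep(0L, m))
  basis <- n + seq_len(m)

  run_phase <- function(cost, basis, stat, maxit) {
    repeat_count <- 0L
    bland <- FALSE
    for (it in seq_len(maxit)) {
      nb <- which(stat != 0L)
      xN <- ifelse(stat[nb] == 1L, lbf[nb], ubf[nb])
      B <- Afull[, basis, drop = FALSE]
      xB <- tryCatch(
        solve(B, b - as.vector(Afull[, nb, drop = FALSE] %*% xN)),
        error = function(e) NULL)
      if (is.null(xB)) stop("singular basis in LP solve")
      y <- solve(t(B), cost[basis])
      d <- cost[nb] - as.vector(t(Afull[, nb, drop = FALSE]) %*% y)
      enter_ok <- (stat[nb] == 1L & d > tol) | (stat[nb] == 2L & d < -tol)
      if (!any(enter_ok)) {
        x <- numeric(n + m)
        x[nb] <- xN
        x[basis] <- xB
        return(list(status = "optimal", x = x, basis = basis, stat = stat))
      }
      cand <- which(enter_ok)
      j <- if (bland) cand[which.min(nb[cand])]
           else cand[which.max(abs(d[cand]))]
      jv <- nb[j]
      up <- stat[jv] == 1L      # entering increases from its lower bound
      w <- solve(B, Afull[, jv])
      sgn <- if (up) 1 else -1
      # basic variable i moves as xB_i - sgn * t * w_i
      tmax <- ubf[jv] - lbf[jv]
      leave <- 0L; leave_to <- 0L
      for (i in seq_len(m)) {
        wi <- sgn * w[i]
        if (wi > tol) {
          ti <- (xB[i] - lbf[basis[i]]) / wi
          if (is.finite(ti) && ti < tmax - 1e-12) {
            tmax <- ti; leave <- i; leave_to <- 1L
          }
        } else if (wi < -tol) {
          ti <- (ubf[basis[i]] - xB[i]) / (-wi)
          if (is.finite(ti) && ti < tmax - 1e-12) {
            tmax <- ti; leave <- i; leave_to <- 2L
          }
        }
      }
      if (!is.finite(tmax)) {
        return(list(status = "unbounded"))
      }
      tmax <- max(tmax, 0)
      if (tmax <= 1e-12) {
        repeat_count <- repeat_count + 1L
        if (repeat_count > m + n) bland <- TRUE   # degeneracy guard
      } else {
        repeat_count <- 0L
      }
      if (leave == 0L) {
        stat[jv] <- if (up) 2L else 1L            # bound flip
      } else {
        stat[basis[leave]] <- leave_to
        basis[leave] <- jv
        stat[jv] <- 0L
      }
    }
    stop("LP iteration limit reached")
  }

  maxit <- 500L * (n + m + 2L)
  # phase 1: drive the artificial residuals to zero
  c1 <- c(rep(0, n), rep(-1, m))                  # maximize -(sum artificials)
  p1 <- run_phase(c1, basis, stat, maxit)
  if (p1$status != "optimal") {
    return(list(x = NULL, objective_value = NA_real_, status = "infeasible"))
  }
  if (sum(p1$x[n + seq_len(m)]) > 1e-7) {
    return(list(x = NULL, objective_value = NA_real_, status = "infeasible"))
  }
  # phase 2: pin artificials at zero and optimize the user objective
  ubf <- c(ub, rep(0, m))
  p2 <- run_phase(c(cc, rep(0, m)), p1$basis, p1$stat, maxit)
  if (p2$status == "unbounded") {
    return(list(x = NULL, objective_value = NA_real_, status = "unbounded"))
  }
  x <- p2$x[seq_len(n)]
  list(x = x, objective_value = sum(obj * x), status = "optimal")
}
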