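#' Bounded-variable linear programming by revised two-phase simplex
#'
#' Solves `max (or min) c'x` subject to `A x = b` and `l <= x <= u`, and
#' returns the optimal basis duals and reduced costs alongside the primal
#' solution. A dense two-phase primal simplex with bounded variables:
#' phase 1 drives signed artificial variables out of the basis, phase 2
#' optimizes the true objective. Pricing is Dantzig's rule with an automatic
#' switch to Bland's rule (anti-cycling, guaranteed finite) after a long
#' degenerate stall.
#'
#' The dual vector `y` solves `B' y = c_B` for the final basis `B`;
#' reduced costs are `d = c - A' y` (zero on basic variables up to
#' round-off). For a maximization, `d_j > 0` at a nonbasic variable means
#' relaxing its active bound upward increases the optimum.
#'
#' @param cvec objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lower,upper variable bounds (finite or infinite).
#' @param maximize logical.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter iteration cap per phase.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x`, `value`, `duals` (length m) and `reduced_costs` (length n).
#' @keywords internal
lp_bounded <- function(cvec, A, b, lower, upper, maximize = TRUE,
                       tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == m,
            length(lower) == n, length(upper) == n)
  if (any(lower > upper + tol)) stop("inconsistent bounds")
  sgn <- if (maximize) 1 else -1

  # start structural variables at the finite bound closest to zero
  start_at <- ifelse(is.finite(lower) & is.finite(upper),
                     ifelse(abs(lower) <= abs(upper), lower, upper),
                     ifelse(is.finite(lower), lower,
                            ifelse(is.finite(upper), upper, 0)))
  r <- b - as.numeric(A %*% start_at)
  Afull <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))  # signed artificials
  lo <- c(lower, rep(0, m))
  hi <- c(upper, rep(Inf, m))
  state <- list(
    x = c(start_at, abs(r)),
    basis = n + seq_len(m),
    at_upper = c(is.finite(upper) & (start_at == upper) & (lower != upper),
                 rep(FALSE, m))
  )

  run_phase <- function(cphase, st) {
    ntot <- length(cphase)
    iter <- 0L; degen <- 0L; bland <- FALSE
    x <- st$x; basis <- st$basis; at_upper <- st$at_upper
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      Bmat <- Afull[, basis, drop = FALSE]
      y <- solve(t(Bmat), cphase[basis])
      d <- cphase - as.numeric(crossprod(Afull, y))
      is_basic <- logical(ntot); is_basic[basis] <- TRUE
      movable <- !is_basic & (hi - lo) > tol
      elig <- movable & ((!at_upper & d > tol) | (at_upper & d < -tol))
      if (!any(elig)) {
        return(list(x = x, basis = basis, at_upper = at_upper, y = y, d = d,
                    status = "optimal"))
      }
      cand <- which(elig)
      j <- if (bland) cand[1] else cand[which.max(abs(d[cand]))]
      dir <- if (at_upper[j]) -1 else 1
      w <- solve(Bmat, Afull[, j]) * dir   # decrease of basics per unit step
      ratios <- rep(Inf, m); to_upper <- logical(m)
      for (k in seq_len(m)) {
        bi <- basis[k]
        if (w[k] > tol) {
          ratios[k] <- max(0, (x[bi] - lo[bi]) / w[k])
        } else if (w[k] < -tol && is.finite(hi[bi])) {
          ratios[k] <- max(0, (hi[bi] - x[bi]) / (-w[k]))
          to_upper[k] <- TRUE
        }
      }
      t_flip <- hi[j] - lo[j]
      rmin <- min(ratios)
      if (!is.finite(rmin) && !is.finite(t_flip)) {
        return(list(x = x, basis = basis, at_upper = at_upper,
                    status = "unbounded"))
      }
      if (rmin < t_flip - tol) {
        tied <- which(ratios <= rmin + tol)
        leave <- tied[which.min(basis[tied])]   # smallest-index tie-break
        step <- rmin
      } else {
        leave <- 0L
        step <- t_flip
      }
      degen <- if (step < tol) degen + 1L else 0L
      if (degen > 2L * (m + ntot)) bland <- TRUE
      x[j] <- x[j] + dir * step
      x[basis] <- x[basis] - w * step
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]             # bound flip, basis unchanged
      } else {
        bi <- basis[leave]
        x[bi] <- if (to_upper[leave]) hi[bi] else lo[bi]  # snap exactly
        at_upper[bi] <- to_upper[leave]
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
    }
  }

  # phase 1: minimize the artificial infeasibility
  p1 <- run_phase(c(rep(0, n), rep(-1, m)), state)
  if (p1$status != "optimal") stop("phase 1 failed: ", p1$status)
  if (sum(p1$x[n + seq_len(m)]) > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                value = NA_real_, duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }
  hi <- c(upper, rep(0, m))                     # freeze artificials
  p2 <- run_phase(c(sgn * cvec, rep(0, m)), p1)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                value = NA_real_, duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }
  xs <- p2$x[seq_len(n)]
  list(status = "optimal",
       x = xs,
       value = sum(cvec * xs),
       duals = sgn * p2$y,
       reduced_costs = sgn * p2$d[seq_len(n)])
}
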