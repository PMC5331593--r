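# Bounded-variable two-phase simplex with dual extraction.
#
# Written because the individual diet models need both the optimal diet and
# the dual value (shadow price) of every constraint row; duals drive the
# binding-constraint diagnostics. The method is the textbook bounded-variable
# primal simplex: nonbasic variables rest at a finite lower (0) or upper
# bound, entering steps may terminate in a bound flip rather than a pivot.

#' Solve a linear program with bounded variables
#'
#' Minimizes (or maximizes) \code{obj \%*\% x} subject to
#' \code{A x (dir) rhs} and \code{0 <= x <= ub}. Duals are reported as
#' \code{d(objective)/d(rhs)} at the optimum, so for a minimization a binding
#' upper-bound row (\code{<=}) carries a non-positive dual and a binding
#' lower-bound row (\code{>=}) a non-negative one.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param dir character vector of row senses: \code{"<="}, \code{">="}, \code{"="}.
#' @param rhs right-hand sides (length m).
#' @param ub upper bounds on variables (default all \code{Inf}); lower bounds are 0.
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivot/reduced-cost tolerance.
#' @param max_iter iteration cap (default scales with problem size).
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{x}, \code{objective}, \code{duals} (one per row), \code{iterations}.
#'   Non-optimal statuses carry \code{x = NULL}.
#' @examples
#' # max x + y s.t. x + 2y <= 4, x <= 3
#' r <- lp_solve(c(1, 1), rbind(c(1, 2)), "<=", 4, ub = c(3, Inf), maximize = TRUE)
#' r$x  # c(3, 0.5)
#' @export
lp_solve <- function(obj, A, dir, rhs, ub = NULL, maximize = FALSE,
                     tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  if (is.null(ub)) ub <- rep(Inf, n)
  stopifnot(length(ub) == n, all(ub >= -tol))
  ub <- pmax(ub, 0)
  if (!all(dir %in% c("<=", ">=", "="))) stop("row senses must be <=, >= or =")
  obj_in <- if (maximize) -obj else obj

  # row scaling for numerical balance; duals are rescaled on the way out
  rsc <- apply(abs(A), 1, max)
  rsc[rsc < tol] <- 1
  A <- A / rsc
  rhs <- rhs / rsc

  # slack columns: + for <=, - for >= ; equalities get none
  n_slack <- sum(dir != "=")
  slack_of_row <- integer(m)
  S <- matrix(0, m, n_slack)
  k <- 0L
  for (i in seq_len(m)) {
    if (dir[i] == "=") next
    k <- k + 1L
    S[i, k] <- if (dir[i] == "<=") 1 else -1
    slack_of_row[i] <- n + k
  }

  # flip rows to make rhs non-negative, then append an identity of artificials
  sgn <- ifelse(rhs < 0, -1, 1)
  Aall <- cbind(A * sgn, S * sgn, diag(m))
  b <- rhs * sgn
  art <- n + n_slack + seq_len(m)
  ncols <- ncol(Aall)
  ubs <- c(ub, rep(Inf, n_slack), rep(Inf, m))

  basis <- art
  Tab <- Aall                       # B = I initially
  xB <- b
  at_ub <- rep(FALSE, ncols)        # nonbasic-at-upper-bound flags
  is_basic <- rep(FALSE, ncols); is_basic[basis] <- TRUE
  if (is.null(max_iter)) max_iter <- 200L * (m + n) + 2000L
  iter <- 0L
  degen_run <- 0L

  run_phase <- function(cc, allow_cols) {
    repeat {
      iter <<- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      d <- cc - as.vector(crossprod(Tab, cc[basis]))
      d[is_basic] <- 0
      cand_lo <- which(!is_basic & allow_cols & !at_ub & d < -tol)
      cand_up <- which(!is_basic & allow_cols & at_ub & d > tol)
      if (!length(cand_lo) && !length(cand_up)) return("optimal")
      use_bland <- degen_run > 2L * m + 10L
      if (use_bland) {
        j <- suppressWarnings(min(c(cand_lo, cand_up)))
      } else {
        best <- c(cand_lo[order(d[cand_lo])][1L], cand_up[order(-d[cand_up])][1L])
        best <- best[!is.na(best)]
        j <- best[which.max(abs(d[best]))]
      }
      s <- if (at_ub[j]) -1 else 1  # direction of change of x_j
      col <- Tab[, j]
      # ratio test: basic lower hits, basic upper hits, own opposite bound
      scol <- s * col
      t_vec <- rep(Inf, m)
      dn <- scol > tol
      t_vec[dn] <- xB[dn] / scol[dn]
      upfin <- scol < -tol & is.finite(ubs[basis])
      t_vec[upfin] <- (ubs[basis][upfin] - xB[upfin]) / (-scol[upfin])
      t_own <- ubs[j]
      t_star <- min(t_vec, t_own)
      if (!is.finite(t_star)) return("unbounded")
      degen_run <<- if (t_star < tol) degen_run + 1L else 0L
      if (is.finite(t_own) && t_own <= min(t_vec)) {
        # bound flip, no basis change
        xB <<- xB - scol * t_own
        at_ub[j] <<- !at_ub[j]
        next
      }
      ties <- which(t_vec <= t_star + tol)
      r <- if (use_bland) ties[which.min(basis[ties])] else ties[which.max(abs(col[ties]))]
      leave <- basis[r]
      x_new <- (if (at_ub[j]) ubs[j] else 0) + s * t_star
      xB <<- xB - scol * t_star
      # leaving variable parks at the bound it reached
      at_ub[leave] <<- scol[r] < 0
      at_ub[j] <<- FALSE
      piv <- Tab[r, j]
      Tab[r, ] <<- Tab[r, ] / piv
      other <- setdiff(seq_len(m), r)
      Tab[other, ] <<- Tab[other, ] - outer(Tab[other, j], Tab[r, ])
      xB[r] <<- x_new
      is_basic[leave] <<- FALSE
      is_basic[j] <<- TRUE
      basis[r] <<- j
    }
  }

  # phase 1: drive artificials to zero
  cc1 <- c(rep(0, n + n_slack), rep(1, m))
  st <- run_phase(cc1, allow_cols = rep(TRUE, ncols))
  p1 <- sum(xB[basis %in% art])
  if (st != "optimal" || p1 > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                duals = NULL, iterations = iter))
  }
  # pin artificials at zero for phase 2 (they may linger in the basis at 0)
  ubs[art] <- 0
  at_ub[art] <- FALSE

  cc2 <- c(obj_in, rep(0, n_slack), rep(0, m))
  allow <- rep(TRUE, ncols); allow[art] <- FALSE
  st <- run_phase(cc2, allow_cols = allow)
  if (st == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_,
                duals = NULL, iterations = iter))
  }

  x_full <- ifelse(at_ub, ubs, 0)
  x_full[basis] <- xB
  x <- x_full[seq_len(n)]
  zval <- sum(obj_in * x)
  # duals via B^{-1} read off the artificial columns
  y <- as.vector(crossprod(Tab[, art, drop = FALSE], cc2[basis]))
  duals <- y * sgn / rsc
  if (maximize) { zval <- -zval; duals <- -duals }
  list(status = "optimal", x = pmax(x, 0), objective = zval,
       duals = duals, iterations = iter)
}

#' Check a candidate solution against an LP's rows
#'
#' Utility used by tests and the optimizer to confirm that a solution
#' satisfies every row within tolerance (violations are scaled by row
#' magnitude, mirroring the solver's internal scaling).
#'
#' @param A,dir,rhs constraint system as in [lp_solve()].
#' @param x candidate solution.
#' @param tol allowed scaled violation.
#' @return logical vector, one entry per row (TRUE = satisfied).
#' @export
lp_row_satisfied <- function(A, dir, rhs, x, tol = 1e-8) {
  A <- as.matrix(A)
  lhs <- as.vector(A %*% x)
  sc <- pmax(apply(abs(A), 1, max) * max(abs(x), 1), 1)
  viol <- ifelse(dir == "<=", lhs - rhs,
          ifelse(dir == ">=", rhs - lhs, abs(lhs - rhs)))
  viol <= tol * sc
}
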