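#' Solve a bounded-variable linear program
#'
#' Solves `max (or min) c'x  subject to  A x = b,  lb <= x <= ub` with a dense
#' two-phase primal simplex supporting variable bounds directly (no slack
#' blow-up). This is the default backend behind [solve_fba()]; it is written
#' for the dense, small-to-medium models this package targets and returns the
#' full optimality certificate: primal solution, row duals and reduced costs.
#'
#' Sign conventions: duals `y` satisfy `y'A_B = c_B`; the reduced cost of
#' variable `j` is `d_j = c_j - y'A_j`. For a maximisation, a variable resting
#' at its lower bound has `d_j <= 0` and `d_j` equals the sensitivity of the
#' optimum to that lower bound (`d objective / d lb_j`), so relaxing the bound
#' downwards gains `|d_j|` per unit. Basic variables have reduced cost 0.
#'
#' @param A constraint matrix (m x n), dense or `Matrix` sparse.
#' @param b right-hand side vector (length m).
#' @param obj objective coefficient vector (length n).
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; `FALSE` minimises.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter simplex iteration cap.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objective`, `x` (primal), `y` (one dual per row),
#'   `reduced_costs` (one per column).
#' @keywords internal
#' @export
lp_solve_bounded <- function(A, b, obj, lb, ub, maximize = TRUE,
                             tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  ## --- set up phase 1 with one artificial per row -------------------------
  x <- numeric(n + m)
  status <- character(n + m)
  for (j in seq_len(n)) {
    if (lb[j] == ub[j]) { status[j] <- "fixed"; x[j] <- lb[j] }
    else if (is.finite(lb[j]) && is.finite(ub[j])) {
      if (abs(lb[j]) <= abs(ub[j])) { status[j] <- "lb"; x[j] <- lb[j] }
      else { status[j] <- "ub"; x[j] <- ub[j] }
    } else if (is.finite(lb[j])) { status[j] <- "lb"; x[j] <- lb[j] }
    else if (is.finite(ub[j])) { status[j] <- "ub"; x[j] <- ub[j] }
    else { status[j] <- "free"; x[j] <- 0 }
  }
  r <- as.numeric(b) - as.numeric(A %*% x[seq_len(n)])
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m, ncol = m))
  LB <- c(as.numeric(lb), rep(0, m))
  UB <- c(as.numeric(ub), rep(Inf, m))
  x[n + seq_len(m)] <- abs(r)
  status[n + seq_len(m)] <- "basic"
  basis <- n + seq_len(m)

  solve_safe <- function(M, v) {
    out <- tryCatch(solve(M, v), error = function(e) NULL)
    if (is.null(out)) out <- tryCatch(qr.solve(M, v, tol = 1e-12),
                                      error = function(e) NULL)
    out
  }

  ## --- simplex core, shared by both phases --------------------------------
  run <- function(cost, basis, status, x, iter0 = 0L) {
    bland_after <- 50L * (n + m)
    iter <- iter0
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(status = "iteration_limit", basis = basis,
                    status_v = status, x = x, iter = iter))
      AB <- Afull[, basis, drop = FALSE]
      nb <- setdiff(seq_len(n + m), basis)
      rhs <- as.numeric(b) -
        if (length(nb)) as.numeric(Afull[, nb, drop = FALSE] %*% x[nb]) else 0
      xB <- solve_safe(AB, rhs)
      if (is.null(xB))
        return(list(status = "singular", basis = basis, status_v = status,
                    x = x, iter = iter))
      x[basis] <- xB
      y <- solve_safe(t(AB), cost[basis])
      if (is.null(y))
        return(list(status = "singular", basis = basis, status_v = status,
                    x = x, iter = iter))
      d <- cost - as.numeric(crossprod(Afull, y))
      d[basis] <- 0
      ## entering variable
      dirs <- numeric(n + m); viol <- numeric(n + m)
      for (j in nb) {
        if (status[j] == "fixed") next
        if (status[j] == "lb" && d[j] > tol) { dirs[j] <- 1; viol[j] <- d[j] }
        else if (status[j] == "ub" && d[j] < -tol) { dirs[j] <- -1; viol[j] <- -d[j] }
        else if (status[j] == "free" && abs(d[j]) > tol) {
          dirs[j] <- sign(d[j]); viol[j] <- abs(d[j])
        }
      }
      if (!any(viol > 0))
        return(list(status = "optimal", basis = basis, status_v = status,
                    x = x, y = y, d = d, iter = iter))
      enter <- if (iter > bland_after) which(viol > 0)[1L] else which.max(viol)
      dir <- dirs[enter]
      w <- solve_safe(AB, Afull[, enter])
      if (is.null(w))
        return(list(status = "singular", basis = basis, status_v = status,
                    x = x, iter = iter))
      step_b <- -dir * w                     # movement of basics per unit step
      tmax <- if (is.finite(LB[enter]) && is.finite(UB[enter]))
        UB[enter] - LB[enter] else Inf
      leave <- 0L; leave_to <- NA_character_; piv <- 0
      for (i in seq_len(m)) {
        bi <- basis[i]; si <- step_b[i]
        lim <- Inf; to <- NA_character_
        if (si > tol) { lim <- (UB[bi] - x[bi]) / si; to <- "ub" }
        else if (si < -tol) { lim <- (x[bi] - LB[bi]) / (-si); to <- "lb" }
        else next
        if (lim < 0) lim <- 0
        better <- lim < tmax - 1e-12 ||
          (lim < tmax + 1e-12 && leave > 0L && abs(si) > abs(piv) &&
             iter <= bland_after)
        if (better) { tmax <- lim; leave <- i; leave_to <- to; piv <- si }
      }
      if (!is.finite(tmax))
        return(list(status = "unbounded", basis = basis, status_v = status,
                    x = x, iter = iter))
      x[enter] <- x[enter] + dir * tmax
      x[basis] <- x[basis] + step_b * tmax
      if (leave == 0L) {                      # bound flip, basis unchanged
        status[enter] <- if (dir > 0) "ub" else "lb"
        x[enter] <- if (dir > 0) UB[enter] else LB[enter]
      } else {
        out <- basis[leave]
        x[out] <- if (leave_to == "ub") UB[out] else LB[out]
        status[out] <- if (LB[out] == UB[out]) "fixed" else leave_to
        basis[leave] <- enter
        status[enter] <- "basic"
      }
    }
  }

  ## --- phase 1: drive artificials to zero ---------------------------------
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run(c1, basis, status, x)
  if (p1$status %in% c("iteration_limit", "singular"))
    return(list(status = p1$status, objective = NA_real_, x = rep(NA_real_, n),
                y = rep(NA_real_, m), reduced_costs = rep(NA_real_, n)))
  infeas <- sum(p1$x[n + seq_len(m)])
  if (infeas > 1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))

  ## --- phase 2: real objective, artificials pinned at zero ----------------
  LB[n + seq_len(m)] <- 0; UB[n + seq_len(m)] <- 0
  status <- p1$status_v; x <- p1$x
  art_nb <- setdiff(n + seq_len(m), p1$basis)
  status[art_nb] <- "fixed"; x[art_nb] <- 0
  c2 <- c(cc, rep(0, m))
  p2 <- run(c2, p1$basis, status, x, iter0 = 0L)
  if (p2$status %in% c("iteration_limit", "singular", "unbounded"))
    return(list(status = if (p2$status == "singular") "iteration_limit" else p2$status,
                objective = NA_real_, x = rep(NA_real_, n),
                y = rep(NA_real_, m), reduced_costs = rep(NA_real_, n)))

  xs <- p2$x[seq_len(n)]
  objv <- sum(cc * xs)
  y <- as.numeric(p2$y); d <- as.numeric(p2$d[seq_len(n)])
  if (!maximize) { objv <- -objv; y <- -y; d <- -d }
  list(status = "optimal", objective = objv, x = xs, y = y,
       reduced_costs = d, iterations = p2$iter)
}
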