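#' Optimizer and tuning settings for ability estimation
#'
#' Controls the damped Newton-Raphson search shared by all estimators,
#' the grid multi-start fallback used when Newton fails, the MAP prior
#' box, and the type-weighted (TWLE) tuning loop.
#'
#' @param tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations per start.
#' @param init Starting ability vector; `NULL` means the zero vector
#'   (forms are centred in the intended designs).
#' @param map_lower,map_upper Bounds of the uniform MAP prior box,
#'   applied per dimension. Defaults `[-4, 4]`.
#' @param hard_lower,hard_upper Numerical safety box for the unbounded
#'   estimators; wide enough that any finite maximiser of a
#'   non-degenerate pattern lies inside it.
#' @param grid_by Spacing of the coarse multi-start grid.
#' @param grid_range Half-width of the multi-start grid around zero.
#' @param twle_epsilon Initial ratio-parameter value used when the
#'   dichotomous block carries at least as much information as the
#'   polytomous block (`epsilon < 0.4` recommended).
#' @param twle_increment Step by which the ratio parameter `alpha` is
#'   raised while tuning.
#' @param twle_max_rounds Cap on tuning iterations.
#' @return A list of class `est_control`.
#' @export
est_control <- function(tol = 1e-6, max_iter = 100L, init = NULL,
                        map_lower = -4, map_upper = 4,
                        hard_lower = -20, hard_upper = 20,
                        grid_by = 0.5, grid_range = 15,
                        twle_epsilon = 0.35, twle_increment = 0.05,
                        twle_max_rounds = 100L) {
  stopifnot(tol > 0, max_iter >= 1L, map_lower < map_upper,
            hard_lower < hard_upper, grid_by > 0, grid_range > 0,
            twle_epsilon > 0, twle_increment > 0, twle_max_rounds >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter), init = init,
                 map_lower = map_lower, map_upper = map_upper,
                 hard_lower = hard_lower, hard_upper = hard_upper,
                 grid_by = grid_by, grid_range = grid_range,
                 twle_epsilon = twle_epsilon,
                 twle_increment = twle_increment,
                 twle_max_rounds = as.integer(twle_max_rounds)),
            class = "est_control")
}

.proj_box <- function(theta, lower, upper) pmin(pmax(theta, lower), upper)

# gradient with components pointing out of the box zeroed
.proj_grad <- function(g, theta, lower, upper) {
  g[theta <= lower & g < 0] <- 0
  g[theta >= upper & g > 0] <- 0
  g
}

# central-difference Hessian from an analytic gradient (TWLE objective)
.fd_hess <- function(obj, theta, h = 1e-4) {
  d <- length(theta)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- h
    gp <- obj(theta + e, deriv = TRUE)$grad
    gm <- obj(theta - e, deriv = TRUE)$grad
    H[, j] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

# damped (projected) Newton ascent of obj(theta)$value
.newton_box <- function(obj, init, lower, upper, tol, max_iter) {
  theta <- .proj_box(init, lower, upper)
  cur <- obj(theta, deriv = TRUE)
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    g <- .proj_grad(cur$grad, theta, lower, upper)
    gnorm <- sqrt(sum(g^2))
    if (is.finite(gnorm) && gnorm <= tol)
      return(list(theta = theta, value = cur$value, converged = TRUE,
                  n_iter = it - 1L, gnorm = gnorm))
    H <- cur$hess
    if (is.null(H)) H <- .fd_hess(obj, theta)
    step <- tryCatch(solve(H, -cur$grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)) || sum(step * g) <= 0) {
      sc <- max(abs(diag(H)), 1)
      step <- g / sc
    }
    # backtrack until the objective does not decrease
    tfac <- 1
    cand <- theta
    repeat {
      cand <- .proj_box(theta + tfac * step, lower, upper)
      cv <- obj(cand, deriv = FALSE)$value
      if (is.finite(cv) && cv >= cur$value - 1e-12) break
      tfac <- tfac / 2
      if (tfac < 1e-8) { cand <- theta; break }
    }
    if (all(cand == theta) && gnorm > tol) break
    theta <- cand
    cur <- obj(theta, deriv = TRUE)
  }
  list(theta = theta, value = cur$value, converged = FALSE,
       n_iter = max_iter, gnorm = gnorm)
}

# value-only evaluation over a coarse grid; ties broken toward the
# smallest theta1, then smallest theta2 (rows are generated in that order)
.grid_best <- function(obj, dim, lower, upper, by) {
  g1 <- seq(max(lower[1L], -Inf), upper[1L], by = by)
  if (dim == 1L) {
    vals <- vapply(g1, function(t) obj(t, deriv = FALSE)$value, numeric(1))
    return(g1[which.max(vals)])
  }
  g2 <- seq(lower[min(2L, length(lower))], upper[min(2L, length(upper))], by = by)
  grid <- expand.grid(t2 = g2, t1 = g1)   # t1 varies slowest -> row order (t1, t2)
  grid <- grid[order(grid$t1, grid$t2), ]
  vals <- apply(grid, 1L, function(r) obj(c(r[["t1"]], r[["t2"]]),
                                          deriv = FALSE)$value)
  best <- which.max(vals)
  c(grid$t1[best], grid$t2[best])
}

# Newton with a multi-start grid fallback; returns theta/converged/etc.
.maximize <- function(obj, dim, control, lower = NULL, upper = NULL) {
  if (is.null(lower)) lower <- rep(control$hard_lower, dim)
  if (is.null(upper)) upper <- rep(control$hard_upper, dim)
  init <- control$init
  if (is.null(init)) init <- rep(0, dim)
  stopifnot(length(init) == dim)
  fit <- .newton_box(obj, init, lower, upper, control$tol, control$max_iter)
  if (fit$converged) return(fit)
  glo <- pmax(lower, -control$grid_range)
  ghi <- pmin(upper, control$grid_range)
  start2 <- .grid_best(obj, dim, glo, ghi, control$grid_by)
  fit2 <- .newton_box(obj, start2, lower, upper, control$tol, control$max_iter)
  if (fit2$converged || fit2$value >= fit$value) {
    fit2$n_iter <- fit2$n_iter + fit$n_iter
    return(fit2)
  }
  fit
}
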