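# Vectorised likelihood and information machinery shared by the
# estimators.  Everything works on the canonical item order of a
# test_form; `theta` is length 1 (unidimensional) or 2 (longitudinal),
# and per-item quantities are derivatives with respect to the item's own
# effective ability t_i = theta1 + occ2_i * theta2.

# effective ability per item
.eff_theta <- function(form, theta) {
  t2 <- if (length(theta) > 1L) theta[[2L]] else 0
  theta[[1L]] + t2 * form$occ2
}

# per-item log-likelihood and its first two derivatives w.r.t. t_i
.ll_parts <- function(form, resp, theta) {
  t_all <- .eff_theta(form, theta)
  l <- d1 <- d2 <- numeric(form$n)

  if (length(form$d_idx)) {
    x <- form$d_a * (t_all[form$d_idx] - form$d_b)
    u <- resp[form$d_idx]
    # log-scale logistic keeps extreme patterns finite (no hard clamp needed)
    lp1 <- stats::plogis(x, log.p = TRUE)
    lp0 <- stats::plogis(-x, log.p = TRUE)
    p <- stats::plogis(x)
    l[form$d_idx] <- u * lp1 + (1 - u) * lp0
    d1[form$d_idx] <- form$d_a * (u - p)
    d2[form$d_idx] <- -form$d_a^2 * p * (1 - p)
  }

  np <- length(form$p_idx)
  if (np) {
    mom <- .poly_moments(form, t_all[form$p_idx])
    j_obs <- resp[form$p_idx]
    l[form$p_idx] <- mom$Z[cbind(seq_len(np), j_obs)] - mom$mx - log(mom$S)
    d1[form$p_idx] <- j_obs - mom$mu
    d2[form$p_idx] <- -mom$var
  }
  list(l = l, d1 = d1, d2 = d2)
}

# category-score moments for all polytomous items at effective abilities tp;
# order = 4 additionally returns the third and fourth central moments
# (needed for information derivatives only)
.poly_moments <- function(form, tp, order = 2L) {
  hmax <- ncol(form$p_cumb)
  js <- seq_len(hmax)
  Z <- tp %o% js - form$p_cumb          # NA beyond each item's h
  mx <- Z[, 1L]
  if (hmax > 1L) for (j in 2:hmax) mx <- pmax(mx, Z[, j], na.rm = TRUE)
  E <- exp(Z - mx)
  E[is.na(E)] <- 0
  S <- rowSums(E)
  P <- E / S
  mu <- as.vector(P %*% js)
  m2 <- as.vector(P %*% js^2)
  v <- pmax(m2 - mu^2, 0)
  out <- list(Z = Z, mx = mx, S = S, P = P, mu = mu, var = v)
  if (order >= 4L) {
    m3 <- as.vector(P %*% js^3)
    m4 <- as.vector(P %*% js^4)
    out$mu3 <- m3 - 3 * mu * m2 + 2 * mu^3
    out$mu4 <- m4 - 4 * mu * m3 + 6 * mu^2 * m2 - 3 * mu^4
  }
  out
}

# per-item information and its first two derivatives w.r.t. t_i
.info_parts <- function(form, theta, deriv = FALSE) {
  t_all <- .eff_theta(form, theta)
  info <- dI <- d2I <- numeric(form$n)

  if (length(form$d_idx)) {
    a <- form$d_a
    p <- stats::plogis(a * (t_all[form$d_idx] - form$d_b))
    pq <- p * (1 - p)
    info[form$d_idx] <- a^2 * pq
    if (deriv) {
      dI[form$d_idx] <- a^3 * pq * (1 - 2 * p)
      d2I[form$d_idx] <- a^4 * pq * (1 - 6 * pq)
    }
  }
  if (length(form$p_idx)) {
    mom <- .poly_moments(form, t_all[form$p_idx],
                         order = if (deriv) 4L else 2L)
    info[form$p_idx] <- mom$var
    if (deriv) {
      dI[form$p_idx] <- mom$mu3
      d2I[form$p_idx] <- mom$mu4 - 3 * mom$var^2
    }
  }
  if (deriv) list(info = info, dI = dI, d2I = d2I) else list(info = info)
}

# map a per-item derivative vector to the gradient in theta space
.theta_grad <- function(form, x, dim) {
  if (dim == 1L) sum(x) else c(sum(x), sum(x * form$occ2))
}

.theta_hess <- function(form, x, dim) {
  if (dim == 1L) return(matrix(sum(x), 1L, 1L))
  hpost <- sum(x * form$occ2)
  matrix(c(sum(x), hpost, hpost, hpost), 2L, 2L)
}

# (weighted) log-likelihood objective: value, gradient, hessian
.ll_eval <- function(form, resp, theta, weights = NULL, deriv = TRUE) {
  w <- if (is.null(weights)) rep(1, form$n) else weights
  parts <- .ll_parts(form, resp, theta)
  val <- sum(w * parts$l)
  if (!deriv) return(list(value = val))
  dim <- length(theta)
  list(value = val,
       grad = .theta_grad(form, w * parts$d1, dim),
       hess = .theta_hess(form, w * parts$d2, dim))
}

# scalar test information: value, gradient, hessian in theta space
.test_info_eval <- function(form, theta, deriv = TRUE) {
  ip <- .info_parts(form, theta, deriv = deriv)
  val <- sum(ip$info)
  if (!deriv) return(list(value = val))
  dim <- length(theta)
  list(value = val,
       grad = .theta_grad(form, ip$dI, dim),
       hess = .theta_hess(form, ip$d2I, dim))
}

#' Log-likelihood of a response pattern
#'
#' Sum over items of the log probability of the observed response, each
#' item evaluated at its occasion's effective ability; the product of
#' the dichotomous and polytomous blocks under local independence.  With
#' `weights`, each item's term is multiplied by its weight (the
#' item-weighted log-likelihood).
#'
#' @param form A [test_form()].
#' @param responses Integer response vector in canonical form order.
#' @param ability Ability vector matching the regime.
#' @param weights Optional per-item weight vector (canonical order).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(form, responses, ability, weights = NULL) {
  stopifnot(inherits(form, "test_form"))
  .check_ability(form, ability)
  resp <- .check_responses(form, responses)
  if (!is.null(weights)) stopifnot(length(weights) == form$n, all(weights > 0))
  .ll_eval(form, resp, ability, weights = weights, deriv = FALSE)$value
}
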