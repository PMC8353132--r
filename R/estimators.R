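#' Detect degenerate (all-extreme) response patterns
#'
#' A block of responses is all-extreme when every dichotomous response
#' is correct and every polytomous response is in the top category, or
#' every dichotomous response is incorrect and every polytomous response
#' is in the bottom category.  For such blocks the likelihood is
#' monotone and Newton-Raphson cannot converge, so the likelihood-based
#' estimators are undefined; simulation runs exclude these patterns from
#' analysis.
#'
#' In the longitudinal regime the check is applied per occasion: the
#' initial ability is identified by the pretest block and the growth
#' dimension by the posttest block, so the two-dimensional maximiser is
#' finite only if *both* occasion blocks have an interior total score
#' (an all-extreme pretest alone sends `theta1` to infinity along a
#' likelihood ridge, however mixed the posttest is).  Unidimensional
#' forms are a single block.  Blocks containing a single item type apply
#' the condition to the responses that are present.
#'
#' @param form A [test_form()].
#' @param responses Integer vector, or matrix (examinees x items).
#' @return Logical scalar (vector input) or vector (matrix input).
#' @export
detect_degenerate <- function(form, responses) {
  stopifnot(inherits(form, "test_form"))
  if (is.matrix(responses))
    return(apply(responses, 1L, function(r) detect_degenerate(form, r)))
  resp <- .check_responses(form, responses)
  block_extreme <- function(occ2) {
    u <- resp[form$d_idx[form$d_occ2 == occ2]]
    hb <- form$p_h[form$p_occ2 == occ2]
    v <- resp[form$p_idx[form$p_occ2 == occ2]]
    if (!length(u) && !length(v)) return(FALSE)
    all_top <- (!length(u) || all(u == 1L)) && (!length(v) || all(v == hb))
    all_bottom <- (!length(u) || all(u == 0L)) && (!length(v) || all(v == 1L))
    all_top || all_bottom
  }
  if (form$regime == "longitudinal")
    block_extreme(0) || block_extreme(1)
  else block_extreme(0)
}

#' Information-share item weights
#'
#' The weight of item `i` at ability `theta` is its information share
#' `I_i(theta) / I(theta)`, each item evaluated at its own occasion's
#' effective ability.  Weights are positive and sum to one; polytomous
#' items, carrying more information over most of the scale, receive
#' larger weights than dichotomous items.
#'
#' @param form A [test_form()].
#' @param ability Ability vector matching the regime (for the
#'   item-weighted estimator this is the maximum likelihood estimate).
#' @return Named numeric weight vector in canonical item order.
#' @export
item_weights <- function(form, ability) {
  stopifnot(inherits(form, "test_form"))
  .check_ability(form, ability)
  info <- .info_parts(form, ability)$info
  total <- sum(info)
  if (!is.finite(total) || total <= 0)
    stop("total test information is zero at this ability; ",
         "item weights are undefined", call. = FALSE)
  stats::setNames(info / total, form$items$item_id)
}

#' Warm's likelihood weight
#'
#' The square root of the scalar test information, the weight function
#' multiplying the likelihood in Warm's weighted likelihood estimator
#' for one- and two-parameter models.
#'
#' @inheritParams item_weights
#' @return Positive scalar.
#' @export
warm_weight <- function(form, ability) sqrt(test_information(form, ability))

.empty_result <- function(estimator, dim, degenerate = FALSE) {
  structure(list(estimator = estimator, theta1 = NA_real_,
                 theta2 = if (dim == 2L) NA_real_ else NA_real_,
                 converged = FALSE, n_iter = 0L, gradient_norm = NA_real_,
                 value = NA_real_, degenerate = degenerate,
                 alpha = NA_real_, beta = NA_real_, weights = NULL),
            class = "ability_estimate")
}

.make_result <- function(estimator, fit, dim, degenerate = FALSE) {
  structure(list(estimator = estimator,
                 theta1 = fit$theta[[1L]],
                 theta2 = if (dim == 2L) fit$theta[[2L]] else NA_real_,
                 converged = fit$converged, n_iter = fit$n_iter,
                 gradient_norm = fit$gnorm, value = fit$value,
                 degenerate = degenerate,
                 alpha = NA_real_, beta = NA_real_, weights = NULL),
            class = "ability_estimate")
}

#' @export
print.ability_estimate <- function(x, ...) {
  cat("<ability_estimate> ", toupper(x$estimator), "\n", sep = "")
  if (x$degenerate && is.na(x$theta1)) {
    cat("  degenerate (all-extreme) pattern: no finite estimate\n")
    return(invisible(x))
  }
  cat("  theta1 =", format(x$theta1, digits = 4))
  if (!is.na(x$theta2)) cat("  theta2 =", format(x$theta2, digits = 4))
  cat("\n  converged =", x$converged, " iterations =", x$n_iter,
      " |grad| =", format(x$gradient_norm, digits = 3), "\n")
  if (!is.na(x$alpha))
    cat("  alpha =", x$alpha, " beta =", x$beta, "\n")
  invisible(x)
}

.fit_mle <- function(form, resp, control) {
  dim <- if (form$regime == "longitudinal") 2L else 1L
  obj <- function(theta, deriv = TRUE) .ll_eval(form, resp, theta, deriv = deriv)
  .make_result("mle", .maximize(obj, dim, control), dim)
}

.fit_map <- function(form, resp, control) {
  dim <- if (form$regime == "longitudinal") 2L else 1L
  obj <- function(theta, deriv = TRUE) .ll_eval(form, resp, theta, deriv = deriv)
  fit <- .maximize(obj, dim, control,
                   lower = rep(control$map_lower, dim),
                   upper = rep(control$map_upper, dim))
  .make_result("map", fit, dim)
}

.fit_wle <- function(form, resp, control) {
  dim <- if (form$regime == "longitudinal") 2L else 1L
  obj <- function(theta, deriv = TRUE) {
    ll <- .ll_eval(form, resp, theta, deriv = deriv)
    ti <- .test_info_eval(form, theta, deriv = deriv)
    if (!deriv) return(list(value = ll$value + 0.5 * log(ti$value)))
    list(value = ll$value + 0.5 * log(ti$value),
         grad = ll$grad + 0.5 * ti$grad / ti$value,
         hess = ll$hess + 0.5 * (ti$hess / ti$value -
                                   tcrossprod(ti$grad) / ti$value^2))
  }
  .make_result("wle", .maximize(obj, dim, control), dim)
}

.fit_iwle <- function(form, resp, control, mle_fit = NULL) {
  dim <- if (form$regime == "longitudinal") 2L else 1L
  if (is.null(mle_fit)) mle_fit <- .fit_mle(form, resp, control)
  if (!mle_fit$converged) {
    out <- .empty_result("iwle", dim)
    out$n_iter <- mle_fit$n_iter
    return(out)
  }
  theta_mle <- c(mle_fit$theta1, if (dim == 2L) mle_fit$theta2)
  w <- item_weights(form, theta_mle)
  obj <- function(theta, deriv = TRUE)
    .ll_eval(form, resp, theta, weights = w, deriv = deriv)
  res <- .make_result("iwle", .maximize(obj, dim, control), dim)
  res$weights <- w
  res
}

# block information (dichotomous vs polytomous) and the tuned type weights
.type_weights <- function(form, theta, alpha, beta) {
  info <- .info_parts(form, theta)$info
  Id <- sum(info[form$is_dich])
  Ip <- sum(info[!form$is_dich])
  I <- Id + Ip
  list(Id = Id, Ip = Ip, w1 = (Id / I)^alpha, w2 = (Ip / I)^beta)
}

.twle_obj <- function(form, resp, alpha, beta) {
  isd <- form$is_dich
  function(theta, deriv = TRUE) {
    parts <- .ll_parts(form, resp, theta)
    ip <- .info_parts(form, theta, deriv = deriv)
    lld <- sum(parts$l[isd]); llp <- sum(parts$l[!isd])
    Id <- sum(ip$info[isd]); Ip <- sum(ip$info[!isd]); I <- Id + Ip
    w1 <- (Id / I)^alpha; w2 <- (Ip / I)^beta
    val <- w1 * lld + w2 * llp
    if (!deriv) return(list(value = val))
    dim <- length(theta)
    gl_d <- .theta_grad(form, parts$d1 * isd, dim)
    gl_p <- .theta_grad(form, parts$d1 * (!isd), dim)
    gId <- .theta_grad(form, ip$dI * isd, dim)
    gIp <- .theta_grad(form, ip$dI * (!isd), dim)
    gI <- gId + gIp
    gw1 <- w1 * alpha * (gId / Id - gI / I)
    gw2 <- w2 * beta * (gIp / Ip - gI / I)
    # quasi-Hessian: exact likelihood curvature plus the rank-one
    # weight-gradient cross terms; the (small) second derivatives of the
    # type weights are dropped.  Convergence is still declared on the
    # exact analytic gradient, so the maximiser is unaffected.
    Hl_d <- .theta_hess(form, parts$d2 * isd, dim)
    Hl_p <- .theta_hess(form, parts$d2 * (!isd), dim)
    H <- w1 * Hl_d + w2 * Hl_p +
      tcrossprod(gw1, gl_d) + tcrossprod(gl_d, gw1) +
      tcrossprod(gw2, gl_p) + tcrossprod(gl_p, gw2)
    list(value = val,
         grad = gw1 * lld + w1 * gl_d + gw2 * llp + w2 * gl_p,
         hess = H)
  }
}

.fit_twle <- function(form, resp, control, mle_fit = NULL) {
  if (!length(form$d_idx) || !length(form$p_idx))
    stop("the type-weighted estimator needs both dichotomous and ",
         "polytomous items", call. = FALSE)
  dim <- if (form$regime == "longitudinal") 2L else 1L
  if (is.null(mle_fit)) mle_fit <- .fit_mle(form, resp, control)
  if (!mle_fit$converged) {
    out <- .empty_result("twle", dim)
    out$n_iter <- mle_fit$n_iter
    return(out)
  }
  theta0 <- c(mle_fit$theta1, if (dim == 2L) mle_fit$theta2)

  tw <- .type_weights(form, theta0, 1, 1)
  if (tw$Id < tw$Ip) {
    alpha <- beta <- 1
  } else {
    alpha <- beta <- control$twle_epsilon
  }
  rounds <- 0L
  # make the dichotomous-block weight the smaller one at the initial estimate
  repeat {
    tw <- .type_weights(form, theta0, alpha, beta)
    if (tw$w1 < tw$w2 || rounds >= control$twle_max_rounds) break
    alpha <- alpha + control$twle_increment
    rounds <- rounds + 1L
  }

  fit <- NULL
  tuned <- FALSE
  while (rounds <= control$twle_max_rounds) {
    fit <- .maximize(.twle_obj(form, resp, alpha, beta), dim, control)
    twh <- .type_weights(form, fit$theta, alpha, beta)
    if (twh$w1 < twh$w2) { tuned <- TRUE; break }
    alpha <- alpha + control$twle_increment
    rounds <- rounds + 1L
  }
  res <- .make_result("twle", fit, dim)
  res$alpha <- alpha
  res$beta <- beta
  if (!tuned) res$converged <- FALSE
  res
}

#' Estimate latent ability from a response pattern
#'
#' Maximises the estimator's objective by damped Newton-Raphson with an
#' analytic gradient (and Hessian where available), falling back to a
#' coarse multi-start grid when Newton does not converge.  Available
#' estimators:
#'
#' * `"mle"` — maximum likelihood.
#' * `"map"` — maximum a posteriori under a non-informative uniform
#'   prior on the box `[-4, 4]` per dimension; equals the MLE whenever
#'   the MLE is interior to the box, otherwise sits on the boundary.
#' * `"wle"` — Warm's weighted likelihood: maximises
#'   `log L + 0.5 * log I(theta)` with the scalar test information.
#' * `"twle"` — type-weighted likelihood: maximises
#'   `w1(theta) log L_d + w2(theta) log L_p` with
#'   `w1 = (I_d/I)^alpha`, `w2 = (I_p/I)^beta`; the ratio parameters are
#'   tuned in increments of `twle_increment` until the dichotomous-block
#'   weight is the smaller one at the estimate.
#' * `"iwle"` — item-weighted likelihood: computes the MLE, fixes each
#'   item's weight at its information share [item_weights()] evaluated
#'   at the MLE, and maximises the item-weighted log-likelihood.
#'
#' Degenerate (all-extreme) patterns yield no finite maximiser for the
#' likelihood-based estimators and are returned flagged, without an
#' estimate; MAP still returns its boundary solution.
#'
#' @param form A [test_form()].
#' @param responses Integer response vector in canonical form order.
#' @param method One of `"mle"`, `"map"`, `"wle"`, `"twle"`, `"iwle"`.
#' @param control An [est_control()].
#' @return An `ability_estimate`: estimates `theta1` (and `theta2` for
#'   longitudinal forms), convergence diagnostics, the `degenerate`
#'   flag, tuned `alpha`/`beta` (TWLE) and the weight vector (IWLE).
#' @examples
#' form <- test_form(bind_items(
#'   dichotomous_item("d1", b = -0.5, occasion = "pretest"),
#'   dichotomous_item("d2", b = 0.5, occasion = "pretest"),
#'   polytomous_item("p1", steps = c(-1.5, -0.5, 0.5, 1.5), occasion = "pretest"),
#'   dichotomous_item("d3", b = 0, occasion = "posttest"),
#'   polytomous_item("p2", steps = c(-1, 0, 1, 2), occasion = "posttest")
#' ), regime = "longitudinal")
#' set.seed(1)
#' resp <- drop(simulate_responses(form, c(0.5, 0.8)))
#' estimate_ability(form, resp, "iwle")
#' @export
estimate_ability <- function(form, responses,
                             method = c("mle", "map", "wle", "twle", "iwle"),
                             control = est_control()) {
  method <- match.arg(method)
  stopifnot(inherits(form, "test_form"), inherits(control, "est_control"))
  resp <- .check_responses(form, responses)
  dim <- if (form$regime == "longitudinal") 2L else 1L
  degen <- detect_degenerate(form, resp)
  if (degen && method != "map")
    return(.empty_result(method, dim, degenerate = TRUE))
  switch(method,
         mle = .fit_mle(form, resp, control),
         map = .fit_map(form, resp, control),
         wle = .fit_wle(form, resp, control),
         twle = .fit_twle(form, resp, control),
         iwle = .fit_iwle(form, resp, control))
}

# estimate one pattern with several methods, sharing the MLE solve
.estimate_pattern <- function(form, resp, methods, control) {
  mle_fit <- NULL
  if (any(methods %in% c("mle", "iwle", "twle")))
    mle_fit <- .fit_mle(form, resp, control)
  out <- vector("list", length(methods))
  names(out) <- methods
  for (m in methods) {
    out[[m]] <- switch(m,
      mle = mle_fit,
      map = .fit_map(form, resp, control),
      wle = .fit_wle(form, resp, control),
      iwle = .fit_iwle(form, resp, control, mle_fit = mle_fit),
      twle = .fit_twle(form, resp, control, mle_fit = mle_fit))
  }
  out
}

#' Score a response matrix with one or more estimators
#'
#' Applies each requested estimator to every row of a response matrix.
#' Degenerate (all-extreme) patterns are flagged and left unestimated
#' (except by MAP, which has a boundary solution).
#'
#' @param form A [test_form()].
#' @param responses Integer matrix, examinees x items.
#' @param methods Character vector of estimator names.
#' @param control An [est_control()].
#' @return A `data.frame` with one row per examinee x estimator:
#'   `examinee`, `estimator`, `theta1_hat`, `theta2_hat`, `converged`,
#'   `degenerate`, `n_iter`, `gradient_norm`, `alpha`, `beta`.
#' @export
score_responses <- function(form, responses,
                            methods = c("mle", "map", "wle", "twle", "iwle"),
                            control = est_control()) {
  stopifnot(inherits(form, "test_form"), is.matrix(responses))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- vector("list", nrow(responses) * length(methods))
  pos <- 0L
  for (ex in seq_len(nrow(responses))) {
    resp <- .check_responses(form, responses[ex, ])
    degen <- detect_degenerate(form, resp)
    fits <- if (degen) {
      dim <- if (form$regime == "longitudinal") 2L else 1L
      lapply(stats::setNames(methods, methods), function(m)
        if (m == "map") .fit_map(form, resp, control)
        else .empty_result(m, dim, degenerate = TRUE))
    } else {
      .estimate_pattern(form, resp, methods, control)
    }
    for (m in methods) {
      f <- fits[[m]]
      pos <- pos + 1L
      rows[[pos]] <- data.frame(
        examinee = ex, estimator = m,
        theta1_hat = f$theta1, theta2_hat = f$theta2,
        converged = f$converged, degenerate = f$degenerate || degen,
        n_iter = f$n_iter, gradient_norm = f$gradient_norm,
        alpha = f$alpha, beta = f$beta, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(pos)])
  rownames(out) <- NULL
  out
}
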