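#' Effective ability at a measurement occasion
#'
#' In the two-occasion longitudinal growth model, performance at the
#' pretest depends on the initial ability `theta1` alone, while posttest
#' performance depends on `theta1 + theta2`, where `theta2` is the
#' modifiability (growth) dimension.  Unidimensional abilities have no
#' posttest.
#'
#' @param ability Numeric vector: `c(theta1)` (unidimensional) or
#'   `c(theta1, theta2)` (longitudinal).
#' @param occasion `"pretest"` or `"posttest"`.
#' @return The scalar ability the item response model is evaluated at.
#' @examples
#' effective_theta(c(1.0, 0.8), "posttest")  # 1.8
#' effective_theta(c(-2.5, 1.0), "pretest")  # -2.5
#' @export
effective_theta <- function(ability, occasion = c("pretest", "posttest")) {
  occasion <- match.arg(occasion)
  stopifnot(is.numeric(ability), length(ability) %in% 1:2,
            all(is.finite(ability)))
  if (occasion == "pretest") return(ability[[1L]])
  if (length(ability) < 2L)
    stop("posttest occasion is invalid for a unidimensional ability: ",
         "no growth component theta2 is present", call. = FALSE)
  ability[[1L]] + ability[[2L]]
}

#' Correct-response probability for a dichotomous item
#'
#' Logistic in `a * (theta_eff - b)`; `a = 1` is the Rasch case.
#'
#' @param theta_eff Effective ability (see [effective_theta()]). Vectorised.
#' @param b Item difficulty.
#' @param a Item discrimination, positive. Default 1.
#' @return Probability in (0, 1).
#' @export
prob_dichotomous <- function(theta_eff, b, a = 1) {
  stopifnot(all(a > 0))
  stats::plogis(a * (theta_eff - b))
}

#' Category probabilities for a polytomous (partial credit) item
#'
#' Categories are scored `1..h` with one step parameter per category:
#' `P_j` is proportional to `exp(j * theta_eff - sum(steps[1:j]))`,
#' normalised over `j = 1..h`.  Computed with a max-shift on the
#' exponents so extreme abilities cannot overflow.
#'
#' Note the scoring convention: there is no category 0.  Users used to
#' Masters' 0..m parameterisation should map their scores up by one; the
#' information function is unaffected (it is a variance) and the first
#' step parameter only shifts all exponents jointly, so it cancels from
#' the probabilities.
#'
#' @param theta_eff Scalar effective ability.
#' @param steps Step-parameter vector `b_1..b_h`.
#' @return Probability vector of length `h`, summing to 1.
#' @export
prob_polytomous <- function(theta_eff, steps) {
  stopifnot(is.numeric(steps), length(steps) >= 2L, length(theta_eff) == 1L)
  z <- seq_along(steps) * theta_eff - cumsum(steps)
  e <- exp(z - max(z))
  e / sum(e)
}

.item_fields <- function(item) {
  if (is.data.frame(item)) {
    stopifnot(nrow(item) == 1L)
    kind <- item$kind
    if (kind == "dichotomous")
      return(list(kind = kind, b = item$b, a = if (is.na(item$a)) 1 else item$a))
    sc <- .step_columns(item)
    steps <- as.numeric(item[1L, sc])
    steps <- steps[!is.na(steps)]
    return(list(kind = kind, steps = steps))
  }
  stopifnot(is.list(item), !is.null(item$kind))
  item
}

#' Fisher information of a single item
#'
#' Dichotomous items contribute `a^2 * P * Q` (which is `P * Q` in the
#' Rasch case `a = 1`); polytomous items contribute the variance of the
#' category score, `sum(j^2 P_j) - (sum(j P_j))^2` with scores
#' `j = 1..h`.
#'
#' @param item A one-row item-bank `data.frame` or a list with fields
#'   `kind` and `b`/`a` or `steps`.
#' @param theta_eff Scalar effective ability.
#' @return Non-negative information value.
#' @export
item_information <- function(item, theta_eff) {
  it <- .item_fields(item)
  if (it$kind == "dichotomous") {
    a <- if (is.null(it$a)) 1 else it$a
    p <- prob_dichotomous(theta_eff, it$b, a)
    return(a^2 * p * (1 - p))
  }
  p <- prob_polytomous(theta_eff, it$steps)
  j <- seq_along(p)
  sum(j^2 * p) - sum(j * p)^2
}

#' Test information at an ability
#'
#' Scalar sum of [item_information()] over all items of the form, each
#' item evaluated at its own occasion's effective ability.
#'
#' @param form A [test_form()].
#' @param ability `c(theta1)` or `c(theta1, theta2)` matching the form's
#'   regime.
#' @return Non-negative scalar information.
#' @export
test_information <- function(form, ability) {
  stopifnot(inherits(form, "test_form"))
  .check_ability(form, ability)
  sum(.info_parts(form, ability)$info)
}

.check_ability <- function(form, ability) {
  want <- if (form$regime == "longitudinal") 2L else 1L
  if (!is.numeric(ability) || length(ability) != want ||
      !all(is.finite(ability)))
    stop(sprintf("'%s' forms need a finite ability vector of length %d",
                 form$regime, want), call. = FALSE)
  invisible(ability)
}

#' Simulate responses to a form
#'
#' Dichotomous responses are Bernoulli draws from the model probability;
#' polytomous responses are categorical draws over `1..h`.  Items are
#' drawn in canonical form order, so results are reproducible under
#' `set.seed()`.
#'
#' @param form A [test_form()].
#' @param ability True ability vector for the simulated examinee(s).
#' @param n Number of response patterns to draw.
#' @return Integer matrix `n x form$n` with item-id column names.
#' @export
simulate_responses <- function(form, ability, n = 1L) {
  stopifnot(inherits(form, "test_form"), n >= 1L)
  .check_ability(form, ability)
  t1 <- ability[[1L]]
  t2 <- if (length(ability) > 1L) ability[[2L]] else 0
  out <- matrix(NA_integer_, nrow = n, ncol = form$n,
                dimnames = list(NULL, form$items$item_id))
  for (pos in seq_len(form$n)) {
    t_eff <- t1 + t2 * form$occ2[pos]
    if (form$is_dich[pos]) {
      di <- match(pos, form$d_idx)
      p <- prob_dichotomous(t_eff, form$d_b[di], form$d_a[di])
      out[, pos] <- as.integer(stats::runif(n) < p)
    } else {
      pi <- match(pos, form$p_idx)
      h <- form$p_h[pi]
      p <- prob_polytomous(t_eff, form$p_steps[pi, seq_len(h)])
      out[, pos] <- findInterval(stats::runif(n), cumsum(p)[-h],
                                 left.open = TRUE) + 1L
    }
  }
  out
}

#' Simulate a single item response
#'
#' @param item One-row item-bank `data.frame` or field list (see
#'   [item_information()]), with an `occasion` field when longitudinal.
#' @param ability Ability vector; `theta2` is used when the item's
#'   occasion is `"posttest"`.
#' @return Integer response (0/1 or category 1..h).
#' @export
simulate_response <- function(item, ability) {
  occ <- if (is.data.frame(item) && !is.na(item$occasion)) item$occasion
         else if (is.list(item) && !is.null(item$occasion) &&
                  !is.na(item$occasion)) item$occasion
         else "pretest"
  t_eff <- effective_theta(ability, occ)
  it <- .item_fields(item)
  if (it$kind == "dichotomous") {
    a <- if (is.null(it$a)) 1 else it$a
    return(as.integer(stats::runif(1) < prob_dichotomous(t_eff, it$b, a)))
  }
  p <- prob_polytomous(t_eff, it$steps)
  findInterval(stats::runif(1), cumsum(p)[-length(p)], left.open = TRUE) + 1L
}
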