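test_that("degenerate patterns are those without a finite maximiser", {
  form <- toy_long_form()   # d1 d2 p1 | d3 d4 p2
  # all correct / top categories
  expect_true(detect_degenerate(form, c(1L, 1L, 4L, 1L, 1L, 4L)))
  # all incorrect / bottom categories
  expect_true(detect_degenerate(form, c(0L, 0L, 1L, 0L, 0L, 1L)))
  # interior response in each occasion block: estimable
  expect_false(detect_degenerate(form, c(1L, 0L, 4L, 1L, 1L, 2L)))
  # one occasion all-extreme still sends its dimension to infinity
  expect_true(detect_degenerate(form, c(0L, 0L, 1L, 1L, 0L, 2L)))
  expect_true(detect_degenerate(form, c(1L, 0L, 2L, 1L, 1L, 4L)))

  # unidimensional: the whole pattern is one block
  uni <- toy_uni_form()
  expect_true(detect_degenerate(uni, c(1L, 1L, 1L, 4L, 4L)))
  expect_true(detect_degenerate(uni, c(0L, 0L, 0L, 1L, 1L)))
  expect_false(detect_degenerate(uni, c(1L, 1L, 0L, 4L, 4L)))

  # matrix interface
  mat <- rbind(c(1L, 1L, 4L, 1L, 1L, 4L), c(1L, 0L, 4L, 1L, 1L, 2L))
  expect_identical(unname(detect_degenerate(form, mat)), c(TRUE, FALSE))

  # estimators refuse degenerate patterns, flagged without an estimate
  fit <- estimate_ability(form, c(1L, 1L, 4L, 1L, 1L, 4L), "mle")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$theta1))
})

test_that("equal-difficulty Rasch MLE equals the closed form log(r/(n-r))", {
  n <- 10
  form <- rasch_form(n, b = 0)
  for (r in c(2, 5, 7)) {
    resp <- c(rep(1L, r), rep(0L, n - r))
    fit <- estimate_ability(form, resp, "mle")
    expect_true(fit$converged)
    expect_equal(fit$theta1, log(r / (n - r)), tolerance = 1e-5)
  }
  # shifted difficulties translate the estimate
  form_b <- rasch_form(n, b = 0.8)
  fit_b <- estimate_ability(form_b, c(rep(1L, 3), rep(0L, 7)), "mle")
  expect_equal(fit_b$theta1, 0.8 + log(3 / 7), tolerance = 1e-5)
})

test_that("every estimator matches the dense-grid argmax of its objective", {
  form <- toy_uni_form()
  set.seed(31)
  patterns <- lapply(c(-2, 0, 1.5), function(t)
    drop(simulate_responses(form, t)))
  for (resp in patterns) {
    if (detect_degenerate(form, resp)) next
    mle_fit <- estimate_ability(form, resp, "mle")
    oracle_mle <- oracle_grid_argmax(function(t) oracle_loglik(form, resp, t))
    expect_equal(mle_fit$theta1, oracle_mle, tolerance = 0.005)

    wle_fit <- estimate_ability(form, resp, "wle")
    oracle_wle <- oracle_grid_argmax(function(t)
      oracle_loglik(form, resp, t) + 0.5 * log(oracle_test_info(form, t)))
    expect_equal(wle_fit$theta1, oracle_wle, tolerance = 0.005)

    map_fit <- estimate_ability(form, resp, "map")
    oracle_map <- oracle_grid_argmax(function(t) oracle_loglik(form, resp, t),
                                     lower = -4, upper = 4)
    expect_equal(map_fit$theta1, oracle_map, tolerance = 0.005)

    # IWLE: weights anchored at the grid-oracle MLE, objective re-derived
    info_i <- vapply(seq_len(form$n), function(i)
      oracle_item_info(form$items[i, ], oracle_mle), numeric(1))
    w <- info_i / sum(info_i)
    iwle_fit <- estimate_ability(form, resp, "iwle")
    oracle_iwle <- oracle_grid_argmax(function(t)
      oracle_loglik(form, resp, t, weights = w))
    expect_equal(iwle_fit$theta1, oracle_iwle, tolerance = 0.005)
    expect_equal(unname(iwle_fit$weights), w, tolerance = 1e-4)

    # TWLE: grid oracle for the tuned (alpha, beta) the estimator reports
    twle_fit <- estimate_ability(form, resp, "twle")
    isd <- form$is_dich
    oracle_twle <- oracle_grid_argmax(function(t) {
      ii <- vapply(seq_len(form$n), function(i)
        oracle_item_info(form$items[i, ], t), numeric(1))
      Id <- sum(ii[isd]); Ip <- sum(ii[!isd]); I <- Id + Ip
      lld <- oracle_loglik(form, resp, t, weights = as.numeric(isd))
      llp <- oracle_loglik(form, resp, t, weights = as.numeric(!isd))
      (Id / I)^twle_fit$alpha * lld + (Ip / I)^twle_fit$beta * llp
    })
    expect_equal(twle_fit$theta1, oracle_twle, tolerance = 0.005)
  }
})

test_that("the longitudinal MLE matches a 2-D grid argmax", {
  form <- toy_long_form()
  set.seed(32)
  resp <- drop(simulate_responses(form, c(0.5, 0.8)))
  fit <- estimate_ability(form, resp, "mle")
  grid1 <- seq(-3, 3, by = 0.01)
  best <- c(NA, NA); bestv <- -Inf
  for (t1 in grid1) {
    vals <- vapply(grid1, function(t2)
      oracle_loglik(form, resp, c(t1, t2)), numeric(1))
    i <- which.max(vals)
    if (vals[i] > bestv) { bestv <- vals[i]; best <- c(t1, grid1[i]) }
  }
  expect_equal(c(fit$theta1, fit$theta2), best, tolerance = 0.011)
})

test_that("MAP equals MLE inside the prior box and hits the boundary outside", {
  form <- toy_uni_form()
  set.seed(33)
  resp <- drop(simulate_responses(form, 0.5))
  mle_fit <- estimate_ability(form, resp, "mle")
  map_fit <- estimate_ability(form, resp, "map")
  expect_true(abs(mle_fit$theta1) < 4)
  expect_equal(map_fit$theta1, mle_fit$theta1, tolerance = 1e-6)

  # all-correct pattern: monotone likelihood, MAP sits at +4 per dimension
  long <- toy_long_form()
  map_ext <- estimate_ability(long, c(1L, 1L, 4L, 1L, 1L, 4L), "map")
  expect_equal(c(map_ext$theta1, map_ext$theta2), c(4, 4), tolerance = 1e-6)
})

test_that("IWLE reduces to MLE when all item weights are equal", {
  form <- rasch_form(6, b = 0.3)
  resp <- c(1L, 1L, 0L, 0L, 0L, 0L)
  mle_fit <- estimate_ability(form, resp, "mle")
  iwle_fit <- estimate_ability(form, resp, "iwle")
  expect_equal(unname(iwle_fit$weights), rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(iwle_fit$theta1, mle_fit$theta1, tolerance = 1e-6)
})

test_that("information-share weights normalise and favour polytomous items", {
  form <- toy_long_form()
  w <- item_weights(form, c(0.5, 0.8))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  # 2-item oracle: P*Q = 0.25 vs uniform 4-category variance 1.25
  two <- test_form(bind_items(
    dichotomous_item("d", b = 0), polytomous_item("p", steps = rep(0, 4))),
    regime = "unidimensional")
  expect_equal(unname(item_weights(two, 0)), c(0.25, 1.25) / 1.5,
               tolerance = 1e-10)
  set.seed(34)
  for (i in 1:20) {
    ab <- c(runif(1, -3, 3), runif(1, 0, 1.5))
    w <- item_weights(toy_long_form(), ab)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("Warm's weight is the root of the test information", {
  one <- test_form(bind_items(
    dichotomous_item("d", b = 0.3, occasion = "pretest"),
    dichotomous_item("far", b = 50, occasion = "posttest")), "longitudinal")
  expect_equal(warm_weight(one, c(0.3, 0)), 0.5, tolerance = 1e-6)
  # doubling every item multiplies the weight by sqrt(2)
  form <- toy_uni_form()
  doubled <- test_form(bind_items(
    form$items,
    transform(form$items, item_id = paste0(item_id, "_copy"))),
    regime = "unidimensional")
  expect_equal(warm_weight(doubled, 0.7), sqrt(2) * warm_weight(form, 0.7),
               tolerance = 1e-10)
})

test_that("WLE removes most of the outward MLE bias (Warm property)", {
  # In the Rasch model the raw score is sufficient, so the exact
  # sampling bias of each estimator follows from the Poisson-binomial
  # score distribution: no Monte-Carlo noise.
  b <- seq(-2, 2, length.out = 15)
  form <- test_form(do.call(bind_items, lapply(1:15, function(i)
    dichotomous_item(paste0("r", i), b = b[i]))), regime = "unidimensional")
  theta_by_score <- function(method) vapply(1:14, function(r)
    estimate_ability(form, c(rep(1L, r), rep(0L, 15 - r)), method)$theta1,
    numeric(1))
  th_mle <- theta_by_score("mle")
  th_wle <- theta_by_score("wle")
  for (theta_true in c(0.75, 1.5)) {
    p <- 1 / (1 + exp(-(theta_true - b)))
    pr <- 1                      # score distribution by convolution
    for (pi in p) pr <- c(pr * (1 - pi), 0) + c(0, pr * pi)
    w <- pr[2:15] / sum(pr[2:15])   # conditional on an interior score
    bias_mle <- sum(w * th_mle) - theta_true
    bias_wle <- sum(w * th_wle) - theta_true
    expect_lt(abs(bias_wle), abs(bias_mle))
    expect_gt(bias_mle, 0)          # MLE biased outward at positive theta
  }
})

test_that("TWLE tunes the type weights as specified", {
  # polytomous block dominant at the MLE: alpha = beta = 1
  poly_heavy <- test_form(bind_items(
    dichotomous_item("d1", b = 0, occasion = "pretest"),
    polytomous_item("p1", steps = c(-1.5, -0.5, 0.5, 1.5), occasion = "pretest"),
    polytomous_item("p2", steps = c(-1, 0, 1, 2), occasion = "pretest"),
    dichotomous_item("d2", b = 0, occasion = "posttest"),
    polytomous_item("p3", steps = c(-1.5, -0.5, 0.5, 1.5), occasion = "posttest"),
    polytomous_item("p4", steps = c(-1, 0, 1, 2), occasion = "posttest")
  ), regime = "longitudinal")
  set.seed(36)
  resp <- drop(simulate_responses(poly_heavy, c(0, 0.8)))
  fit <- estimate_ability(poly_heavy, resp, "twle")
  expect_equal(fit$alpha, 1)
  expect_equal(fit$beta, 1)

  # post-condition across random mixed forms: the tuned weights put less
  # mass on the dichotomous block at the returned estimate
  set.seed(37)
  for (i in 1:60) {
    d <- study_design()
    bank <- draw_item_bank(6, sample(2:4, 1), d)
    t1 <- runif(1, -2.5, 2.5)
    resp <- drop(simulate_responses(bank, c(t1, 0.8)))
    if (detect_degenerate(bank, resp)) next
    fit <- estimate_ability(bank, resp, "twle")
    if (!fit$converged) next
    theta_hat <- c(fit$theta1, fit$theta2)
    info_i <- vapply(seq_len(bank$n), function(j)
      oracle_item_info(bank$items[j, ],
                       theta_hat[1] + theta_hat[2] * bank$occ2[j]), numeric(1))
    Id <- sum(info_i[bank$is_dich]); Ip <- sum(info_i[!bank$is_dich])
    I <- Id + Ip
    expect_lt((Id / I)^fit$alpha, (Ip / I)^fit$beta)
  }

  # single-type forms are refused
  expect_error(estimate_ability(rasch_form(5), c(1L, 0L, 1L, 0L, 0L), "twle"),
               "both dichotomous and polytomous")
})

test_that("score_responses returns one row per examinee and estimator", {
  form <- toy_long_form()
  set.seed(38)
  resp <- simulate_responses(form, c(0.5, 0.8), n = 6)
  resp[1, ] <- c(1L, 1L, 4L, 1L, 1L, 4L)   # degenerate row
  scores <- score_responses(form, resp, methods = c("mle", "iwle", "map"))
  expect_equal(nrow(scores), 18L)
  expect_setequal(unique(scores$estimator), c("mle", "iwle", "map"))
  deg <- scores[scores$examinee == 1, ]
  expect_true(all(deg$degenerate))
  expect_true(all(is.na(deg$theta1_hat[deg$estimator != "map"])))
  # MAP still reports its boundary solution for the degenerate row
  expect_equal(deg$theta1_hat[deg$estimator == "map"], 4, tolerance = 1e-6)
  # the short toy form can throw further (per-occasion) degenerate rows;
  # every non-degenerate estimate must be finite and converged
  ok <- scores[!scores$degenerate, ]
  expect_gt(nrow(ok), 0L)
  expect_true(all(ok$converged))
  expect_true(all(is.finite(ok$theta1_hat)))
})
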