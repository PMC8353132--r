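#' Construct a dichotomous item
#'
#' One row of an item bank for a 0/1-scored item.  Under the Rasch
#' parameterisation the probability of a correct response is logistic in
#' `a * (theta - b)`; `a = 1` (the default) gives the Rasch model used by
#' the longitudinal regime, `a != 1` the two-parameter logistic model.
#'
#' @param item_id Label for the item (coerced to character).
#' @param b Difficulty parameter.
#' @param a Discrimination parameter, strictly positive. Default 1.
#' @param occasion `"pretest"`, `"posttest"`, or `NA` (unidimensional forms).
#' @return A one-row `data.frame` with the item-bank columns.
#' @seealso [polytomous_item()], [test_form()]
#' @export
dichotomous_item <- function(item_id, b, a = 1, occasion = NA_character_) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  data.frame(item_id = as.character(item_id), kind = "dichotomous",
             occasion = as.character(occasion), a = as.numeric(a),
             b = as.numeric(b), stringsAsFactors = FALSE)
}

#' Construct a polytomous (partial credit) item
#'
#' One row of an item bank for an item scored in categories `1..h`, with
#' `h` step parameters.  Category probabilities follow the adjacent-category
#' (partial credit) form: `P_j` is proportional to
#' `exp(j * theta - sum(steps[1:j]))`.
#'
#' @param item_id Label for the item.
#' @param steps Numeric vector of step parameters `b_1..b_h`, `h >= 2`.
#' @param occasion `"pretest"`, `"posttest"`, or `NA`.
#' @return A one-row `data.frame` with columns `b1..bh`.
#' @export
polytomous_item <- function(item_id, steps, occasion = NA_character_) {
  stopifnot(is.numeric(steps), length(steps) >= 2L, all(is.finite(steps)))
  row <- data.frame(item_id = as.character(item_id), kind = "polytomous",
                    occasion = as.character(occasion), a = NA_real_,
                    b = NA_real_, stringsAsFactors = FALSE)
  for (v in seq_along(steps)) row[[paste0("b", v)]] <- steps[[v]]
  row
}

#' Combine item rows into one bank
#'
#' `rbind` for item rows produced by [dichotomous_item()] and
#' [polytomous_item()], padding step columns so items with different
#' category counts can coexist in one bank.
#'
#' @param ... Item-bank data.frames (one or more rows each).
#' @return A single item-bank `data.frame`.
#' @export
bind_items <- function(...) {
  rows <- list(...)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  stopifnot(length(rows) > 0L)
  cols <- unique(unlist(lapply(rows, names)))
  # keep canonical column order: id/kind/occasion/a/b then b1, b2, ...
  fixed <- c("item_id", "kind", "occasion", "a", "b")
  steps <- sort(setdiff(cols, fixed))
  steps <- steps[order(as.integer(sub("^b", "", steps)))]
  cols <- c(fixed, steps)
  padded <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA_real_
    r[, cols, drop = FALSE]
  })
  out <- do.call(rbind, padded)
  rownames(out) <- NULL
  out
}

.step_columns <- function(items) {
  sc <- grep("^b[0-9]+$", names(items), value = TRUE)
  sc[order(as.integer(sub("^b", "", sc)))]
}

#' Assemble a test form
#'
#' Validates an item bank and fixes the canonical item layout used
#' throughout the package: pretest dichotomous items first (`1..k`), then
#' pretest polytomous (`k+1..n1`), posttest dichotomous (`n1+1..m`), and
#' posttest polytomous (`m+1..n`).  Unidimensional forms use only the
#' dichotomous/polytomous split (`k`, `n1 = m = n`) and ignore occasions.
#'
#' Longitudinal forms must contain at least one pretest and one posttest
#' item: the initial ability is identified by the pretest block and the
#' growth dimension only enters through the posttest block, so both blocks
#' are required for the two-dimensional estimation problem to be
#' well-posed.
#'
#' @param items Item-bank `data.frame` (see [dichotomous_item()],
#'   [polytomous_item()], [bind_items()], [read_item_bank()]).
#' @param regime `"longitudinal"` (two-occasion growth model) or
#'   `"unidimensional"`.
#' @return An object of class `test_form`.
#' @examples
#' form <- test_form(bind_items(
#'   dichotomous_item("d1", b = -1, occasion = "pretest"),
#'   polytomous_item("p1", steps = c(-1.5, -0.5, 0.5, 1.5), occasion = "pretest"),
#'   dichotomous_item("d2", b = 0.5, occasion = "posttest"),
#'   polytomous_item("p2", steps = c(-1, 0, 1, 2), occasion = "posttest")
#' ), regime = "longitudinal")
#' form
#' @export
test_form <- function(items, regime = c("longitudinal", "unidimensional")) {
  regime <- match.arg(regime)
  stopifnot(is.data.frame(items), nrow(items) >= 1L)
  required <- c("item_id", "kind", "occasion", "a", "b")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols))
    stop("item bank is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(items$kind %in% c("dichotomous", "polytomous")))
    stop("item kind must be 'dichotomous' or 'polytomous'", call. = FALSE)
  if (anyDuplicated(items$item_id))
    stop("duplicated item_id in bank", call. = FALSE)

  is_dich <- items$kind == "dichotomous"
  items$a[is_dich & is.na(items$a)] <- 1
  if (any(is_dich & (!is.finite(items$b) | items$a <= 0)))
    stop("dichotomous items need finite b and a > 0", call. = FALSE)

  step_cols <- .step_columns(items)
  steps <- as.matrix(items[, step_cols, drop = FALSE])
  storage.mode(steps) <- "double"
  h <- if (length(step_cols)) rowSums(!is.na(steps)) else rep(0L, nrow(items))
  if (any(!is_dich & h < 2))
    stop("polytomous items need at least 2 step parameters", call. = FALSE)
  # steps must be contiguous b1..bh
  for (i in which(!is_dich)) {
    if (any(is.na(steps[i, seq_len(h[i])])))
      stop("polytomous item '", items$item_id[i],
           "' has non-contiguous step parameters", call. = FALSE)
  }
  if (length(step_cols) && any(is_dich & rowSums(!is.na(steps)) > 0))
    stop("dichotomous items must not carry step parameters", call. = FALSE)

  if (regime == "longitudinal") {
    if (!all(items$occasion %in% c("pretest", "posttest")))
      stop("longitudinal items need occasion 'pretest' or 'posttest'",
           call. = FALSE)
    if (!any(items$occasion == "pretest") || !any(items$occasion == "posttest"))
      stop("longitudinal forms need items on both occasions", call. = FALSE)
    post <- items$occasion == "posttest"
  } else {
    post <- rep(FALSE, nrow(items))
    items$occasion <- NA_character_
  }

  ord <- order(post, !is_dich, seq_len(nrow(items)))
  items <- items[ord, , drop = FALSE]
  rownames(items) <- NULL
  post <- post[ord]
  is_dich <- is_dich[ord]
  steps <- steps[ord, , drop = FALSE]
  h <- h[ord]

  n <- nrow(items)
  k <- sum(!post & is_dich)
  n1 <- sum(!post)
  m <- n1 + sum(post & is_dich)

  p_idx <- which(!is_dich)
  p_steps <- steps[p_idx, , drop = FALSE]
  p_cumb <- if (length(p_idx)) t(apply(p_steps, 1L, cumsum)) else
    matrix(0, 0, max(1L, ncol(steps)))
  if (length(p_idx) == 1L) p_cumb <- matrix(p_cumb, nrow = 1L)

  structure(list(
    items = items, regime = regime,
    k = k, n1 = n1, m = m, n = n,
    is_dich = is_dich, occ2 = as.numeric(post),
    d_idx = which(is_dich), p_idx = p_idx,
    d_b = items$b[is_dich], d_a = items$a[is_dich],
    d_occ2 = as.numeric(post[is_dich]),
    p_steps = p_steps, p_cumb = p_cumb,
    p_h = as.integer(h[p_idx]), p_occ2 = as.numeric(post[p_idx])
  ), class = "test_form")
}

#' @export
print.test_form <- function(x, ...) {
  cat("<test_form> ", x$regime, ", ", x$n, " items\n", sep = "")
  cat("  layout: k=", x$k, " n1=", x$n1, " m=", x$m, " n=", x$n,
      "  (", sum(x$is_dich), " dichotomous, ", length(x$p_idx),
      " polytomous)\n", sep = "")
  invisible(x)
}

# responses: integer vector aligned with the canonical item order
.check_responses <- function(form, responses) {
  if (length(responses) != form$n)
    stop("response vector length ", length(responses),
         " does not match the ", form$n, "-item form", call. = FALSE)
  if (anyNA(responses))
    stop("missing responses are not supported in estimation", call. = FALSE)
  responses <- as.integer(responses)
  u <- responses[form$d_idx]
  if (length(u) && !all(u %in% c(0L, 1L)))
    stop("dichotomous responses must be 0/1", call. = FALSE)
  v <- responses[form$p_idx]
  if (length(v) && (any(v < 1L) || any(v > form$p_h)))
    stop("polytomous responses must lie in 1..h for each item", call. = FALSE)
  responses
}

#' Read an item bank from CSV
#'
#' Expected columns: `item_id`, `kind` (`dichotomous`/`polytomous`),
#' `occasion` (`pretest`/`posttest`, blank for unidimensional forms),
#' `a`, `b` (dichotomous only) and `b1..bh` (polytomous only); blank
#' cells where a column does not apply.
#'
#' @param path CSV file path.
#' @param regime Passed to [test_form()].
#' @return A `test_form`.
#' @export
read_item_bank <- function(path, regime = c("longitudinal", "unidimensional")) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(items$occasion)) items$occasion <- as.character(items$occasion)
  test_form(items, regime = match.arg(regime))
}

#' Write an item bank to CSV
#'
#' @param form A `test_form`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(form, path) {
  stopifnot(inherits(form, "test_form"))
  utils::write.csv(form$items, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a response matrix from CSV
#'
#' Rows are examinees, columns are items (header = item ids); codes are
#' 0/1 for dichotomous items and 1..h for polytomous items.  Columns are
#' reordered to match the form's canonical layout.
#'
#' @param path CSV file path.
#' @param form `test_form` the responses belong to.
#' @return Integer matrix, examinees x items.
#' @export
read_responses <- function(path, form) {
  stopifnot(inherits(form, "test_form"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- form$items$item_id
  missing_items <- setdiff(ids, names(df))
  if (length(missing_items))
    stop("response file lacks columns for items: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  mat <- as.matrix(df[, ids, drop = FALSE])
  storage.mode(mat) <- "integer"
  mat
}

#' Write a response matrix to CSV
#'
#' @param responses Integer matrix (examinees x items) with item-id columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}
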