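#' Assemble a complete feature matrix for modeling
#'
#' Takes the feature rows of one duration (one row per subject), drops
#' subjects flagged incomplete (missing wristband streams), drops feature
#' columns containing missing values (e.g. P300 features at truncations with
#' no usable rare epoch, or spectral bands empty at a coarse resolution) with
#' a message, and returns a modeling-ready tibble: `subject_id`, `fas`, then
#' feature columns only.
#'
#' @param features Tibble from [extract_features()]/[cohort_features()],
#'   restricted to a single duration (or any tibble with `subject_id`, `fas`,
#'   optional `incomplete`, and feature columns).
#' @return A `feature_matrix` tibble; attribute `feature_cols` holds the
#'   retained feature names, `excluded_subjects` the dropped ids.
#' @export
assemble_feature_matrix <- function(features) {
  if ("duration_s" %in% names(features) && length(unique(features$duration_s)) > 1) {
    abort("`features` mixes several durations; filter to one before assembling.")
  }
  if (anyDuplicated(names(features))) {
    abort(sprintf("duplicate feature column(s): %s",
                  paste(unique(names(features)[duplicated(names(features))]),
                        collapse = ", ")))
  }
  excluded <- character(0)
  if ("incomplete" %in% names(features)) {
    excluded <- features$subject_id[features$incomplete]
    features <- features[!features$incomplete, , drop = FALSE]
  }
  if (nrow(features) < 3) abort("at least 3 complete subjects are required.")
  meta <- intersect(c("subject_id", "duration_s", "fas", "incomplete"), names(features))
  feat_cols <- setdiff(names(features), meta)
  has_na <- feat_cols[vapply(features[feat_cols], anyNA, logical(1))]
  if (length(has_na)) {
    inform(sprintf("dropping %d feature column(s) with missing values: %s",
                   length(has_na), paste(head(has_na, 8), collapse = ", ")))
    feat_cols <- setdiff(feat_cols, has_na)
  }
  out <- features[, c("subject_id", "fas", feat_cols)]
  structure(out, class = c("feature_matrix", class(out)),
            feature_cols = feat_cols, excluded_subjects = excluded)
}

#' Correlation-based feature selection
#'
#' Correlates every feature column with the FAS totals (Pearson), computes
#' the two-tailed p-value from `t = r * sqrt((m - 2) / (1 - r^2))` on `m - 2`
#' degrees of freedom, keeps features with `p < alpha`, and sorts ascending
#' by p (ties: larger `|r|` first, then name). Zero-variance columns are
#' assigned p = 1 (never selected).
#'
#' @param fm A `feature_matrix` (or tibble with `fas` plus feature columns).
#' @param alpha Significance level (default 0.05). `alpha = Inf` keeps and
#'   ranks every feature.
#' @return An `nf_selection` tibble: `feature`, `r`, `p`, sorted; attributes
#'   `alpha`, `m`.
#' @export
select_features <- function(fm, alpha = 0.05) {
  feat_cols <- attr(fm, "feature_cols") %||%
    setdiff(names(fm), c("subject_id", "duration_s", "fas", "incomplete"))
  y <- fm$fas
  m <- length(y)
  if (m < 3) abort("need at least 3 subjects to test correlations.")
  X <- as.matrix(fm[, feat_cols, drop = FALSE])
  r <- suppressWarnings(as.vector(cor(X, y)))   # NA for zero-variance columns
  p <- rep(1, length(r))
  ok <- !is.na(r)
  exact <- ok & abs(r) >= 1 - 1e-15
  p[exact] <- 0
  mid <- ok & !exact
  tval <- r[mid] * sqrt((m - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * pt(-abs(tval), df = m - 2)
  stats_tbl <- tibble(feature = feat_cols, r = r, p = p)
  kept <- stats_tbl[stats_tbl$p < alpha, , drop = FALSE]
  kept <- kept[order(kept$p, -abs(kept$r), kept$feature), , drop = FALSE]
  structure(as_tibble(kept), class = c("nf_selection", class(kept)),
            alpha = alpha, m = m)
}

#' Remove redundant reciprocal ratio features
#'
#' When both members of a reciprocal band-ratio pair on the same channel
#' (e.g. `ratio_alpha_theta_O2` and `ratio_theta_alpha_O2`) survive
#' selection, the one with the larger p-value is removed; all other features
#' are untouched.
#'
#' @param sel An `nf_selection` from [select_features()].
#' @return The pruned `nf_selection`, order preserved.
#' @export
drop_redundant <- function(sel) {
  parts <- stringr::str_match(sel$feature,
                              "^ratio_([a-z]+)_([a-z]+)_([A-Za-z0-9]+)$")
  is_ratio <- !is.na(parts[, 1])
  key <- rep(NA_character_, nrow(sel))
  key[is_ratio] <- paste(
    pmin(parts[is_ratio, 2], parts[is_ratio, 3]),
    pmax(parts[is_ratio, 2], parts[is_ratio, 3]),
    parts[is_ratio, 4])
  drop <- rep(FALSE, nrow(sel))
  for (k in unique(stats::na.omit(key))) {
    idx <- which(!is.na(key) & key == k)
    if (length(idx) > 1) {
      ## rows are p-sorted; keep the best-ranked member
      drop[idx[-1]] <- TRUE
    }
  }
  out <- sel[!drop, , drop = FALSE]
  structure(out, class = class(sel), alpha = attr(sel, "alpha"), m = attr(sel, "m"))
}

#' Multiple linear regression by the normal equation
#'
#' Fits `y = X w` with an intercept via the normal equations, using the
#' Moore-Penrose pseudo-inverse of the Gram matrix so rank-deficient designs
#' (e.g. more features than training subjects, reachable under leave-one-out
#' with large k) yield the minimum-norm solution with a logged warning
#' instead of failing.
#'
#' @param X Numeric matrix or data frame, n x k (no intercept column; one is
#'   added).
#' @param y Numeric response of length n.
#' @return An `nf_mlr` object: `coefficients` (named, `(Intercept)` first),
#'   `fitted`, `residuals`, `k`, `n`, `rank_deficient`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) abort("need at least 2 training observations.")
  if (length(y) != n) abort("`X` and `y` sizes disagree.")
  Xi <- cbind(`(Intercept)` = 1, X)
  G <- crossprod(Xi)
  rank_def <- n < ncol(Xi) || qr(Xi)$rank < ncol(Xi)
  if (rank_def) {
    inform(sprintf("normal-equation fit is rank-deficient (n = %d, k+1 = %d); using the minimum-norm solution.",
                   n, ncol(Xi)))
  }
  w <- MASS::ginv(G) %*% crossprod(Xi, y)
  w <- drop(w)
  names(w) <- colnames(Xi)
  fitted <- drop(Xi %*% w)
  structure(list(coefficients = w, fitted = fitted, residuals = y - fitted,
                 k = ncol(X), n = n, rank_deficient = rank_def,
                 feature_names = colnames(X)),
            class = "nf_mlr")
}

#' @export
print.nf_mlr <- function(x, ...) {
  cat(sprintf("<nf_mlr> %d features, n = %d%s\n", x$k, x$n,
              if (x$rank_deficient) " (rank-deficient)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.nf_mlr <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  drop(cbind(1, X) %*% object$coefficients)
}

#' @rdname fit_mlr
#' @param x An `nf_mlr` object.
#' @param ... Unused.
#' @export
tidy.nf_mlr <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname fit_mlr
#' @export
glance.nf_mlr <- function(x, ...) {
  y <- x$fitted + x$residuals
  tss <- sum((y - mean(y))^2)
  tibble(
    r.squared = if (tss > 0) 1 - sum(x$residuals^2) / tss else NA_real_,
    rmse = rmse_value(y, x$fitted),
    nobs = x$n,
    k = x$k,
    rank_deficient = x$rank_deficient
  )
}

#' Root mean square error
#'
#' `sqrt(sum((y - yhat)^2) / n)` between observed and predicted FAS totals.
#'
#' @param y,yhat Equal-length numeric vectors.
#' @return A single number.
#' @export
rmse_value <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("`y` and `yhat` must have equal length.")
  if (length(y) < 1) abort("need at least one observation.")
  sqrt(sum((y - yhat)^2) / length(y))
}
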