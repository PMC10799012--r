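#' Per-variable scaling statistics for the composite score
#'
#' Computes, on a declared reference set, the sample mean, sample
#' standard deviation and coefficient of variation (CV = sd/mean) of each
#' response variable. Variables whose mean is within
#' `near_zero_threshold` of zero are flagged: their mean-relative
#' standardisation is undefined and [cv_standardize()] falls back to
#' plain unit-variance standardisation for them. Variables with zero
#' standard deviation are flagged for exclusion with a warning (their
#' z-score is undefined).
#'
#' @param data a game-log `data.frame`.
#' @param variables character vector of numeric response columns;
#'   defaults to [on_variables()].
#' @param near_zero_threshold flag `|mean| <= near_zero_threshold`.
#' @return an object of class `on_scaling`: a `data.frame` with columns
#'   `variable`, `mean`, `sd`, `cv`, `near_zero`, `zero_sd`.
#' @export
#' @examples
#' d <- data.frame(Pts = c(8, 12, 10), Ast = c(1, 3, 2))
#' scaling_stats(d, c("Pts", "Ast"))
scaling_stats <- function(data, variables = on_variables(),
                          near_zero_threshold = 1e-8) {
  .assert_columns(data, variables, "game log")
  if (nrow(data) < 2) stop("need at least 2 rows to compute scaling statistics",
                           call. = FALSE)
  num <- vapply(data[variables], is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric response column(s): ",
         paste(variables[!num], collapse = ", "), call. = FALSE)
  m <- vapply(data[variables], mean, numeric(1))
  s <- vapply(data[variables], sd, numeric(1))
  near_zero <- abs(m) <= near_zero_threshold
  zero_sd <- s == 0
  cv <- ifelse(near_zero, NA_real_, s / m)
  cv[zero_sd] <- 0
  if (any(zero_sd))
    warning("constant column(s) excluded from the composite (zero SD): ",
            paste(variables[zero_sd], collapse = ", "), call. = FALSE)
  out <- data.frame(variable = variables, mean = unname(m), sd = unname(s),
                    cv = unname(cv), near_zero = unname(near_zero),
                    zero_sd = unname(zero_sd), stringsAsFactors = FALSE)
  attr(out, "near_zero_threshold") <- near_zero_threshold
  class(out) <- c("on_scaling", "data.frame")
  out
}

#' Mean-relative (CV-adjusted) standardisation
#'
#' Transforms each retained response `r` to `z* = (r - mean)/mean`, the
#' z-score multiplied by the variable's coefficient of variation, using
#' statistics from a reference set (see [scaling_stats()]). Variables
#' flagged as near-zero-mean fall back to the plain z-score
#' `(r - mean)/sd` with a warning; zero-SD variables are dropped.
#'
#' @param data a game-log `data.frame` holding the same variables the
#'   statistics were computed on.
#' @param stats an `on_scaling` object.
#' @return a numeric matrix (rows aligned to `data`, one column per
#'   retained variable) with the row keys (season, team, athlete, game,
#'   when present) attached as attribute `"keys"`.
#' @export
cv_standardize <- function(data, stats) {
  stopifnot(inherits(stats, "on_scaling"))
  .assert_columns(data, stats$variable, "game log")
  keep <- !stats$zero_sd
  st <- stats[keep, , drop = FALSE]
  if (any(st$near_zero))
    warning("near-zero-mean variable(s) use unit-variance standardisation: ",
            paste(st$variable[st$near_zero], collapse = ", "), call. = FALSE)
  z <- mapply(function(v, m, s, nz) {
    x <- data[[v]]
    if (nz) (x - m) / s else (x - m) / m
  }, st$variable, st$mean, st$sd, st$near_zero)
  z <- matrix(as.numeric(z), nrow = nrow(data),
              dimnames = list(NULL, st$variable))
  if (any(!is.finite(z)))
    stop("standardised matrix contains non-finite values", call. = FALSE)
  keys <- intersect(.on_keys(), names(data))
  if (length(keys)) attr(z, "keys") <- data[keys]
  z
}

#' Eigenvalue-weighted PCA composite weights
#'
#' Eigendecomposes the covariance matrix of the standardised responses
#' (covariance, not correlation: the mean-relative scaling is the
#' deliberate departure from correlation PCA), retains all components,
#' and forms the weight matrix `W[c, j] = (lambda_c / S) * alpha_cj` with
#' `S = sum(lambda)`, so each variable's composite weight
#' `w_j = sum_c W[c, j]` is the eigenvalue-weighted mean of its loadings
#' across all components. A deterministic sign convention is applied to
#' each eigenvector (its largest-absolute loading is made positive) and
#' recorded.
#'
#' @param zstar standardised matrix from [cv_standardize()].
#' @return an object of class `on_pca`: list with eigenvector matrix `A`
#'   (columns are components), eigenvalues `lambda` (descending),
#'   eigenvalue total `S`, weight matrix `W` (components x variables),
#'   composite weight vector `w`, and the sign `flips` applied.
#' @export
pca_weights <- function(zstar) {
  if (!is.matrix(zstar) || !is.numeric(zstar))
    stop("zstar must be a numeric matrix", call. = FALSE)
  n <- ncol(zstar)
  if (nrow(zstar) < n + 1)
    stop("need at least ncol(zstar) + 1 rows for the covariance PCA",
         call. = FALSE)
  if (any(!is.finite(zstar))) stop("zstar must be finite", call. = FALSE)
  V <- cov(zstar)
  e <- eigen(V, symmetric = TRUE)
  lambda <- e$values
  if (any(lambda < 0)) {
    if (any(lambda < -1e-8 * max(abs(lambda))))
      warning("rank-deficient covariance: negative eigenvalues clipped at 0",
              call. = FALSE)
    lambda <- pmax(lambda, 0)
  }
  A <- e$vectors
  ## sign convention: largest-absolute loading of each component positive
  flips <- vapply(seq_len(n), function(c) {
    j <- which.max(abs(A[, c]))
    if (A[j, c] < 0) -1 else 1
  }, numeric(1))
  A <- sweep(A, 2, flips, "*")
  dimnames(A) <- list(colnames(zstar), paste0("PC", seq_len(n)))
  S <- sum(lambda)
  if (S <= 0) stop("degenerate standardised matrix: all eigenvalues are 0",
                   call. = FALSE)
  W <- sweep(t(A), 1, lambda / S, "*")
  w <- colSums(W)
  out <- list(A = A, lambda = lambda, S = S, W = W, w = w, flips = flips,
              variables = colnames(zstar))
  class(out) <- "on_pca"
  out
}

#' @export
print.on_pca <- function(x, ...) {
  cat(sprintf("Eigenvalue-weighted PCA composite over %d variables\n",
              length(x$w)))
  cat(sprintf("  eigenvalue shares: %s\n",
              paste(sprintf("%.3f", x$lambda / x$S), collapse = " ")))
  cat("  composite weights:\n")
  print(round(x$w, 4))
  invisible(x)
}

#' Per-observation composite scores
#'
#' Applies the composite weight vector to each standardised row:
#' `score_k = sum_j w_j z*_kj`.
#'
#' @param zstar standardised matrix from [cv_standardize()].
#' @param weights an `on_pca` object fitted on the same variable set.
#' @return numeric vector of scores, keyed (as attribute `"keys"`) like
#'   `zstar` when keys are available.
#' @export
on_scores <- function(zstar, weights) {
  stopifnot(inherits(weights, "on_pca"))
  if (!identical(colnames(zstar), weights$variables))
    stop("column mismatch between the standardised matrix and the PCA weights",
         call. = FALSE)
  s <- drop(zstar %*% weights$w)
  attr(s, "keys") <- attr(zstar, "keys")
  s
}

#' Min-max rescaling of scores
#'
#' Order-preserving affine map sending the observed minimum to `a` and
#' the observed maximum to `b` (defaults 0 and 100).
#'
#' @param scores numeric vector.
#' @param a,b target range bounds, `a < b`.
#' @return rescaled numeric vector in `[a, b]`.
#' @export
minmax_scale <- function(scores, a = 0, b = 100) {
  if (a >= b) stop("need a < b", call. = FALSE)
  rng <- range(scores)
  if (rng[1] == rng[2])
    stop("constant score vector cannot be min-max scaled", call. = FALSE)
  a + (scores - rng[1]) * (b - a) / (rng[2] - rng[1])
}

#' Leave-one-season-out stability of composite weights
#'
#' For each season, recomputes the scaling statistics and PCA composite
#' weights on the data excluding that season, and summarises the
#' per-variable spread of the resulting weights together with per-season
#' means and SDs of every variable. Variables whose weight spread is far
#' above the rest (e.g. a variable recorded only in the final season)
#' are flagged as outliers.
#'
#' @param data a game-log `data.frame` with at least 2 seasons.
#' @param variables response columns, defaults to [on_variables()].
#' @param season_col name of the season column.
#' @param outlier_mult a variable is flagged when its weight range
#'   exceeds `outlier_mult` times the median range.
#' @param near_zero_threshold passed to [scaling_stats()].
#' @return an object of class `on_weight_stability`: list with `weights`
#'   (variables x excluded-season matrix), `summary` (per-variable mean,
#'   spread and outlier flag) and `season_summary` (per-season mean/SD of
#'   each variable).
#' @export
weight_stability <- function(data, variables = on_variables(),
                             season_col = "season", outlier_mult = 5,
                             near_zero_threshold = 1e-8) {
  .assert_columns(data, c(season_col, variables), "game log")
  seasons <- sort(unique(data[[season_col]]))
  if (length(seasons) < 2)
    stop("weight stability needs at least 2 seasons", call. = FALSE)
  wmat <- sapply(seasons, function(s) {
    sub <- data[data[[season_col]] != s, , drop = FALSE]
    st <- suppressWarnings(scaling_stats(sub, variables, near_zero_threshold))
    keep_vars <- st$variable[!st$zero_sd]
    z <- suppressWarnings(cv_standardize(sub, st))
    w <- pca_weights(z)$w
    full <- setNames(rep(NA_real_, length(variables)), variables)
    full[keep_vars] <- w
    full
  })
  colnames(wmat) <- paste0("excl_", seasons)
  spread <- apply(wmat, 1, function(x) diff(range(x, na.rm = TRUE)))
  med <- median(spread, na.rm = TRUE)
  summ <- data.frame(variable = variables,
                     mean_weight = rowMeans(wmat, na.rm = TRUE),
                     spread = unname(spread),
                     outlier = unname(spread > outlier_mult * pmax(med, 1e-12)),
                     stringsAsFactors = FALSE)
  season_summary <- do.call(rbind, lapply(seasons, function(s) {
    sub <- data[data[[season_col]] == s, variables, drop = FALSE]
    data.frame(season = s, variable = variables,
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, sd, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out <- list(weights = wmat, summary = summ, season_summary = season_summary)
  class(out) <- "on_weight_stability"
  out
}

#' @export
print.on_weight_stability <- function(x, ...) {
  cat(sprintf("Composite-weight stability over %d season exclusions\n",
              ncol(x$weights)))
  print(x$summary, digits = 4)
  if (any(x$summary$outlier))
    cat("Outlier variable(s):",
        paste(x$summary$variable[x$summary$outlier], collapse = ", "), "\n")
  invisible(x)
}
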