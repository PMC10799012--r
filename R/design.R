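#' Build fixed-effect design matrices for the stage-2 model
#'
#' Constructs the response vector, the fixed-effect design matrix
#' `X = [1 | factors | orthogonal polynomials]` and the hierarchy index
#' for the three-level model. Factor covariates are coded with
#' sum-to-zero contrasts by default (`contr.sum`; pass
#' `contrasts = "contr.treatment"` for reference coding against the
#' first level). Polynomial blocks use orthogonal polynomials against
#' the observed covariate values (zero mean, orthogonal columns).
#' Aliased columns are dropped with a warning so `X` has full column
#' rank. The grouping unit is the triple (season, team, athlete): a
#' traded athlete forms two units.
#'
#' @param data a game-log `data.frame` carrying the hierarchy columns
#'   (`season`, `team`, `athlete`), the covariates named in `fixed`, and
#'   the response column.
#' @param fixed one-sided formula for the fixed effects; defaults to
#'   [on_default_fixed()].
#' @param response name of the response column (default `"score"`).
#' @param contrasts contrast function name applied to factor covariates.
#' @return an object of class `on_design`: list with `y`, `X`, `groups`
#'   (a `data.frame` of hierarchy ids including the `unit` factor),
#'   `data` (the augmented model data used for fitting), `fixed`,
#'   `response`, `terms` and `contrasts`.
#' @export
build_design <- function(data, fixed = on_default_fixed(),
                         response = "score", contrasts = "contr.sum") {
  .assert_columns(data, c("season", "team", "athlete", response), "model data")
  stopifnot(inherits(fixed, "formula"), length(fixed) == 2)
  dat <- as.data.frame(data)
  ## stable covariate types: characters and logicals become factors
  for (nm in names(dat)) {
    if (is.character(dat[[nm]]) || is.logical(dat[[nm]]))
      dat[[nm]] <- factor(dat[[nm]])
  }
  full_formula <- stats::as.formula(
    paste(response, "~", deparse(fixed[[2]], width.cutoff = 500L)),
    env = globalenv())
  mf <- tryCatch(
    model.frame(full_formula, dat, na.action = na.fail),
    error = function(e) stop("cannot build the model frame: ",
                             conditionMessage(e), call. = FALSE))
  trm <- attr(mf, "terms")
  fac_cols <- names(mf)[vapply(mf, is.factor, logical(1))]
  ctr <- if (length(fac_cols))
    setNames(rep(list(contrasts), length(fac_cols)), fac_cols) else NULL
  X <- model.matrix(trm, mf, contrasts.arg = ctr)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_idx <- qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]
    warning("dropping aliased design column(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
    X <- X[, -drop_idx, drop = FALSE]
  }
  groups <- data.frame(season = as.character(dat$season),
                       team = as.character(dat$team),
                       athlete = as.character(dat$athlete),
                       stringsAsFactors = FALSE)
  if ("game" %in% names(dat)) groups$game <- dat$game
  groups$unit <- .unit_factor(dat)
  dat$.unit <- groups$unit
  dat$.team <- .team_factor(dat)
  out <- list(y = mf[[1L]], X = X, groups = groups, data = dat,
              fixed = fixed, response = response, terms = trm,
              contrasts = ctr)
  class(out) <- "on_design"
  out
}

#' @export
print.on_design <- function(x, ...) {
  cat(sprintf("Stage-2 design: %d rows, %d fixed-effect columns\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  %d season(s), %d team-season(s), %d athlete unit(s)\n",
              length(unique(x$groups$season)),
              nlevels(x$data$.team), nlevels(x$groups$unit)))
  cat("  fixed: ~", deparse(x$fixed[[2]], width.cutoff = 500L), "\n")
  invisible(x)
}
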