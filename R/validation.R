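#' Train/test split plans for systematic validation
#'
#' Two schemes. `"season_holdout"`: each season in turn is the test set
#' and the remaining seasons the training set (one plan per season).
#' `"game_sample"`: within every season a simple random sample of games
#' (10\% of the distinct game ids by default, or a fixed count) is held
#' out, the remaining rows form the training set, and the procedure is
#' repeated `reps` times. Train and test always partition the rows.
#'
#' @param data a game-log or score `data.frame` with `season` and `game`
#'   columns.
#' @param scheme `"season_holdout"` or `"game_sample"`.
#' @param fraction fraction of games per season held out
#'   (`game_sample`).
#' @param games_per_season fixed number of held-out games per season
#'   (`game_sample`); overrides `fraction`.
#' @param reps number of replicates (`game_sample`, default 100).
#' @param seed seed for the game sampling.
#' @return list of `on_split` objects, each a list with `scheme`,
#'   `test` and `train` row indices, `heldout` labels and `rep`.
#' @export
make_split <- function(data, scheme = c("season_holdout", "game_sample"),
                       fraction = 0.10, games_per_season = NULL,
                       reps = 100, seed = 1L) {
  scheme <- match.arg(scheme)
  .assert_columns(data, c("season", "game"), "table")
  seasons <- sort(unique(data$season))
  n <- nrow(data)
  if (scheme == "season_holdout") {
    if (length(seasons) < 2)
      stop("season_holdout needs at least 2 seasons", call. = FALSE)
    plans <- lapply(seq_along(seasons), function(i) {
      test <- which(data$season == seasons[i])
      out <- list(scheme = scheme, test = test,
                  train = setdiff(seq_len(n), test),
                  heldout = as.character(seasons[i]), rep = i)
      class(out) <- "on_split"
      out
    })
    return(plans)
  }
  set.seed(seed)
  plans <- lapply(seq_len(reps), function(rp) {
    test <- integer(0)
    labs <- character(0)
    for (s in seasons) {
      games <- sort(unique(data$game[data$season == s]))
      k <- if (!is.null(games_per_season)) games_per_season
      else max(1L, round(fraction * length(games)))
      if (k > length(games))
        stop(sprintf("requested %d games but season %s has only %d",
                     k, s, length(games)), call. = FALSE)
      g_sel <- sample(games, k)
      test <- c(test, which(data$season == s & data$game %in% g_sel))
      labs <- c(labs, paste0(s, ":", g_sel))
    }
    out <- list(scheme = scheme, test = test,
                train = setdiff(seq_len(n), test), heldout = labs,
                rep = rp)
    class(out) <- "on_split"
    out
  })
  plans
}

#' Agreement metrics between reference and predicted scores
#'
#' Computes the root mean square error, Pearson correlation `r`, Lin's
#' concordance correlation coefficient
#' `CCC = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` (population
#' moments), and the accuracy factor `Cb = CCC / r`, together with a
#' confidence interval for the CCC from the Fisher z transform with
#' Lin's asymptotic standard error.
#'
#' @param x reference scores.
#' @param y predicted scores (same length, >= 3).
#' @param ci_level confidence level for the CCC interval.
#' @return an object of class `on_concordance`: a one-row `data.frame`
#'   with `rmse`, `ccc`, `ccc_lower`, `ccc_upper`, `r`, `cb`.
#' @export
#' @examples
#' concordance_metrics(c(1, 2, 3), c(2, 3, 4))  # r = 1, CCC = 4/7
concordance_metrics <- function(x, y, ci_level = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in x or y; concordance undefined", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  cb <- ccc / r
  rmse <- sqrt(mean((x - y)^2))
  ## Lin's asymptotic variance of atanh(CCC)
  u <- (mx - my) / (sx2 * sy2)^0.25
  z <- atanh(ccc)
  se_z <- sqrt(max(0, ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                         4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                         2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2)))
  zc <- qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(rmse = rmse, ccc = ccc,
                    ccc_lower = tanh(z - zc * se_z),
                    ccc_upper = tanh(z + zc * se_z),
                    r = r, cb = cb)
  class(out) <- c("on_concordance", "data.frame")
  out
}

#' Run a systematic validation scheme
#'
#' For each split: refits stage 1 (scaling statistics and PCA weights)
#' and the stage-2 mixed model on the training rows, predicts the test
#' rows' composite scores (population mode under `season_holdout`, where
#' the test season is unseen; conditional mode under `game_sample`,
#' where the grouping units are known), and compares the predictions
#' against reference values from the model fitted to the complete data
#' (`reference = "full_model"`, the default) or against the raw stage-1
#' scores (`reference = "stage1"`). `game_sample` rows are averaged over
#' replicates.
#'
#' @param data a game-log `data.frame`.
#' @param scheme `"season_holdout"` or `"game_sample"`.
#' @param variables response columns for the composite.
#' @param fixed fixed-effect formula for the stage-2 model.
#' @param structure random structure passed to [fit_reml()].
#' @param fraction,games_per_season,reps passed to [make_split()].
#' @param seed seed for the game sampling.
#' @param reference `"full_model"` or `"stage1"`.
#' @param refit_weights logical; recompute the stage-1 weights on each
#'   training set (`TRUE`, the stricter default) or reuse the full-data
#'   weights.
#' @param ci_level confidence level for the CCC intervals.
#' @return an object of class `on_validation`: a `data.frame` with one
#'   row per test set (or per-scheme average), columns `test_set`,
#'   `rmse`, `ccc`, `ccc_lower`, `ccc_upper`, `r`, `cb`, `n_test`,
#'   `n_train`.
#' @export
run_validation <- function(data, scheme = c("season_holdout", "game_sample"),
                           variables = on_variables(),
                           fixed = on_default_fixed(),
                           structure = "reduced",
                           fraction = 0.10, games_per_season = NULL,
                           reps = 100, seed = 1L,
                           reference = c("full_model", "stage1"),
                           refit_weights = TRUE, ci_level = 0.95) {
  scheme <- match.arg(scheme)
  reference <- match.arg(reference)
  dat <- as.data.frame(data)
  ## stage 1 and reference model on the complete data
  st_full <- suppressWarnings(scaling_stats(dat, variables))
  z_full <- suppressWarnings(cv_standardize(dat, st_full))
  w_full <- pca_weights(z_full)
  dat$score <- on_scores(z_full, w_full)
  des_full <- build_design(dat, fixed, "score")
  fit_full <- fit_reml(des_full, structure)
  ref_all <- if (reference == "full_model") fitted(fit_full$model)
  else dat$score

  plans <- make_split(dat, scheme, fraction, games_per_season, reps, seed)
  frac_train <- vapply(plans, function(p) length(p$train) / nrow(dat),
                       numeric(1))
  if (any(frac_train < 0.70 | frac_train > 0.85))
    warning("training fraction outside the 70-85% guardrail for ",
            sum(frac_train < 0.70 | frac_train > 0.85), " split(s)",
            call. = FALSE)

  one_split <- function(pl) {
    train <- dat[pl$train, , drop = FALSE]
    test <- dat[pl$test, , drop = FALSE]
    if (refit_weights) {
      st <- suppressWarnings(scaling_stats(train, variables))
      z_tr <- suppressWarnings(cv_standardize(train, st))
      w <- pca_weights(z_tr)
      train$score <- on_scores(z_tr, w)
    }
    des <- build_design(train, fixed, "score")
    fit <- fit_reml(des, structure)
    mode <- if (scheme == "season_holdout") "population" else "conditional"
    pred <- predict(fit, newdata = test, mode = mode)
    cm <- concordance_metrics(ref_all[pl$test], pred, ci_level)
    cbind(data.frame(test_set = if (scheme == "season_holdout")
      paste("Season", pl$heldout) else sprintf("rep %d", pl$rep)),
      cm, n_test = nrow(test), n_train = nrow(train))
  }

  res <- lapply(plans, function(pl) {
    tryCatch(one_split(pl), error = function(e) {
      warning(sprintf("split %s failed and was skipped: %s",
                      paste(pl$heldout, collapse = ","),
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  failed <- sum(vapply(res, is.null, logical(1)))
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(test_set = character(0), rmse = numeric(0),
                      ccc = numeric(0), ccc_lower = numeric(0),
                      ccc_upper = numeric(0), r = numeric(0),
                      cb = numeric(0), n_test = integer(0),
                      n_train = integer(0))
    warning("all splits failed; returning an empty report", call. = FALSE)
  }
  if (scheme == "game_sample" && !is.null(res) && nrow(res) > 1) {
    avg <- data.frame(test_set = sprintf("%s x %d seasons (avg of %d reps)",
                                         if (!is.null(games_per_season))
                                           games_per_season else
                                             sprintf("%.0f%% games", 100 * fraction),
                                         length(unique(dat$season)), nrow(res)),
                      rmse = mean(res$rmse), ccc = mean(res$ccc),
                      ccc_lower = mean(res$ccc_lower),
                      ccc_upper = mean(res$ccc_upper),
                      r = mean(res$r), cb = mean(res$cb),
                      n_test = round(mean(res$n_test)),
                      n_train = round(mean(res$n_train)))
    attr(avg, "replicates") <- res
    res <- avg
  }
  attr(res, "scheme") <- scheme
  attr(res, "failed") <- failed
  attr(res, "reference") <- reference
  class(res) <- c("on_validation", "data.frame")
  res
}

#' @export
print.on_validation <- function(x, ...) {
  cat(sprintf("Predictive validation (%s scheme, reference: %s)\n",
              attr(x, "scheme"), attr(x, "reference")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  if (isTRUE(attr(x, "failed") > 0))
    cat(sprintf("NOTE: %d split(s) failed and were skipped\n",
                attr(x, "failed")))
  invisible(x)
}
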