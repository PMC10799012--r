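## Consistency scores: empirical-Bayes prediction of the random effects,
## conditioning each grouping unit on its own observation vector.
##
## For a group g at hierarchy level l with L rows, marginal residual
## vector r and per-group marginal covariance V_g, the point score is
## sigma_l^2 * 1' V_g^{-1} r and the conditional (posterior) variance is
## sigma_l^2 - sigma_l^4 * 1' V_g^{-1} 1. V_g is compound-symmetric at
## the athlete level and nested-block at the team and season levels, so
## both quadratic forms have closed forms via per-block
## Sherman-Morrison accumulation (no matrix inversion).

## per-group point score and conditional variance at a given level
.cs_point <- function(fit, level = c("athlete", "team", "season")) {
  level <- match.arg(level)
  comp <- fit$components
  v1 <- comp[["season"]]; v2 <- comp[["team"]]
  v3 <- comp[["athlete"]]; s2 <- comp[["residual"]]
  d <- fit$design
  r <- d$y - drop(d$X %*% fit$beta_hat)
  fu <- d$groups$unit
  ft <- d$data$.team
  fs <- factor(d$groups$season)

  ## per-unit accumulators: a_u = 1'B^{-1} r, b_u = 1'B^{-1} 1 with
  ## B = s2*I + v3*J on the unit's rows
  Sr_m <- rowsum(r, fu, reorder = FALSE)
  u_names <- rownames(Sr_m)
  Sr <- Sr_m[, 1L]
  L <- as.numeric(rowsum(rep(1, length(r)), fu, reorder = FALSE)[, 1L])
  den_u <- s2 + L * v3
  a_u <- Sr / den_u
  b_u <- L / den_u

  key <- unique(data.frame(season = d$groups$season, team = d$groups$team,
                           athlete = d$groups$athlete, unit = fu,
                           tf = ft, stringsAsFactors = FALSE))
  key <- key[match(u_names, as.character(key$unit)), ]

  if (level == "athlete") {
    c_out <- v1 + v2 + v3
    den <- s2 + L * c_out
    score <- v3 * Sr / den
    condvar <- v3 - v3^2 * L / den
    out <- data.frame(season = key$season, team = key$team,
                      athlete = key$athlete, games = L,
                      score = unname(score), condvar = pmax(0, condvar),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }

  ## fold units into team blocks: B_t = s2*I + v3*bd(J_u) + v2*J_t
  tf_u <- as.character(key$tf)
  A_t <- rowsum(a_u, tf_u, reorder = FALSE)[, 1L]
  B_t <- rowsum(b_u, tf_u, reorder = FALSE)[, 1L]
  t_names <- unique(tf_u)
  if (level == "team") {
    c_out <- v1 + v2
    q_r <- A_t / (1 + c_out * B_t)
    q_1 <- B_t / (1 + c_out * B_t)
    tk <- unique(data.frame(season = key$season, team = key$team,
                            tf = tf_u, stringsAsFactors = FALSE))
    tk <- tk[match(t_names, tk$tf), ]
    games_t <- rowsum(L, tf_u, reorder = FALSE)[, 1L]
    out <- data.frame(season = tk$season, team = tk$team,
                      games = unname(games_t),
                      score = unname(v2 * q_r),
                      condvar = pmax(0, v2 - v2^2 * q_1),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }

  ## fold team blocks into seasons: V_i = (teams) + v1*J_i
  a_t <- A_t / (1 + v2 * B_t)
  b_t <- B_t / (1 + v2 * B_t)
  season_of_t <- key$season[match(t_names, tf_u)]
  A_s <- rowsum(a_t, season_of_t, reorder = FALSE)[, 1L]
  B_s <- rowsum(b_t, season_of_t, reorder = FALSE)[, 1L]
  s_names <- unique(season_of_t)
  games_s <- rowsum(L, key$season, reorder = FALSE)
  out <- data.frame(season = s_names,
                    games = unname(games_s[match(s_names, rownames(games_s)), 1L]),
                    score = unname(v1 * A_s / (1 + v1 * B_s)),
                    condvar = pmax(0, v1 - v1^2 * B_s / (1 + v1 * B_s)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consistency scores with Monte-Carlo interval estimates
#'
#' The consistency score of a grouping unit is the empirical-Bayes
#' prediction (BLUP) of its random effect: positive values flag units
#' performing above the level expected from the fixed effects and the
#' rest of the hierarchy, values near zero performance as expected, and
#' negative values performance below expectation. Interval estimates are
#' percentile bands of Monte-Carlo draws from each unit's empirical-Bayes
#' posterior, `Normal(BLUP, sigma_l^2 - sigma_l^4 * 1' V^{-1} 1)`,
#' with 10,000 draws by default.
#'
#' @param fit an `on_lmm` (or `on_fit`) object.
#' @param level `"athlete"` (athlete within team within season),
#'   `"team"` (team within season; needs the full structure) or
#'   `"season"`.
#' @param ci `NULL` for point scores only, or a list with elements
#'   `n_sim` (default 10000), `level` (default 0.95) and `seed`.
#' @return an object of class `on_consistency`: a `data.frame` with the
#'   grouping ids, `games`, `score` and (with `ci`) `lower`, `upper`.
#' @export
#' @examples
#' p <- on_sim_params(n_seasons = 2, n_teams = 3, athletes_per_team = 3,
#'                    games_range = c(8, 12), seed = 3)
#' log1 <- simulate_game_log(p)
#' f <- on_fit(log1, fixed = ~ venue, structure = "reduced")
#' head(consistency_scores(f, "athlete"))
consistency_scores <- function(fit, level = c("athlete", "team", "season"),
                               ci = NULL) {
  if (inherits(fit, "on_fit")) fit <- fit$lmm
  stopifnot(inherits(fit, "on_lmm"))
  level <- match.arg(level)
  if (level == "team" && fit$structure == "reduced")
    stop("the reduced structure has no team component; refit with structure = \"full\"",
         call. = FALSE)
  pt <- .cs_point(fit, level)
  out <- pt[setdiff(names(pt), "condvar")]
  if (!is.null(ci)) {
    n_sim <- if (is.null(ci$n_sim)) 10000L else as.integer(ci$n_sim)
    lv <- if (is.null(ci$level)) 0.95 else ci$level
    if (!is.null(ci$seed)) set.seed(ci$seed)
    alpha <- (1 - lv) / 2
    qs <- t(vapply(seq_len(nrow(pt)), function(i) {
      draws <- rnorm(n_sim, pt$score[i], sqrt(pt$condvar[i]))
      quantile(draws, c(alpha, 1 - alpha), names = FALSE)
    }, numeric(2)))
    out$lower <- qs[, 1]
    out$upper <- qs[, 2]
    attr(out, "ci") <- list(n_sim = n_sim, level = lv, seed = ci$seed)
  }
  attr(out, "level") <- level
  attr(out, "condvar") <- pt$condvar
  class(out) <- c("on_consistency", "data.frame")
  out
}

#' @export
print.on_consistency <- function(x, ...) {
  cat(sprintf("Consistency scores at the %s level (%d units)\n",
              attr(x, "level"), nrow(x)))
  print.data.frame(head(x[order(-x$score), ], 10), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
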