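## fixtures built in code: skeleton hierarchies and small simulated logs

## minimal hierarchy skeleton (no box scores) for response simulation
skeleton_table <- function(I, J, K, Lmin, Lmax, seed = 1) {
  set.seed(seed)
  n <- I * J * K
  L <- sample(Lmin:Lmax, n, replace = TRUE)
  idx <- rep(seq_len(n), L)
  g <- data.frame(i = rep(rep(seq_len(I), each = J * K), L),
                  j = rep(rep(rep(seq_len(J), each = K), I), L))
  out <- data.frame(season = sprintf("S%d", g$i),
                    team = sprintf("T%02d", g$j),
                    athlete = sprintf("A%04d", idx),
                    game = unlist(lapply(L, seq_len)),
                    stringsAsFactors = FALSE)
  out$venue <- ifelse(out$game %% 2 == 0, "home", "away")
  out$score <- 0
  out
}

small_params <- function(...) {
  args <- list(n_seasons = 2, n_teams = 3, athletes_per_team = 4,
               games_range = c(6, 12), seed = 7)
  args[names(list(...))] <- list(...)
  do.call(on_sim_params, args)
}

small_log <- function(...) simulate_game_log(small_params(...))

## a small fitted model over a simulated score with known truth
small_fit <- function(I = 3, J = 4, K = 4, Lmin = 6, Lmax = 14,
                      sd_season = 0.3, sd_team = 0, sd_athlete = 0.25,
                      sd_resid = 0.4, seed = 5, structure = "reduced",
                      fixed = ~ venue) {
  sk <- skeleton_table(I, J, K, Lmin, Lmax, seed)
  des0 <- build_design(sk, fixed)
  p <- on_sim_params(n_seasons = I, n_teams = J, athletes_per_team = K,
                     games_range = c(Lmin, Lmax), sd_season = sd_season,
                     sd_team = sd_team, sd_athlete = sd_athlete,
                     sd_resid = sd_resid, seed = seed)
  resp <- simulate_on_response(p, des0, beta = c("(Intercept)" = 1))
  sk$score <- resp$score
  des <- build_design(sk, fixed)
  fit <- fit_reml(des, structure)
  attr(fit, "truth") <- attr(resp, "truth")
  fit
}

## exhaustive enumeration of the signed-rank null: distribution of
## T+ = sum of ranks of the positively-signed observations over all 2^L
## equiprobable sign patterns
enum_signrank_upper <- function(L, alpha) {
  ranks <- seq_len(L)
  tvals <- vapply(0:(2^L - 1), function(m) {
    signs <- bitwAnd(m, 2^(ranks - 1)) > 0
    sum(ranks[signs])
  }, numeric(1))
  tab <- table(tvals) / 2^L
  supp <- as.numeric(names(tab))
  ## smallest t with P(T+ >= t) <= alpha / 2; if the null is too coarse
  ## for the level, no t qualifies and the interval degenerates to the
  ## full Walsh range
  tail_p <- rev(cumsum(rev(as.numeric(tab))))
  ok <- supp[tail_p <= alpha / 2]
  if (!length(ok)) L * (L + 1) / 2 else min(ok)
}

enum_walsh_ci <- function(x, conf.level) {
  L <- length(x)
  M <- L * (L + 1) / 2
  t_crit <- enum_signrank_upper(L, 1 - conf.level)
  C <- max(1, M + 1 - t_crit)
  xs <- sort(x)
  w <- sort(c(outer(xs, xs, "+")[upper.tri(diag(L), diag = TRUE)] / 2))
  c(w[C], w[M + 1 - C])
}

## dense-matrix marginal covariance for a reduced/full fit (oracle)
dense_V <- function(fit) {
  v <- fit$components
  d <- fit$design
  fs <- factor(d$groups$season)
  fu <- d$groups$unit
  ft <- d$data$.team
  Zs <- stats::model.matrix(~ 0 + fs)
  Zu <- stats::model.matrix(~ 0 + fu)
  Zt <- stats::model.matrix(~ 0 + ft)
  v[["season"]] * tcrossprod(Zs) + v[["team"]] * tcrossprod(Zt) +
    v[["athlete"]] * tcrossprod(Zu) +
    v[["residual"]] * diag(nrow(d$X))
}
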