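#' Simulation parameters for the synthetic game-log generator
#'
#' Bundles the study conditions used by [simulate_game_log()] and
#' [simulate_on_response()]: the hierarchy dimensions, the random-effect
#' standard deviations of the three-level score model (season,
#' team-within-season, athlete-within-team-within-season) plus the
#' residual standard deviation, the fixed-effect coefficients, the
#' two-factor loading structure that induces the two observed correlation
#' blocks among box-score variables (a physical/rebounding factor and an
#' offence/defence factor), and the seed.
#'
#' Default variance components are set to the magnitudes estimated on
#' four seasons of elite-basketball data (variances 0.005136 for season,
#' 0 for team, 0.007496 for athlete, 0.012019 residual), so the default
#' generator reproduces the hierarchy signal-to-noise regime of real
#' league data. `games_range` defaults to `c(1, 82)`: repeats per athlete
#' unit are drawn uniformly in that range, giving the strongly unbalanced
#' design seen in practice.
#'
#' @param n_seasons,n_teams,athletes_per_team positive integers giving the
#'   hierarchy dimensions.
#' @param games_range integer vector `c(min, max)` of games per athlete
#'   unit, within `[1, 82]`.
#' @param sd_season,sd_team,sd_athlete,sd_resid non-negative standard
#'   deviations of the random effects and residual, in score units.
#' @param fixed_effects list of generator fixed effects: `intercept` (the
#'   mean score) and optionally a named coefficient vector `beta` used by
#'   [simulate_on_response()].
#' @param factor_shifts list of deterministic latent-factor shifts for the
#'   categorical covariates: `position1`, `position2` (named by position),
#'   `rookie2`, `venue2`.
#' @param skill_loadings 22 x 2 matrix of per-variable loadings of the two
#'   latent factors; rownames must be [on_variables()]. `NULL` uses the
#'   built-in block structure.
#' @param noise_scale non-negative multiplier on all stochastic box-score
#'   dispersion (0 gives deterministic box scores given the covariates).
#' @param rookie_rate per-season probability that an athlete's debut
#'   falls in that season (their rookie year); 0 disables rookies.
#' @param trade_fraction fraction of athletes per season that appear for
#'   two teams (a traded athlete forms two grouping units).
#' @param seed integer seed; identical parameters imply byte-identical
#'   output.
#' @return an object of class `on_sim_params` (a validated list).
#' @export
#' @examples
#' p <- on_sim_params(n_seasons = 2, n_teams = 3, athletes_per_team = 4,
#'                    games_range = c(5, 10), seed = 1)
#' log1 <- simulate_game_log(p)
#' head(log1)
on_sim_params <- function(n_seasons = 4, n_teams = 10, athletes_per_team = 12,
                          games_range = c(1, 82),
                          sd_season = sqrt(0.005136),
                          sd_team = 0,
                          sd_athlete = sqrt(0.007496),
                          sd_resid = sqrt(0.012019),
                          fixed_effects = list(intercept = 1),
                          factor_shifts = NULL,
                          skill_loadings = NULL,
                          noise_scale = 1,
                          rookie_rate = 0.15,
                          trade_fraction = 0.05,
                          seed = 1L) {
  stopifnot(length(games_range) == 2)
  games_range <- as.integer(round(games_range))
  if (n_seasons < 1 || n_teams < 1 || athletes_per_team < 1)
    stop("degenerate hierarchy: n_seasons, n_teams and athletes_per_team must all be >= 1",
         call. = FALSE)
  if (games_range[1] < 1 || games_range[2] > 82 || games_range[1] > games_range[2])
    stop("games_range must satisfy 1 <= min <= max <= 82", call. = FALSE)
  sds <- c(sd_season = sd_season, sd_team = sd_team,
           sd_athlete = sd_athlete, sd_resid = sd_resid)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all random-effect standard deviations must be finite and >= 0",
         call. = FALSE)
  if (!is.finite(noise_scale) || noise_scale < 0)
    stop("noise_scale must be finite and >= 0", call. = FALSE)
  if (trade_fraction < 0 || trade_fraction > 0.5)
    stop("trade_fraction must be in [0, 0.5]", call. = FALSE)
  if (rookie_rate < 0 || rookie_rate > 1 / max(1, n_seasons))
    stop("rookie_rate must be in [0, 1/n_seasons]", call. = FALSE)
  if (is.null(factor_shifts)) {
    factor_shifts <- list(
      position1 = c(PG = -0.5, SG = -0.2, SF = 0, PF = 0.3, C = 0.6),
      position2 = c(PG = 0.4, SG = 0.2, SF = 0, PF = -0.1, C = -0.3),
      rookie2 = -0.2, venue2 = 0.05)
  }
  if (is.null(skill_loadings)) skill_loadings <- .default_loadings()
  if (!is.matrix(skill_loadings) || ncol(skill_loadings) != 2 ||
      !all(on_variables() %in% rownames(skill_loadings)))
    stop("skill_loadings must be a matrix with 2 columns and one row per response variable",
         call. = FALSE)
  if (any(!is.finite(skill_loadings)))
    stop("skill_loadings must be finite", call. = FALSE)
  if (is.null(fixed_effects$intercept)) fixed_effects$intercept <- 1
  out <- list(n_seasons = as.integer(n_seasons),
              n_teams = as.integer(n_teams),
              athletes_per_team = as.integer(athletes_per_team),
              games_range = games_range,
              sd_season = sd_season, sd_team = sd_team,
              sd_athlete = sd_athlete, sd_resid = sd_resid,
              fixed_effects = fixed_effects,
              factor_shifts = factor_shifts,
              skill_loadings = skill_loadings[on_variables(), , drop = FALSE],
              noise_scale = noise_scale,
              rookie_rate = rookie_rate,
              trade_fraction = trade_fraction,
              seed = as.integer(seed))
  class(out) <- "on_sim_params"
  out
}

## Marginal anchors (mean, sd) for each response, taken from published
## per-game league summaries, and two-factor loadings reproducing the two
## correlation blocks: factor 1 = physical/rebounding, factor 2 =
## offence/defence. Derived count identities (FgAtt, FgMade, Pts) are
## built from the shot families, not drawn.
.box_anchor <- function() {
  data.frame(
    variable = on_variables(),
    mean = c(200.82, 99.81, 28.73, 5.51, 2.79, 2.65, 0.95, 8.15, 3.73,
             2.15, 1.65, 0.96, 3.20, 2.19, 10.06, 1.28, 0.73, 0.46,
             0.46, 1366.42, 2.65, 0.50),
    sd = c(8.72, 11.40, 4.46, 4.44, 2.59, 2.71, 1.32, 5.64, 3.03,
           2.77, 2.27, 1.35, 2.75, 2.48, 8.12, 1.39, 0.97, 0.84,
           0.76, 620.54, 2.41, 1.34),
    stringsAsFactors = FALSE)
}

.default_loadings <- function() {
  v <- on_variables()
  l <- matrix(0, nrow = length(v), ncol = 2,
              dimnames = list(v, c("physical", "offence")))
  l[c("Height", "Weight"), 1] <- c(0.90, 0.80)
  l[c("OffReb", "DefReb", "Blk", "BlkAgainst", "Fouls"), 1] <-
    c(0.60, 0.55, 0.55, 0.35, 0.30)
  l[c("Age"), 2] <- 0.10
  l[c("Fg2PtAtt", "Fg3PtAtt", "FtAtt", "Ast", "Tov", "Stl",
      "MinSeconds", "FoulsDrawn"), 2] <-
    c(0.60, 0.45, 0.50, 0.55, 0.45, 0.40, 0.65, 0.40)
  l[c("DefReb"), 2] <- 0.25
  l
}

## per-variable shot-success base rates (made/attempt), from the same
## marginal anchors
.shot_rates <- function() c(Fg2 = 2.79 / 5.51, Fg3 = 0.95 / 2.65, Ft = 1.65 / 2.15)

#' Generate a synthetic hierarchical game log
#'
#' Simulates one row per athlete-game across `n_seasons` seasons,
#' `n_teams` teams and `athletes_per_team` athletes per team, with an
#' unbalanced number of repeats per athlete unit drawn from
#' `games_range`. Box-score counts are produced by rounding truncated
#' latent Gaussians driven by two hierarchical latent factors (so the two
#' empirical correlation blocks among responses are reproduced), with
#' made counts derived from attempts through a latent success rate so
#' that made <= attempted within each shot family and
#' `FgAtt = Fg2PtAtt + Fg3PtAtt`, `Pts = 2*Fg2PtMade + 3*Fg3PtMade +
#' FtMade` hold by construction. Static attributes (height, weight, age)
#' are constant within athlete-season. A `trade_fraction` of athletes
#' appears for two teams within a season, forming two grouping units.
#'
#' The per-game latent score (season + team + athlete random effects plus
#' a per-game innovation, on the score scale) is returned in
#' `attr(x, "truth")$latent` together with the generating parameters, for
#' parameter-recovery studies.
#'
#' @param params an [on_sim_params()] object.
#' @return a `data.frame` of class `game_log` with hierarchy columns
#'   (`season`, `team`, `athlete`, `game`), covariates (`venue`,
#'   `position`, `rookie`) and the 22 response columns; the generator
#'   truth is attached as attribute `"truth"`.
#' @export
simulate_game_log <- function(params) {
  stopifnot(inherits(params, "on_sim_params"))
  p <- params
  set.seed(p$seed)
  anchor <- .box_anchor()
  rownames(anchor) <- anchor$variable
  load <- p$skill_loadings
  c_norm <- sqrt(p$sd_season^2 + p$sd_team^2 + p$sd_athlete^2 + p$sd_resid^2)
  if (c_norm == 0) c_norm <- 1

  seasons <- sprintf("S%d", seq_len(p$n_seasons))
  teams <- sprintf("T%02d", seq_len(p$n_teams))
  positions <- c("PG", "SG", "SF", "PF", "C")

  ## persistent athlete roster: identity, position, physique
  n_ath <- p$n_teams * p$athletes_per_team
  roster <- data.frame(
    athlete = sprintf("P%03d", seq_len(n_ath)),
    home_team = rep(teams, each = p$athletes_per_team),
    position = positions[(seq_len(n_ath) - 1L) %% 5L + 1L],
    stringsAsFactors = FALSE)
  roster$phys1 <- rnorm(n_ath)           # athlete-level factor-1 skill (z)
  roster$phys2 <- rnorm(n_ath)           # athlete-level factor-2 skill (z)
  roster$age0 <- round(28.73 + 4.46 * p$noise_scale * rnorm(n_ath))
  rr <- p$rookie_rate
  roster$rookie_season <- if (rr == 0) rep(0L, n_ath) else
    sample.int(p$n_seasons + 1L, n_ath, replace = TRUE,
               prob = c(rep(rr, p$n_seasons), 1 - rr * p$n_seasons))

  rows <- vector("list", p$n_seasons)
  latent <- vector("list", p$n_seasons)
  for (si in seq_len(p$n_seasons)) {
    u_season <- rnorm(2, 0, p$sd_season)        # one per latent factor
    u_team <- matrix(rnorm(2 * p$n_teams, 0, p$sd_team), ncol = 2,
                     dimnames = list(teams, NULL))
    ## units: every athlete on their home team; traded athletes add a
    ## second unit on another team
    units <- data.frame(athlete = roster$athlete, team = roster$home_team,
                        position = roster$position, stringsAsFactors = FALSE)
    n_trade <- floor(p$trade_fraction * n_ath)
    if (n_trade > 0 && p$n_teams > 1) {
      traded <- sample.int(n_ath, n_trade)
      second <- vapply(roster$home_team[traded], function(tm)
        sample(setdiff(teams, tm), 1), character(1))
      units <- rbind(units,
                     data.frame(athlete = roster$athlete[traded], team = second,
                                position = roster$position[traded],
                                stringsAsFactors = FALSE))
    }
    m <- nrow(units)
    idx <- match(units$athlete, roster$athlete)
    u_unit <- matrix(rnorm(2 * m, 0, p$sd_athlete), ncol = 2)
    L <- sample(seq(p$games_range[1], p$games_range[2]), m, replace = TRUE)

    per_unit <- vector("list", m)
    per_lat <- vector("list", m)
    for (u in seq_len(m)) {
      games <- sort(sample.int(82L, L[u]))
      venue <- ifelse(games %% 2L == 0L, "home", "away")
      rookie <- roster$rookie_season[idx[u]] == si
      pos <- units$position[u]
      e_game <- matrix(rnorm(2 * L[u], 0, p$sd_resid), ncol = 2)
      ## standardised hierarchical latent factors per game
      g1 <- (u_season[1] + u_team[units$team[u], 1] + u_unit[u, 1] +
               e_game[, 1]) / c_norm
      g2 <- (u_season[2] + u_team[units$team[u], 2] + u_unit[u, 2] +
               e_game[, 2]) / c_norm
      sh <- p$factor_shifts
      d1 <- sh$position1[[pos]]
      d2 <- sh$position2[[pos]] + if (rookie) sh$rookie2 else 0
      d2 <- d2 + ifelse(venue == "home", sh$venue2, 0)
      f1 <- d1 + g1 * p$noise_scale
      f2 <- d2 + g2 * p$noise_scale

      lat_gauss <- function(v, fa1, fa2) {
        l1 <- load[v, 1]; l2 <- load[v, 2]
        tau <- sqrt(max(0, 1 - l1^2 - l2^2))
        anchor[v, "mean"] + anchor[v, "sd"] *
          (l1 * fa1 + l2 * fa2 + tau * p$noise_scale * rnorm(L[u]))
      }
      cnt <- function(x) pmax(0L, as.integer(round(x)))

      ## static physique: constant within athlete-season
      ph1 <- roster$phys1[idx[u]] * p$noise_scale
      ph2 <- roster$phys2[idx[u]] * p$noise_scale
      height <- cnt(anchor["Height", "mean"] + anchor["Height", "sd"] *
                      (load["Height", 1] * (p$factor_shifts$position1[[pos]] + ph1) +
                         sqrt(1 - load["Height", 1]^2) * ph2))
      weight <- cnt(anchor["Weight", "mean"] + anchor["Weight", "sd"] *
                      (load["Weight", 1] * (p$factor_shifts$position1[[pos]] + ph1) +
                         sqrt(1 - load["Weight", 1]^2) * ph1))
      age <- max(19L, roster$age0[idx[u]])

      fg2a <- cnt(lat_gauss("Fg2PtAtt", f1, f2))
      fg3a <- cnt(lat_gauss("Fg3PtAtt", f1, f2))
      fta <- cnt(lat_gauss("FtAtt", f1, f2))
      rate <- .shot_rates()
      pr <- function(base, f) pmin(0.99, pmax(0.01, base + 0.08 * f))
      fg2m <- pmin(fg2a, cnt(fg2a * pr(rate["Fg2"], f2)))
      fg3m <- pmin(fg3a, cnt(fg3a * pr(rate["Fg3"], f2)))
      ftm <- pmin(fta, cnt(fta * pr(rate["Ft"], f2)))

      oreb <- cnt(lat_gauss("OffReb", f1, f2))
      dreb <- cnt(lat_gauss("DefReb", f1, f2))
      ast <- cnt(lat_gauss("Ast", f1, f2))
      tov <- cnt(lat_gauss("Tov", f1, f2))
      stl <- cnt(lat_gauss("Stl", f1, f2))
      blk <- cnt(lat_gauss("Blk", f1, f2))
      blka <- cnt(lat_gauss("BlkAgainst", f1, f2))
      mins <- cnt(lat_gauss("MinSeconds", f1, f2))
      fouls <- cnt(lat_gauss("Fouls", f1, f2))
      fdrawn <- cnt(lat_gauss("FoulsDrawn", f1, f2))

      per_unit[[u]] <- data.frame(
        season = seasons[si], team = units$team[u],
        athlete = units$athlete[u], game = games,
        venue = venue, position = pos, rookie = rookie,
        Height = height, Weight = weight, Age = age,
        Fg2PtAtt = fg2a, Fg2PtMade = fg2m,
        Fg3PtAtt = fg3a, Fg3PtMade = fg3m,
        FgAtt = fg2a + fg3a, FgMade = fg2m + fg3m,
        FtAtt = fta, FtMade = ftm,
        OffReb = oreb, DefReb = dreb, Ast = ast,
        Pts = 2L * fg2m + 3L * fg3m + ftm,
        Tov = tov, Stl = stl, Blk = blk, BlkAgainst = blka,
        MinSeconds = mins, Fouls = fouls, FoulsDrawn = fdrawn,
        stringsAsFactors = FALSE)
      ## latent score on the score scale: mean of the two factor chains
      per_lat[[u]] <- data.frame(
        season = seasons[si], team = units$team[u],
        athlete = units$athlete[u], game = games,
        latent = p$fixed_effects$intercept +
          (u_season[1] + u_team[units$team[u], 1] + u_unit[u, 1] +
             e_game[, 1]),
        stringsAsFactors = FALSE)
    }
    rows[[si]] <- do.call(rbind, per_unit)
    latent[[si]] <- do.call(rbind, per_lat)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  lat <- do.call(rbind, latent)
  rownames(lat) <- NULL
  attr(out, "truth") <- list(params = p, latent = lat)
  class(out) <- c("game_log", class(out))
  out
}

#' Simulate composite scores from the three-level model
#'
#' Draws the per-observation composite score exactly from the three-level
#' random-intercept model: fixed part `X beta` plus season, team-within-
#' season and athlete-within-team-within-season random intercepts plus
#' i.i.d. Gaussian error, using the standard deviations stored in
#' `params`. The drawn random effects and the coefficient vector are
#' recorded in `attr(x, "truth")` for recovery tests.
#'
#' @param params an [on_sim_params()] object (supplies the variance truth
#'   and the seed).
#' @param design an `on_design` object from [build_design()]; its rows
#'   carry the hierarchy ids.
#' @param beta coefficient vector: `NULL` (intercept = the params
#'   intercept, all else 0), a full unnamed vector of length
#'   `ncol(design$X)`, or a named vector whose names are a subset of the
#'   design columns.
#' @return a `data.frame` with the hierarchy keys and the simulated
#'   `score` column; truth attached as attribute `"truth"`.
#' @export
simulate_on_response <- function(params, design, beta = NULL) {
  stopifnot(inherits(params, "on_sim_params"), inherits(design, "on_design"))
  p <- params
  X <- design$X
  full <- setNames(numeric(ncol(X)), colnames(X))
  if (is.null(beta)) {
    full["(Intercept)"] <- p$fixed_effects$intercept
    if (!is.null(p$fixed_effects$beta)) beta <- p$fixed_effects$beta
  }
  if (!is.null(beta)) {
    if (is.null(names(beta))) {
      if (length(beta) != ncol(X))
        stop(sprintf("coefficient vector has length %d but the design has %d columns",
                     length(beta), ncol(X)), call. = FALSE)
      full[] <- beta
    } else {
      bad <- setdiff(names(beta), colnames(X))
      if (length(bad))
        stop("unknown coefficient(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      full[names(beta)] <- beta
    }
  }
  set.seed(p$seed)
  g <- design$groups
  season_f <- factor(g$season)
  team_f <- .team_factor(g)
  unit_f <- g$unit
  b_season <- setNames(rnorm(nlevels(season_f), 0, p$sd_season),
                       levels(season_f))
  b_team <- setNames(rnorm(nlevels(team_f), 0, p$sd_team), levels(team_f))
  b_unit <- setNames(rnorm(nlevels(unit_f), 0, p$sd_athlete), levels(unit_f))
  eps <- rnorm(nrow(X), 0, p$sd_resid)
  score <- drop(X %*% full) + b_season[season_f] + b_team[team_f] +
    b_unit[unit_f] + eps
  out <- cbind(g[intersect(c("season", "team", "athlete", "game"), names(g))],
               score = unname(score))
  rownames(out) <- NULL
  attr(out, "truth") <- list(beta = full, b_season = b_season,
                             b_team = b_team, b_unit = b_unit, params = p)
  out
}
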