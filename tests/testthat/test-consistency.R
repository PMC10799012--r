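## a hand-built on_lmm shell so the closed forms can be driven directly
fake_fit <- function(y, season, team, athlete, components,
                     beta = 0, structure = "full") {
  dat <- data.frame(season = season, team = team, athlete = athlete,
                    stringsAsFactors = FALSE)
  dat$.unit <- interaction(dat$season, dat$team, dat$athlete,
                           drop = TRUE, sep = ":")
  dat$.team <- interaction(dat$season, dat$team, drop = TRUE, sep = ":")
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- list(components = components, beta_hat = c("(Intercept)" = beta),
              structure = structure,
              design = list(y = y, X = X, data = dat,
                            groups = data.frame(season = dat$season,
                                                team = dat$team,
                                                athlete = dat$athlete,
                                                unit = dat$.unit)))
  class(fit) <- "on_lmm"
  fit
}

test_that("the single-group worked example gives CS = 2/3", {
  ## one athlete, L = 2, sigma_athlete^2 = 1, sigma^2 = 1, residuals
  ## (1, 1): V = [[2, 1], [1, 2]], CS = 1 * [1,1] V^-1 [1,1]' = 2/3
  fit <- fake_fit(c(1, 1), c("S1", "S1"), c("T1", "T1"), c("A", "A"),
                  c(season = 0, team = 0, athlete = 1, residual = 1))
  cs <- consistency_scores(fit, "athlete")
  expect_equal(cs$score, 2 / 3, tolerance = 1e-12)
  ## dense-matrix confirmation
  V <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(cs$score, drop(1 * crossprod(c(1, 1), solve(V, c(1, 1)))),
               tolerance = 1e-12)
})

test_that("zero residuals give zero consistency scores at every level", {
  fit <- small_fit(seed = 41, sd_team = 0.1, structure = "full")
  fit$design$y <- drop(fit$design$X %*% fit$beta_hat)  # residuals all 0
  for (lv in c("athlete", "team", "season"))
    expect_equal(consistency_scores(fit, lv)$score,
                 rep(0, nrow(consistency_scores(fit, lv))))
})

test_that("closed-form scores equal a dense-matrix V inversion at all levels", {
  fit <- small_fit(seed = 42, sd_team = 0.12, structure = "full")
  V <- dense_V(fit)
  v <- fit$components
  d <- fit$design
  r <- d$y - drop(d$X %*% fit$beta_hat)
  fs <- factor(d$groups$season); ft <- d$data$.team; fu <- d$groups$unit

  cs_s <- consistency_scores(fit, "season")
  dense_s <- vapply(cs_s$season, function(s) {
    i <- fs == s; v[["season"]] * sum(solve(V[i, i], r[i])) }, numeric(1))
  expect_equal(cs_s$score, unname(dense_s), tolerance = 1e-10)

  cs_t <- consistency_scores(fit, "team")
  dense_t <- vapply(seq_len(nrow(cs_t)), function(k) {
    i <- ft == paste(cs_t$season[k], cs_t$team[k], sep = ":")
    v[["team"]] * sum(solve(V[i, i], r[i])) }, numeric(1))
  expect_equal(cs_t$score, dense_t, tolerance = 1e-10)

  cs_a <- consistency_scores(fit, "athlete")
  dense_a <- vapply(seq_len(nrow(cs_a)), function(k) {
    i <- fu == paste(cs_a$season[k], cs_a$team[k], cs_a$athlete[k],
                     sep = ":")
    v[["athlete"]] * sum(solve(V[i, i], r[i])) }, numeric(1))
  expect_equal(cs_a$score, dense_a, tolerance = 1e-10)

  ## conditional variances against the dense posterior formula
  cv_a <- attr(cs_a, "condvar")
  dense_cv <- vapply(seq_len(nrow(cs_a)), function(k) {
    i <- fu == paste(cs_a$season[k], cs_a$team[k], cs_a$athlete[k],
                     sep = ":")
    v[["athlete"]] - v[["athlete"]]^2 *
      sum(solve(V[i, i], rep(1, sum(i)))) }, numeric(1))
  expect_equal(cv_a, dense_cv, tolerance = 1e-10)
})

test_that("per-group empirical Bayes equals the joint BLUP when levels collapse", {
  ## in a single-level model the per-group conditioning and the joint
  ## mixed-model equations coincide, so lme4's ranef is an oracle
  set.seed(43)
  un <- rep(sprintf("A%02d", 1:15), times = sample(4:9, 15, replace = TRUE))
  y <- rnorm(length(un), rep(rnorm(15, 0, 0.5),
                             times = table(factor(un, unique(un)))), 0.8)
  m <- lme4::lmer(y ~ 1 + (1 | un))
  comps <- c(season = 0, team = 0,
             athlete = unname(attr(lme4::VarCorr(m)$un, "stddev"))^2,
             residual = sigma(m)^2)
  fit <- fake_fit(y, rep("S1", length(y)), rep("T1", length(y)), un,
                  comps, beta = unname(lme4::fixef(m)))
  cs <- consistency_scores(fit, "athlete")
  re <- lme4::ranef(m)$un
  expect_equal(cs$score, re[cs$athlete, 1], tolerance = 1e-8)
})

test_that("BLUP shrinkage bounds every score by its raw group mean residual", {
  fit <- small_fit(seed = 44)
  d <- fit$design
  r <- d$y - drop(d$X %*% fit$beta_hat)
  raw <- tapply(r, d$groups$unit, mean)
  cs <- consistency_scores(fit, "athlete")
  key <- paste(cs$season, cs$team, cs$athlete, sep = ":")
  expect_true(all(abs(cs$score) <= abs(raw[key]) + 1e-12))
  ## strict shrinkage away from the degenerate sigma^2 = 0 case
  expect_true(all(abs(cs$score) < abs(raw[key]) |
                    abs(raw[key]) < 1e-12))
})

test_that("Monte-Carlo intervals are seeded, ordered and shrink with games", {
  ## ladder of group sizes with identical residual means
  L <- c(2, 10, 50)
  y <- unlist(lapply(L, function(l) rep(0.5, l)))
  fit <- fake_fit(y, rep("S1", sum(L)), rep("T1", sum(L)),
                  rep(c("A2", "B10", "C50"), L),
                  c(season = 0, team = 0, athlete = 0.4, residual = 1))
  cs1 <- consistency_scores(fit, "athlete",
                            ci = list(n_sim = 4000, seed = 9))
  cs2 <- consistency_scores(fit, "athlete",
                            ci = list(n_sim = 4000, seed = 9))
  expect_identical(cs1, cs2)
  expect_true(all(cs1$lower <= cs1$upper))
  width <- (cs1$upper - cs1$lower)[order(cs1$games)]
  expect_true(all(diff(width) < 0))
  ## conditional variance decreases in L exactly
  cv <- attr(cs1, "condvar")[order(cs1$games)]
  expect_true(all(diff(cv) < 0))
})

test_that("athlete scores centre near zero", {
  fit <- small_fit(I = 3, J = 4, K = 6, Lmin = 10, Lmax = 20, seed = 46)
  cs <- consistency_scores(fit, "athlete")
  ## the distribution of athlete scores is centred at 0 relative to its
  ## own spread (individual teams fluctuate by ~ sd/sqrt(K))
  expect_lt(abs(mean(cs$score)), 3 * sd(cs$score) / sqrt(nrow(cs)))
  expect_lt(abs(stats::weighted.mean(cs$score, cs$games)),
            3 * sd(cs$score) / sqrt(nrow(cs)))
})

test_that("team-level scores are refused under the reduced structure", {
  fit <- small_fit(seed = 47, structure = "reduced")
  expect_error(consistency_scores(fit, "team"), "no team component")
})
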