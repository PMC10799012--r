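test_that("REML matches nested-ANOVA moment estimators on a balanced design", {
  I <- 6; K <- 8; n <- 10
  sk <- do.call(rbind, lapply(1:I, function(i)
    do.call(rbind, lapply(1:K, function(k)
      data.frame(season = sprintf("S%d", i), team = "T1",
                 athlete = sprintf("A%d_%d", i, k), game = 1:n)))))
  set.seed(99)
  sk$score <- rep(rnorm(I, 0, 0.6), each = K * n) +
    rep(rnorm(I * K, 0, 0.5), each = n) + rnorm(I * K * n, 0, 0.8)
  des <- build_design(sk, ~ 1)
  fit <- fit_reml(des, "reduced")
  ## hand-computed nested mean squares (method-of-moments oracle)
  y <- sk$score
  mu_i <- tapply(y, sk$season, mean)
  un <- interaction(sk$season, sk$athlete, drop = TRUE)
  mu_ik <- tapply(y, un, mean)
  msa <- K * n * sum((mu_i - mean(y))^2) / (I - 1)
  msb <- n * sum((mu_ik - rep(mu_i, each = K))^2) / (I * (K - 1))
  mse <- sum((y - ave(y, un))^2) / (I * K * (n - 1))
  oracle <- c(season = (msa - msb) / (K * n), athlete = (msb - mse) / n,
              residual = mse)
  expect_equal(fit$components[c("season", "athlete", "residual")], oracle,
               tolerance = 1e-5)
  ## dual route: independent closed-form REML optimiser agrees with lme4
  alt <- onscore:::.nested_reml_fit(des$y, des$X, factor(des$groups$season),
                                    des$groups$unit)
  expect_equal(unname(alt$vars),
               unname(fit$components[c("season", "athlete", "residual")]),
               tolerance = 1e-4)
  expect_equal(alt$logLik, fit$logLik, tolerance = 1e-6)
  ## Satterthwaite df of the grand mean in this balanced layout is the
  ## between-season df, I - 1
  expect_equal(unname(summary(fit$model)$coefficients[1, "df"]), I - 1,
               tolerance = 0.01)
})

test_that("identical group means put the between-group components at the boundary", {
  sk <- skeleton_table(3, 3, 4, 6, 10, seed = 4)
  set.seed(8)
  sk$score <- rnorm(nrow(sk))
  un <- interaction(sk$season, sk$team, sk$athlete, drop = TRUE)
  sk$score <- sk$score - ave(sk$score, un)   # every unit mean exactly 0
  fit <- fit_reml(build_design(sk, ~ 1), "reduced")
  expect_lt(fit$components[["athlete"]], 1e-8)
  expect_lt(fit$components[["season"]], 1e-8)
})

test_that("ICC is the cumulative variance share with its invariants", {
  ic <- icc(c(1, 1, 1, 1))
  expect_equal(ic$icc, c(0.25, 0.5, 0.75))
  set.seed(2)
  for (i in 1:20) {
    v <- rexp(4)
    ici <- icc(v)$icc
    expect_true(all(diff(ici) >= 0) && all(ici >= 0 & ici <= 1))
    expect_equal(ici[3], sum(v[1:3]) / sum(v))
  }
  expect_error(icc(c(0, 0, 0, 0)), "total variance")
  expect_error(icc(c(-1, 1, 1, 1)), "non-negative")
})

test_that("boundary LRT is clipped at zero and rejects mismatched fits", {
  fit <- small_fit(seed = 6)
  ful <- fit_reml(fit$design, "full")
  lrt <- lrt_variance_component(ful, fit)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p.value >= 0 && lrt$p.value <= 1)
  ## zero statistic (team variance at boundary) gives p = 1
  if (lrt$statistic < 1e-10) expect_equal(lrt$p.value, 1)
  ## mismatched fixed effects rejected
  sk <- fit$design$data
  des2 <- build_design(sk, ~ 1)
  red2 <- fit_reml(des2, "reduced")
  expect_error(lrt_variance_component(ful, red2), "same fixed effects")
  expect_error(lrt_variance_component(fit, fit), "nested")
})

test_that("coefficient t tests carry finite Satterthwaite df and honest size", {
  fit <- small_fit(I = 3, J = 5, K = 5, seed = 16, fixed = ~ venue)
  tt <- satterthwaite_tests(fit)
  expect_true(all(is.finite(tt$coefficients$df)))
  expect_true(all(tt$coefficients$df > 0))
  expect_true(all(tt$coefficients$p >= 0 & tt$coefficients$p <= 1))
  expect_true(!is.null(tt$anova))

  ## size of the venue test under a null venue effect: 300 replicates;
  ## nominal 0.05, binomial 95% band 0.05 +/- 2*sqrt(.05*.95/300)
  nrep <- 300
  sk <- skeleton_table(3, 5, 4, 6, 10, seed = 71)
  des0 <- build_design(sk, ~ venue)
  pvals <- vapply(seq_len(nrep), function(r) {
    p <- on_sim_params(n_seasons = 3, n_teams = 5, athletes_per_team = 4,
                       sd_season = 0.07, sd_team = 0, sd_athlete = 0.087,
                       sd_resid = 0.11, seed = onscore:::.sub_seed(11, r))
    resp <- simulate_on_response(p, des0, beta = c("(Intercept)" = 1))
    sk$score <- resp$score
    f <- suppressWarnings(fit_reml(build_design(sk, ~ venue), "reduced"))
    satterthwaite_tests(f, type3 = FALSE)$coefficients["venue1", "p"]
  }, numeric(1))
  size <- mean(pvals < 0.05)
  expect_lt(abs(size - 0.05), 2 * sqrt(0.05 * 0.95 / nrep) + 1e-9)
})

test_that("top-down selection drops a boundary team component and null effects", {
  ## single candidate returns unchanged with a trivial trace
  fit <- small_fit(seed = 18)
  sel1 <- select_model(fit$design, structures = "reduced",
                       fixed_search = FALSE)
  expect_identical(sel1$fit$structure, "reduced")
  expect_identical(sel1$trace$action[1], "single candidate")

  ## zero generating team variance: structure LRT keeps the reduced
  ## model and BIC removes the null venue effect (one realisation)
  sk <- skeleton_table(3, 6, 5, 10, 16, seed = 201)
  des0 <- build_design(sk, ~ venue)
  p <- on_sim_params(n_seasons = 3, n_teams = 6, athletes_per_team = 5,
                     sd_season = 0.1, sd_team = 0, sd_athlete = 0.1,
                     sd_resid = 0.15, seed = 301)
  resp <- simulate_on_response(p, des0, beta = c("(Intercept)" = 1))
  sk$score <- resp$score
  sel <- select_model(build_design(sk, ~ venue))
  expect_identical(sel$fit$structure, "reduced")
  expect_false("venue" %in%
                 attr(terms(sel$fit$design$fixed), "term.labels"))
  expect_true(all(c("structure", "final") %in% sel$trace$step))

  ## a strong real effect survives the BIC step
  resp2 <- simulate_on_response(p, des0,
                                beta = c("(Intercept)" = 1, venue1 = 0.2))
  sk$score <- resp2$score
  sel2 <- select_model(build_design(sk, ~ venue))
  expect_true("venue" %in%
                attr(terms(sel2$fit$design$fixed), "term.labels"))
})

test_that("predictions respect conditioning mode and new levels", {
  fit <- small_fit(I = 3, J = 4, K = 4, seed = 23, fixed = ~ venue)
  dat <- fit$design$data
  ## conditional predictions at training rows equal fitted values
  expect_equal(predict(fit, dat[5:10, ], mode = "conditional"),
               unname(fitted(fit)[5:10]), tolerance = 1e-10)
  ## population prediction for a brand-new season is X beta only
  nd <- data.frame(season = "S99", team = "T99", athlete = "ZZ",
                   venue = "home")
  Xb <- unname(drop(cbind(1, -1) %*% fit$beta_hat))  # home = -1 in contr.sum
  expect_equal(predict(fit, nd, mode = "population"), Xb,
               tolerance = 1e-10)
  ## a new unit's conditional prediction collapses to the population one
  expect_equal(predict(fit, nd, mode = "conditional"),
               predict(fit, nd, mode = "population"))

  ## bootstrap intervals: deterministic under a seed and ordered
  pr1 <- predict(fit, nd, mode = "population", interval = "bootstrap",
                 B = 60, seed = 2)
  pr2 <- predict(fit, nd, mode = "population", interval = "bootstrap",
                 B = 60, seed = 2)
  expect_identical(pr1, pr2)
  expect_lt(pr1$lwr, pr1$upr)
  expect_error(predict(fit, nd, mode = "conditional",
                       interval = "bootstrap"), "population")
})

test_that("population bootstrap intervals cover the true mean at close to nominal rate", {
  ## 50 replicates at B = 99: binomial 95% band 0.95 +/- 2*sqrt(.95*.05/50)
  ## (4 seasons so the season-level uncertainty is estimable; percentile
  ## bootstrap undercovers badly with 2 seasons)
  nrep <- 50
  sk <- skeleton_table(4, 3, 3, 4, 8, seed = 31)
  des0 <- build_design(sk, ~ venue)
  truth_home <- 1 - 0.1  # intercept 1, venue1 (away) +0.1 => home -0.1
  nd <- data.frame(season = "SNEW", team = "TNEW", athlete = "ANEW",
                   venue = "home")
  hits <- vapply(seq_len(nrep), function(r) {
    p <- on_sim_params(n_seasons = 4, n_teams = 3, athletes_per_team = 3,
                       sd_season = 0.1, sd_team = 0, sd_athlete = 0.15,
                       sd_resid = 0.2, seed = onscore:::.sub_seed(19, r))
    resp <- simulate_on_response(p, des0,
                                 beta = c("(Intercept)" = 1, venue1 = 0.1))
    sk$score <- resp$score
    f <- suppressWarnings(fit_reml(build_design(sk, ~ venue), "reduced"))
    pr <- predict(f, nd, mode = "population", interval = "bootstrap",
                  B = 99, seed = r)
    pr$lwr <= truth_home && truth_home <= pr$upr
  }, logical(1))
  expect_gt(mean(hits), 0.95 - 2 * sqrt(0.95 * 0.05 / nrep))
})

test_that("marginal covariance implied by the components matches the blocks", {
  fit <- small_fit(seed = 26)
  V <- dense_V(fit)
  v <- fit$components
  expect_equal(unname(diag(V)),
               rep(sum(v), nrow(fit$design$X)), tolerance = 1e-12)
  ## off-diagonal within a unit: season + team + athlete variance
  fu <- fit$design$groups$unit
  i <- which(fu == fu[1])
  expect_equal(V[i[1], i[2]], sum(v[c("season", "team", "athlete")]),
               tolerance = 1e-12)
})
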