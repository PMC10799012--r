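## Closed-form REML machinery for nested random-intercept models.
##
## The marginal covariance of a nested random-intercept model is
## V = sigma2*I + sum_k v_k * sum_b 1_b 1_b^T over the blocks b of level
## k. Because the levels are nested, V^{-1} applied to any vector can be
## accumulated level by level with a rank-one (Sherman-Morrison) update
## per block, in O(n) per level; the log-determinant accumulates the
## same way. This gives an independent O(n) REML objective used as a
## cross-check for the lme4-based fits and as the engine for
## profile-likelihood intervals in recovery studies.

## yX: cbind(X, y); levels: list of list(f = factor, v = variance >= 0),
## innermost first. Returns logdet(V) and crossprod(cbind(X, y), V^{-1}
## cbind(X, y)).
.nested_quad <- function(yX, sigma2, levels) {
  n <- nrow(yX)
  R <- yX / sigma2
  W <- rep(1 / sigma2, n)
  logdet <- n * log(sigma2)
  for (lv in levels) {
    if (lv$v <= 0) next
    f <- lv$f
    S <- rowsum(R, f, reorder = FALSE)
    d <- rowsum(W, f, reorder = FALSE)[, 1L]
    denom <- 1 + lv$v * d
    logdet <- logdet + sum(log(denom))
    idx <- match(f, rownames(S))
    R <- R - lv$v * W * (S / denom)[idx, , drop = FALSE]
    W <- W / denom[idx]
  }
  list(logdet = logdet, C = crossprod(yX, R))
}

## Restricted log-likelihood of the nested model at the given variances.
## vars: named or positional c(season, team, athlete); team may be
## omitted/0. Matches lme4's REML logLik definition.
.nested_reml_loglik <- function(vars, sigma2, y, X, season, unit,
                                team = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(y)
  lv <- list(list(f = unit, v = vars[["athlete"]]))
  if (!is.null(team)) lv <- c(lv, list(list(f = team, v = vars[["team"]])))
  lv <- c(lv, list(list(f = season, v = vars[["season"]])))
  q <- .nested_quad(cbind(X, y), sigma2, lv)
  C <- q$C
  XtViX <- C[seq_len(p), seq_len(p), drop = FALSE]
  XtViy <- C[seq_len(p), p + 1L]
  ytViy <- C[p + 1L, p + 1L]
  ch <- chol(XtViX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
  rVr <- ytViy - sum(XtViy * beta)
  -0.5 * (q$logdet + 2 * sum(log(diag(ch))) + rVr + (n - p) * log(2 * pi))
}

## -2 * restricted log-likelihood on the log-variance scale (3 free
## parameters: season, athlete, residual), reduced structure
.nested_dev3 <- function(lpar, y, X, season, unit) {
  v <- unname(exp(lpar))
  -2 * .nested_reml_loglik(c(season = v[1], athlete = v[2]), v[3],
                           y, X, season, unit)
}

## REML fit of the reduced nested model by direct optimisation of the
## closed-form objective (independent of lme4)
.nested_reml_fit <- function(y, X, season, unit, start = NULL) {
  if (is.null(start)) {
    vt <- var(y)
    start <- log(c(0.15 * vt, 0.35 * vt, 0.5 * vt))
  }
  opt <- optim(start, .nested_dev3, y = y, X = X, season = season,
               unit = unit, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  list(vars = setNames(exp(opt$par), c("season", "athlete", "residual")),
       deviance = opt$value, logLik = -opt$value / 2,
       convergence = opt$convergence)
}

## Membership check: is each true variance inside the profile-likelihood
## interval? Equivalent to computing the interval bounds (truth is inside
## iff the profiled deviance at the truth is within qchisq(level, 1) of
## the minimum) but needs only one inner optimisation per component, so
## it scales to replicated recovery studies.
.profile_covers <- function(y, X, season, unit, truth, level = 0.95,
                            start = NULL) {
  fit <- .nested_reml_fit(y, X, season, unit,
                          start = if (is.null(start)) NULL else log(start))
  lhat <- log(fit$vars)
  qc <- qchisq(level, 1)
  covered <- vapply(1:3, function(k) {
    obj <- function(lo) {
      lp <- numeric(3)
      lp[k] <- log(truth[k])
      lp[-k] <- lo
      .nested_dev3(lp, y, X, season, unit)
    }
    dev_p <- optim(lhat[-k], obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-8, maxit = 500))$value
    dev_p - fit$deviance <= qc
  }, logical(1))
  list(estimate = fit$vars, covered = covered)
}

## Profile-likelihood confidence intervals for the three variance
## parameters of the reduced structure. Profiles the closed-form REML
## deviance over the remaining parameters; bounds that run into the
## boundary are reported as 0.
.nested_profile_ci <- function(y, X, season, unit, level = 0.95,
                               start = NULL) {
  fit <- .nested_reml_fit(y, X, season, unit,
                          start = if (is.null(start)) NULL else log(start))
  lhat <- log(fit$vars)
  devmin <- fit$deviance
  thresh <- devmin + qchisq(level, 1)
  prof_dev <- function(k, lval) {
    others <- lhat[-k]
    obj <- function(lo) {
      lp <- numeric(3)
      lp[k] <- lval
      lp[-k] <- lo
      .nested_dev3(lp, y, X, season, unit)
    }
    optim(others, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-10, maxit = 1000))$value
  }
  one_bound <- function(k, dir) {
    g <- function(lv) prof_dev(k, lv) - thresh
    stp <- 0.5
    a <- lhat[k]
    repeat {
      b <- a + dir * stp
      gb <- g(b)
      if (gb > 0) break
      a <- b
      stp <- stp * 1.7
      if (dir < 0 && b < lhat[k] - 18) return(0)       # boundary: v -> 0
      if (dir > 0 && b > lhat[k] + 18) return(Inf)
    }
    exp(uniroot(g, sort(c(a, b)), tol = 1e-4)$root)
  }
  ci <- t(vapply(1:3, function(k) c(one_bound(k, -1), one_bound(k, 1)),
                 numeric(2)))
  dimnames(ci) <- list(c("season", "athlete", "residual"),
                       c("lower", "upper"))
  list(estimate = fit$vars, ci = ci, logLik = fit$logLik)
}
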