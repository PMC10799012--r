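#' Fit the three-level random-intercept model by REML
#'
#' Fits the composite score with random intercepts for season, team
#' within season and athlete within team within season (`structure =
#' "full"`), or with the team component dropped (`structure = "reduced"`,
#' the default final structure when the team component is estimated at
#' the boundary). Variance components are estimated by REML, fixed
#' effects by GLS at the fitted components (BLUE), and random effects by
#' empirical-Bayes prediction (BLUP).
#'
#' @param design an `on_design` object from [build_design()].
#' @param structure `"reduced"` (season + athlete unit) or `"full"`
#'   (season + team + athlete unit).
#' @param control optional [lme4::lmerControl()] object.
#' @return an object of class `on_lmm`; see Details.
#' @details The returned list carries `components` (named variances
#'   `season`, `team`, `athlete`, `residual`; `team` is 0 in the reduced
#'   structure), `beta` (coefficient table), `blups` (per-level
#'   empirical-Bayes predictions conditioning on each group's own
#'   observation vector, the closed form used by [consistency_scores()]),
#'   `ranef_joint` (the joint-conditioning BLUPs from the mixed-model
#'   equations), the restricted log-likelihood, a convergence flag, and
#'   the fitted `lmerMod` in `$model`.
#' @export
fit_reml <- function(design, structure = c("reduced", "full"),
                     control = NULL) {
  stopifnot(inherits(design, "on_design"))
  structure <- match.arg(structure)
  if (nlevels(factor(design$groups$season)) < 2 ||
      nlevels(design$groups$unit) < 2)
    stop("need at least 2 groups at each modelled level", call. = FALSE)
  if (structure == "full" && nlevels(design$data$.team) < 2)
    stop("full structure needs at least 2 team-season groups", call. = FALSE)
  rand <- if (structure == "full")
    "(1 | season) + (1 | .team) + (1 | .unit)"
  else
    "(1 | season) + (1 | .unit)"
  fml <- stats::as.formula(
    paste(design$response, "~",
          deparse(design$fixed[[2]], width.cutoff = 500L), "+", rand),
    env = globalenv())
  if (is.null(control))
    control <- lme4::lmerControl(check.conv.singular = "ignore")
  model <- lmerTest::lmer(fml, data = design$data, REML = TRUE,
                          contrasts = design$contrasts, control = control)
  ## self-contained call so update()/bootMer() work outside this scope
  model@call$data <- design$data
  model@call$control <- control
  if (!is.null(design$contrasts)) model@call$contrasts <- design$contrasts
  out <- .as_on_lmm(model, design, structure)
  out
}

## package an lmerMod into the on_lmm structure
.as_on_lmm <- function(model, design, structure) {
  vc <- lme4::VarCorr(model)
  comp <- c(season = unname(attr(vc$season, "stddev"))^2,
            team = if (structure == "full")
              unname(attr(vc$.team, "stddev"))^2 else 0,
            athlete = unname(attr(vc$.unit, "stddev"))^2,
            residual = stats::sigma(model)^2)
  sm <- summary(model)
  beta <- as.data.frame(sm$coefficients)
  beta_hat <- lme4::fixef(model)
  conv <- length(model@optinfo$conv$lme4$messages) == 0 &&
    model@optinfo$conv$opt == 0
  out <- list(model = model, structure = structure,
              components = comp, beta = beta, beta_hat = beta_hat,
              design = design,
              logLik = as.numeric(logLik(model)),
              converged = conv,
              iterations = model@optinfo$feval,
              ngroups = c(season = nlevels(factor(design$groups$season)),
                          team = nlevels(design$data$.team),
                          athlete = nlevels(design$groups$unit)))
  class(out) <- "on_lmm"
  out$ranef_joint <- lme4::ranef(model)
  out$blups <- list(season = .cs_point(out, "season"),
                    team = if (structure == "full") .cs_point(out, "team"),
                    athlete = .cs_point(out, "athlete"))
  out
}

#' @export
print.on_lmm <- function(x, ...) {
  cat(sprintf("Three-level score model (%s structure, REML)\n", x$structure))
  cat(sprintf("  groups: %d seasons, %d team-seasons, %d athlete units; n = %d\n",
              x$ngroups["season"], x$ngroups["team"], x$ngroups["athlete"],
              nrow(x$design$X)))
  cat("  variance components:\n")
  print(round(x$components, 6))
  ic <- icc(x)
  cat(sprintf("  ICC (cumulative): %.4f / %.4f / %.4f\n",
              ic$icc[1], ic$icc[2], ic$icc[3]))
  if (!x$converged) cat("  WARNING: optimiser did not report clean convergence\n")
  invisible(x)
}

#' @export
summary.on_lmm <- function(object, ...) {
  out <- list(structure = object$structure,
              components = object$components,
              icc = icc(object), beta = object$beta,
              logLik = object$logLik, ngroups = object$ngroups,
              converged = object$converged)
  class(out) <- "summary.on_lmm"
  out
}

#' @export
print.summary.on_lmm <- function(x, ...) {
  cat(sprintf("Three-level score model (%s structure)\n", x$structure))
  cat("\nVariance components:\n"); print(round(x$components, 6))
  cat("\nCumulative intraclass correlations:\n")
  print(x$icc, digits = 4)
  cat("\nFixed effects (Satterthwaite t tests):\n")
  print(round(x$beta, 4))
  cat(sprintf("\nRestricted log-likelihood: %.3f\n", x$logLik))
  invisible(x)
}

#' @export
coef.on_lmm <- function(object, ...) {
  setNames(object$beta[["Estimate"]], rownames(object$beta))
}

#' @export
logLik.on_lmm <- function(object, ...) logLik(object$model)

#' @export
fitted.on_lmm <- function(object, ...) fitted(object$model)

#' @export
residuals.on_lmm <- function(object,
                             type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "conditional") resid(object$model)
  else object$design$y - drop(object$design$X %*% lme4::fixef(object$model))
}

#' @export
simulate.on_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed, ...)
}

#' Intraclass correlation coefficients of the hierarchy
#'
#' Cumulative variance shares: `ICC1 = s1/(s1+s2+s3+s)`,
#' `ICC2 = (s1+s2)/total`, `ICC3 = (s1+s2+s3)/total`, where `s1, s2, s3`
#' are the season, team-within-season and athlete-within-team variance
#' components and `s` the residual variance. In the reduced structure
#' the team component is identically 0, so ICC2 = ICC1.
#'
#' @param object an `on_lmm` or `on_fit` object, or a numeric vector of
#'   the four variance components `(season, team, athlete, residual)`.
#' @param ... unused.
#' @return a `data.frame` of class `on_icc` with columns `level` and
#'   `icc`.
#' @export
#' @examples
#' icc(c(0.005136, 0, 0.007496, 0.012019))
icc <- function(object, ...) UseMethod("icc")

#' @export
icc.numeric <- function(object, ...) {
  if (length(object) != 4 || any(object < 0) || any(!is.finite(object)))
    stop("need 4 finite non-negative variance components (season, team, athlete, residual)",
         call. = FALSE)
  tot <- sum(object)
  if (tot <= 0) stop("total variance is 0; ICC undefined", call. = FALSE)
  out <- data.frame(
    level = c("season", "team_in_season", "athlete_in_team"),
    icc = cumsum(object[1:3]) / tot)
  class(out) <- c("on_icc", "data.frame")
  out
}

#' @export
icc.on_lmm <- function(object, ...) icc(unname(object$components))

#' @export
icc.on_fit <- function(object, ...) icc(object$lmm)

#' Boundary likelihood-ratio test for a variance component
#'
#' Tests whether the team-within-season variance component is zero by
#' comparing the REML log-likelihoods of the full and reduced
#' structures. Because the null value lies on the boundary of the
#' parameter space, the statistic's null distribution is the equal
#' mixture `0.5 chi2_0 + 0.5 chi2_1`.
#'
#' @param full,reduced `on_lmm` fits with identical fixed effects, the
#'   reduced random structure nested in the full one.
#' @return an object of class `on_lrt`: list with `statistic` (clipped
#'   at 0), `p.value`, `structures` and a `df` note.
#' @export
lrt_variance_component <- function(full, reduced) {
  stopifnot(inherits(full, "on_lmm"), inherits(reduced, "on_lmm"))
  if (!(full$structure == "full" && reduced$structure == "reduced"))
    stop("expected a 'full' fit and a nested 'reduced' fit", call. = FALSE)
  f1 <- deparse(full$design$fixed[[2]], width.cutoff = 500L)
  f2 <- deparse(reduced$design$fixed[[2]], width.cutoff = 500L)
  if (!identical(f1, f2))
    stop("the two fits must share the same fixed effects", call. = FALSE)
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  out <- list(statistic = stat, p.value = p,
              structures = c(full = "full", reduced = "reduced"),
              df = "0.5*chisq(0) + 0.5*chisq(1) boundary mixture")
  class(out) <- "on_lrt"
  out
}

#' @export
print.on_lrt <- function(x, ...) {
  cat("Boundary LRT for the team variance component\n")
  cat(sprintf("  statistic = %.4f, p = %.4g (%s)\n",
              x$statistic, x$p.value, x$df))
  invisible(x)
}

#' Satterthwaite tests for the fixed effects
#'
#' Per-coefficient t statistics with Satterthwaite denominator degrees
#' of freedom, and (optionally) the per-term type-III F table under the
#' sum-to-zero contrasts used by [build_design()].
#'
#' @param fit an `on_lmm` object.
#' @param type3 logical; also compute the per-term F table.
#' @return an object of class `on_fixed_tests`: list with
#'   `coefficients` (Estimate, SE, df, t, p) and `anova` (or `NULL`).
#' @export
satterthwaite_tests <- function(fit, type3 = TRUE) {
  stopifnot(inherits(fit, "on_lmm"))
  ct <- as.data.frame(summary(fit$model)$coefficients)
  names(ct) <- c("estimate", "se", "df", "t", "p")
  bad <- !is.finite(ct$df) | ct$df <= 0
  if (any(bad)) {
    rdf <- nrow(fit$design$X) - ncol(fit$design$X)
    warning("non-finite Satterthwaite df for ",
            paste(rownames(ct)[bad], collapse = ", "),
            "; falling back to residual df", call. = FALSE)
    ct$df[bad] <- rdf
    ct$p[bad] <- 2 * stats::pt(abs(ct$t[bad]), rdf, lower.tail = FALSE)
  }
  an <- NULL
  if (type3) {
    an <- tryCatch(
      as.data.frame(stats::anova(fit$model, type = "III",
                                 ddf = "Satterthwaite")),
      error = function(e) NULL)
  }
  out <- list(coefficients = ct, anova = an)
  class(out) <- "on_fixed_tests"
  out
}

#' @export
print.on_fixed_tests <- function(x, ...) {
  cat("Fixed-effect t tests (Satterthwaite df):\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$anova)) {
    cat("\nType III F table (Satterthwaite df):\n")
    print(round(x$anova, 4))
  }
  invisible(x)
}

#' Top-down model selection
#'
#' Selects the random structure first (boundary-aware REML likelihood
#' ratio test of full vs reduced), then refines the fixed effects by
#' backward elimination on BIC using maximum-likelihood refits, and
#' finally refits the chosen model by REML. Every decision is logged in
#' the returned trace.
#'
#' @param design an `on_design` object.
#' @param structures candidate random structures, a subset of
#'   `c("reduced", "full")`.
#' @param fixed_search logical; run the backward BIC refinement.
#' @param alpha significance level for the structure LRT.
#' @return list of class `on_selection` with the final `fit` (an
#'   `on_lmm`) and the decision `trace` (a `data.frame`).
#' @export
select_model <- function(design, structures = c("reduced", "full"),
                         fixed_search = TRUE, alpha = 0.05) {
  stopifnot(inherits(design, "on_design"))
  structures <- match.arg(structures, c("reduced", "full"),
                          several.ok = TRUE)
  if (!length(structures)) stop("empty candidate list", call. = FALSE)
  trace <- list()
  note <- function(step, action, detail, crit = NA_real_) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, action = action, detail = detail, criterion = crit,
      stringsAsFactors = FALSE)
  }
  if (length(unique(structures)) == 1L) {
    structure <- structures[[1L]]
    note("structure", "single candidate", structure)
  } else {
    red <- fit_reml(design, "reduced")
    ful <- fit_reml(design, "full")
    lrt <- lrt_variance_component(ful, red)
    structure <- if (lrt$p.value < alpha) "full" else "reduced"
    note("structure", "boundary LRT full vs reduced",
         sprintf("kept %s (stat=%.4f)", structure, lrt$statistic),
         lrt$p.value)
  }
  fixed <- design$fixed
  if (fixed_search) {
    rand <- if (structure == "full")
      "(1 | season) + (1 | .team) + (1 | .unit)"
    else "(1 | season) + (1 | .unit)"
    ml_fit <- function(rhs) {
      f2 <- stats::as.formula(paste(design$response, "~", rhs, "+", rand),
                              env = globalenv())
      ctr <- design$contrasts[intersect(names(design$contrasts),
                                        all.vars(f2))]
      if (!length(ctr)) ctr <- NULL
      lme4::lmer(f2, data = design$data, REML = FALSE, contrasts = ctr,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    }
    repeat {
      labs <- attr(terms(fixed), "term.labels")
      if (!length(labs)) break
      bic_cur <- BIC(ml_fit(paste(labs, collapse = " + ")))
      drops <- stats::drop.scope(terms(stats::reformulate(labs)))
      if (!length(drops)) break
      cand <- vapply(drops, function(tl) {
        new_labs <- setdiff(labs, tl)
        BIC(ml_fit(if (length(new_labs))
          paste(new_labs, collapse = " + ") else "1"))
      }, numeric(1))
      best <- which.min(cand)
      if (cand[best] < bic_cur) {
        note("fixed", "drop term", names(cand)[best], cand[best])
        labs <- setdiff(labs, names(cand)[best])
        fixed <- stats::as.formula(
          paste("~", if (length(labs)) paste(labs, collapse = " + ") else "1"),
          env = globalenv())
      } else {
        note("fixed", "stop", "no BIC improvement", bic_cur)
        break
      }
    }
  }
  final_design <- if (identical(deparse(fixed), deparse(design$fixed)))
    design
  else build_design(design$data, fixed, design$response)
  fit <- fit_reml(final_design, structure)
  note("final", "REML refit", structure)
  out <- list(fit = fit, trace = do.call(rbind, trace))
  class(out) <- "on_selection"
  out
}

#' @export
print.on_selection <- function(x, ...) {
  cat("Top-down model selection\n")
  print(x$trace)
  cat("\nFinal model:\n")
  print(x$fit)
  invisible(x)
}

#' Predictions from the fitted three-level model
#'
#' `"conditional"` predictions add the BLUPs of every known grouping
#' unit to the fixed part; unknown units (a new athlete, team or season)
#' contribute 0, so a row from an entirely new season reduces to the
#' population prediction `X beta`. `"population"` predictions use the
#' fixed effects only. Percentile confidence intervals for the
#' population prediction are available by parametric bootstrap
#' (simulate from the fitted model, refit, re-predict).
#'
#' @param object an `on_lmm` object.
#' @param newdata `data.frame` carrying the model covariates and, for
#'   conditional predictions, the hierarchy columns.
#' @param mode `"conditional"` or `"population"`.
#' @param interval `"none"` or `"bootstrap"`.
#' @param B number of parametric-bootstrap resamples (default 1000).
#' @param level confidence level for the bootstrap interval.
#' @param seed optional seed for the bootstrap.
#' @param ... unused.
#' @return numeric vector of predictions, or a `data.frame` with
#'   columns `fit`, `lwr`, `upr` when `interval = "bootstrap"`.
#' @export
predict.on_lmm <- function(object, newdata = NULL,
                           mode = c("conditional", "population"),
                           interval = c("none", "bootstrap"),
                           B = 1000, level = 0.95, seed = NULL, ...) {
  mode <- match.arg(mode)
  interval <- match.arg(interval)
  if (is.null(newdata)) {
    nd <- object$design$data
  } else {
    nd <- as.data.frame(newdata)
    for (nm in names(nd))
      if (is.character(nd[[nm]]) || is.logical(nd[[nm]]))
        nd[[nm]] <- factor(nd[[nm]])
    if (all(c("season", "team", "athlete") %in% names(nd))) {
      nd$.unit <- interaction(nd$season, nd$team, nd$athlete,
                              drop = TRUE, sep = ":")
      nd$.team <- interaction(nd$season, nd$team, drop = TRUE, sep = ":")
    } else if (mode == "conditional") {
      stop("conditional predictions need season, team and athlete columns",
           call. = FALSE)
    } else {
      nd$.unit <- factor("new"); nd$.team <- factor("new")
      if (!"season" %in% names(nd)) nd$season <- factor("new")
    }
  }
  re_form <- if (mode == "population") NA else NULL
  pt <- predict(object$model, newdata = nd, re.form = re_form,
                allow.new.levels = TRUE)
  if (interval == "none") return(unname(pt))
  if (mode != "population")
    stop("bootstrap intervals are available for population predictions",
         call. = FALSE)
  bo <- lme4::bootMer(object$model,
                      FUN = function(m) predict(m, newdata = nd,
                                                re.form = NA,
                                                allow.new.levels = TRUE),
                      nsim = B, type = "parametric", seed = seed)
  qs <- apply(bo$t, 2, quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  data.frame(fit = unname(pt), lwr = unname(qs[1, ]), upr = unname(qs[2, ]))
}
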