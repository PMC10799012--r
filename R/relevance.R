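## Relevance scores: per-athlete medians of conditional expected scores
## with Wilcoxon signed-rank confidence intervals.

## positive signed-rank statistic T+ about mu: exact zeros dropped,
## mid-ranks for tied absolute values
.signed_rank_stat <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  if (!length(d)) return(0)
  r <- rank(abs(d))
  sum(r[d > 0])
}

## upper alpha/2 critical point of the exact signed-rank null for n
## observations: smallest t with P(T+ >= t) <= alpha/2
.signed_rank_upper <- function(n, alpha = 0.05) {
  qsignrank(1 - alpha / 2, n) + 1
}

## Tukey construction: CI endpoints are order statistics of the
## M = L(L+1)/2 Walsh averages, at index C = M + 1 - t_{alpha/2} from
## each end. Returns list(lower, upper, degenerate).
.walsh_ci <- function(x, conf.level = 0.95) {
  L <- length(x)
  if (L == 1)
    return(list(lower = x, upper = x, degenerate = TRUE))
  xs <- sort(x)
  w <- sort(c(outer(xs, xs, "+")[upper.tri(diag(L), diag = TRUE)] / 2))
  M <- L * (L + 1) / 2
  t_crit <- .signed_rank_upper(L, 1 - conf.level)
  C <- M + 1 - t_crit
  degenerate <- FALSE
  if (C < 1) {                       # too few games for the nominal level
    C <- 1
    degenerate <- TRUE
  }
  list(lower = w[C], upper = w[M + 1 - C], degenerate = degenerate)
}

## median by the explicit parity rule
.parity_median <- function(zeta) {
  L <- length(zeta)
  z <- sort(zeta)
  if (L %% 2 == 1) z[(L + 1) / 2] else (z[L / 2] + z[L / 2 + 1]) / 2
}

#' Median relevance scores with signed-rank confidence intervals
#'
#' For each athlete unit (athlete within team within season), takes the
#' per-game conditional expected scores from the fitted model (fixed
#' part plus BLUPs), orders them, and reports their median (middle value
#' for an odd number of games, mean of the two middle values for an even
#' number). The `100*(1-alpha)%` confidence interval is the classical
#' signed-rank interval: the `C`-th smallest and `C`-th largest of the
#' `L(L+1)/2` ordered Walsh averages, with `C = L(L+1)/2 + 1 - t_{alpha/2}`
#' and `t_{alpha/2}` the upper critical point of the exact signed-rank
#' null distribution. Units with a single game get a degenerate interval
#' equal to the single value, flagged; units with too few games for the
#' nominal level use the full Walsh range, also flagged.
#'
#' @param fit an `on_lmm` (or `on_fit`) object.
#' @param conf.level interval confidence level (default 0.95).
#' @return an object of class `on_relevance`: a `data.frame` with
#'   `season`, `team`, `athlete`, `games`, `median`, `lower`, `upper`
#'   and a `degenerate` flag.
#' @export
relevance_scores <- function(fit, conf.level = 0.95) {
  if (inherits(fit, "on_fit")) fit <- fit$lmm
  stopifnot(inherits(fit, "on_lmm"))
  gam <- fitted(fit$model)
  g <- fit$design$groups
  sp <- split(seq_along(gam), g$unit, drop = TRUE)
  key <- unique(data.frame(season = g$season, team = g$team,
                           athlete = g$athlete, unit = as.character(g$unit),
                           stringsAsFactors = FALSE))
  rows <- lapply(names(sp), function(u) {
    idx <- sp[[u]]
    zeta <- gam[idx]
    ci <- .walsh_ci(zeta, conf.level)
    k <- key[match(u, key$unit), ]
    data.frame(season = k$season, team = k$team, athlete = k$athlete,
               games = length(idx), median = .parity_median(zeta),
               lower = ci$lower, upper = ci$upper,
               degenerate = ci$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "conf.level") <- conf.level
  class(out) <- c("on_relevance", "data.frame")
  out
}

#' @export
print.on_relevance <- function(x, ...) {
  cat(sprintf("Median relevance scores (%d athlete units, %.0f%% signed-rank CIs)\n",
              nrow(x), 100 * attr(x, "conf.level")))
  print.data.frame(head(x[order(-x$median), ], 10), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Rank athletes or teams by a score table
#'
#' Sorts a relevance or consistency table by descending point estimate.
#' Ties are broken by the wider-information rule (more games first),
#' then lexicographically by the grouping ids. An optional min-max
#' scaled column (computed over the full score set before truncation to
#' the top `top_m`) is added; confidence-interval columns are carried
#' through so overlapping intervals can be inspected, since ranking on
#' point estimates alone invites classification bias.
#'
#' @param scores an `on_relevance` or `on_consistency` object.
#' @param top_m number of rows to keep (default all).
#' @param scale `NULL`, or `c(a, b)` bounds for the min-max scaled
#'   column.
#' @return an object of class `on_ranking`: the sorted `data.frame` with
#'   a leading `rank` column (and `scaled` when requested).
#' @export
rank_entities <- function(scores, top_m = Inf, scale = NULL) {
  if (top_m < 1) stop("top_m must be >= 1", call. = FALSE)
  point_col <- if (inherits(scores, "on_relevance")) "median"
  else if (inherits(scores, "on_consistency")) "score"
  else stop("scores must be an on_relevance or on_consistency object",
            call. = FALSE)
  if (!nrow(scores)) stop("empty score table", call. = FALSE)
  df <- as.data.frame(scores)
  if (!is.null(scale)) {
    stopifnot(length(scale) == 2)
    df$scaled <- minmax_scale(df[[point_col]], scale[1], scale[2])
  }
  id_cols <- intersect(c("season", "team", "athlete"), names(df))
  ord <- do.call(order, c(list(-df[[point_col]], -df$games),
                          lapply(id_cols, function(cn) df[[cn]])))
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  out <- head(df, top_m)
  attr(out, "point_col") <- point_col
  class(out) <- c("on_ranking", "data.frame")
  out
}

#' @export
print.on_ranking <- function(x, ...) {
  cat(sprintf("Ranking by %s (top %d)\n", attr(x, "point_col"), nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
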