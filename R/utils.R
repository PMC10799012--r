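## small internal helpers shared across modules

#' Names of the standard box-score response variables
#'
#' Returns the canonical 22 response variable names used throughout the
#' package: static physical attributes (`Height`, `Weight`, `Age`), shot
#' families (`Fg2PtAtt`/`Fg2PtMade`, `Fg3PtAtt`/`Fg3PtMade`,
#' `FgAtt`/`FgMade`, `FtAtt`/`FtMade`), rebounds (`OffReb`, `DefReb`),
#' and the remaining counting statistics (`Ast`, `Pts`, `Tov`, `Stl`,
#' `Blk`, `BlkAgainst`, `MinSeconds`, `Fouls`, `FoulsDrawn`).
#'
#' @return character vector of length 22.
#' @export
#' @examples
#' on_variables()
on_variables <- function() {
  c("Height", "Weight", "Age",
    "Fg2PtAtt", "Fg2PtMade", "Fg3PtAtt", "Fg3PtMade",
    "FgAtt", "FgMade", "FtAtt", "FtMade",
    "OffReb", "DefReb", "Ast", "Pts", "Tov", "Stl",
    "Blk", "BlkAgainst", "MinSeconds", "Fouls", "FoulsDrawn")
}

#' Default fixed-effect specification for the stage-2 model
#'
#' The default right-hand side used by [build_design()] and [on_fit()]:
#' venue, position and rookie factors plus orthogonal polynomial terms in
#' five in-game covariates (cubic in points and assists, quadratic in
#' blocks received, free-throw attempts and offensive rebounds).
#'
#' @param interactions logical; if `TRUE`, all first-order interactions
#'   among the listed main effects are added.
#' @return a one-sided formula.
#' @export
on_default_fixed <- function(interactions = FALSE) {
  rhs <- paste(
    "venue + position + rookie",
    "+ poly(Pts, 3) + poly(BlkAgainst, 2) + poly(Ast, 3)",
    "+ poly(FtAtt, 2) + poly(OffReb, 2)")
  if (interactions) rhs <- paste0("(", rhs, ")^2")
  stats::as.formula(paste("~", rhs), env = globalenv())
}

## hierarchy key columns
.on_keys <- function() c("season", "team", "athlete", "game")

## grouping-unit factor: athlete within team within season (a traded
## player forms a distinct unit on each team)
.unit_factor <- function(data) {
  interaction(data$season, data$team, data$athlete, drop = TRUE, sep = ":")
}

.team_factor <- function(data) {
  interaction(data$season, data$team, drop = TRUE, sep = ":")
}

.assert_columns <- function(data, cols, what = "table") {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

## derive a reproducible sub-seed (< 2^31) from a base seed and index
.sub_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7907 * as.numeric(k)) %% 2147483629
}

.is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}
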