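#' Read and validate a game-log CSV
#'
#' Reads a long-format game log (one row per athlete-game) and validates
#' it against the expected schema. Hard failures (missing hierarchy
#' columns, duplicated `(season, team, athlete, game)` rows) abort;
#' soft invariant violations (negative or non-integer counts, made
#' exceeding attempted within a shot family, field-goal attempts not
#' equal to the two-point plus three-point attempts, more than 82 games
#' for a unit, negative minutes) are collected into a validation report
#' attached as `attr(x, "violations")`.
#'
#' @param path CSV file path.
#' @param schema_config optional named character vector mapping canonical
#'   column names (names) to the file's column names (values).
#' @param variables response columns expected; only those present are
#'   validated.
#' @return a `data.frame` of class `game_log` with a `violations`
#'   attribute (a `data.frame` with columns `rule` and `rows`, empty
#'   when the file is clean).
#' @export
read_game_log <- function(path, schema_config = NULL,
                          variables = on_variables()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema_config)) {
    for (canon in names(schema_config)) {
      src <- schema_config[[canon]]
      if (src %in% names(dat)) names(dat)[names(dat) == src] <- canon
    }
  }
  .assert_columns(dat, .on_keys(), basename(path))
  key <- do.call(paste, c(dat[.on_keys()], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (season, team, athlete, game) rows in ", basename(path),
         call. = FALSE)
  if (any(!complete.cases(dat[.on_keys()])))
    stop("missing values in hierarchy key columns", call. = FALSE)
  if ("rookie" %in% names(dat) && !is.logical(dat$rookie))
    dat$rookie <- as.logical(dat$rookie)

  violations <- list()
  flag <- function(rule, bad) {
    if (any(bad)) violations[[length(violations) + 1L]] <<-
        data.frame(rule = rule,
                   rows = paste(head(which(bad), 10), collapse = ","),
                   n = sum(bad), stringsAsFactors = FALSE)
  }
  counts <- intersect(setdiff(variables, c("Height", "Weight", "Age")),
                      names(dat))
  for (v in counts) flag(paste0(v, " must be a non-negative integer"),
                         !.is_count(dat[[v]]))
  fam <- list(c("Fg2PtMade", "Fg2PtAtt"), c("Fg3PtMade", "Fg3PtAtt"),
              c("FgMade", "FgAtt"), c("FtMade", "FtAtt"))
  for (f in fam) if (all(f %in% names(dat)))
    flag(paste(f[1], "<=", f[2]), dat[[f[1]]] > dat[[f[2]]])
  if (all(c("FgAtt", "Fg2PtAtt", "Fg3PtAtt") %in% names(dat)))
    flag("FgAtt == Fg2PtAtt + Fg3PtAtt",
         dat$FgAtt != dat$Fg2PtAtt + dat$Fg3PtAtt)
  if ("MinSeconds" %in% names(dat))
    flag("MinSeconds >= 0", !is.na(dat$MinSeconds) & dat$MinSeconds < 0)
  gpu <- table(.unit_factor(dat))
  if (any(gpu > 82)) violations[[length(violations) + 1L]] <-
    data.frame(rule = "at most 82 games per (season, team, athlete)",
               rows = paste(head(names(gpu)[gpu > 82], 10), collapse = ","),
               n = sum(gpu > 82), stringsAsFactors = FALSE)

  attr(dat, "violations") <- if (length(violations))
    do.call(rbind, violations)
  else data.frame(rule = character(0), rows = character(0),
                  n = integer(0), stringsAsFactors = FALSE)
  class(dat) <- c("game_log", class(dat))
  dat
}

#' Write a game log to CSV
#'
#' Writes the table with a deterministic column order (hierarchy keys,
#' covariates, responses) so [read_game_log()] round-trips it.
#'
#' @param data a game-log `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_game_log <- function(data, path) {
  lead <- intersect(c(.on_keys(), "venue", "position", "rookie"),
                    names(data))
  rest <- setdiff(names(data), lead)
  write.csv(as.data.frame(data)[c(lead, rest)], path, row.names = FALSE)
  invisible(path)
}

#' Export a report table as CSV or JSON
#'
#' Writes any of the package's report objects (rankings, validation
#' reports, consistency or relevance tables, scaling or concordance
#' tables) with a deterministic column order and configured numeric
#' precision. JSON output embeds a metadata header (package version,
#' object class, optional seed).
#'
#' @param object a report `data.frame` (e.g. `on_ranking`,
#'   `on_validation`, `on_consistency`, `on_relevance`, `on_scaling`).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param digits numeric precision retained in the output.
#' @param seed optional seed to record in the JSON metadata.
#' @return `path`, invisibly.
#' @export
write_report <- function(object, path, format = c("csv", "json"),
                         digits = 6, seed = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(object))
    stop("object is not an exportable report table", call. = FALSE)
  df <- as.data.frame(object)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    payload <- list(
      meta = list(package = "onscore",
                  version = as.character(packageVersion("onscore")),
                  class = class(object)[1], digits = digits, seed = seed),
      data = df)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON file path.
#' @return list with `meta` and the report `data` as a `data.frame`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$data <- as.data.frame(x$data, stringsAsFactors = FALSE)
  x
}
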