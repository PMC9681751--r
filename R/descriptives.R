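## Descriptive audit tabulations: counts with percentages for
## categorical review/study characteristics and median [Q1, Q3] for
## quantitative ones, overall and stratified by review design
## (therapeutic intervention vs pathophysiology).

# round-half-up, matching how the printed tables round percentages
.round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

.format_cell <- function(count, denominator, digits = 1) {
  ifelse(denominator > 0,
         sprintf("%d (%.*f%%)", count, digits,
                 .round_half_up(100 * count / denominator, digits)),
         sprintf("%d (—)", count))
}

#' Tabulate a categorical characteristic as count (percentage)
#'
#' Counts each level of `variable` and expresses it as a percentage of
#' an explicit denominator, overall and optionally within strata.
#' Denominator rules vary across audit tables, so they are explicit:
#' by default the denominator is the number of records in the stratum
#' with a non-missing value of `denominator_var` (or all records when
#' `denominator_var` is `NULL`); `among` restricts both numerator and
#' denominator to a nested subset (e.g. "PRISMA among reviews that
#' reported following guidelines"). Multi-select variables (a record
#' carrying several values separated by `multi_sep`) are counted once
#' per value, so their percentages may sum above 100.
#'
#' @param records Data frame, one row per review or study.
#' @param variable Column name to tabulate.
#' @param by Optional stratification column (e.g. `"design"`); output
#'   then contains an `"overall"` stratum plus one per level.
#' @param among Optional `list(variable =, value =)` restricting the
#'   denominator to records where `variable == value`.
#' @param denominator_var Optional column whose non-missingness defines
#'   the denominator ("among those assessed/reporting").
#' @param multi_sep Optional separator for multi-select values.
#'
#' @return Data frame with columns `stratum`, `level`, `count`,
#'   `denominator`, `percent` (rounded half-up to 1 decimal, `NA` for
#'   empty denominators) and `cell` (formatted `"N (P%)"`).
#' @export
tabulate_categorical <- function(records, variable, by = NULL, among = NULL,
                                 denominator_var = NULL, multi_sep = NULL) {
  if (!variable %in% names(records)) stop("unknown variable: ", variable)
  if (!is.null(by) && !by %in% names(records)) stop("unknown stratum variable: ", by)
  if (!is.null(among)) {
    if (!among$variable %in% names(records)) {
      stop("unknown nesting variable: ", among$variable)
    }
    records <- records[!is.na(records[[among$variable]]) &
                         records[[among$variable]] == among$value, , drop = FALSE]
  }
  strata <- list(overall = rep(TRUE, nrow(records)))
  if (!is.null(by)) {
    for (lev in sort(unique(stats::na.omit(records[[by]])))) {
      strata[[lev]] <- !is.na(records[[by]]) & records[[by]] == lev
    }
  }
  denom_ok <- if (is.null(denominator_var)) {
    rep(TRUE, nrow(records))
  } else {
    !is.na(records[[denominator_var]])
  }
  vals <- records[[variable]]
  all_levels <- if (is.null(multi_sep)) {
    sort(unique(stats::na.omit(vals)))
  } else {
    sort(unique(unlist(strsplit(stats::na.omit(vals), multi_sep, fixed = TRUE))))
  }
  out <- list()
  for (sname in names(strata)) {
    in_s <- strata[[sname]] & denom_ok
    denom <- sum(in_s)
    for (lev in all_levels) {
      cnt <- if (is.null(multi_sep)) {
        sum(in_s & !is.na(vals) & vals == lev)
      } else {
        sum(vapply(which(in_s & !is.na(vals)), function(i)
          lev %in% strsplit(vals[i], multi_sep, fixed = TRUE)[[1]], logical(1)))
      }
      out[[length(out) + 1]] <- data.frame(
        stratum = sname, level = lev, count = cnt, denominator = denom,
        percent = if (denom > 0) .round_half_up(100 * cnt / denom, 1) else NA_real_,
        cell = .format_cell(cnt, denom))
    }
  }
  if (!length(out)) {
    return(data.frame(stratum = character(0), level = character(0),
                      count = integer(0), denominator = integer(0),
                      percent = numeric(0), cell = character(0)))
  }
  do.call(rbind, out)
}

#' Summarize a quantitative characteristic as median [Q1, Q3]
#'
#' Quartiles use linear-interpolation (type-7) quantiles. Missing
#' values are dropped and counted.
#'
#' @inheritParams tabulate_categorical
#'
#' @return Data frame with columns `stratum`, `n`, `n_missing`,
#'   `median`, `q1`, `q3` and a formatted `cell`; all-missing strata
#'   report `NA`.
#' @export
summarize_numeric <- function(records, variable, by = NULL) {
  if (!variable %in% names(records)) stop("unknown variable: ", variable)
  strata <- list(overall = rep(TRUE, nrow(records)))
  if (!is.null(by)) {
    for (lev in sort(unique(stats::na.omit(records[[by]])))) {
      strata[[lev]] <- !is.na(records[[by]]) & records[[by]] == lev
    }
  }
  vals <- records[[variable]]
  out <- lapply(names(strata), function(sname) {
    x <- vals[strata[[sname]]]
    miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(data.frame(stratum = sname, n = 0L, n_missing = miss,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                        cell = "NA"))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(stratum = sname, n = length(x), n_missing = miss,
               median = q[2], q1 = q[1], q3 = q[3],
               cell = sprintf("%g [%g, %g]", q[2], q[1], q[3]))
  })
  do.call(rbind, out)
}
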