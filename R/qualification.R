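#' Classify a pair of permissible limits
#'
#' Regulatory limits for a test project (analyte) come as a pair
#' `(min_limit, max_limit)`. The pair determines which branch of the
#' optimal-distance scoring rule applies:
#'
#' * `max_only`   — `min = 0 < max`: only an upper bound exists.
#' * `min_only`   — `0 < min`, `max` infinite: only a lower bound exists.
#' * `band`       — `0 < min < max`: the result must sit inside a band.
#' * `point`      — `0 < min = max`: a single target value.
#' * `exact_zero` — `min = max = 0`: the analyte must be absent.
#'
#' @param min_limit numeric vector of minimum permissible limits (mg/kg or
#'   mg/L; the two units are treated as numerically interchangeable).
#' @param max_limit numeric vector of maximum permissible limits. `Inf`
#'   means "no upper bound". `NA` in either position marks a record with
#'   no usable limit; such records are classified `missing`.
#' @return character vector of limit kinds.
#' @examples
#' classify_limit(0, 1)    # "max_only"
#' classify_limit(0, 0)    # "exact_zero"
#' classify_limit(2, 2)    # "point"
#' classify_limit(1, 3)    # "band"
#' @export
classify_limit <- function(min_limit, max_limit) {
  n <- max(length(min_limit), length(max_limit))
  min_limit <- rep_len(as.numeric(min_limit), n)
  max_limit <- rep_len(as.numeric(max_limit), n)
  missing <- is.na(min_limit) | is.na(max_limit)
  bad <- !missing & (min_limit < 0 | min_limit > max_limit)
  if (any(bad)) {
    stop_stage("qualification", sprintf(
      "invalid limit pair(s): need 0 <= min <= max (first offender: min=%g, max=%g)",
      min_limit[bad][1], max_limit[bad][1]))
  }
  kind <- rep(NA_character_, n)
  kind[missing] <- "missing"
  idx <- !missing
  kind[idx & min_limit == 0 & max_limit == 0] <- "exact_zero"
  kind[idx & min_limit == 0 & max_limit > 0 & is.finite(max_limit)] <- "max_only"
  kind[idx & min_limit > 0 & is.infinite(max_limit)] <- "min_only"
  kind[idx & min_limit > 0 & min_limit == max_limit & is.finite(max_limit)] <- "point"
  kind[idx & min_limit > 0 & min_limit < max_limit & is.finite(max_limit)] <- "band"
  kind[idx & min_limit == 0 & is.infinite(max_limit)] <- "missing"  # no bound at all
  kind
}

#' Simple qualification degree of a test result
#'
#' Scores a laboratory test result `T` against its permissible limits with
#' the optimal-distance rule: `Q` lies in `[0, 1]`, equals 0 for a
#' non-qualified (out-of-bound) result, and grows as the result moves away
#' from the offending bound into the safe interior.
#'
#' Branches, by limit kind:
#' * `max_only` (`0 = min < max`): `Q = 1 - T/max` for `0 <= T < max`,
#'   else 0.
#' * `point` (`0 < min = max`): `Q = 0` for `T < min`, else
#'   `Q = max(0, 2 - T/min)` clamped to `[0, 1]` — value 1 at `T = min`,
#'   decreasing with relative deviation above the target.
#' * `band` (`0 < min < max`): `Q = 1 - |(T - min)/(max - min) - 0.5|`
#'   inside `[min, max)`, else 0; maximal (1) at the band midpoint.
#' * `exact_zero` (`min = max = 0`): `Q = 1` iff `T = 0`, else 0.
#' * `min_only` (`0 < min`, no upper bound): the piecewise rule has no
#'   graded branch for a pure lower bound, so these score pass/fail:
#'   `Q = 1` for `T >= min`, 0 otherwise.
#'
#' The point and band branches are printed ambiguously in their original
#' formulation; the parses above are the package's documented reading (see
#' the methods vignette) and can be swapped for the alternative point-limit
#' parse via `point_parse`.
#'
#' @param test_result numeric vector of non-negative measured values
#'   (mg/kg or mg/L).
#' @param min_limit,max_limit numeric vectors of limits, recycled to the
#'   length of `test_result`. See [classify_limit()].
#' @param point_parse `"clamped"` (default, `Q = 2 - T/min` clamped) or
#'   `"reciprocal"` (`Q = min/T`, the decreasing alternative reading).
#' @param na_action `"error"` (default) to fail on records with missing
#'   limits, or `"na"` to return `NA` for them (callers exclude and log).
#' @return numeric vector of scores in `[0, 1]` (or `NA` where limits are
#'   missing and `na_action = "na"`).
#' @examples
#' simple_qualification_degree(1.2, 0, 1)   # 0   (exceeds the maximum)
#' simple_qualification_degree(0.5, 0, 1)   # 0.5
#' simple_qualification_degree(2,   1, 3)   # 1   (band midpoint)
#' simple_qualification_degree(0,   0, 0)   # 1   (absent, as required)
#' @export
simple_qualification_degree <- function(test_result, min_limit, max_limit,
                                        point_parse = c("clamped", "reciprocal"),
                                        na_action = c("error", "na")) {
  point_parse <- match.arg(point_parse)
  na_action <- match.arg(na_action)
  n <- max(length(test_result), length(min_limit), length(max_limit))
  t_res <- rep_len(as.numeric(test_result), n)
  mn <- rep_len(as.numeric(min_limit), n)
  mx <- rep_len(as.numeric(max_limit), n)
  if (anyNA(t_res) || any(t_res < 0)) {
    stop_stage("qualification", "test results must be non-negative and non-missing")
  }
  kind <- classify_limit(mn, mx)
  if (na_action == "error" && any(kind == "missing")) {
    stop_stage("qualification", sprintf(
      "%d record(s) have no usable permissible limit", sum(kind == "missing")))
  }
  q <- rep(NA_real_, n)

  i <- kind == "max_only"
  q[i] <- ifelse(t_res[i] < mx[i], 1 - t_res[i] / mx[i], 0)

  i <- kind == "exact_zero"
  q[i] <- ifelse(t_res[i] == 0, 1, 0)

  i <- kind == "point"
  if (point_parse == "clamped") {
    q[i] <- ifelse(t_res[i] < mn[i], 0,
                   pmin(1, pmax(0, 2 - t_res[i] / mn[i])))
  } else {
    q[i] <- ifelse(t_res[i] < mn[i], 0, pmin(1, mn[i] / t_res[i]))
  }

  i <- kind == "band"
  inside <- i & t_res >= mn & t_res < mx
  q[i] <- 0
  q[inside] <- 1 - abs((t_res[inside] - mn[inside]) /
                         (mx[inside] - mn[inside]) - 0.5)

  i <- kind == "min_only"
  q[i] <- ifelse(t_res[i] >= mn[i], 1, 0)

  q
}

#' Score a table of inspection records
#'
#' Appends a `Q` column to a records table and excludes (with a log
#' summary) records whose test project has no usable limit.
#'
#' @param records data.frame with at least columns `test_result`,
#'   `min_limit`, `max_limit`. Empty/`NA` limit cells mean "no limit on
#'   that side": `NA` minimum is read as 0, `NA` maximum as absent, and a
#'   record with no bound on either side is excluded.
#' @param point_parse passed to [simple_qualification_degree()].
#' @return list with `records` (scored rows, `Q` column appended),
#'   `excluded` (rows without limits), and `log` (character summary).
#' @export
score_records <- function(records, point_parse = "clamped") {
  needed <- c("test_result", "min_limit", "max_limit")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop_stage("qualification", "records table lacks column(s): ",
               paste(miss, collapse = ", "))
  }
  mn <- ifelse(is.na(records$min_limit), 0, as.numeric(records$min_limit))
  mx <- as.numeric(records$max_limit)
  mx[is.na(mx) & mn > 0] <- Inf     # pure lower bound
  kind <- classify_limit(mn, mx)
  keep <- kind != "missing"
  q <- rep(NA_real_, nrow(records))
  q[keep] <- simple_qualification_degree(records$test_result[keep],
                                         mn[keep], mx[keep],
                                         point_parse = point_parse)
  scored <- records[keep, , drop = FALSE]
  scored$Q <- q[keep]
  log_msg <- sprintf("scored %d record(s); excluded %d with missing limits",
                     sum(keep), sum(!keep))
  list(records = scored,
       excluded = records[!keep, , drop = FALSE],
       log = log_msg)
}
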