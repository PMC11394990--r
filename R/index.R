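#' Comprehensive food safety qualification degree
#'
#' The per-sample product of the simple qualification degree with the
#' five modifying weights:
#' `Qbar = wc * wh * ws * wr * wFADM * Q`.
#' The expert-elicitation baseline is the same product with the FADM
#' correction fixed at 1 (it uses only the simple degree and the expert
#' weights).
#'
#' @param q simple qualification degree in `[0, 1]`.
#' @param wc consumption weight (positive).
#' @param wh project hazard weight (1-5, used raw).
#' @param ws sales-channel weight.
#' @param wr production-region weight.
#' @param wfadm FADM correction weight (in `(1, k)`), or 1 for the expert
#'   baseline.
#' @return numeric vector of comprehensive degrees (non-negative; 0
#'   exactly where `q` is 0).
#' @examples
#' comprehensive_degree(0.5, 0.2, 3, 1.4, 0.8, 50)  # 16.8
#' expert_baseline_degree(0.5, 0.2, 3, 1.4, 0.8)    # 0.336
#' @export
comprehensive_degree <- function(q, wc, wh, ws, wr, wfadm) {
  args <- list(q = q, wc = wc, wh = wh, ws = ws, wr = wr, wfadm = wfadm)
  for (nm in names(args)) {
    if (anyNA(args[[nm]])) stop_stage("index", "missing values in '", nm, "'")
  }
  for (nm in c("wc", "wh", "ws", "wr", "wfadm")) {
    if (any(args[[nm]] <= 0)) stop_stage("index", "'", nm, "' must be positive")
  }
  if (any(q < 0 | q > 1)) stop_stage("index", "'q' must lie in [0, 1]")
  q * wc * wh * ws * wr * wfadm
}

#' @rdname comprehensive_degree
#' @export
expert_baseline_degree <- function(q, wc, wh, ws, wr) {
  comprehensive_degree(q, wc, wh, ws, wr, wfadm = 1)
}

#' Group means of comprehensive degrees
#'
#' Averages per-sample comprehensive degrees within each group (city or
#' food category). Groups without samples do not appear.
#'
#' @param q_bar numeric vector of comprehensive degrees.
#' @param group character/factor vector of group labels, same length.
#' @return data.frame with columns `unit`, `n`, `raw_mean`, ordered by
#'   unit label.
#' @export
aggregate_degrees <- function(q_bar, group) {
  if (!length(q_bar)) stop_stage("index", "no scored samples to aggregate")
  if (length(q_bar) != length(group)) {
    stop_stage("index", "q_bar and group lengths differ")
  }
  group <- as.character(group)
  means <- tapply(q_bar, group, mean)
  counts <- tapply(q_bar, group, length)
  units <- sort(names(means))
  data.frame(unit = units,
             n = as.integer(counts[units]),
             raw_mean = as.numeric(means[units]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Min-max scale raw group means to a 0-100 index
#'
#' Within one report, the lowest raw mean maps to 0 and the highest to
#' 100; intermediate units scale linearly, which preserves their order.
#' If all units tie (or there is a single unit) every index is 100 by
#' convention. Indexes from different reports are therefore comparable in
#' rank only, not in absolute value.
#'
#' @param raw numeric vector of raw group means.
#' @return numeric vector of indexes in `[0, 100]`.
#' @examples
#' scale_index(c(10, 20, 30))  # 0 50 100
#' @export
scale_index <- function(raw) {
  if (!length(raw)) stop_stage("index", "empty report")
  rng <- range(raw)
  if (diff(rng) == 0) return(rep(100, length(raw)))
  (raw - rng[1]) / diff(rng) * 100
}

#' Build an index report for one grouping and method
#'
#' @param q_bar per-sample comprehensive degrees.
#' @param group grouping labels (cities or categories).
#' @param method `"fadm"` or `"expert"`.
#' @param scaling `"minmax"` (0-100 index) or `"raw"` (index equals the
#'   raw mean).
#' @return data.frame with columns `unit`, `method`, `n`, `raw_mean`,
#'   `index`.
#' @export
index_report <- function(q_bar, group, method = c("fadm", "expert"),
                         scaling = c("minmax", "raw")) {
  method <- match.arg(method)
  scaling <- match.arg(scaling)
  agg <- aggregate_degrees(q_bar, group)
  agg$method <- method
  agg$index <- if (scaling == "minmax") scale_index(agg$raw_mean) else agg$raw_mean
  agg[, c("unit", "method", "n", "raw_mean", "index")]
}
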