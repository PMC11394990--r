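#' Parameters for the mixed-data factor analysis
#'
#' @param k transform ceiling for [transform_score()]; transformed factor
#'   scores lie in the open interval `(1, k)`. Must exceed 1; default 100.
#' @param retention factor retention rule: `"cumulative"` keeps the
#'   smallest `r` whose variance contributions sum to at least
#'   `threshold`; `"kaiser"` keeps factors whose eigenvalue exceeds the
#'   mean eigenvalue; `"fixed"` keeps exactly `r` factors.
#' @param threshold cumulative-variance threshold in `(0, 1]` (default
#'   0.80).
#' @param r number of factors for `retention = "fixed"`.
#' @param transform `"increasing"` (default; higher factor scores give
#'   higher transformed scores) or `"decreasing"` (the alternative branch
#'   orientation).
#' @return object of class `fadm_params`.
#' @export
fadm_params <- function(k = 100,
                        retention = c("cumulative", "kaiser", "fixed"),
                        threshold = 0.80, r = NULL,
                        transform = c("increasing", "decreasing")) {
  retention <- match.arg(retention)
  transform <- match.arg(transform)
  assert_scalar_number(k, "k", "famd")
  if (k <= 1) stop_stage("famd", "'k' must exceed 1")
  if (retention == "cumulative" &&
      (!is.numeric(threshold) || threshold <= 0 || threshold > 1)) {
    stop_stage("famd", "'threshold' must lie in (0, 1]")
  }
  if (retention == "fixed" && (is.null(r) || r < 1)) {
    stop_stage("famd", "retention = 'fixed' needs r >= 1")
  }
  structure(list(k = k, retention = retention, threshold = threshold,
                 r = if (is.null(r)) NULL else as.integer(r),
                 transform = transform),
            class = "fadm_params")
}

#' Encode mixed quantitative/qualitative variables for factor analysis
#'
#' Builds the two blocks of the mixed design: quantitative columns are
#' standardized (centered, unit variance); qualitative columns are one-hot
#' expanded into indicator columns (one per observed level) which are then
#' centered. Constant quantitative columns and qualitative variables with
#' a single observed level carry no information and are dropped with a log
#' entry.
#'
#' @param data data.frame of auxiliary variables (one row per sample).
#' @param variable_spec data.frame with columns `variable`, `type`
#'   (`"quantitative"` or `"qualitative"`) and optionally `include`
#'   (logical, default `TRUE`).
#' @return object of class `mixed_design`: list with `quant` (n x p1
#'   standardized matrix), `qual` (n x m centered indicator matrix),
#'   `qual_raw` (uncentered 0/1 indicators), `n`, `dropped`, `log`.
#' @export
encode_mixed <- function(data, variable_spec) {
  if (!all(c("variable", "type") %in% names(variable_spec))) {
    stop_stage("famd", "variable_spec needs columns 'variable' and 'type'")
  }
  if (!is.null(variable_spec$include)) {
    variable_spec <- variable_spec[as.logical(variable_spec$include), , drop = FALSE]
  }
  miss <- setdiff(variable_spec$variable, names(data))
  if (length(miss)) {
    stop_stage("famd", "variable(s) absent from data: ", paste(miss, collapse = ", "))
  }
  n <- nrow(data)
  if (n < 3) stop_stage("famd", "need at least 3 samples, got ", n)
  dropped <- character(0)

  quant_vars <- variable_spec$variable[variable_spec$type == "quantitative"]
  quant <- NULL
  if (length(quant_vars)) {
    qm <- as.matrix(as.data.frame(lapply(data[quant_vars], as.numeric)))
    centered <- sweep(qm, 2, colMeans(qm))
    # population (1/n) standard deviation, so a standardized column has
    # first eigenvalue exactly 1 under the t(X) X / n convention
    sds <- sqrt(colMeans(centered^2))
    keep <- is.finite(sds) & sds > 0
    dropped <- c(dropped, quant_vars[!keep])
    if (any(keep)) {
      quant <- sweep(centered[, keep, drop = FALSE], 2, sds[keep], "/")
    }
  }

  qual_vars <- variable_spec$variable[variable_spec$type == "qualitative"]
  ind_cols <- list()
  for (v in qual_vars) {
    f <- factor(as.character(data[[v]]))
    f <- droplevels(f)            # no empty levels
    if (nlevels(f) < 2) {
      dropped <- c(dropped, v)
      next
    }
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste(v, levels(f), sep = ".")
    ind_cols[[v]] <- m
  }
  qual_raw <- if (length(ind_cols)) do.call(cbind, ind_cols) else NULL
  qual <- if (!is.null(qual_raw)) scale(qual_raw, center = TRUE, scale = FALSE) else NULL
  if (!is.null(qual)) attr(qual, "scaled:center") <- NULL

  if (is.null(quant) && is.null(qual)) {
    stop_stage("famd", "degenerate design: every variable is constant")
  }
  structure(list(
    quant = quant, qual = qual, qual_raw = qual_raw, n = n,
    dropped = dropped,
    log = sprintf("encoded %d quantitative column(s), %d indicator column(s); dropped %d constant variable(s)",
                  if (is.null(quant)) 0L else ncol(quant),
                  if (is.null(qual)) 0L else ncol(qual),
                  length(dropped))
  ), class = "mixed_design")
}

#' First eigenvalue of a variable block
#'
#' The largest eigenvalue of `t(X) %*% X / n`, i.e. the squared largest
#' singular value of `X` divided by the number of rows. Used to rescale
#' each block so that neither the quantitative nor the qualitative block
#' dominates the joint decomposition.
#'
#' @param block numeric matrix (n x p).
#' @return positive scalar.
#' @export
first_eigenvalue <- function(block) {
  block <- as.matrix(block)
  if (ncol(block) < 1) stop_stage("famd", "block has no columns")
  s1 <- svd(block, nu = 0, nv = 0)$d[1]
  lambda <- s1^2 / nrow(block)
  if (!is.finite(lambda) || lambda <= 0) {
    stop_stage("famd", "degenerate block: first eigenvalue is not positive")
  }
  lambda
}

#' Factor analysis of mixed data by block-scaled SVD
#'
#' Concatenates the standardized quantitative block and the centered
#' indicator block, each divided by its first eigenvalue, into a global
#' matrix `G`, and decomposes `G = U S V'` by singular value
#' decomposition. With the uniform mass matrix `M = (1/n) I`, the factor
#' scores are `F = M^(-1/2) U S = sqrt(n) U S` (rows are samples, columns
#' principal factors). The variance contribution rate of factor `i` is
#' `s_i^2 / sum(s_j^2)`; the retention rule in `params` fixes the number
#' of principal factors `r` used downstream.
#'
#' @param design a [encode_mixed()] result (or any list with `quant`,
#'   `qual`, `n`).
#' @param params a [fadm_params()].
#' @return object of class `fadm_model` with elements `lambda1_quant`,
#'   `lambda1_qual`, `u`, `d`, `v`, `factor_scores`,
#'   `variance_contributions`, `n_retained`, `n`, `global`.
#' @export
famd_decompose <- function(design, params = fadm_params()) {
  blocks <- list()
  lambda_quant <- lambda_qual <- NA_real_
  if (!is.null(design$quant)) {
    lambda_quant <- first_eigenvalue(design$quant)
    blocks$quant <- design$quant / lambda_quant
  }
  if (!is.null(design$qual)) {
    lambda_qual <- first_eigenvalue(design$qual)
    blocks$qual <- design$qual / lambda_qual
  }
  if (!length(blocks)) stop_stage("famd", "design has no variable blocks")
  g <- do.call(cbind, blocks)
  n <- nrow(g)
  dec <- tryCatch(svd(g), error = function(e) {
    stop_stage("famd", "singular value decomposition failed: ", conditionMessage(e))
  })
  d <- dec$d
  # deterministic sign convention: the largest-magnitude loading of each
  # right singular vector is positive. V depends on G only through G'G,
  # so this makes factor scores equivariant under sample permutation.
  for (j in seq_along(d)) {
    pivot <- which.max(abs(dec$v[, j]))
    if (dec$v[pivot, j] < 0) {
      dec$v[, j] <- -dec$v[, j]
      dec$u[, j] <- -dec$u[, j]
    }
  }
  total <- sum(d^2)
  if (total <= 0) stop_stage("famd", "degenerate design: all singular values are zero")
  omega <- d^2 / total
  f <- sqrt(n) * dec$u %*% diag(d, nrow = length(d))
  r <- switch(params$retention,
    cumulative = which(cumsum(omega) >= params$threshold - 1e-12)[1],
    kaiser = max(1L, sum(d^2 / n > mean(d^2 / n))),
    fixed = min(params$r, length(d))
  )
  if (is.na(r) || r < 1) stop_stage("famd", "retention rule kept no factors")
  structure(list(
    lambda1_quant = lambda_quant, lambda1_qual = lambda_qual,
    u = dec$u, d = d, v = dec$v,
    factor_scores = f,
    variance_contributions = omega,
    n_retained = as.integer(r),
    n = n, global = g
  ), class = "fadm_model")
}

#' Bounded exponential transform of factor scores
#'
#' Factor scores are deviations from the mean (positive and negative), so
#' they are mapped into the positive interval `(1, k)` before being used
#' as weights: `f(F) = k - (k-1)/2 * exp(-F)` for `F >= 0` and
#' `f(F) = 1 + (k-1)/2 * exp(F)` for `F < 0`. Both branches meet at
#' `f(0) = (k+1)/2`; the map is continuous, strictly increasing, and
#' asymptotes to `k` above and `1` below. The mirrored (decreasing)
#' orientation is available via `direction`.
#'
#' @param f_score numeric vector/matrix of factor scores.
#' @param k ceiling of the transform; must exceed 1.
#' @param direction `"increasing"` (default) or `"decreasing"`.
#' @return transformed scores, same shape as `f_score`, in `(1, k)`.
#' @examples
#' transform_score(0, k = 100)    # 50.5
#' @export
transform_score <- function(f_score, k = 100,
                            direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  assert_scalar_number(k, "k", "famd")
  if (k <= 1) stop_stage("famd", "'k' must exceed 1")
  x <- f_score
  if (direction == "decreasing") x <- -x
  half <- (k - 1) / 2
  out <- ifelse(x >= 0, k - half * exp(-x), 1 + half * exp(x))
  if (is.matrix(f_score)) dim(out) <- dim(f_score)
  out
}

#' Per-sample FADM correction weight
#'
#' For each sample, the FADM weight is the variance-contribution-weighted
#' mean of its transformed factor scores over the retained principal
#' factors: `w = sum_i f(F_i) w_i / sum_i w_i`, `i = 1..r`. Because each
#' `f(F_i)` lies in `(1, k)`, so does the weight.
#'
#' @param model a [famd_decompose()] result.
#' @param params a [fadm_params()] (supplies `k`, transform orientation).
#' @return numeric vector, one weight per sample, in `(1, k)`.
#' @export
fadm_weight <- function(model, params = fadm_params()) {
  r <- model$n_retained
  if (is.null(r) || r < 1) stop_stage("famd", "model retains no factors")
  f <- transform_score(model$factor_scores[, seq_len(r), drop = FALSE],
                       k = params$k, direction = params$transform)
  w <- model$variance_contributions[seq_len(r)]
  as.numeric(f %*% w) / sum(w)
}

#' @export
print.fadm_model <- function(x, ...) {
  cat("Mixed-data factor model\n")
  cat(sprintf("  samples: %d, factors: %d (retained %d)\n",
              x$n, length(x$d), x$n_retained))
  cat(sprintf("  block eigenvalues: quant %.4g, qual %.4g\n",
              x$lambda1_quant, x$lambda1_qual))
  cat("  variance contributions:",
      paste(sprintf("%.3f", utils::head(x$variance_contributions, 6)),
            collapse = " "),
      if (length(x$d) > 6) "..." else "", "\n")
  invisible(x)
}
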