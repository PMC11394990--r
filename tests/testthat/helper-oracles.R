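# independent oracles and small fixture builders shared across tests

# brute-force factor scores for a quantitative-only design, via an
# eigendecomposition of the cross-product (never calls famd_decompose)
oracle_factor_scores <- function(quant_block) {
  n <- nrow(quant_block)
  lambda1 <- eigen(crossprod(quant_block) / n, symmetric = TRUE)$values[1]
  g <- quant_block / lambda1
  ev <- eigen(crossprod(g), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-12
  v <- ev$vectors[, keep, drop = FALSE]
  scores <- sqrt(n) * g %*% v        # sqrt(n) * U %*% Sigma = sqrt(n) * G %*% V
  list(scores = scores, d = sqrt(pmax(ev$values[keep], 0)))
}

# align column signs of b to a (SVD columns are sign-ambiguous)
align_signs <- function(a, b) {
  for (j in seq_len(min(ncol(a), ncol(b)))) {
    if (sum(a[, j] * b[, j]) < 0) b[, j] <- -b[, j]
  }
  b
}

# population-sd standardization matching encode_mixed()
standardize_pop <- function(m) {
  centered <- sweep(m, 2, colMeans(m))
  sweep(centered, 2, sqrt(colMeans(centered^2)), "/")
}

tiny_weight_config <- function(permissive = FALSE) {
  weight_config(
    consumption = data.frame(category = c("A", "B", "C"),
                             per_capita = c(2, 1, 1)),
    hazards = data.frame(project_id = c("P1", "P2"), score = c(5L, 1L)),
    channels = data.frame(channel_name = c("mall", "stall", "shop"),
                          size_class = c("large", "small", "medium")),
    region_city_map = data.frame(city = c("city_A", "city_B"),
                                 region = "region_X"),
    permissive = permissive)
}

small_campaign <- function(n = 300, seed = 7, rate = 0.1, structure = 1) {
  generate_campaign(campaign_config(n_samples = n, seed = seed,
                                    contamination_rate = rate,
                                    aux_structure = structure))
}
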