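default_categories <- function() {
  c("dairy_products", "starch_products", "grain_processing_products",
    "meat_products", "soy_products", "edible_agricultural_products",
    "edible_oil_products", "catering_food")
}

default_channel_names <- function(n = 16) {
  pool <- c("supermarket", "shopping_mall", "vegetable_market",
            "wholesale_market", "farm_product_market", "convenience_store",
            "grocery_store", "snack_bar", "fast_food", "restaurant",
            "canteen", "online_shop", "specialty_store", "street_vendor",
            "food_stall", "bakery")
  if (n <= length(pool)) pool[seq_len(n)] else
    c(pool, sprintf("channel_%02d", seq_len(n - length(pool))))
}

#' Configuration for a synthetic inspection campaign
#'
#' Describes a sampling-and-inspection campaign with the structure of a
#' provincial surveillance database: 15 cities, 8 food categories, a pool
#' of test projects each carrying permissible limits and a hazard score,
#' 16 sales channels in three size classes, production-region labels, and
#' a set of mixed quantitative/qualitative auxiliary variables (default
#' 25, matching the number of valid items such databases typically
#' expose). Contamination is controllable: each record exceeds its limit
#' with probability `contamination_rate`, by a relative margin drawn from
#' an exponential of mean `severity_mean`.
#'
#' @param n_samples number of records to generate.
#' @param n_cities number of cities in the home region (default 15).
#' @param categories character vector of food category labels (default 8).
#' @param n_projects size of the test-project pool (default 40; real
#'   programmes use ~200, scaled to keep every project observed at desk
#'   sample sizes).
#' @param n_channels number of sales channels (default 16).
#' @param contamination_rate probability in `[0, 1]` that a record's test
#'   result exceeds its limit (default 0.05, a typical national
#'   non-conformity rate).
#' @param severity_mean mean of the exponential relative-exceedance
#'   multiplier: an exceeding result is `max * (1 + s)`.
#' @param n_quant_aux,n_qual_aux counts of quantitative and qualitative
#'   auxiliary variables (defaults 10 + 15 = 25).
#' @param aux_levels integer range of level counts for qualitative
#'   auxiliaries.
#' @param aux_structure strength of the planted one-factor structure in
#'   the auxiliaries (0 = independent noise; default 1 = moderate
#'   city/category-driven correlation).
#' @param home_region label of the home region.
#' @param seed integer seed; the same config generates byte-identical
#'   tables.
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(n_samples = 1000,
                            n_cities = 15,
                            categories = default_categories(),
                            n_projects = 40,
                            n_channels = 16,
                            contamination_rate = 0.05,
                            severity_mean = 0.5,
                            n_quant_aux = 10,
                            n_qual_aux = 15,
                            aux_levels = c(2L, 5L),
                            aux_structure = 1,
                            home_region = "region_X",
                            seed = 1L) {
  if (n_samples < 1 || n_cities < 1 || n_projects < 1 || n_channels < 1) {
    stop_stage("synthetic", "all counts must be at least 1")
  }
  if (contamination_rate < 0 || contamination_rate > 1) {
    stop_stage("synthetic", "contamination_rate must lie in [0, 1]")
  }
  if (severity_mean <= 0) stop_stage("synthetic", "severity_mean must be positive")
  assert_scalar_number(seed, "seed", "synthetic")
  structure(as.list(environment()), class = "campaign_config")
}

#' Generate the configuration tables of a campaign
#'
#' Draws the consumption, hazard, channel, project-limit and region-map
#' tables implied by a [campaign_config()]: per-capita consumption is
#' log-normal and positive; hazard scores are uniform on 1..5; every
#' channel is mapped to a size class; each project carries a limit pair
#' (mostly maximum-only, with some band, target-value, and must-be-absent
#' projects).
#'
#' @param config a [campaign_config()].
#' @return list of data.frames: `consumption`, `hazards`, `channels`,
#'   `projects`, `region_city_map`.
#' @export
generate_weight_tables <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  with_rng_seed(config$seed + 1L, {
    cities <- sprintf("city_%s", LETTERS[seq_len(config$n_cities)])
    consumption <- data.frame(
      category = config$categories,
      per_capita = round(stats::rlnorm(length(config$categories),
                                       meanlog = 2, sdlog = 0.8), 2),
      stringsAsFactors = FALSE)
    consumption$per_capita[consumption$per_capita <= 0] <- 0.01
    projects <- sprintf("P%03d", seq_len(config$n_projects))
    hazards <- data.frame(project_id = projects,
                          score = sample(1:5, config$n_projects, replace = TRUE),
                          stringsAsFactors = FALSE)
    chan <- default_channel_names(config$n_channels)
    channels <- data.frame(
      channel_name = chan,
      size_class = sample(c("large", "medium", "small"), length(chan),
                          replace = TRUE, prob = c(0.3, 0.4, 0.3)),
      stringsAsFactors = FALSE)
    kind <- sample(c("max_only", "band", "point", "exact_zero"),
                   config$n_projects, replace = TRUE,
                   prob = c(0.80, 0.10, 0.05, 0.05))
    mx <- signif(stats::rlnorm(config$n_projects, meanlog = 0, sdlog = 1.2), 4)
    limits <- data.frame(project_id = projects, stringsAsFactors = FALSE)
    limits$min_limit <- ifelse(kind == "band", signif(mx * 0.3, 4),
                        ifelse(kind == "point", mx, 0))
    limits$max_limit <- ifelse(kind == "exact_zero", 0, mx)
    limits$unit <- sample(c("mg_per_kg", "mg_per_L"), config$n_projects,
                          replace = TRUE, prob = c(0.8, 0.2))
    region_city_map <- data.frame(city = cities, region = config$home_region,
                                  stringsAsFactors = FALSE)
    list(consumption = consumption, hazards = hazards, channels = channels,
         projects = limits, region_city_map = region_city_map)
  })
}

#' Generate a synthetic inspection campaign
#'
#' Produces a records table plus the configuration tables consumed by the
#' scoring, weighting and factor-analysis stages. Safe results are drawn
#' uniformly inside the safe interval of each record's limit; exceeding
#' results multiply the maximum limit by `1 + s` with `s` exponential.
#' Auxiliary variables share a latent factor shifted by city and category
#' (strength `aux_structure`), so the mixed-data factor analysis has
#' recoverable structure. Fully reproducible: the same config (including
#' seed) yields byte-identical tables.
#'
#' @param config a [campaign_config()].
#' @return list with `records` (data.frame, one row per sample x project
#'   measurement) and the tables of [generate_weight_tables()], plus the
#'   `config` itself.
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  tables <- generate_weight_tables(config)
  n <- config$n_samples
  with_rng_seed(config$seed, {
    cities <- tables$region_city_map$city
    city <- sample(cities, n, replace = TRUE)
    category <- sample(config$categories, n, replace = TRUE)
    pidx <- sample.int(nrow(tables$projects), n, replace = TRUE)
    proj <- tables$projects[pidx, ]
    channel <- sample(tables$channels$channel_name, n, replace = TRUE)
    origin <- sample(c("local_city", "local_region", "other_region"), n,
                     replace = TRUE, prob = c(0.5, 0.3, 0.2))
    production_region <- character(n)
    production_region[origin == "local_city"] <- city[origin == "local_city"]
    production_region[origin == "local_region"] <-
      vapply(which(origin == "local_region"),
             function(i) sample(setdiff(cities, city[i]), 1), character(1))
    production_region[origin == "other_region"] <-
      sample(sprintf("outside_region_%d", 1:5), sum(origin == "other_region"),
             replace = TRUE)

    exceeds <- stats::runif(n) < config$contamination_rate
    mn <- proj$min_limit
    mx <- proj$max_limit
    t_res <- numeric(n)
    band <- mn > 0 & mn < mx & is.finite(mx)
    maxo <- mn == 0 & mx > 0 & is.finite(mx)
    point <- mn > 0 & mn == mx
    zero <- mn == 0 & mx == 0
    safe <- !exceeds
    t_res[safe & maxo] <- stats::runif(sum(safe & maxo), 0, 1) * mx[safe & maxo]
    t_res[safe & band] <- mn[safe & band] +
      stats::runif(sum(safe & band)) * (mx[safe & band] - mn[safe & band])
    t_res[safe & point] <- mn[safe & point] *
      (1 + 0.8 * stats::runif(sum(safe & point)))
    t_res[safe & zero] <- 0
    sev <- 1 + stats::rexp(sum(exceeds), rate = 1 / config$severity_mean)
    t_res[exceeds] <- ifelse(zero[exceeds],
                             sev - 1,            # any positive finding violates
                             mx[exceeds] * sev)

    year <- sample(c(2020L, 2021L), n, replace = TRUE)

    # latent one-factor structure shared by the auxiliaries
    city_eff <- stats::setNames(stats::rnorm(length(cities)), cities)
    cat_eff <- stats::setNames(stats::rnorm(length(config$categories)),
                               config$categories)
    latent <- city_eff[city] + cat_eff[category] + stats::rnorm(n, sd = 0.5)
    aux <- list()
    for (j in seq_len(config$n_quant_aux)) {
      loading <- stats::runif(1, 0.5, 1.5)
      aux[[sprintf("q%02d", j)]] <-
        round(config$aux_structure * loading * latent + stats::rnorm(n), 4)
    }
    lv_lo <- config$aux_levels[1]
    lv_hi <- config$aux_levels[2]
    for (j in seq_len(config$n_qual_aux)) {
      nl <- sample(lv_lo:lv_hi, 1)
      score <- config$aux_structure * latent + stats::rnorm(n)
      cuts <- stats::quantile(score, probs = seq(0, 1, length.out = nl + 1))
      cuts[1] <- -Inf
      cuts[nl + 1] <- Inf
      aux[[sprintf("a%02d", j)]] <-
        paste0("l", as.integer(cut(score, breaks = unique(cuts),
                                   labels = FALSE, include.lowest = TRUE)))
    }

    records <- data.frame(
      sample_id = sprintf("S%06d", seq_len(n)),
      city = city, category = category,
      project_id = proj$project_id,
      channel = channel,
      production_region = production_region,
      year = year,
      test_result = t_res,
      method_test_limit = signif(pmax(mx, mn) / 100, 4),
      min_limit = mn, max_limit = mx, unit = proj$unit,
      stringsAsFactors = FALSE, row.names = NULL)
    records <- cbind(records, as.data.frame(aux, stringsAsFactors = FALSE))
    c(list(records = records), tables, list(config = config))
  })
}

#' Variable specification for a campaign's auxiliary columns
#'
#' Builds the `variable_spec` table that [encode_mixed()] expects for the
#' auxiliary columns of a generated (or identically shaped) records
#' table: `q*` columns are quantitative, `a*` columns qualitative; the
#' sampled city, food category and sales channel also enter the factor
#' analysis as qualitative items.
#'
#' @param records a records data.frame.
#' @return data.frame with columns `variable`, `type`, `include`.
#' @export
campaign_variable_spec <- function(records) {
  quant <- grep("^q[0-9]+$", names(records), value = TRUE)
  qual <- grep("^a[0-9]+$", names(records), value = TRUE)
  core_qual <- intersect(c("city", "category", "channel", "year"),
                         names(records))
  data.frame(
    variable = c(quant, qual, core_qual),
    type = c(rep("quantitative", length(quant)),
             rep("qualitative", length(qual) + length(core_qual))),
    include = TRUE,
    stringsAsFactors = FALSE)
}
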