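#' Default expert weight tables
#'
#' Size-class weights for sales channels (large 1.0, medium 1.4,
#' small 1.1) and production-region class weights (local city 1.0, rest of
#' the home region 0.8, other regions 0.7), as elicited from expert
#' questionnaires in the surveillance programme this package models.
#'
#' @return named numeric vector.
#' @export
default_channel_weights <- function() {
  c(large = 1.0, medium = 1.4, small = 1.1)
}

#' @rdname default_channel_weights
#' @export
default_region_weights <- function() {
  c(local_city = 1.0, local_region = 0.8, other_region = 0.7)
}

#' Assemble a weight configuration
#'
#' Bundles the four expert/consumption weight sources used to modify the
#' simple qualification degree: per-capita consumption by food category,
#' 1-5 hazard scores by test project, a channel -> size-class map with
#' size weights, and region-class weights.
#'
#' @param consumption data.frame with columns `category`, `per_capita`
#'   (non-negative; per-capita purchase quantities from a statistical
#'   yearbook).
#' @param hazards data.frame with columns `project_id`, `score` (integers
#'   1-5, 5 = highest toxicity).
#' @param channels data.frame with columns `channel_name`, `size_class`
#'   (one of `large`, `medium`, `small`).
#' @param channel_weights,region_weights named numeric overrides of the
#'   expert defaults.
#' @param region_city_map optional data.frame (`city`, `region`) mapping
#'   production cities to their parent region, used to classify
#'   production-region labels.
#' @param permissive logical; if `TRUE`, unknown projects fall back to
#'   hazard score 1 and unknown channels to size `small`, with a warning.
#' @return object of class `weight_config`.
#' @export
weight_config <- function(consumption, hazards, channels,
                          channel_weights = default_channel_weights(),
                          region_weights = default_region_weights(),
                          region_city_map = NULL,
                          permissive = FALSE) {
  for (nm in c("category", "per_capita")) {
    if (!nm %in% names(consumption)) {
      stop_stage("weights", "consumption table lacks column '", nm, "'")
    }
  }
  if (anyDuplicated(consumption$category)) {
    stop_stage("weights", "duplicate categories in consumption table")
  }
  if (any(consumption$per_capita < 0) || all(consumption$per_capita == 0)) {
    stop_stage("weights", "consumption must be non-negative with a positive total")
  }
  if (!all(c("project_id", "score") %in% names(hazards))) {
    stop_stage("weights", "hazards table needs columns project_id, score")
  }
  if (!all(hazards$score %in% 1:5)) {
    stop_stage("weights", "hazard scores must be integers in 1..5")
  }
  if (!all(c("channel_name", "size_class") %in% names(channels))) {
    stop_stage("weights", "channels table needs columns channel_name, size_class")
  }
  if (!all(channels$size_class %in% names(channel_weights))) {
    stop_stage("weights", "channel size classes must be one of: ",
               paste(names(channel_weights), collapse = ", "))
  }
  if (any(channel_weights <= 0) || any(region_weights <= 0)) {
    stop_stage("weights", "all weights must be positive")
  }
  structure(list(
    consumption_weights = consumption_weights(consumption),
    hazard_scores = stats::setNames(as.integer(hazards$score),
                                    as.character(hazards$project_id)),
    channel_size_map = stats::setNames(as.character(channels$size_class),
                                       as.character(channels$channel_name)),
    channel_weights = channel_weights,
    region_weights = region_weights,
    region_city_map = region_city_map,
    permissive = isTRUE(permissive)
  ), class = "weight_config")
}

#' Consumption weights from a per-capita consumption table
#'
#' Normalizes per-capita consumption `n_i` of each food category to
#' weights `w_i = n_i / sum(n)`, which sum to 1.
#'
#' @param consumption data.frame with columns `category`, `per_capita`.
#' @return named numeric vector of weights summing to 1.
#' @examples
#' consumption_weights(data.frame(category = c("A", "B", "C"),
#'                                per_capita = c(2, 1, 1)))
#' @export
consumption_weights <- function(consumption) {
  total <- sum(consumption$per_capita)
  if (!is.finite(total) || total <= 0) {
    stop_stage("weights", "degenerate consumption table: total must be > 0")
  }
  stats::setNames(consumption$per_capita / total,
                  as.character(consumption$category))
}

#' Project hazard weight
#'
#' Looks up the expert 1-5 hazard score of a test project. Used raw (not
#' normalized) in the comprehensive degree.
#'
#' @param project_id character vector of project identifiers.
#' @param config a [weight_config()].
#' @return integer vector of scores in 1..5.
#' @export
hazard_weight <- function(project_id, config) {
  key <- as.character(project_id)
  score <- config$hazard_scores[key]
  unknown <- is.na(score)
  if (any(unknown)) {
    if (config$permissive) {
      warning(sprintf("weights: %d unknown project(s), falling back to hazard score 1",
                      sum(unknown)), call. = FALSE)
      score[unknown] <- 1L
    } else {
      stop_stage("weights", "no hazard score for project(s): ",
                 paste(unique(key[unknown]), collapse = ", "))
    }
  }
  unname(score)
}

#' Sales channel weight
#'
#' Maps a channel name to its size class and returns the size weight
#' (defaults: large 1.0, medium 1.4, small 1.1).
#'
#' @inheritParams hazard_weight
#' @param channel_name character vector of channel names.
#' @return numeric vector of channel weights.
#' @export
channel_weight <- function(channel_name, config) {
  size <- config$channel_size_map[as.character(channel_name)]
  unknown <- is.na(size)
  if (any(unknown)) {
    if (config$permissive) {
      warning(sprintf("weights: %d unmapped channel(s), treated as 'small'",
                      sum(unknown)), call. = FALSE)
      size[unknown] <- "small"
    } else {
      stop_stage("weights", "no size class for channel(s): ",
                 paste(unique(as.character(channel_name)[unknown]), collapse = ", "))
    }
  }
  unname(config$channel_weights[size])
}

#' Production-region weight
#'
#' Classifies where a food was produced relative to where it was sampled:
#' `local_city` if the production region equals the sampled city,
#' `local_region` if the production city belongs to the home region, else
#' `other_region`; then returns the configured class weight (defaults
#' 1.0 / 0.8 / 0.7). Classification is total: any unrecognized label is
#' `other_region`.
#'
#' @param production_region character vector: city of the labeled
#'   production enterprise, or an outside-region label.
#' @param sampled_city character vector: city where the sample was taken.
#' @param home_region single string naming the home region.
#' @inheritParams hazard_weight
#' @return numeric vector of region weights.
#' @export
region_weight <- function(production_region, sampled_city, home_region, config) {
  n <- max(length(production_region), length(sampled_city))
  prod <- rep_len(as.character(production_region), n)
  city <- rep_len(as.character(sampled_city), n)
  cls <- rep("other_region", n)
  if (!is.null(config$region_city_map)) {
    in_region <- prod %in%
      config$region_city_map$city[config$region_city_map$region == home_region]
    cls[in_region] <- "local_region"
  } else {
    cls[prod == home_region] <- "local_region"
  }
  cls[prod == city] <- "local_city"
  unname(config$region_weights[cls])
}
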