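# Seeded synthetic ratings cohorts emulating a liquid-food validation study:
# fixed dish composition, an empirical intake distribution, and per-method,
# per-dish additive Gaussian rater error discretized onto the 0-10 scale.

#' Empirical converted-intake distribution of the reference study
#'
#' Probability mass over converted values 0-10, normalized from the
#' published dish counts 23, 6, 3, 2, 9, 6, 6, 6, 3, 6, 230 (N = 300;
#' mean intake rate 84.7%). Heavy mass at 10 reflects that three quarters
#' of hospital liquid-food dishes are finished completely.
#'
#' @return Named numeric vector of length 11 summing to 1 (names "0".."10").
#' @export
reference_intake_pmf <- function() {
  counts <- c(23, 6, 3, 2, 9, 6, 6, 6, 3, 6, 230)
  stats::setNames(counts / sum(counts), as.character(0:10))
}

#' Side-dish-2 composition of the reference study
#'
#' Exact counts of the five side-2 items per 100 meals.
#'
#' @return Named integer vector (dish ids of [reference_menu()]).
#' @export
reference_side2_counts <- function() {
  c(ferm_milk = 31L, peach = 18L, grape = 12L, orange = 13L, mixed = 26L)
}

#' Default per-channel rater error models
#'
#' One model per estimation channel. Per-dish signed biases follow the
#' published per-dish mean errors of each method (AI underestimates gruel
#' and soup; image-visual estimation overestimates most dishes;
#' direct-visual estimation is close to unbiased). Dispersions — the
#' standard deviation of the additive Gaussian error before rounding and
#' clamping — default to 1.0 scale units for the photo-based channels (AI
#' and image-visual) and 0.4 for direct-visual, matching the published
#' ordering of method accuracies qualitatively, not exactly.
#'
#' @return Named list of channel models, each a list with `method`, `bias`
#'   (named per-dish vector) and `dispersion` (named per-dish vector).
#' @export
reference_channel_models <- function() {
  dishes <- c("gruel", "soup", "orange", "ferm_milk", "grape", "peach", "mixed")
  bias <- list(
    ai            = c(-0.22, -0.53, -0.15, -0.06, 0.25, 0.22, 0.08),
    image_visual  = c( 0.54,  0.13,  0.85,  0.19, 0.50, 0.00, 0.23),
    direct_visual = c( 0.24, -0.07,  0.00,  0.00, -0.25, 0.11, 0.04)
  )
  disp <- c(ai = 1.0, image_visual = 1.0, direct_visual = 0.4)
  lapply(stats::setNames(names(bias), names(bias)), function(m) {
    channel_error_model(
      method = m,
      bias = stats::setNames(bias[[m]], dishes),
      dispersion = stats::setNames(rep(disp[[m]], length(dishes)), dishes)
    )
  })
}

#' Construct a channel error model
#'
#' An estimation channel is modelled as `clamp(round(true + bias_dish +
#' Normal(0, dispersion_dish)), 0, 10)`: an additive per-dish systematic
#' bias plus Gaussian rater noise, rounded to the nearest scale value and
#' clamped to the valid range. The clamp produces the pileup of estimates
#' at 10 seen when most dishes are fully eaten.
#'
#' @param method Method label (one of `"ai"`, `"image_visual"`,
#'   `"direct_visual"`).
#' @param bias Named numeric vector: signed bias per dish id, in converted
#'   scale units.
#' @param dispersion Named numeric vector (or scalar, recycled): standard
#'   deviation of the pre-discretization error per dish id; must be >= 0.
#' @return List of class `channel_error_model`.
#' @export
channel_error_model <- function(method, bias, dispersion) {
  if (!is.character(method) || length(method) != 1L) {
    stop_validation("method must be a single label")
  }
  if (is.null(names(bias)) || anyNA(names(bias))) {
    stop_validation("bias must be a named per-dish vector")
  }
  if (length(dispersion) == 1L && is.null(names(dispersion))) {
    dispersion <- stats::setNames(rep(dispersion, length(bias)), names(bias))
  }
  if (!all(names(bias) %in% names(dispersion))) {
    stop_validation("dispersion must cover every dish in bias")
  }
  if (any(!is.finite(bias)) || any(!is.finite(dispersion)) || any(dispersion < 0)) {
    stop_validation("bias must be finite and dispersion finite and >= 0")
  }
  structure(list(method = method, bias = bias, dispersion = dispersion),
            class = "channel_error_model")
}

#' Configure a synthetic cohort
#'
#' @param n_meals Number of meals to simulate (default 100, the reference
#'   study size). Each meal is thin rice gruel + vegetable soup + one
#'   side-2 item.
#' @param side2_counts Named vector of side-2 composition. When the counts
#'   sum to `n_meals` they are used exactly (randomly assigned to meals);
#'   otherwise they act as sampling weights.
#' @param intake_pmf Probability mass over converted values 0-10 for true
#'   per-dish intake; must sum to 1.
#' @param appetite_coupling In `[0, 1]`: probability that a dish inherits a
#'   shared per-meal latent intake draw instead of an independent draw.
#'   0 (default) draws every dish independently; the marginal distribution
#'   is `intake_pmf` either way.
#' @param channels Named list of [channel_error_model()]s for the
#'   estimation methods to simulate.
#' @param menu An `intake_menu` supplying dish ids and portion weights.
#' @param seed Master integer seed; per-channel substreams are derived from
#'   it so adding or removing one channel never perturbs another.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_meals = 100,
                          side2_counts = reference_side2_counts(),
                          intake_pmf = reference_intake_pmf(),
                          appetite_coupling = 0,
                          channels = reference_channel_models(),
                          menu = reference_menu(),
                          seed = 1L) {
  if (!is_count(n_meals) || n_meals < 1) {
    stop_validation("n_meals must be a positive integer")
  }
  if (length(intake_pmf) != 11L || any(intake_pmf < 0) || any(intake_pmf > 1) ||
      abs(sum(intake_pmf) - 1) > 1e-9) {
    stop_validation("intake_pmf must be 11 probabilities summing to 1")
  }
  if (!is.numeric(appetite_coupling) || appetite_coupling < 0 ||
      appetite_coupling > 1) {
    stop_validation("appetite_coupling must lie in [0, 1]")
  }
  if (is.null(names(side2_counts)) || any(side2_counts < 0)) {
    stop_validation("side2_counts must be a named non-negative vector")
  }
  if (!all(names(side2_counts) %in% menu$dish_id)) {
    stop_validation("side2_counts names must be menu dish ids")
  }
  stopifnot(inherits(menu, "intake_menu"))
  if (!is_count(seed)) stop_validation("seed must be an integer")
  structure(
    list(n_meals = as.integer(n_meals), side2_counts = side2_counts,
         intake_pmf = stats::setNames(as.numeric(intake_pmf), as.character(0:10)),
         appetite_coupling = appetite_coupling, channels = channels,
         menu = menu, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# run expr under a fixed seed without disturbing the caller's RNG state
with_seed_local <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic substream seed for a labelled channel; stays within exact
# double-precision integer range and below 2^31
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 1009 + h * 97) %% (2^31 - 1))
}

#' Draw true per-dish intakes with consistent weight pairs
#'
#' Builds `n_meals` meals (gruel + soup + one side-2 item per the
#' configured composition), draws each dish's true converted value from
#' the intake distribution (optionally mixed with a shared per-meal draw),
#' and back-computes a pre/post weight pair whose weighed fraction
#' reconverts to the true value exactly.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `meal_id`, `dish_instance_id`, `dish_id`,
#'   `true_value`, `pre_weight_g`, `post_weight_g`.
#' @export
generate_true_intakes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_local(substream_seed(config$seed, "truth"), {
    n <- config$n_meals
    counts <- config$side2_counts
    if (sum(counts) == n) {
      side2 <- sample(rep(names(counts), counts))
    } else {
      side2 <- sample(names(counts), n, replace = TRUE,
                      prob = counts / sum(counts))
    }
    meal_ids <- sprintf("meal%03d", seq_len(n))
    grid <- tibble(
      meal_id = rep(meal_ids, each = 3),
      dish_id = as.vector(rbind("gruel", "soup", side2))
    )
    grid$dish_instance_id <- paste(grid$meal_id, grid$dish_id, sep = "_")
    values <- 0:10
    shared <- sample(values, n, replace = TRUE, prob = config$intake_pmf)
    indep <- sample(values, nrow(grid), replace = TRUE, prob = config$intake_pmf)
    use_shared <- stats::runif(nrow(grid)) < config$appetite_coupling
    grid$true_value <- as.integer(ifelse(
      use_shared, shared[match(grid$meal_id, meal_ids)], indep
    ))
    menu <- config$menu
    grid$pre_weight_g <- menu$portion_weight_g[match(grid$dish_id, menu$dish_id)]
    grid$post_weight_g <- grid$pre_weight_g * (1 - grid$true_value / 10)
    grid[c("meal_id", "dish_instance_id", "dish_id", "true_value",
           "pre_weight_g", "post_weight_g")]
  })
}

#' Apply a channel error model to true converted values
#'
#' Simulates one estimation channel: per-dish bias plus Gaussian noise,
#' rounded to the nearest integer and clamped to 0-10.
#'
#' @param true_values Integer vector of true converted values.
#' @param dish_ids Character vector of dish ids, parallel to `true_values`.
#' @param model A [channel_error_model()].
#' @return Integer vector of estimated converted values.
#' @export
apply_channel <- function(true_values, dish_ids, model) {
  stopifnot(inherits(model, "channel_error_model"))
  assert_converted(true_values, "true_values")
  unknown <- setdiff(unique(dish_ids), names(model$bias))
  if (length(unknown) > 0) {
    stop_validation(
      paste0("channel model has no entry for dish(es): ",
             paste(unknown, collapse = ", ")),
      class = "intakeval_config_error"
    )
  }
  bias <- model$bias[dish_ids]
  disp <- model$dispersion[dish_ids]
  noisy <- true_values + bias + stats::rnorm(length(true_values), 0, disp)
  as.integer(clamp(round(noisy), 0, 10))
}

#' Generate a complete synthetic ratings dataset
#'
#' One weighing record (weight pair) plus one record per configured
#' estimation channel for every evaluable dish instance, in the long
#' ratings format of [load_ratings()]. Each channel consumes an
#' independent random substream derived from the master seed, so two runs
#' with the same seed are identical and adding a channel leaves the
#' others' draws untouched.
#'
#' @param config A [cohort_config()].
#' @return Tibble of ratings rows (`meal_id`, `dish_instance_id`,
#'   `dish_id`, `method`, `pre_weight_g`, `post_weight_g`,
#'   `converted_value`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- generate_true_intakes(config)
  weighing <- tibble(
    meal_id = truth$meal_id,
    dish_instance_id = truth$dish_instance_id,
    dish_id = truth$dish_id,
    method = "weighing",
    pre_weight_g = truth$pre_weight_g,
    post_weight_g = truth$post_weight_g,
    converted_value = truth$true_value
  )
  channel_rows <- lapply(config$channels, function(model) {
    est <- with_seed_local(
      substream_seed(config$seed, model$method),
      apply_channel(truth$true_value, truth$dish_id, model)
    )
    tibble(
      meal_id = truth$meal_id,
      dish_instance_id = truth$dish_instance_id,
      dish_id = truth$dish_id,
      method = model$method,
      pre_weight_g = NA_real_,
      post_weight_g = NA_real_,
      converted_value = est
    )
  })
  dplyr::bind_rows(c(list(weighing), channel_rows))
}

#' Read a cohort configuration from JSON
#'
#' The JSON document mirrors [cohort_config()]: optional fields
#' `n_meals`, `side2_counts` (object dish -> count), `intake_pmf` (array
#' of 11 probabilities), `appetite_coupling`, `seed`, and `channels`
#' (object method -> `{bias: {dish: value}, dispersion: {dish: value}}`).
#' Omitted fields take the reference-study defaults.
#'
#' @param path Path to the JSON config, or `NULL` for all defaults.
#' @param seed Optional seed overriding the file's.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- if (is.null(raw$channels)) {
    reference_channel_models()
  } else {
    lapply(stats::setNames(names(raw$channels), names(raw$channels)), function(m) {
      ch <- raw$channels[[m]]
      channel_error_model(m, unlist(ch$bias), unlist(ch$dispersion))
    })
  }
  cohort_config(
    n_meals = raw$n_meals %|||% 100,
    side2_counts = if (is.null(raw$side2_counts)) reference_side2_counts()
                   else unlist(raw$side2_counts),
    intake_pmf = raw$intake_pmf %|||% reference_intake_pmf(),
    appetite_coupling = raw$appetite_coupling %|||% 0,
    channels = channels,
    seed = seed %|||% (raw$seed %|||% 1L)
  )
}
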