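# Conversions between weighed leftovers, the 11-point converted intake value,
# and nutrient intake.

# Upper bin boundaries of the converted-value scale. Class 0 covers [0, 0.05],
# class k (k = 1..9) covers (0.05 + 0.10(k-1), 0.05 + 0.10k], class 10 covers
# (0.95, 1]: bins are lower-open / upper-closed so the rule is a total
# function on [0, 1].
CONVERTED_BOUNDARIES <- seq(0.05, 0.95, by = 0.10)
BOUNDARY_TOL <- 1e-9

#' Intake fraction from a pre/post weight pair
#'
#' Weighed intake is the difference between the served (pre-meal) and
#' returned (post-meal) dish weight, expressed as a fraction of the served
#' weight. Post-meal weights slightly above the pre-meal weight are expected
#' measurement noise on a +/- 2 g kitchen scale, so negative fractions are
#' clamped to 0 with a warning rather than rejected; fractions above 1
#' (post weight below zero cannot occur) are clamped likewise.
#'
#' @param pre_weight_g Served weight in grams (> 0). Vectorised.
#' @param post_weight_g Returned weight in grams (>= 0). Vectorised.
#' @return Numeric vector of intake fractions in `[0, 1]`.
#' @export
weight_pair_to_fraction <- function(pre_weight_g, post_weight_g) {
  if (!is.numeric(pre_weight_g) || !is.numeric(post_weight_g)) {
    stop_validation("weights must be numeric")
  }
  if (length(pre_weight_g) != length(post_weight_g)) {
    stop_validation("pre and post weight vectors must have equal length")
  }
  if (any(!is.finite(pre_weight_g)) || any(pre_weight_g <= 0)) {
    stop_validation("pre_weight_g must be positive and finite")
  }
  if (any(!is.finite(post_weight_g)) || any(post_weight_g < 0)) {
    stop_validation("post_weight_g must be non-negative and finite")
  }
  frac <- (pre_weight_g - post_weight_g) / pre_weight_g
  n_clamped <- sum(frac < 0 | frac > 1)
  if (n_clamped > 0) {
    warning(sprintf(
      "%d weight pair(s) outside [0, 1] intake fraction; clamped (scale noise)",
      n_clamped
    ), call. = FALSE)
  }
  clamp(frac, 0, 1)
}

#' Convert an intake fraction to the 11-point scale
#'
#' Maps a fraction of the portion eaten to the integer converted value 0-10:
#' 0 for 5% or less, 10 for more than 95%, and otherwise the decile bin the
#' fraction falls in (bins are lower-open / upper-closed, so exactly 15%
#' scores 1, not 2). Each unit of the scale represents roughly 10% of the
#' served portion.
#'
#' @param fraction Numeric vector of intake fractions in `[0, 1]`.
#' @return Integer vector of converted values in `0:10`.
#' @export
fraction_to_converted <- function(fraction) {
  if (!is.numeric(fraction)) stop_validation("fraction must be numeric")
  if (any(!is.finite(fraction)) || any(fraction < -BOUNDARY_TOL) ||
      any(fraction > 1 + BOUNDARY_TOL)) {
    stop_validation("fraction must lie in [0, 1]")
  }
  # count strictly exceeded boundaries; the tolerance keeps values that are
  # mathematically on a boundary (e.g. 3/20) in the lower bin despite
  # floating-point representation error
  vapply(
    fraction,
    function(f) sum(f > CONVERTED_BOUNDARIES + BOUNDARY_TOL),
    integer(1)
  )
}

#' Converted intake value from a leftover class
#'
#' Leftover raters (human or model) report the amount left over in tenths of
#' the portion; intake is the complement on the same 11-point scale.
#'
#' @param leftover_class Integer vector in `0:10`; 0 means no leftovers.
#' @return Integer vector of converted intake values, `10 - leftover_class`.
#' @export
leftover_class_to_intake <- function(leftover_class) {
  assert_converted(leftover_class, "leftover_class")
  10L - as.integer(leftover_class)
}

assert_converted <- function(v, name = "converted_value") {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v != trunc(v)) ||
      any(v < 0) || any(v > 10)) {
    stop_validation(sprintf("`%s` must be integer(s) in 0..10", name))
  }
  invisible(v)
}

#' Nutrient intake of one dish at a converted value
#'
#' Scales the dish's full-portion nutrient content by the ingested fraction
#' `converted_value / 10`. A converted value of 10 returns the full portion
#' content; 0 returns an all-zero profile.
#'
#' @param dish One row of an `intake_menu` (or any list-like with
#'   `energy_kcal`, `protein_g`, `fat_g`, `carbohydrate_g`).
#' @param converted_value Integer in `0:10`.
#' @return Named numeric vector with elements `energy_kcal`, `protein_g`,
#'   `fat_g`, `carbohydrate_g`.
#' @export
dish_nutrient_intake <- function(dish, converted_value) {
  assert_converted(converted_value)
  if (length(converted_value) != 1L) {
    stop_validation("converted_value must be a single value")
  }
  nut <- vapply(NUTRIENT_COLS, function(col) {
    x <- dish[[col]]
    if (is.null(x) || !is.numeric(x) || length(x) != 1L) {
      stop_validation(sprintf("dish is missing nutrient column `%s`", col))
    }
    as.numeric(x)
  }, numeric(1))
  nut * (converted_value / 10)
}

#' Nutrient intake totals for one meal under one method
#'
#' Sums [dish_nutrient_intake()] over the meal's evaluable dishes. Records
#' for non-evaluable dishes (packaged beverages, seasonings) are ignored;
#' every evaluable dish of the meal must have exactly one record.
#'
#' @param records Data frame of intake records for a single meal and single
#'   method, with columns `dish_id` and `converted_value`.
#' @param menu An `intake_menu` containing every `dish_id` referenced.
#' @param meal_dish_ids Dish ids composing the meal. Defaults to the dish ids
#'   present in `records`; pass the meal's full composition to have missing
#'   evaluable records rejected.
#' @return Named numeric vector of meal totals (`energy_kcal`, `protein_g`,
#'   `fat_g`, `carbohydrate_g`).
#' @export
meal_nutrient_intake <- function(records, menu, meal_dish_ids = NULL) {
  stopifnot(inherits(menu, "intake_menu"))
  records <- as_tibble(records)
  meal_dish_ids <- meal_dish_ids %|||% unique(records$dish_id)
  unknown <- setdiff(c(records$dish_id, meal_dish_ids), menu$dish_id)
  if (length(unknown) > 0) {
    stop_validation(
      paste0("dish_id(s) not in menu: ", paste(unknown, collapse = ", ")),
      class = "intakeval_join_error"
    )
  }
  evaluable_ids <- intersect(meal_dish_ids, menu$dish_id[menu$evaluable])
  joined <- records[records$dish_id %in% evaluable_ids, , drop = FALSE]
  if (anyDuplicated(joined$dish_id)) {
    stop_validation("more than one record for the same evaluable dish")
  }
  unrated <- setdiff(evaluable_ids, joined$dish_id)
  if (length(unrated) > 0 || nrow(joined) == 0L) {
    stop_validation(
      paste0("meal is missing record(s) for evaluable dish(es): ",
             paste(unrated, collapse = ", ")),
      class = "intakeval_incomplete_meal_error"
    )
  }
  totals <- c(energy_kcal = 0, protein_g = 0, fat_g = 0, carbohydrate_g = 0)
  for (i in seq_len(nrow(joined))) {
    row <- menu[menu$dish_id == joined$dish_id[i], ]
    totals <- totals + dish_nutrient_intake(row, joined$converted_value[i])
  }
  totals
}

#' Read a long-format ratings file
#'
#' Expects a UTF-8 CSV with header
#' `meal_id,dish_instance_id,dish_id,method,pre_weight_g,post_weight_g,converted_value`.
#' Weighing rows carry the weight pair and leave `converted_value` empty;
#' their converted value is derived via [weight_pair_to_fraction()] and
#' [fraction_to_converted()]. Estimation rows carry `converted_value`
#' directly.
#'
#' @param path Path to the ratings CSV.
#' @return Tibble of intake records with a populated integer
#'   `converted_value` column for every row.
#' @export
load_ratings <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      meal_id = readr::col_character(),
      dish_instance_id = readr::col_character(),
      dish_id = readr::col_character(),
      method = readr::col_character(),
      pre_weight_g = readr::col_double(),
      post_weight_g = readr::col_double(),
      converted_value = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_ratings(raw)
}

validate_ratings <- function(raw) {
  raw <- as_tibble(raw)
  required <- c("meal_id", "dish_instance_id", "dish_id", "method",
                "pre_weight_g", "post_weight_g", "converted_value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_format(paste0("ratings file missing columns: ",
                       paste(missing, collapse = ", ")))
  }
  bad_method <- setdiff(unique(raw$method), intake_methods())
  if (length(bad_method) > 0) {
    stop_format(paste0("unknown method label(s): ",
                       paste(bad_method, collapse = ", ")))
  }
  is_weighing <- raw$method == "weighing"
  if (any(is_weighing & (is.na(raw$pre_weight_g) | is.na(raw$post_weight_g)))) {
    stop_validation("weighing rows must carry pre and post weights")
  }
  if (any(!is_weighing & is.na(raw$converted_value))) {
    stop_validation("estimation rows must carry a converted_value")
  }
  if (any(is_weighing)) {
    frac <- weight_pair_to_fraction(
      raw$pre_weight_g[is_weighing], raw$post_weight_g[is_weighing]
    )
    raw$converted_value[is_weighing] <- fraction_to_converted(frac)
  }
  assert_converted(raw$converted_value)
  raw$converted_value <- as.integer(raw$converted_value)
  raw
}

#' Write a ratings table to CSV
#'
#' Writes the long ratings format defined in [load_ratings()]. Weighing rows
#' keep their weight pair and an empty `converted_value` field (it is
#' re-derived on load); estimation rows keep the converted value and empty
#' weights.
#'
#' @param ratings Ratings tibble (as produced by [generate_dataset()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  out <- as_tibble(ratings)
  out$converted_value[out$method == "weighing"] <- NA_integer_
  out$pre_weight_g[out$method != "weighing"] <- NA_real_
  out$post_weight_g[out$method != "weighing"] <- NA_real_
  cols <- c("meal_id", "dish_instance_id", "dish_id", "method",
            "pre_weight_g", "post_weight_g", "converted_value")
  readr::write_csv(out[cols], path, na = "")
  invisible(path)
}
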