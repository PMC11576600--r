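#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select group_by summarise ungroup
#'   arrange left_join bind_rows across all_of n
NULL

MENU_CATEGORIES <- c("staple", "side1", "side2", "beverage", "seasoning")
NUTRIENT_COLS <- c("energy_kcal", "protein_g", "fat_g", "carbohydrate_g")

#' Construct a validated menu registry
#'
#' A menu registry is a tibble with one row per dish: its identifier, display
#' name, course category, per-full-portion nutrient content (kcal and grams)
#' and served portion weight in grams. Dishes in the `beverage` and
#' `seasoning` categories are flagged non-evaluable: leftover fractions of
#' packaged items cannot be scored visually, so they are excluded from all
#' downstream intake statistics.
#'
#' @param dishes Data frame with columns `dish_id`, `name`, `category`,
#'   `energy_kcal`, `protein_g`, `fat_g`, `carbohydrate_g`,
#'   `portion_weight_g`.
#' @return A tibble of class `intake_menu` with a derived logical
#'   `evaluable` column.
#' @export
new_menu <- function(dishes) {
  dishes <- as_tibble(dishes)
  required <- c("dish_id", "name", "category", NUTRIENT_COLS, "portion_weight_g")
  missing <- setdiff(required, names(dishes))
  if (length(missing) > 0) {
    stop_format(paste0("menu is missing columns: ", paste(missing, collapse = ", ")))
  }
  dishes$dish_id <- as.character(dishes$dish_id)
  dishes$name <- as.character(dishes$name)
  dishes$category <- as.character(dishes$category)
  bad_cat <- setdiff(unique(dishes$category), MENU_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop_format(paste0("unknown category label(s): ", paste(bad_cat, collapse = ", ")))
  }
  if (anyDuplicated(dishes$dish_id)) {
    stop_validation("duplicate dish_id in menu")
  }
  nut <- as.matrix(dishes[NUTRIENT_COLS])
  if (!all(is.finite(nut)) || any(nut < 0)) {
    stop_validation("nutrient values must be finite and non-negative")
  }
  if (!all(is.finite(dishes$portion_weight_g)) || any(dishes$portion_weight_g <= 0)) {
    stop_validation("portion_weight_g must be positive and finite")
  }
  dishes$evaluable <- !(dishes$category %in% c("beverage", "seasoning"))
  out <- dishes[c(required, "evaluable")]
  class(out) <- c("intake_menu", class(out))
  out
}

#' Read a menu registry from CSV
#'
#' Expects a UTF-8 CSV with header
#' `dish_id,name,category,energy_kcal,protein_g,fat_g,carbohydrate_g,portion_weight_g`.
#'
#' @param path Path to the menu CSV file.
#' @return An `intake_menu` tibble (see [new_menu()]).
#' @export
load_menu <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  new_menu(raw)
}

#' Write a menu registry to CSV
#'
#' The derived `evaluable` column is not written; it is recomputed from the
#' category on reload, so a write/read cycle is an identity.
#'
#' @param menu An `intake_menu` tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_menu <- function(menu, path) {
  stopifnot(inherits(menu, "intake_menu"))
  readr::write_csv(menu[setdiff(names(menu), "evaluable")], path)
  invisible(path)
}

#' Reference liquid-food study menu
#'
#' The seven-dish lunch menu of a hospital liquid-food validation cohort:
#' thin rice gruel (staple), vegetable soup (side dish 1), and five side-2
#' items (fermented milk and peach, grape, orange and mixed juices), with
#' published per-portion energy (kcal), protein, fat and carbohydrate (g).
#' Portion weights are not part of the published composition table; the
#' registry carries plausible serving weights (200 g gruel, 150 g soup and
#' beverages). All intake arithmetic depends only on the ingested fraction,
#' so these weights never affect converted values or nutrient totals.
#'
#' @return An `intake_menu` tibble with seven evaluable dishes.
#' @export
reference_menu <- function() {
  new_menu(tibble(
    dish_id = c("gruel", "soup", "ferm_milk", "peach", "grape", "orange", "mixed"),
    name = c(
      "Thin rice gruel", "Vegetable soup", "Fermented milk",
      "Peach juice", "Grape juice", "Orange juice", "Mixed juice"
    ),
    category = c("staple", "side1", rep("side2", 5)),
    energy_kcal = c(32, 3, 42, 47, 47, 46, 66),
    protein_g = c(0.5, 0.1, 0.3, 0.1, 0.1, 0.1, 0.5),
    fat_g = c(0.1, 0, 0, 0.1, 0.1, 0.1, 0),
    carbohydrate_g = c(7.0, 0.5, 10.5, 13.0, 13.0, 12.6, 13.7),
    portion_weight_g = c(200, 150, 150, 150, 150, 150, 150)
  ))
}
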