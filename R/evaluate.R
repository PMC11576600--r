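# Orchestrates a menu registry plus a long ratings table into the full
# method-agreement result set: intake distribution, meal-level per-nutrient
# comparisons, dish-level error breakdowns, per-dish signed-error tests and
# ordinal confusion matrices.

# report-layer display units: energy kcal, protein/fat mg, carbohydrate g
NUTRIENTS <- c(energy = "energy_kcal", protein = "protein_g",
               fat = "fat_g", carbohydrate = "carbohydrate_g")
NUTRIENT_UNIT_FACTOR <- c(energy = 1, protein = 1000, fat = 1000, carbohydrate = 1)
NUTRIENT_UNIT_LABEL <- c(energy = "kcal", protein = "mg", fat = "mg",
                         carbohydrate = "g")

#' Run the full agreement evaluation
#'
#' Joins ratings against the menu, aligns every estimation channel with the
#' weighing reference, and computes: the distribution of weighed converted
#' values with the mean intake rate; meal-level nutrient-intake agreement
#' per nutrient and method (mean, SD, paired t, Spearman, RMSE, R-squared
#' and Bland-Altman limits); dish-level RMSE/R-squared per dish, nutrient
#' and method; per-dish signed mean errors with a Friedman test across the
#' estimation channels; and one 11x11 confusion matrix per method.
#'
#' Meal-level statistics use one observation per meal (summed evaluable
#' dishes); dish-level statistics use one observation per dish instance.
#' Protein and fat are reported in mg, energy in kcal, carbohydrate in g.
#' Only dish instances rated by the weighing channel and every estimation
#' channel present in the data enter the comparison (complete-case
#' alignment); excluded instances are counted in `n_excluded`.
#'
#' @param menu An `intake_menu` registry.
#' @param ratings Ratings tibble from [load_ratings()] or
#'   [generate_dataset()] (a `converted_value` for every row; weighing
#'   rows may carry weight pairs instead, as in the CSV interface).
#' @return List of class `intake_report`.
#' @export
run_evaluation <- function(menu, ratings) {
  stopifnot(inherits(menu, "intake_menu"))
  ratings <- as_tibble(ratings)
  if (nrow(ratings) == 0L) stop_validation("ratings table is empty")
  if (anyNA(ratings$converted_value)) {
    ratings <- validate_ratings(ratings)
  }
  unknown <- setdiff(unique(ratings$dish_id), menu$dish_id)
  if (length(unknown) > 0) {
    stop_validation(paste0("ratings reference unknown dish_id(s): ",
                           paste(unknown, collapse = ", ")),
                    class = "intakeval_join_error")
  }
  # non-evaluable dishes never enter the analysis
  evaluable_ids <- menu$dish_id[menu$evaluable]
  ratings <- ratings[ratings$dish_id %in% evaluable_ids, , drop = FALSE]
  methods_present <- intersect(estimation_methods(), unique(ratings$method))
  if (!"weighing" %in% ratings$method) {
    stop_validation("ratings contain no weighing (reference) records")
  }
  if (length(methods_present) == 0L) {
    stop_validation("ratings contain no estimation-method records")
  }
  weighed_ids <- ratings$dish_instance_id[ratings$method == "weighing"]
  orphans <- setdiff(ratings$dish_instance_id[ratings$method != "weighing"],
                     weighed_ids)
  if (length(orphans) > 0) {
    stop_validation(
      paste0("estimation record(s) without a weighing pair: ",
             paste(utils::head(orphans, 5), collapse = ", ")),
      class = "intakeval_alignment_error"
    )
  }

  # complete-case alignment across weighing + all present channels
  wide <- tidyr::pivot_wider(
    ratings[c("meal_id", "dish_instance_id", "dish_id", "method",
              "converted_value")],
    names_from = "method", values_from = "converted_value"
  )
  need <- c("weighing", methods_present)
  complete <- stats::complete.cases(wide[need])
  n_excluded <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2L) {
    stop_validation("fewer than 2 complete dish instances; nothing to evaluate")
  }

  # -- distribution of weighed converted values ------------------------------
  v <- wide$weighing
  dist_counts <- as.integer(table(factor(v, levels = 0:10)))
  distribution <- tibble(
    converted_value = 0:10,
    n = dist_counts,
    pct = 100 * dist_counts / length(v)
  )
  mean_intake_rate_pct <- mean(v) * 10

  # -- meal-level nutrient totals per method ---------------------------------
  nut_content <- menu[match(wide$dish_id, menu$dish_id), NUTRIENT_COLS]
  meal_totals <- lapply(stats::setNames(need, need), function(m) {
    frac <- wide[[m]] / 10
    per_dish <- nut_content * frac
    per_dish$meal_id <- wide$meal_id
    out <- per_dish %>%
      group_by(.data$meal_id) %>%
      summarise(across(all_of(NUTRIENT_COLS), sum), .groups = "drop") %>%
      arrange(.data$meal_id)
    out
  })

  per_nutrient <- dplyr::bind_rows(lapply(names(NUTRIENTS), function(nu) {
    col <- NUTRIENTS[[nu]]
    fac <- NUTRIENT_UNIT_FACTOR[[nu]]
    y <- meal_totals$weighing[[col]] * fac
    dplyr::bind_rows(lapply(methods_present, function(m) {
      x <- meal_totals[[m]][[col]] * fac
      s <- agreement_summary(x, y)
      tibble(
        nutrient = nu, unit = NUTRIENT_UNIT_LABEL[[nu]], method = m,
        n = s$n,
        measured_mean = mean(y), measured_sd = stats::sd(y),
        estimated_mean = mean(x), estimated_sd = stats::sd(x),
        t_p = s$t_p, rho = s$rho, rho_p = s$rho_p,
        rmse = s$rmse, r2 = s$r2,
        ba_mean_diff = s$bland_altman$mean_diff,
        ba_sd_diff = s$bland_altman$sd_diff,
        ba_loa_lower = s$bland_altman$loa_lower,
        ba_loa_upper = s$bland_altman$loa_upper
      )
    }))
  }))

  # -- dish-level nutrient errors --------------------------------------------
  per_dish <- dplyr::bind_rows(lapply(unique(wide$dish_id), function(d) {
    sel <- wide$dish_id == d
    dish_row <- menu[menu$dish_id == d, ]
    dplyr::bind_rows(lapply(names(NUTRIENTS), function(nu) {
      col <- NUTRIENTS[[nu]]
      fac <- NUTRIENT_UNIT_FACTOR[[nu]]
      content <- dish_row[[col]] * fac
      y <- content * wide$weighing[sel] / 10
      dplyr::bind_rows(lapply(methods_present, function(m) {
        x <- content * wide[[m]][sel] / 10
        tibble(
          dish_id = d, nutrient = nu, unit = NUTRIENT_UNIT_LABEL[[nu]],
          method = m, n = sum(sel),
          rmse = rmse(x, y),
          r2 = r_squared_or_degenerate(x, y)
        )
      }))
    }))
  }))

  # -- per-dish signed mean error + Friedman across channels -----------------
  per_dish_me <- dplyr::bind_rows(lapply(unique(wide$dish_id), function(d) {
    sel <- wide$dish_id == d
    y <- wide$weighing[sel]
    rows <- dplyr::bind_rows(lapply(methods_present, function(m) {
      tibble(dish_id = d, method = m, n = sum(sel),
             me = mean_error(wide[[m]][sel], y))
    }))
    if (length(methods_present) >= 2 && sum(sel) >= 2) {
      err <- sapply(methods_present, function(m) wide[[m]][sel] - y)
      fr <- friedman_rank_test(err)
      rows$friedman_chisq <- fr$chisq
      rows$friedman_p <- fr$p
    } else {
      rows$friedman_chisq <- NA_real_
      rows$friedman_p <- NA_real_
    }
    rows
  }))

  # -- confusion matrices (dish level, converted scale) ----------------------
  confusions <- lapply(stats::setNames(methods_present, methods_present),
                       function(m) confusion_matrix11(wide[[m]], wide$weighing))

  structure(
    list(
      n_meals = length(unique(wide$meal_id)),
      n_dishes = nrow(wide),
      n_excluded = n_excluded,
      methods = methods_present,
      distribution = distribution,
      mean_intake_rate_pct = mean_intake_rate_pct,
      per_nutrient = per_nutrient,
      per_dish = per_dish,
      per_dish_me = per_dish_me,
      confusions = confusions
    ),
    class = "intake_report"
  )
}

# dish-level series can be degenerate: dishes with zero content of a
# nutrient (or an all-equal reference) have zero total variance. Zero
# residual on zero variance is perfect agreement (R^2 = 1); nonzero
# residual on zero variance has no defined R^2 and is reported NA.
r_squared_or_degenerate <- function(x, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    if (sum((x - y)^2) == 0) return(1)
    return(NA_real_)
  }
  r_squared(x, y)
}

#' @export
print.intake_report <- function(x, ...) {
  cat(sprintf(
    "<intake_report> %d meals, %d dish instances (%d excluded), methods: %s\n",
    x$n_meals, x$n_dishes, x$n_excluded, paste(x$methods, collapse = ", ")
  ))
  cat(sprintf("mean intake rate: %.1f%%\n", x$mean_intake_rate_pct))
  invisible(x)
}

#' Serialize a report to full-precision JSON and 2-decimal tables
#'
#' Writes `report.json` (every statistic at full double precision) and
#' `tables.md` (aligned markdown tables rounded to 2 decimals, protein and
#' fat in mg) into `dir`. If the report contains no estimation methods a
#' notice is written instead of empty tables.
#'
#' @param report An `intake_report`.
#' @param dir Destination directory (created if absent).
#' @return Invisible named list of the paths written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "intake_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "tables.md")

  ser <- report
  ser$confusions <- lapply(report$confusions, function(cm) {
    list(counts = unname(apply(cm$counts, 1, as.list)), n = cm$n, mae = cm$mae)
  })
  class(ser) <- NULL
  jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  lines <- c("# Intake estimation agreement report", "")
  if (length(report$methods) == 0L) {
    lines <- c(lines, "No estimation methods present in the input.")
  } else {
    lines <- c(
      lines,
      sprintf("- Meals: %d; dish instances: %d (excluded: %d)",
              report$n_meals, report$n_dishes, report$n_excluded),
      sprintf("- Mean intake rate: %.1f%%", report$mean_intake_rate_pct),
      "",
      "## Distribution of weighed converted values", "",
      md_table(report$distribution),
      "",
      "## Meal-level nutrient agreement (protein/fat in mg)", "",
      md_table(report$per_nutrient),
      "",
      "## Dish-level errors by nutrient and method", "",
      md_table(report$per_dish),
      "",
      "## Per-dish signed mean error and Friedman test", "",
      md_table(report$per_dish_me),
      ""
    )
    for (m in names(report$confusions)) {
      cm <- report$confusions[[m]]
      mat <- as.data.frame(cm$counts)
      mat <- cbind(actual = rownames(cm$counts), mat)
      lines <- c(lines,
                 sprintf("## Confusion matrix: %s (MAE %.2f)", m, cm$mae), "",
                 md_table(mat), "")
    }
  }
  writeLines(lines, md_path)
  invisible(list(json = json_path, tables = md_path))
}

# minimal markdown pipe-table formatter, numbers to 2 decimals
md_table <- function(df) {
  df <- as.data.frame(df)
  fmt <- vapply(seq_along(df), function(j) {
    col <- df[[j]]
    if (is.numeric(col) && !all(col == trunc(col), na.rm = TRUE)) {
      formatC(col, format = "f", digits = 2)
    } else {
      as.character(col)
    }
  }, character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  fmt[is.na(df)] <- ""
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, rows), collapse = "\n")
}

#' Bland-Altman plot for one nutrient
#'
#' Scatter of per-meal differences (estimated minus weighed) against the
#' pair means, with the mean difference and 1.96 SD limits of agreement as
#' horizontal lines, faceted by estimation method. Requires ggplot2.
#'
#' @param menu,ratings As for [run_evaluation()].
#' @param nutrient One of `"energy"`, `"protein"`, `"fat"`,
#'   `"carbohydrate"`.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(menu, ratings, nutrient = "energy") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_validation("ggplot2 is required for plotting")
  }
  nutrient <- match.arg(nutrient, names(NUTRIENTS))
  report <- run_evaluation(menu, ratings)
  # rebuild meal-level series for the scatter
  ratings <- as_tibble(ratings)
  if (anyNA(ratings$converted_value)) ratings <- validate_ratings(ratings)
  col <- NUTRIENTS[[nutrient]]
  fac <- NUTRIENT_UNIT_FACTOR[[nutrient]]
  totals <- ratings %>%
    filter(.data$dish_id %in% menu$dish_id[menu$evaluable]) %>%
    left_join(menu[c("dish_id", col)], by = "dish_id") %>%
    mutate(intake = .data[[col]] * .data$converted_value / 10 * fac) %>%
    group_by(.data$meal_id, .data$method) %>%
    summarise(total = sum(.data$intake), .groups = "drop")
  wide <- tidyr::pivot_wider(totals, names_from = "method",
                             values_from = "total")
  long <- dplyr::bind_rows(lapply(report$methods, function(m) {
    tibble(method = m,
           avg = (wide[[m]] + wide$weighing) / 2,
           diff = wide[[m]] - wide$weighing)
  }))
  ba <- report$per_nutrient %>% filter(.data$nutrient == !!nutrient)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(data = ba, ggplot2::aes(yintercept = .data$ba_mean_diff)) +
    ggplot2::geom_hline(data = ba, ggplot2::aes(yintercept = .data$ba_loa_lower),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = ba, ggplot2::aes(yintercept = .data$ba_loa_upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(
      x = sprintf("Mean of methods (%s)", NUTRIENT_UNIT_LABEL[[nutrient]]),
      y = "Estimated - weighed",
      title = sprintf("Bland-Altman: %s intake", nutrient)
    )
}

#' @importFrom dplyr .data
NULL
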