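perfect_channels <- function(methods = c("ai", "image_visual", "direct_visual")) {
  dishes <- reference_menu()$dish_id
  lapply(setNames(methods, methods), function(m) {
    channel_error_model(m, bias = setNames(rep(0, length(dishes)), dishes),
                        dispersion = 0)
  })
}

test_that("perfect raters yield zero error and diagonal confusions", {
  cfg <- cohort_config(n_meals = 40, channels = perfect_channels(), seed = 2)
  report <- run_evaluation(reference_menu(), generate_dataset(cfg))
  expect_true(all(report$per_nutrient$rmse == 0))
  expect_true(all(report$per_nutrient$r2 == 1))
  expect_true(all(report$per_dish_me$me == 0))
  for (cm in report$confusions) {
    expect_equal(sum(cm$counts) , report$n_dishes)
    expect_equal(sum(diag(cm$counts)), report$n_dishes)
    expect_equal(cm$mae, 0)
  }
})

test_that("the published intake distribution reproduces its summary figures", {
  ratings <- ratings_with_distribution()
  report <- run_evaluation(reference_menu(), ratings)
  expect_equal(report$n_dishes, 300)
  expect_equal(report$distribution$n, study_counts)
  expect_equal(round(report$mean_intake_rate_pct, 1), 84.7)
  expect_equal(round(report$distribution$pct[report$distribution$converted_value == 10], 1),
               76.7)
})

test_that("report tables are internally consistent", {
  cfg <- cohort_config(n_meals = 50, seed = 14)
  report <- run_evaluation(reference_menu(), generate_dataset(cfg))
  # conservation: distribution and every confusion matrix count all dishes
  expect_equal(sum(report$distribution$n), report$n_dishes)
  for (cm in report$confusions) expect_equal(sum(cm$counts), report$n_dishes)
  # every present method appears in every table
  for (tbl in list(report$per_nutrient, report$per_dish, report$per_dish_me)) {
    expect_setequal(unique(tbl$method), report$methods)
  }
  # meal-level n is the number of meals
  expect_true(all(report$per_nutrient$n == report$n_meals))
})

test_that("evaluation is reproducible bit-for-bit from a fixed seed", {
  run_once <- function() {
    cfg <- cohort_config(n_meals = 25, seed = 77)
    dir <- tempfile()
    paths <- render_report(run_evaluation(reference_menu(),
                                          generate_dataset(cfg)), dir)
    on.exit(unlink(dir, recursive = TRUE))
    readLines(paths$json)
  }
  expect_identical(run_once(), run_once())
})

test_that("higher channel dispersion never lowers mean dish-level RMSE", {
  rmse_at <- function(disp, seed) {
    dishes <- reference_menu()$dish_id
    ch <- list(ai = channel_error_model(
      "ai", bias = setNames(rep(0, length(dishes)), dishes), dispersion = disp))
    cfg <- cohort_config(n_meals = 100, channels = ch, seed = seed)
    ds <- generate_dataset(cfg)
    wide <- tidyr::pivot_wider(
      ds[c("dish_instance_id", "method", "converted_value")],
      names_from = "method", values_from = "converted_value")
    rmse(wide$ai, wide$weighing)
  }
  seeds <- 1:20
  low <- vapply(seeds, function(s) rmse_at(0.5, s), numeric(1))
  high <- vapply(seeds, function(s) rmse_at(1.5, s), numeric(1))
  expect_gt(mean(high), mean(low))
})

test_that("meal-level energy RMSE matches a from-scratch recomputation", {
  cfg <- cohort_config(n_meals = 60, seed = 33)
  menu_path <- withr::local_tempfile(fileext = ".csv")
  ratings_path <- withr::local_tempfile(fileext = ".csv")
  write_menu(reference_menu(), menu_path)
  write_ratings(generate_dataset(cfg), ratings_path)

  report <- run_evaluation(load_menu(menu_path), load_ratings(ratings_path))

  # independent recomputation with base R only, straight from the CSVs
  menu_raw <- utils::read.csv(menu_path, stringsAsFactors = FALSE)
  raw <- utils::read.csv(ratings_path, stringsAsFactors = FALSE)
  frac <- ifelse(raw$method == "weighing",
                 (raw$pre_weight_g - raw$post_weight_g) / raw$pre_weight_g,
                 raw$converted_value / 10)
  conv <- ifelse(raw$method == "weighing",
                 as.integer(cut(pmin(pmax(frac, 0), 1),
                                breaks = c(-Inf, 0.05 + 0.1 * (0:9) + 1e-9, Inf),
                                labels = FALSE)) - 1L,
                 raw$converted_value)
  raw$energy <- menu_raw$energy_kcal[match(raw$dish_id, menu_raw$dish_id)] *
    conv / 10
  totals <- aggregate(energy ~ meal_id + method, raw, sum)
  for (m in report$methods) {
    xs <- totals$energy[totals$method == m]
    ys <- totals$energy[totals$method == "weighing"]
    ord_x <- order(totals$meal_id[totals$method == m])
    ord_y <- order(totals$meal_id[totals$method == "weighing"])
    expected <- sqrt(mean((xs[ord_x] - ys[ord_y])^2))
    got <- report$per_nutrient$rmse[report$per_nutrient$nutrient == "energy" &
                                      report$per_nutrient$method == m]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("misaligned or empty inputs are rejected", {
  cfg <- cohort_config(n_meals = 5, seed = 1)
  ds <- generate_dataset(cfg)
  orphan <- ds[!(ds$method == "weighing" & ds$dish_instance_id ==
                   ds$dish_instance_id[1]), ]
  expect_error(run_evaluation(reference_menu(), orphan),
               class = "intakeval_alignment_error")
  expect_error(run_evaluation(reference_menu(), ds[0, ]),
               class = "intakeval_validation_error")
  weighing_only <- ds[ds$method == "weighing", ]
  expect_error(run_evaluation(reference_menu(), weighing_only),
               class = "intakeval_validation_error")
})

test_that("rendered reports round-trip through JSON and survive empty methods", {
  cfg <- cohort_config(n_meals = 20, seed = 6)
  report <- run_evaluation(reference_menu(), generate_dataset(cfg))
  dir <- withr::local_tempdir()
  paths <- render_report(report, dir)
  parsed <- jsonlite::read_json(paths$json, simplifyVector = TRUE)
  expect_equal(parsed$mean_intake_rate_pct, report$mean_intake_rate_pct)
  expect_equal(parsed$per_nutrient$rmse, report$per_nutrient$rmse)
  expect_equal(sort(names(parsed$confusions)), sort(report$methods))
  md <- readLines(paths$tables)
  for (m in report$methods) {
    expect_true(any(grepl(m, md, fixed = TRUE)))
  }

  empty <- structure(list(methods = character(0), confusions = list()),
                     class = "intake_report")
  paths2 <- render_report(empty, withr::local_tempdir())
  expect_true(any(grepl("No estimation methods",
                        readLines(paths2$tables))))
})
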