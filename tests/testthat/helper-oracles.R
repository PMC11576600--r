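# Independent naive re-implementations of every agreement statistic, written
# as direct formula evaluations (explicit loops, no code shared with the
# package), plus small analytic oracles used by the generator tests.

naive_rmse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s / length(x))
}

naive_r_squared <- function(x, y) {
  ybar <- sum(y) / length(y)
  ss_res <- 0
  ss_tot <- 0
  for (i in seq_along(x)) {
    ss_res <- ss_res + (x[i] - y[i])^2
    ss_tot <- ss_tot + (y[i] - ybar)^2
  }
  1 - ss_res / ss_tot
}

naive_me <- function(x, y) sum(x - y) / length(x)

naive_mae <- function(x, y) sum(abs(x - y)) / length(x)

# midrank of each element by direct counting
naive_midranks <- function(v) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    less <- sum(v < v[i])
    eq <- sum(v == v[i])
    out[i] <- less + (eq + 1) / 2
  }
  out
}

naive_spearman <- function(x, y) {
  rx <- naive_midranks(x)
  ry <- naive_midranks(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  rho <- num / den
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p)
}

naive_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tval <- m / (s / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), df = n - 1))
}

# Conover's form of the tie-corrected Friedman statistic, built from
# midranks obtained by counting (algebraically distinct route from the
# package's rank-sum formula)
naive_friedman <- function(blocks) {
  n <- nrow(blocks)
  k <- ncol(blocks)
  r <- matrix(0, n, k)
  for (i in seq_len(n)) r[i, ] <- naive_midranks(blocks[i, ])
  Rj <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  S <- sum(Rj^2) - n^2 * k * (k + 1)^2 / 4
  if (A1 == C1) return(list(chisq = 0, p = 1))
  chisq <- (k - 1) * S / (A1 - C1)
  list(chisq = chisq, p = pchisq(chisq, df = k - 1, lower.tail = FALSE))
}

naive_bland_altman <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(mean_diff = m, sd_diff = s, loa_lower = m - 1.96 * s,
       loa_upper = m + 1.96 * s)
}

# literal transcription of the verbal conversion-bin table
bin_table_convert <- function(f) {
  tol <- 1e-9
  if (f <= 0.05 + tol) return(0L)
  for (k in 1:9) {
    lo <- 0.05 + 0.10 * (k - 1)
    hi <- 0.05 + 0.10 * k
    if (f > lo + tol && f <= hi + tol) return(k)
  }
  10L
}

# analytic expected signed error of an additive-Gaussian channel with
# rounding and clamping to 0..10, over a pmf on true values 0..10
clamp_adjusted_expected_me <- function(pmf, bias, sigma) {
  vals <- 0:10
  total <- 0
  for (v in vals) {
    mu <- v + bias
    for (k in vals) {
      lo <- if (k == 0) -Inf else k - 0.5
      hi <- if (k == 10) Inf else k + 0.5
      pk <- pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
      total <- total + pmf[v + 1] * pk * (k - v)
    }
  }
  total
}

# small random paired series on mixed scales for property tests
random_series <- function(n, integer_scale = FALSE) {
  if (integer_scale) {
    list(x = sample(0:10, n, replace = TRUE), y = sample(0:10, n, replace = TRUE))
  } else {
    list(x = rnorm(n, 5, 3), y = rnorm(n, 5, 3))
  }
}

# reference study intake counts over converted values 0..10
study_counts <- c(23, 6, 3, 2, 9, 6, 6, 6, 3, 6, 230)

# ratings table in which the weighing channel reproduces the study's
# published intake distribution exactly, plus estimation channels that are
# optionally perfect copies
ratings_with_distribution <- function(counts = study_counts,
                                      methods = "ai") {
  values <- rep(0:10, counts)
  n <- length(values)
  dish_cycle <- rep(c("gruel", "soup", "mixed"), length.out = n)
  base <- tibble::tibble(
    meal_id = sprintf("m%03d", rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)]),
    dish_instance_id = sprintf("inst%03d", seq_len(n)),
    dish_id = dish_cycle,
    method = "weighing",
    pre_weight_g = 200,
    post_weight_g = 200 * (1 - values / 10),
    converted_value = as.integer(values)
  )
  est <- dplyr::bind_rows(lapply(methods, function(m) {
    out <- base
    out$method <- m
    out$pre_weight_g <- NA_real_
    out$post_weight_g <- NA_real_
    out
  }))
  dplyr::bind_rows(base, est)
}
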