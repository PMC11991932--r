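make_records <- function(df) {
  tibble::as_tibble(df)
}

test_that("absolute errors are |measured - true| and require truth", {
  rec <- make_records(data.frame(
    rater = 1, method = "bone", stone_id = c("a", "b"),
    density_hu = 1000, true_mm = c(5.2, 3.8), measured_mm = c(5.0, 3.8)
  ))
  out <- add_absolute_errors(rec)
  expect_equal(out$abs_error, c(0.2, 0.0))
  rec$true_mm[2] <- NA
  expect_error(add_absolute_errors(rec), "b")
  # loop oracle on a full synthetic table
  truth <- synthesize_study(seed = 5, acquire = FALSE)$truth
  tbl <- simulate_raters(truth, rater_model(n_raters = 4, bias = 0.3,
                                            sd = 0.5), seed = 2)
  got <- add_absolute_errors(tbl)$abs_error
  oracle <- numeric(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    oracle[i] <- abs(tbl$measured_mm[i] - tbl$true_mm[i])
  }
  expect_equal(got, oracle)
})

test_that("the printed per-stone automated errors average to the printed MAE", {
  # the 1000 HU automated column of the reference variability table
  auto_1000 <- reference_stone_errors()
  auto_1000 <- auto_1000$automated[auto_1000$density_hu == 1000]
  expect_equal(auto_1000, c(0.2, 0.3, 0.1, 0.1, 0.4, 0.3, 0.3, 0.0))
  rec <- make_records(data.frame(
    rater = "automated", method = "automated",
    stone_id = paste0("s", 1:8), density_hu = 1000,
    true_mm = stone_sizes(), measured_mm = stone_sizes() + auto_1000
  ))
  tab <- mae_table(rec)
  expect_equal(tab$mae_display, 0.21)
  ref <- reference_mae_table()
  expect_equal(tab$mae_display,
               ref$mae[ref$density_hu == 1000 & ref$method == "automated"])
})

test_that("mae_table matches a spreadsheet-style oracle over raters", {
  truth <- data.frame(stone_id = c("a", "b", "c"), density_hu = 1000,
                      true_mm = c(2, 4, 6))
  set <- expand.grid(rater = 1:5, stone_id = truth$stone_id)
  set <- merge(set, truth)
  withr::with_seed(11, {
    set$measured_mm <- set$true_mm + rnorm(nrow(set), 0.4, 0.6)
  })
  set$method <- "bone"
  tab <- mae_table(make_records(set))
  # oracle: per-rater MAE by explicit loop, then mean and sd
  per_rater <- vapply(1:5, function(r) {
    rows <- set[set$rater == r, ]
    mean(abs(rows$measured_mm - rows$true_mm))
  }, 0)
  expect_equal(tab$mae, mean(per_rater))
  expect_equal(tab$sd, sd(per_rater))
  expect_equal(tab$n_raters, 5L)
  # all-zero errors give MAE 0.00 +/- 0.00
  set$measured_mm <- set$true_mm
  tab0 <- mae_table(make_records(set))
  expect_equal(tab0$mae, 0)
  expect_equal(tab0$sd, 0)
})

test_that("per-stone variability reports mean, sd, and range per stone", {
  rec <- make_records(data.frame(
    rater = rep(1:3, 2), method = "bone",
    stone_id = rep(c("a", "b"), each = 3), density_hu = 100,
    true_mm = rep(c(2, 4), each = 3),
    measured_mm = c(2, 3, 4, 4, 4, 4)
  ))
  out <- per_stone_variability(rec)
  a <- out[out$stone_id == "a", ]
  expect_equal(a$mean_error, 1)
  expect_equal(a$min_error, 0)
  expect_equal(a$max_error, 2)
  b <- out[out$stone_id == "b", ]
  expect_equal(b$sd_error, 0)
  expect_equal(b$min_error, b$max_error)
  # invariant: min <= mean <= max, sd >= 0 on random tables
  truth <- synthesize_study(seed = 6, acquire = FALSE)$truth
  tbl <- simulate_raters(truth, rater_model(n_raters = 7), seed = 3)
  v <- per_stone_variability(tbl)
  expect_true(all(v$min_error <= v$mean_error + 1e-12))
  expect_true(all(v$mean_error <= v$max_error + 1e-12))
  expect_true(all(v$sd_error >= 0))
})

test_that("signed differences track over- and underestimation", {
  rec <- make_records(data.frame(
    rater = 1:4, method = "mediastinum", stone_id = "a", density_hu = 100,
    true_mm = 5, measured_mm = c(4.0, 4.5, 4.9, 3.8)
  ))
  sd_tbl <- signed_differences(rec)
  expect_true(all(sd_tbl$signed_diff < 0))
  truth <- synthesize_study(seed = 7, acquire = FALSE)$truth
  tbl <- simulate_raters(truth, rater_model(n_raters = 10, bias = -0.5,
                                            sd = 0), seed = 1)
  s <- summarise_signed_differences(tbl)
  expect_equal(s$mean_signed, rep(-0.5, nrow(s)))
})

test_that("compare_methods implements the t-test constructions", {
  base <- expand.grid(rater = 1:6, stone_id = c("a", "b"))
  base$true_mm <- ifelse(base$stone_id == "a", 3, 6)
  base$density_hu <- 1000
  mk <- function(method, offset) {
    d <- base
    d$method <- method
    d$measured_mm <- d$true_mm + offset[d$rater]
    d
  }
  # identical per-rater MAE vectors: paired t = 0, p = 1
  off <- c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3)
  rec <- make_records(rbind(mk("mediastinum", off), mk("bone", off)))
  out <- compare_methods(rec, "mediastinum", "bone")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  # closed-form paired t on distinct vectors
  off_b <- c(0.05, 0.15, 0.22, 0.08, 0.11, 0.25)
  rec2 <- make_records(rbind(mk("mediastinum", off), mk("bone", off_b)))
  out2 <- compare_methods(rec2, "mediastinum", "bone", type = "paired")
  d <- abs(off) - abs(off_b)
  t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out2$statistic, t_closed, tolerance = 1e-9)
  expect_equal(out2$df, 5)
  expect_equal(out2$p_value, 2 * pt(-abs(t_closed), df = 5),
               tolerance = 1e-9)
  # a large injected bias difference is significant at p < 0.05
  truth <- synthesize_study(seed = 8, acquire = FALSE)$truth
  biased <- rbind(
    simulate_raters(truth, rater_model(n_raters = 20, bias = 2, sd = 0.2,
                                       methods = "mediastinum"), seed = 4),
    simulate_raters(truth, rater_model(n_raters = 20, bias = 0.2, sd = 0.2,
                                       methods = "bone"), seed = 5)
  )
  out3 <- compare_methods(biased, "mediastinum", "bone", type = "paired")
  expect_true(all(out3$p_value < 0.05))
  expect_error(compare_methods(rec[rec$rater == 1, ], "mediastinum", "bone"),
               ">= 2 raters")
})

test_that("manual-vs-automated comparison is a one-sample t-test", {
  base <- expand.grid(rater = 1:6, stone_id = c("a", "b"))
  base$true_mm <- ifelse(base$stone_id == "a", 3, 6)
  base$density_hu <- 1000
  base$method <- "bone"
  base$measured_mm <- base$true_mm + 0.1 * base$rater
  auto <- data.frame(rater = "automated", stone_id = c("a", "b"),
                     true_mm = c(3, 6), density_hu = 1000,
                     method = "automated", measured_mm = c(3.2, 6.2))
  rec <- make_records(rbind(base, auto))
  out <- compare_methods(rec, "bone", "automated")
  expect_equal(out$test, "onesample")
  pr <- per_rater_mae(rec)
  x <- pr$mae[pr$method == "bone"]
  ht <- t.test(x, mu = 0.2)
  expect_equal(out$statistic, unname(ht$statistic), tolerance = 1e-9)
  expect_equal(out$p_value, ht$p.value, tolerance = 1e-9)
})

test_that("raters_beaten counts strict wins and reports printed percentages", {
  # construct 52 raters of which exactly 10 have MAE above the challenger
  truth <- data.frame(stone_id = "a", density_hu = 100, true_mm = 5)
  rec <- make_records(data.frame(
    rater = 1:52, method = "mediastinum", stone_id = "a", density_hu = 100,
    true_mm = 5, measured_mm = 5 + c(rep(2, 10), rep(0.5, 42))
  ))
  auto <- data.frame(rater = "automated", method = "automated",
                     stone_id = "a", density_hu = 100, true_mm = 5,
                     measured_mm = 6)  # MAE 1
  out <- raters_beaten(rbind(rec, auto), "mediastinum")
  expect_equal(out$n_beaten, 10L)
  expect_equal(out$pct_beaten, 19.2)
  # 45 of 52, as printed for the bone setting at 1000 HU
  rec2 <- rec
  rec2$density_hu <- 1000
  rec2$measured_mm <- 5 + c(rep(2, 45), rep(0.5, 7))
  auto2 <- auto
  auto2$density_hu <- 1000
  out2 <- raters_beaten(rbind(rec2, auto2), "mediastinum")
  expect_equal(out2$pct_beaten, 86.5)
  # challenger worse than every rater: 0 and 0.0%; ties are not wins
  auto3 <- auto
  auto3$measured_mm <- 10
  out3 <- raters_beaten(rbind(rec, auto3), "mediastinum")
  expect_equal(out3$n_beaten, 0L)
  expect_equal(out3$pct_beaten, 0)
  ties <- rec
  ties$measured_mm <- 6  # every rater MAE equals the challenger's
  out4 <- raters_beaten(rbind(ties, auto), "mediastinum")
  expect_equal(out4$n_beaten, 0L)
})

test_that("beaten and not-beaten percentages partition the panel", {
  truth <- synthesize_study(seed = 9, acquire = FALSE)$truth
  rec <- simulate_raters(truth, rater_model(n_raters = 13), seed = 7)
  auto <- simulate_raters(truth,
                          rater_model(n_raters = 1, bias = 0.5, sd = 0.1,
                                      methods = "automated"), seed = 8)
  auto$rater <- "automated"
  out <- raters_beaten(rbind(rec, auto), "bone")
  pr <- per_rater_mae(rbind(rec, auto))
  for (i in seq_len(nrow(out))) {
    d <- out$density_hu[i]
    ch <- pr$mae[pr$method == "automated" & pr$density_hu == d]
    at_or_below <- sum(pr$mae[pr$method == "bone" & pr$density_hu == d] <= ch)
    expect_equal(out$n_beaten[i] + at_or_below, out$n_raters[i])
  }
})

test_that("evaluate_study bundles the summaries with tidy/glance", {
  truth <- synthesize_study(seed = 10, acquire = FALSE)$truth
  rec <- simulate_raters(truth, rater_model(n_raters = 6), seed = 2)
  auto <- simulate_raters(truth,
                          rater_model(n_raters = 1, bias = 0.3, sd = 0,
                                      methods = "automated"), seed = 3)
  auto$rater <- "automated"
  ev <- evaluate_study(rbind(rec, auto))
  expect_s3_class(ev, "stone_eval")
  expect_equal(nrow(ev$mae), 9L)  # 3 methods x 3 densities
  expect_equal(nrow(tidy(ev)), 24L * 3L)
  gl <- glance(ev)
  expect_equal(gl$n_stones, 24L)
  expect_true(gl$overall_mae > 0)
})
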