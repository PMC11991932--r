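#' Attach absolute errors to measurement records
#'
#' @param records Measurement-record tibble with at least `measured_mm` and
#'   `true_mm` (see [simulate_raters()] for the full schema; the automated
#'   method appears as `method = "automated"`, `rater = "automated"` or any
#'   single rater id).
#' @return `records` with an `abs_error` column, `|measured_mm - true_mm|`.
#' @export
add_absolute_errors <- function(records) {
  if (anyNA(records$true_mm)) {
    bad <- unique(records$stone_id[is.na(records$true_mm)])
    stop("records are missing true_mm for stone(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(records, abs_error = abs(.data$measured_mm - .data$true_mm))
}

#' Per-rater mean absolute error
#'
#' The unit of analysis of the reader study: each rater's MAE over the
#' stones of one density group, per method.
#'
#' @param records Measurement records.
#' @return Tibble with `method`, `density_hu`, `rater`, `mae`.
#' @export
per_rater_mae <- function(records) {
  records |>
    add_absolute_errors() |>
    dplyr::group_by(.data$method, .data$density_hu, .data$rater) |>
    dplyr::summarise(mae = mean(.data$abs_error), .groups = "drop")
}

#' MAE summary table by method and density
#'
#' For each `(method, density)` cell, the mean and standard deviation of the
#' per-rater MAEs (for a single-rater method such as the automated model the
#' single MAE is reported and the sd is `NA`). `mae_display` rounds to 2
#' decimals for presentation; full precision is retained in `mae`.
#'
#' @param records Measurement records.
#' @return Tibble with `method`, `density_hu`, `n_raters`, `mae`, `sd`,
#'   `mae_display`.
#' @export
mae_table <- function(records) {
  pr <- per_rater_mae(records)
  if (nrow(pr) == 0L) stop("no measurement records", call. = FALSE)
  pr |>
    dplyr::group_by(.data$method, .data$density_hu) |>
    dplyr::summarise(
      n_raters = dplyr::n(),
      sd = stats::sd(.data$mae),
      mae = mean(.data$mae),
      .groups = "drop"
    ) |>
    dplyr::mutate(mae_display = round(.data$mae, 2)) |>
    dplyr::select("method", "density_hu", "n_raters", "mae", "sd",
                  "mae_display")
}

#' Per-stone rater-to-rater variability
#'
#' For each `(density, stone, method)`: mean, sd, minimum and maximum of the
#' per-rater absolute errors -- one row per stone and method, the shape of a
#' reader-variability table.
#'
#' @param records Measurement records.
#' @return Tibble with `density_hu`, `stone_id`, `true_mm`, `method`,
#'   `mean_error`, `sd_error`, `min_error`, `max_error`, `n_raters`.
#' @export
per_stone_variability <- function(records) {
  records |>
    add_absolute_errors() |>
    dplyr::group_by(.data$density_hu, .data$stone_id, .data$true_mm,
                    .data$method) |>
    dplyr::summarise(
      mean_error = mean(.data$abs_error),
      sd_error = stats::sd(.data$abs_error),
      min_error = min(.data$abs_error),
      max_error = max(.data$abs_error),
      n_raters = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$density_hu, .data$true_mm)
}

#' Signed measurement differences
#'
#' Retains the per-record signed differences `measured_mm - true_mm` for
#' plotting and export; negative mean signed error means underestimation.
#'
#' @param records Measurement records.
#' @return List-free tibble of the records with a `signed_diff` column;
#'   the per-cell summary is available via `attr(, "summary")` or
#'   [summarise_signed_differences()].
#' @export
signed_differences <- function(records) {
  out <- dplyr::mutate(records,
                       signed_diff = .data$measured_mm - .data$true_mm)
  class(out) <- c("signed_differences", class(out))
  out
}

#' @rdname signed_differences
#' @export
summarise_signed_differences <- function(records) {
  sd_tbl <- if (inherits(records, "signed_differences")) records else
    signed_differences(records)
  sd_tbl |>
    dplyr::group_by(.data$method, .data$density_hu) |>
    dplyr::summarise(mean_signed = mean(.data$signed_diff),
                     sd_signed = stats::sd(.data$signed_diff),
                     n = dplyr::n(), .groups = "drop")
}

#' Compare two measurement methods by t-test
#'
#' Within each density group, compares the per-rater MAE vectors of two
#' methods. Manual vs manual uses a paired two-sided Student's t-test on the
#' per-rater MAEs (selectable: `"paired"` or `"welch"`); manual vs a
#' single-value method (e.g. the automated model) uses a one-sample
#' two-sided t-test of the manual per-rater MAEs against the single MAE
#' constant.
#'
#' @param records Measurement records.
#' @param method_a,method_b Method labels present in `records`.
#' @param type `"auto"` (default: one-sample when either side has a single
#'   rater, else paired), `"paired"`, `"welch"`, or `"onesample"`.
#' @return Tidy tibble with one row per density: `density_hu`, `method_a`,
#'   `method_b`, `estimate` (MAE difference a - b), `statistic` (t), `df`,
#'   `p_value`, `test`.
#' @export
compare_methods <- function(records, method_a, method_b,
                            type = c("auto", "paired", "welch",
                                     "onesample")) {
  type <- match.arg(type)
  pr <- per_rater_mae(records)
  densities <- sort(unique(pr$density_hu))
  purrr::map_dfr(densities, function(d) {
    a <- pr[pr$method == method_a & pr$density_hu == d, ]
    b <- pr[pr$method == method_b & pr$density_hu == d, ]
    if (nrow(a) == 0L || nrow(b) == 0L) {
      stop("no per-rater MAEs for one of the methods at density ", d,
           call. = FALSE)
    }
    tt <- type
    if (tt == "auto") {
      tt <- if (nrow(a) == 1L || nrow(b) == 1L) "onesample" else "paired"
    }
    if (tt == "onesample") {
      if (nrow(b) == 1L) {
        x <- a$mae; mu <- b$mae
      } else {
        x <- b$mae; mu <- a$mae
        if (nrow(a) != 1L) {
          stop("onesample comparison needs one single-value method",
               call. = FALSE)
        }
      }
      if (length(x) < 2L) stop("need >= 2 raters for a t-test", call. = FALSE)
      ht <- stats::t.test(x, mu = mu)
      est <- mean(a$mae) - mean(b$mae)
    } else if (tt == "paired") {
      if (nrow(a) < 2L || nrow(a) != nrow(b)) {
        stop("paired comparison needs matched rater panels (>= 2 raters)",
             call. = FALSE)
      }
      a <- a[order(a$rater), ]; b <- b[order(b$rater), ]
      diffs <- a$mae - b$mae
      if (stats::sd(diffs) == 0) {
        # degenerate paired test: identical vectors give t = 0, p = 1
        ht <- list(statistic = c(t = 0), parameter = c(df = nrow(a) - 1),
                   p.value = 1)
      } else {
        ht <- stats::t.test(a$mae, b$mae, paired = TRUE)
      }
      est <- mean(diffs)
    } else {
      if (nrow(a) < 2L || nrow(b) < 2L) {
        stop("need >= 2 raters per method for a t-test", call. = FALSE)
      }
      ht <- stats::t.test(a$mae, b$mae)
      est <- mean(a$mae) - mean(b$mae)
    }
    tibble::tibble(density_hu = d, method_a = method_a, method_b = method_b,
                   estimate = est,
                   statistic = unname(ht$statistic),
                   df = unname(ht$parameter),
                   p_value = ht$p.value, test = tt)
  })
}

#' Head-to-head rater counts
#'
#' How many raters of a reference manual method have a strictly greater MAE
#' than the challenger method in each density group (ties count as not
#' beaten), with the percentage reported to 1 decimal.
#'
#' @param records Measurement records.
#' @param reference_method Manual method whose raters are compared.
#' @param challenger Method providing the single challenger MAE per density
#'   (default `"automated"`).
#' @return Tibble with `density_hu`, `n_raters`, `n_beaten`, `pct_beaten`.
#' @export
raters_beaten <- function(records, reference_method,
                          challenger = "automated") {
  pr <- per_rater_mae(records)
  ref <- pr[pr$method == reference_method, ]
  ch <- pr[pr$method == challenger, ]
  if (nrow(ref) == 0L) stop("no raters for method ", reference_method,
                            call. = FALSE)
  purrr::map_dfr(sort(unique(ref$density_hu)), function(d) {
    r <- ref$mae[ref$density_hu == d]
    c_mae <- ch$mae[ch$density_hu == d]
    if (length(c_mae) != 1L) {
      stop("challenger must contribute exactly one MAE per density",
           call. = FALSE)
    }
    n <- length(r)
    if (n == 0L) stop("zero raters at density ", d, call. = FALSE)
    beaten <- sum(r > c_mae)
    tibble::tibble(density_hu = d, n_raters = n, n_beaten = beaten,
                   pct_beaten = round(100 * beaten / n, 1))
  })
}

#' Evaluate a study's measurement records
#'
#' One-stop summary: MAE table, per-stone variability, signed-difference
#' summary and head-to-head counts against the automated method, bundled in
#' a `stone_eval` object with [generics::tidy()] and [generics::glance()]
#' methods.
#'
#' @param records Measurement records (manual raters plus, optionally, an
#'   `"automated"` series).
#' @return A `stone_eval` object.
#' @export
evaluate_study <- function(records) {
  records <- add_absolute_errors(records)
  methods <- unique(records$method)
  beaten <- NULL
  if ("automated" %in% methods && length(setdiff(methods, "automated"))) {
    beaten <- purrr::map_dfr(setdiff(methods, "automated"), function(m) {
      dplyr::mutate(raters_beaten(records, m), reference_method = m,
                    .before = 1)
    })
  }
  structure(list(records = records,
                 mae = mae_table(records),
                 per_stone = per_stone_variability(records),
                 signed = summarise_signed_differences(records),
                 beaten = beaten),
            class = "stone_eval")
}

#' @export
print.stone_eval <- function(x, ...) {
  cat("<stone_eval> MAE by method and density:\n")
  print(as.data.frame(x$mae), digits = 3)
  if (!is.null(x$beaten)) {
    cat("\nRaters beaten by the automated method:\n")
    print(as.data.frame(x$beaten), digits = 3)
  }
  invisible(x)
}
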