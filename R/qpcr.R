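# qPCR standard curves, plate-effect normalization, and phage:host
# copy-ratio tests.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Ct = slope * log10(copies) + intercept` to a
#' dilution series; amplification efficiency is `10^(-1/slope) - 1` (100%
#' at a slope of -log2(10) ~ -3.32, i.e. perfect doubling per cycle).
#'
#' @param points Data frame with columns `log10_copies` and `ct`
#'   (at least 3 points spanning at least 2 log10 units).
#' @return A `std_curve`: list with `slope`, `intercept`, `efficiency`
#'   (fraction, 1 = 100%), `r_squared`, `n_points`, and the fitted `model`.
#' @examples
#' pts <- data.frame(log10_copies = 3:7, ct = 38 - 1 / log10(2) * (3:7))
#' fit_standard_curve(pts)$efficiency # 1 (100%)
#' @export
fit_standard_curve <- function(points) {
  points <- as_tibble(points)
  stopifnot(all(c("log10_copies", "ct") %in% names(points)))
  if (nrow(points) < 3) abort("need at least 3 standard points")
  if (diff(range(points$log10_copies)) < 2) {
    warn("standard series spans less than 2 log10 units")
  }
  if (any(points$ct <= 0)) abort("Ct values must be positive")
  fit <- lm(ct ~ log10_copies, data = points)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    abort(sprintf("invalid standard curve: slope %.3f is not negative", slope))
  }
  structure(
    list(
      slope = slope, intercept = unname(coef(fit)[1]),
      efficiency = 10^(-1 / slope) - 1,
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_points = nrow(points), model = fit, points = points
    ),
    class = "std_curve"
  )
}

#' @export
print.std_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Ct = %.3f * log10(copies) + %.2f\n",
              x$slope, x$intercept))
  cat(sprintf("  efficiency %.1f%%, R^2 = %.4f, %d points\n",
              100 * x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `std_curve`.
#' @param ... Unused.
#' @export
glance.std_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency_percent = 100 * x$efficiency,
         r_squared = x$r_squared, n_points = x$n_points)
}

#' @export
tidy.std_curve <- function(x, ...) {
  generics::tidy(x$model)
}

#' Convert Ct values to absolute copy numbers via a standard curve
#'
#' @param ct Numeric Ct values.
#' @param curve A `std_curve` from [fit_standard_curve()].
#' @return Copy numbers.
#' @export
copies_from_ct <- function(ct, curve) {
  10^((ct - curve$intercept) / curve$slope)
}

#' Remove between-plate scale effects from qPCR copy numbers
#'
#' Each plate's copy numbers are rescaled so that the plate mean of the
#' calibrator gene equals the cross-plate calibrator mean. With a single
#' plate this is the identity transform.
#'
#' @param copies Data frame with columns `plate`, `gene`, `copies` (one row
#'   per well/replicate).
#' @param calibrator Gene measured on every plate used as the scale anchor.
#' @return The input tibble with `copies` adjusted and the applied
#'   `plate_factor` column added.
#' @export
normalize_plate_effects <- function(copies, calibrator) {
  copies <- as_tibble(copies)
  stopifnot(all(c("plate", "gene", "copies") %in% names(copies)))
  cal <- filter(copies, .data$gene == calibrator)
  plates <- unique(copies$plate)
  if (!all(plates %in% cal$plate)) {
    abort(sprintf("calibrator \"%s\" is not measured on every plate", calibrator))
  }
  grand <- mean(cal$copies)
  factors <- cal |>
    group_by(.data$plate) |>
    summarise(plate_factor = grand / mean(.data$copies), .groups = "drop")
  copies |>
    left_join(factors, by = "plate") |>
    mutate(copies = .data$copies * .data$plate_factor)
}

#' Copy-ratio test against an expected ratio
#'
#' Forms per-replicate ratios of paired copy numbers and applies a
#' one-sample two-tailed t-test against the expected ratio (default 1: one
#' lysogenic phage copy per host genome).
#'
#' @param copies_num,copies_den Paired per-replicate copy numbers for the
#'   numerator and denominator genes.
#' @param expected Expected ratio under the null.
#' @param numerator,denominator Optional gene labels for the record.
#' @return A `copy_ratio`: list with `ratio_mean`, `ratio_sd`, `n`,
#'   `t_statistic`, `p_value`, `expected`, labels, and the ratios.
#' @export
copy_ratio_test <- function(copies_num, copies_den, expected = 1,
                            numerator = "numerator", denominator = "denominator") {
  if (length(copies_num) != length(copies_den)) {
    abort("numerator and denominator replicates must be paired")
  }
  drop <- copies_den == 0
  if (any(drop)) {
    ph_log("qpcr", sprintf("%d replicate(s) dropped: zero denominator copies",
                           sum(drop)), force = TRUE)
    copies_num <- copies_num[!drop]
    copies_den <- copies_den[!drop]
  }
  if (length(copies_num) < 2) {
    abort("need at least 2 paired replicates for a copy-ratio test")
  }
  ratios <- copies_num / copies_den
  if (sd(ratios) == 0) {
    # degenerate noiseless case: the t statistic is 0 or unbounded
    off <- mean(ratios) - expected
    t_stat <- if (off == 0) 0 else sign(off) * Inf
    p_val <- if (off == 0) 1 else 0
  } else {
    ht <- t.test(ratios, mu = expected)
    t_stat <- unname(ht$statistic)
    p_val <- ht$p.value
  }
  structure(
    list(
      numerator = numerator, denominator = denominator,
      ratio_mean = mean(ratios), ratio_sd = sd(ratios), n = length(ratios),
      t_statistic = t_stat, p_value = p_val,
      expected = expected, ratios = ratios
    ),
    class = "copy_ratio"
  )
}

#' @export
print.copy_ratio <- function(x, ...) {
  cat(sprintf("Copy ratio %s : %s = %.2f +/- %.2f (n = %d)\n",
              x$numerator, x$denominator, x$ratio_mean, x$ratio_sd, x$n))
  cat(sprintf("  t = %.2f vs expected %.2f, two-tailed p = %.3g\n",
              x$t_statistic, x$expected, x$p_value))
  invisible(x)
}

#' Tidy a copy-ratio test
#'
#' @param x A `copy_ratio`.
#' @param ... Unused.
#' @export
tidy.copy_ratio <- function(x, ...) {
  tibble(numerator = x$numerator, denominator = x$denominator,
         ratio_mean = x$ratio_mean, ratio_sd = x$ratio_sd, n = x$n,
         t_statistic = x$t_statistic, p_value = x$p_value,
         expected = x$expected)
}

#' Plot relative copy numbers with the expected-ratio line
#'
#' @param ratios A list of `copy_ratio` objects or a tibble from
#'   [tidy.copy_ratio()] rows.
#' @return A ggplot object (bar of mean ratio with one-SD error bars and a
#'   horizontal line at the expected copy number).
#' @export
plot_copy_ratios <- function(ratios) {
  if (is.list(ratios) && !is.data.frame(ratios)) {
    ratios <- bind_rows(lapply(ratios, tidy))
  }
  ratios <- mutate(ratios,
                   label = paste(.data$numerator, .data$denominator, sep = " : "))
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$label, y = .data$ratio_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ratio_mean - .data$ratio_sd,
                   ymax = .data$ratio_mean + .data$ratio_sd),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 1, linewidth = 0.6) +
    ggplot2::labs(x = NULL, y = "Relative copy number") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a fitted standard curve
#'
#' @param object A `std_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.std_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$log10_copies, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "log10 copies", y = "Ct",
                  subtitle = sprintf("efficiency %.1f%%, R^2 %.4f",
                                     100 * object$efficiency, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
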