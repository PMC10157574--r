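#' Bin a set of disability weights into fixed-width severity bins
#'
#' Half-open bins `[0, 0.1), [0.1, 0.2), ...` (lower edge inclusive).
#' Missing weights (states with no estimable DW) are excluded from the
#' counts but — by default — kept in the percentage denominator, the
#' convention used when a catalog state lacks a weight yet the table is
#' presented per catalog.
#'
#' @param dws Numeric vector of DWs in \[0, 1\], possibly with `NA`s, or a
#'   data frame with a `dw` column.
#' @param bin_width Bin width (default 0.1).
#' @param denominator Denominator for percentages; default `length(dws)`
#'   including missing entries.
#' @return Tibble `bin_lower`, `bin_upper`, `count`, `percent`.
#' @export
bin_distribution <- function(dws, bin_width = 0.1, denominator = NULL) {
  if (is.data.frame(dws)) dws <- dws$dw
  denominator <- denominator %||% length(dws)
  x <- dws[!is.na(dws)]
  if (any(x < 0 | x > 1)) abort("disability weights must lie in [0, 1]")
  n_bins <- ceiling(1 / bin_width)
  idx <- pmin(floor(x / bin_width), n_bins - 1L)  # dw = 1 into top bin
  counts <- tabulate(idx + 1L, nbins = n_bins)
  tibble(bin_lower = bin_width * (seq_len(n_bins) - 1L),
         bin_upper = bin_width * seq_len(n_bins),
         count = counts,
         percent = if (denominator > 0) 100 * counts / denominator else
           rep(NA_real_, n_bins))
}

#' Proportional difference between a local and a reference weight
#'
#' `100 * (local - reference) / reference`, the percent by which the local
#' estimate exceeds the reference. Undefined for a reference of 0. Note
#' the formula is not symmetric in its arguments.
#'
#' @param local_dw,reference_dw Numeric vectors (recycled).
#' @return Percent differences.
#' @export
proportional_difference <- function(local_dw, reference_dw) {
  if (any(reference_dw <= 0, na.rm = TRUE)) {
    abort("reference_dw must be > 0 for a proportional difference")
  }
  100 * (local_dw - reference_dw) / reference_dw
}

#' Build the cross-survey comparison table
#'
#' Joins local estimates with a reference table and the catalog's symptom
#' flags, computing the proportional difference `d` per state. States
#' missing either weight, or with a reference of 0, are dropped with a
#' warning.
#'
#' @param local Tibble `state_id`, `dw` (local estimates).
#' @param reference Tibble `state_id`, `reference_dw` (see
#'   [load_reference_dws()]).
#' @param catalog A `dw_catalog` (source of the symptom flags).
#' @return Tibble `state_id`, `dw`, `reference_dw`, `d`, plus the eleven
#'   `flag_*` columns.
#' @export
compare_dws <- function(local, reference, catalog) {
  rows <- local |>
    dplyr::inner_join(reference, by = "state_id") |>
    dplyr::inner_join(dplyr::select(as_tibble(catalog), "state_id",
                                    dplyr::all_of(flag_cols())),
                      by = "state_id")
  bad <- is.na(rows$dw) | is.na(rows$reference_dw) | rows$reference_dw == 0
  if (any(bad)) {
    warn(paste0(sum(bad), " state(s) dropped from comparison ",
                "(missing weight or reference of 0)"))
    rows <- rows[!bad, ]
  }
  dplyr::mutate(rows, d = proportional_difference(.data$dw,
                                                  .data$reference_dw),
                .after = "reference_dw")
}

#' Regression of proportional DW differences on symptom categories
#'
#' Ordinary least squares of the proportional difference `d` on all eleven
#' binary symptom-category flags entered simultaneously (plus an
#' intercept). A positive coefficient means states mentioning that symptom
#' have higher local weights than the reference, relative to states
#' without it. Reports t-based 95% confidence intervals and two-sided
#' p-values.
#'
#' @param comparison_rows Output of [compare_dws()] (needs `d` and the
#'   `flag_*` columns).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `term`, `n_states`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @export
symptom_regression <- function(comparison_rows, conf_level = 0.95) {
  if (nrow(comparison_rows) < 13) {
    abort("need >= 13 rows to fit 11 coefficients plus an intercept")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(comparison_rows[flag_cols()]) * 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("symptom design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm(comparison_rows$d ~ X - 1)
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tibble(term = sub("^X", "", rownames(sm)),
         n_states = unname(c(nrow(comparison_rows),
                             colSums(X[, -1, drop = FALSE]))),
         estimate = unname(sm[, 1]),
         conf.low = unname(sm[, 1] - tcrit * sm[, 2]),
         conf.high = unname(sm[, 1] + tcrit * sm[, 2]),
         p.value = unname(sm[, 4]))
}

#' Pearson correlation between local and reference disability weights
#'
#' Product-moment correlation over the states present in both tables,
#' with the two-sided t-test p-value.
#'
#' @param local Tibble `state_id`, `dw`.
#' @param reference Tibble `state_id`, `reference_dw`.
#' @return Tibble `r`, `p.value`, `n`.
#' @export
dw_correlation <- function(local, reference) {
  rows <- dplyr::inner_join(local, reference, by = "state_id")
  rows <- rows[!is.na(rows$dw) & !is.na(rows$reference_dw), ]
  if (nrow(rows) < 3) abort("need >= 3 paired values")
  if (stats::var(rows$dw) == 0 || stats::var(rows$reference_dw) == 0) {
    abort("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(rows$dw, rows$reference_dw, method = "pearson")
  tibble(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(rows))
}

#' Plot a disability-weight distribution
#'
#' Bar chart of the output of [bin_distribution()].
#'
#' @param bins Tibble from [bin_distribution()].
#' @return A ggplot object.
#' @export
plot_dw_distribution <- function(bins) {
  width <- bins$bin_upper[1] - bins$bin_lower[1]
  bins <- dplyr::mutate(bins, mid = (.data$bin_lower + .data$bin_upper) / 2)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 0.9 * width, fill = "steelblue") +
    ggplot2::labs(x = "Disability weight", y = "Number of health states") +
    ggplot2::theme_minimal()
}
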