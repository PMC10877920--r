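# Descriptive stage: elderly-household filtering, currency conversion,
# grouped expenditure summaries and zero-spender accounting.

#' Convert Iranian Rials to US Dollars
#'
#' Divides by the central-bank exchange rate of 129,000 Rials per USD;
#' no rounding is applied.
#'
#' @param amount_rials non-negative numeric vector of Rial amounts.
#' @return amounts in USD.
#' @examples
#' convert_rial_to_usd(129000)  # 1
#' @export
convert_rial_to_usd <- function(amount_rials) {
  x <- as.numeric(amount_rials)
  if (any(is.na(x)) || any(x < 0))
    stop_input("amounts must be non-negative and non-missing")
  x / 129000
}

#' Keep households with at least one elderly member
#'
#' Retains households with one or more members aged at or above the
#' threshold (65 by default, "aged 65 or more"). The table must carry
#' either a logical `has_elderly` flag or a `member_ages` field
#' (numeric list-column, or a character column of ages separated by
#' `;`).
#'
#' @param table data frame of household records.
#' @param age_threshold minimum age counting as elderly (default 65,
#'   inclusive).
#' @return the filtered table.
#' @examples
#' tab <- data.frame(id = 1:2, member_ages = c("40;70", "40;64"))
#' filter_elderly_households(tab)$id  # 1
#' @export
filter_elderly_households <- function(table, age_threshold = 65) {
  if (!is.data.frame(table)) stop_input("'table' must be a data frame")
  if ("has_elderly" %in% names(table)) {
    keep <- as.logical(table$has_elderly)
    if (any(is.na(keep))) stop_input("missing values in 'has_elderly'")
  } else if ("member_ages" %in% names(table)) {
    ages <- table$member_ages
    keep <- vapply(seq_along(ages), function(i) {
      a <- ages[[i]]
      if (is.character(a)) a <- as.numeric(strsplit(a, ";", fixed = TRUE)[[1]])
      if (length(a) == 0 || any(is.na(a)))
        stop_input("missing or unparsable member ages at row ", i)
      any(a >= age_threshold)
    }, logical(1))
  } else {
    stop_input("table needs a 'has_elderly' flag or a 'member_ages' field")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grouped expenditure summary
#'
#' For one categorical household field, tabulates each category's
#' frequency, percentage of households, and the mean and SD (n-1
#' denominator) of out-of-pocket pharmaceutical spending — the layout of
#' a survey characteristics table. Zero-spending households are included
#' in the means by default.
#'
#' @param table data frame of household records with an `oop_pharma`
#'   column.
#' @param variable name of a categorical field.
#' @param include_zeros logical; include zero spenders in mean/SD
#'   (default `TRUE`).
#' @return data frame with columns `variable`, `level`, `frequency`,
#'   `percent`, `mean_oop`, `sd_oop`.
#' @export
group_summary <- function(table, variable, include_zeros = TRUE) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop_input("'table' must be a non-empty data frame")
  if (!variable %in% names(table))
    stop_input("no field '", variable, "' in the table")
  if (!"oop_pharma" %in% names(table))
    stop_input("table has no 'oop_pharma' column")
  lv <- household_levels()
  levels_v <- if (variable %in% names(lv)) lv[[variable]]
              else sort(unique(as.character(table[[variable]])))
  v <- as.character(table[[variable]])
  n <- nrow(table)
  rows <- lapply(levels_v, function(l) {
    sel <- v == l
    yy <- table$oop_pharma[sel]
    if (!include_zeros) yy <- yy[yy > 0]
    data.frame(variable = variable, level = l,
               frequency = sum(sel),
               percent = 100 * sum(sel) / n,
               mean_oop = if (length(yy)) mean(yy) else NA_real_,
               sd_oop = if (length(yy) > 1) stats::sd(yy) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Zero-spending accounting
#'
#' Exact count and share of households reporting zero out-of-pocket
#' pharmaceutical spending.
#'
#' @param table data frame with an `oop_pharma` column.
#' @return list with `n_zero`, `n_total` and `share`.
#' @export
zero_share <- function(table) {
  if (!is.data.frame(table) || !"oop_pharma" %in% names(table))
    stop_input("'table' must be a data frame with an 'oop_pharma' column")
  y <- table$oop_pharma
  list(n_zero = sum(y == 0), n_total = length(y),
       share = if (length(y)) sum(y == 0) / length(y) else NA_real_)
}

#' Spending extremes and mean
#'
#' Minimum positive spending, maximum, and mean. The mean includes
#' zero-spending households by default (the per-household convention);
#' the minimum is taken over positive values only, since exact zeros are
#' non-participation rather than small purchases.
#'
#' @param table data frame with an `oop_pharma` column.
#' @param include_zeros_in_mean logical (default `TRUE`).
#' @return list with `min_positive`, `max` and `mean`.
#' @export
oop_extremes <- function(table, include_zeros_in_mean = TRUE) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop_input("'table' must be a non-empty data frame")
  y <- table$oop_pharma
  ypos <- y[y > 0]
  list(min_positive = if (length(ypos)) min(ypos) else NA_real_,
       max = max(y),
       mean = if (include_zeros_in_mean) mean(y)
              else if (length(ypos)) mean(ypos) else NA_real_)
}
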