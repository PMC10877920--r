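# Covariate encoding: household table -> design matrices for the two
# hurdles, with fixed category sets and survey-table reference levels.

#' Closed category sets for household covariates
#'
#' The categorical fields of a household record and their admissible
#' levels, in display order. Dummy coding is always based on these fixed
#' sets (never on the levels observed in a particular table), so design
#' matrices have a stable column layout across subsamples.
#'
#' @return named list of character vectors.
#' @export
household_levels <- function() {
  list(
    head_gender       = c("female", "male"),
    head_age_group    = c("18-34", "35-51", "52-68", "69-85", "86+"),
    living_sector     = c("urban", "rural"),
    marital_status    = c("single", "divorced", "widowed", "married"),
    education         = c("illiterate", "primary", "secondary", "college+"),
    job_status        = c("housekeeper", "unemployed", "employed"),
    ownership         = c("free", "tenant", "owner"),
    family_size_group = c("1-2", "3-5", "6+")
  )
}

# Continuous (or count) fields passed through unchanged.
hh_continuous_fields <- c("income", "insurance_cost", "n_children_under5")

default_reference_levels <- function() {
  c(head_gender = "female", head_age_group = "18-34", living_sector = "urban",
    marital_status = "single", education = "college+",
    job_status = "housekeeper", ownership = "free", family_size_group = "1-2")
}

default_terms <- function() {
  c("income", "insurance_cost", "head_gender", "head_age_group",
    "living_sector", "marital_status", "education", "job_status",
    "ownership", "n_children_under5", "family_size_group")
}

#' Specify the covariates entering each hurdle
#'
#' Defines which household fields enter the participation equation (`z`)
#' and the expenditure equation (`X`), the reference category for each
#' categorical covariate, and whether an intercept column is included.
#' By default both hurdles use the same full covariate set (income,
#' insurance cost, head's gender / age group / marital status / education
#' / job status, living sector, housing ownership, number of children
#' under five, and family-size group), and reference levels are female,
#' 18-34, urban, single, college+, housekeeper, free housing and family
#' size 1-2.
#'
#' @param participation_terms character vector of field names for the
#'   first hurdle.
#' @param expenditure_terms character vector of field names for the
#'   second hurdle (defaults to the participation terms).
#' @param reference_levels named character vector mapping each categorical
#'   field to its reference category.
#' @param include_intercept logical; include a constant column in both
#'   hurdles (default `TRUE`).
#' @param log_money logical; if `TRUE`, `income` and `insurance_cost`
#'   enter as `log1p(.)` instead of raw currency amounts.
#' @return an object of class `dh_design_spec`.
#' @export
design_spec <- function(participation_terms = default_terms(),
                        expenditure_terms = participation_terms,
                        reference_levels = default_reference_levels(),
                        include_intercept = TRUE,
                        log_money = FALSE) {
  lv <- household_levels()
  all_terms <- unique(c(participation_terms, expenditure_terms))
  known <- c(names(lv), hh_continuous_fields)
  bad <- setdiff(all_terms, known)
  if (length(bad))
    stop_input("unknown covariate term(s): ", paste(bad, collapse = ", "))
  refs <- default_reference_levels()
  refs[names(reference_levels)] <- reference_levels
  for (v in intersect(all_terms, names(lv))) {
    if (!refs[[v]] %in% lv[[v]])
      stop_input("reference level '", refs[[v]], "' is not a valid category of '", v, "'")
  }
  structure(list(participation_terms = participation_terms,
                 expenditure_terms = expenditure_terms,
                 reference_levels = refs,
                 include_intercept = isTRUE(include_intercept),
                 log_money = isTRUE(log_money)),
            class = "dh_design_spec")
}

encode_block <- function(table, terms, spec) {
  lv <- household_levels()
  n <- nrow(table)
  cols <- list()
  if (spec$include_intercept) cols[["(Intercept)"]] <- rep(1, n)
  for (tm in terms) {
    if (!tm %in% names(table))
      stop_input("covariate '", tm, "' is missing from the table")
    v <- table[[tm]]
    if (tm %in% names(lv)) {
      v <- as.character(v)
      bad <- which(is.na(v) | !(v %in% lv[[tm]]))
      if (length(bad))
        stop_input("unknown category '", v[bad[1]], "' in field '", tm,
                   "' at row ", bad[1])
      ref <- spec$reference_levels[[tm]]
      for (l in setdiff(lv[[tm]], ref))
        cols[[paste0(tm, "=", l)]] <- as.numeric(v == l)
    } else {
      x <- as.numeric(v)
      if (any(!is.finite(x)))
        stop_input("non-finite value in continuous field '", tm, "' at row ",
                   which(!is.finite(x))[1])
      if (spec$log_money && tm %in% c("income", "insurance_cost")) x <- log1p(x)
      cols[[tm]] <- x
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

#' Encode a household table into double-hurdle design matrices
#'
#' Expands categorical covariates into 0/1 dummies (one column per
#' non-reference level, in the fixed level order of [household_levels()]),
#' passes continuous covariates through unchanged, and extracts the
#' non-negative outcome `oop_pharma` when present.
#'
#' @param table data frame of household records (one row per household).
#' @param spec a [design_spec()].
#' @return a `dh_design` object (see [design_matrices()]).
#' @examples
#' cfg <- synthetic_config(n_households = 50, seed = 7)
#' hh <- simulate_households(cfg)
#' dm <- encode_design(hh)
#' dim(dm$z)
#' @export
encode_design <- function(table, spec = design_spec()) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop_input("'table' must be a non-empty data frame of household records")
  if (!inherits(spec, "dh_design_spec")) stop_input("'spec' must be a design_spec()")
  z <- encode_block(table, spec$participation_terms, spec)
  X <- encode_block(table, spec$expenditure_terms, spec)
  y <- NULL
  if ("oop_pharma" %in% names(table)) {
    y <- as.numeric(table$oop_pharma)
    if (any(is.na(y))) stop_input("missing values in 'oop_pharma'; run complete_cases() first")
    if (any(y < 0)) stop_input("'oop_pharma' must be non-negative")
  }
  design_matrices(z, X, y)
}

#' Drop design columns with no variation
#'
#' Removes non-intercept columns that are constant in the sample —
#' typically dummies for rare categories (e.g. unemployed heads, below
#' one percent of households) that happen not to occur in a small
#' subsample and would make the design rank deficient. A warning names
#' the dropped columns.
#'
#' @param dm a `dh_design`.
#' @return a `dh_design` with constant columns removed.
#' @export
drop_empty_columns <- function(dm) {
  if (!inherits(dm, "dh_design")) stop_input("'dm' must be a dh_design")
  prune <- function(M) {
    keep <- colnames(M) == "(Intercept)" |
      apply(M, 2, function(cl) stats::sd(cl) > 0)
    if (any(!keep))
      warning("dropping constant design column(s): ",
              paste(colnames(M)[!keep], collapse = ", "), call. = FALSE)
    M[, keep, drop = FALSE]
  }
  design_matrices(prune(dm$z), prune(dm$X), dm$y)
}

#' Drop household records with missing values
#'
#' Removes rows with a missing value in any field named by the design
#' spec (plus the outcome, when present) and reports how many rows were
#' dropped.
#'
#' @param table data frame of household records.
#' @param spec a [design_spec()] naming the fields that must be complete.
#' @return the filtered table.
#' @export
complete_cases <- function(table, spec = design_spec()) {
  if (!is.data.frame(table)) stop_input("'table' must be a data frame")
  fields <- unique(c(spec$participation_terms, spec$expenditure_terms))
  fields <- intersect(c(fields, "oop_pharma"), names(table))
  if (nrow(table) == 0) return(table)
  ok <- stats::complete.cases(table[fields])
  dropped <- sum(!ok)
  if (dropped > 0)
    message(dropped, " of ", nrow(table), " household record(s) dropped for missing values")
  out <- table[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no complete household records remain", call. = FALSE)
  out
}
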