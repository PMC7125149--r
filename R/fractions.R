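# Compositional analysis of gradient fraction profiles. Raw per-replicate
# abundances over the four groups F, M, LP, HP are first closed (divided by
# their total so components sum to 1), then fraction differences such as
# HP - F are computed per replicate and compared between conditions with
# Welch's t-test.

#' Close a composition so its components sum to 1
#'
#' The closure operator of compositional data analysis: each component is
#' divided by the row total. Closure is idempotent and scale-invariant.
#'
#' @param x Either a numeric vector of non-negative components, or a profile
#'   data frame with columns `F`, `M`, `LP`, `HP` (other columns are kept).
#' @return The closed vector, or the data frame with the four fraction
#'   columns closed row-wise.
#' @export
#' @examples
#' close_composition(c(2, 3, 5, 10))
close_composition <- function(x) {
  if (is.data.frame(x)) {
    missing_cols <- setdiff(.gradient_fractions, names(x))
    if (length(missing_cols)) {
      abort(paste0("Profile table is missing fraction column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "polystate_validation_error")
    }
    vals <- as.matrix(x[.gradient_fractions])
    if (any(vals < 0) || anyNA(vals)) {
      abort("Fraction abundances must be non-negative and non-missing.",
            class = "polystate_validation_error")
    }
    totals <- rowSums(vals)
    if (any(totals == 0)) {
      abort("All-zero profile cannot be closed.",
            class = "polystate_degenerate_error")
    }
    x[.gradient_fractions] <- vals / totals
    return(as_tibble(x))
  }
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) {
    abort("Composition must be non-negative numeric.",
          class = "polystate_validation_error")
  }
  total <- sum(x)
  if (total == 0) {
    abort("All-zero profile cannot be closed.",
          class = "polystate_degenerate_error")
  }
  x / total
}

#' Per-replicate fraction differences and per-condition means
#'
#' Computes `minuend - subtrahend` (e.g. HP - F) on closed profiles, per
#' replicate, and the per-condition mean difference. A higher mean difference
#' means greater relative abundance in the minuend fraction.
#'
#' @param profiles Profile tibble with columns `condition`, `replicate`,
#'   `F`, `M`, `LP`, `HP` (raw or closed; closure is applied).
#' @param minuend,subtrahend Distinct fraction labels among
#'   `c("F", "M", "LP", "HP")`.
#' @return A list with `replicates` (tibble: condition, replicate,
#'   difference) and `means` (tibble: condition, mean_difference, n).
#' @export
fraction_difference <- function(profiles, minuend = "HP", subtrahend = "F") {
  for (lab in c(minuend, subtrahend)) {
    if (!lab %in% .gradient_fractions) {
      abort(sprintf("Unknown fraction label '%s' (allowed: %s).", lab,
                    paste(.gradient_fractions, collapse = ", ")),
            class = "polystate_validation_error")
    }
  }
  if (minuend == subtrahend) {
    abort("`minuend` and `subtrahend` must differ.",
          class = "polystate_validation_error")
  }
  closed <- close_composition(profiles)
  replicates <- tibble(
    condition = closed$condition,
    replicate = closed$replicate,
    difference = closed[[minuend]] - closed[[subtrahend]]
  )
  means <- dplyr::summarise(
    dplyr::group_by(replicates, .data$condition),
    mean_difference = mean(.data$difference),
    n = dplyr::n(),
    .groups = "drop"
  )
  list(replicates = replicates, means = means)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided, unpaired Welch's t with Welch-Satterthwaite degrees of freedom.
#' When both groups have zero variance, the convention is `t = 0, p = 1` for
#' equal means and `p = 0` for separated means, flagged via `degenerate`.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `degenerate`.
#' @export
#' @examples
#' welch_t_test(c(2.1, 2.5, 1.9), c(3.0, 3.4, 3.2))
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs at least 2 values.",
          class = "polystate_validation_error")
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    abort("Missing values are not allowed.",
          class = "polystate_validation_error")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    equal <- mean(group_a) == mean(group_b)
    return(tibble(
      statistic = if (equal) 0 else sign(mean(group_b) - mean(group_a)) * Inf,
      df = NA_real_,
      p_value = if (equal) 1 else 0,
      mean_a = mean(group_a), mean_b = mean(group_b),
      degenerate = TRUE
    ))
  }
  ht <- stats::t.test(group_b, group_a, var.equal = FALSE)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(group_a), mean_b = mean(group_b),
    degenerate = FALSE
  )
}

#' Test a fraction difference between two conditions
#'
#' Closes the profiles, computes the per-replicate `minuend - subtrahend`
#' difference, and compares the two conditions with Welch's t-test
#' (two-sided).
#'
#' @inheritParams fraction_difference
#' @param conditions Optional length-2 vector selecting and ordering the two
#'   conditions (reference first); defaults to their order of appearance.
#' @return A one-row `polystate_fraction_test` tibble: `minuend`,
#'   `subtrahend`, per-condition mean differences, `statistic`, `df`,
#'   `p_value`.
#' @export
fraction_difference_test <- function(profiles, minuend = "HP",
                                     subtrahend = "F", conditions = NULL) {
  diffs <- fraction_difference(profiles, minuend, subtrahend)
  conditions <- conditions %||% unique(diffs$replicates$condition)
  if (length(conditions) != 2L ||
      !all(conditions %in% diffs$replicates$condition)) {
    abort("Exactly two conditions present in `profiles` are required.",
          class = "polystate_validation_error")
  }
  pick <- function(cond) {
    diffs$replicates$difference[diffs$replicates$condition == cond]
  }
  wt <- welch_t_test(pick(conditions[1]), pick(conditions[2]))
  res <- tibble(
    minuend = minuend,
    subtrahend = subtrahend,
    condition_a = conditions[1],
    condition_b = conditions[2],
    mean_difference_a = wt$mean_a,
    mean_difference_b = wt$mean_b,
    statistic = wt$statistic,
    df = wt$df,
    p_value = wt$p_value,
    degenerate = wt$degenerate
  )
  class(res) <- c("polystate_fraction_test", class(res))
  res
}

#' Relative quantification with the delta-delta-Ct method
#'
#' Livak's method: per sample, `dCt = Ct_target - Ct_reference`; per
#' condition, `ddCt = mean dCt(condition) - mean dCt(control)` and
#' `fold = 2^(-ddCt)`. The control condition has fold 1 by construction.
#' Spread is reported as the standard deviation of dCt.
#'
#' @param records Tibble with columns `condition`, `ct_target`,
#'   `ct_reference` (one row per sample; e.g. Gapdh as the reference gene).
#' @param control The control condition label.
#' @return A tibble with one row per condition: `condition`, `n`, `mean_dct`,
#'   `sd_dct`, `ddct`, `fold_change`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   condition = rep(c("ctrl", "treated"), each = 3),
#'   ct_target = c(24.1, 24.3, 23.9, 22.0, 22.2, 21.8),
#'   ct_reference = c(20.0, 20.1, 19.9, 20.0, 20.2, 19.8))
#' ddct_fold_change(recs, control = "ctrl")
ddct_fold_change <- function(records, control) {
  required <- c("condition", "ct_target", "ct_reference")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort(paste0("Ct table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "polystate_validation_error")
  }
  ct <- c(records$ct_target, records$ct_reference)
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
    abort("Ct values must be positive and finite; missing reference or target Ct.",
          class = "polystate_validation_error")
  }
  if (!control %in% records$condition) {
    abort(sprintf("Control condition '%s' is absent from the records.",
                  control),
          class = "polystate_validation_error")
  }
  per_condition <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(records, dct = .data$ct_target - .data$ct_reference),
      .data$condition),
    n = dplyr::n(),
    mean_dct = mean(.data$dct),
    sd_dct = sd(.data$dct),
    .groups = "drop"
  )
  control_mean <- per_condition$mean_dct[per_condition$condition == control]
  dplyr::mutate(
    per_condition,
    ddct = .data$mean_dct - control_mean,
    fold_change = 2^(-.data$ddct)
  )
}
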