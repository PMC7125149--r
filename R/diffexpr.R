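# Per-fraction differential abundance between the two stages, on
# log2(abundance + pseudocount) across replicates, with Benjamini-Hochberg
# FDR control within the fraction. This is a defined, reproducible stand-in
# for pipeline-specific differential calls, so results can be recomputed
# from any abundance table. Two statistics are offered: an empirical-Bayes
# moderated t (limma, default — with 2-3 replicates per group the
# per-isoform variance estimate has so few degrees of freedom that an
# unmoderated test has almost no power after FDR correction) and the
# textbook Welch's t.

# Vectorised Welch's t over the rows of two matrices (replicates in columns).
# Returns statistic, Welch-Satterthwaite df and two-sided p. Rows where both
# groups have zero variance get p = 1 (equal means) or p = 0 (separated
# means), flagged via `degenerate`.
row_welch <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(stat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    equal <- degenerate & (mb == ma)
    stat[equal] <- 0; p[equal] <- 1; df[degenerate] <- NA_real_
    sep <- degenerate & (mb != ma)
    stat[sep] <- sign(mb - ma)[sep] * Inf; p[sep] <- 0
  }
  list(statistic = stat, df = df, p_value = p, degenerate = degenerate)
}

# Moderated t via limma on log2 values: ordinary linear fit per isoform with
# empirical-Bayes shrinkage of the residual variances toward a mean-variance
# trend. Falls back to the Welch result when the variance-prior fit is not
# estimable (e.g. all-constant toy matrices).
row_moderated <- function(la, lb) {
  welch <- row_welch(la, lb)
  design <- cbind(intercept = 1,
                  stage_b = rep(c(0, 1), c(ncol(la), ncol(lb))))
  mod <- tryCatch({
    withCallingHandlers({
      fit <- limma::lmFit(cbind(la, lb), design)
      fit <- limma::eBayes(fit, trend = nrow(la) >= 10)
    }, warning = function(w) {
      # zero-variance rows are re-assigned our degenerate convention below
      if (grepl("Zero sample variances", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
    list(statistic = fit$t[, "stage_b"],
         df = fit$df.total,
         p_value = fit$p.value[, "stage_b"])
  }, error = function(e) NULL)
  if (is.null(mod)) return(welch)
  stat <- unname(mod$statistic)
  p <- unname(mod$p_value)
  df <- unname(mod$df)
  # keep the fixed convention for rows that are constant in both groups
  equal <- welch$degenerate & welch$statistic == 0
  stat[equal] <- 0; p[equal] <- 1
  bad <- !is.finite(p)
  stat[bad] <- welch$statistic[bad]
  p[bad] <- welch$p_value[bad]
  df[bad] <- welch$df[bad]
  list(statistic = stat, df = df, p_value = p,
       degenerate = welch$degenerate)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values with the Benjamini-Hochberg step-up procedure; output
#' order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].",
          class = "polystate_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Per-fraction differential abundance between stages
#'
#' For one RNA fraction, tests each isoform for a change between stage A
#' (earlier) and stage B (later) on `log2(abundance + pseudocount)` across
#' replicates, two-sided. The default statistic is the empirical-Bayes
#' moderated t (limma, variances shrunk toward a mean-variance trend), which
#' retains power at typical polysome-profiling replication (2-3 replicates
#' per stage); `method = "welch"` gives the unmoderated Welch's t with
#' Welch-Satterthwaite degrees of freedom. q-values are
#' Benjamini-Hochberg adjusted within the fraction; `direction` is `"up"` or
#' `"down"` (B relative to A, from the sign of the log2 fold change) when
#' `q <= alpha`, otherwise `"none"`. Detection flags record whether the mean
#' abundance per stage reaches `detection_threshold`.
#'
#' @param abundance Isoform-by-sample tibble (`isoform_id` first column).
#' @param samples Sample sheet tibble (`sample_id`, `stage`, `fraction`,
#'   `replicate`).
#' @param fraction One of `"input"`, `"monosome"`, `"polysome"`.
#' @param alpha FDR level for direction calls (default 0.05).
#' @param pseudocount Added before the log2 transform and to stage means in
#'   the fold change (default 1).
#' @param detection_threshold Mean-abundance detection threshold (default 1).
#' @param stages Optional length-2 vector giving the (earlier, later) stage
#'   labels; defaults to their order of appearance in `samples`.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return A `polystate_contrast` tibble with one row per isoform: columns
#'   `isoform_id`, `log2fc`, `statistic`, `df`, `p_value`, `q_value`,
#'   `detected_A`, `detected_B`, `direction`, `degenerate`.
#' @export
test_contrast <- function(abundance, samples, fraction,
                          alpha = 0.05, pseudocount = 1,
                          detection_threshold = 1, stages = NULL,
                          method = c("moderated", "welch")) {
  method <- match.arg(method)
  checked <- validate_abundance(abundance, samples)
  stages <- stages %||% checked$stages
  if (length(stages) != 2L || !all(stages %in% checked$samples$stage)) {
    abort("`stages` must name the two stage labels present in `samples`.",
          class = "polystate_validation_error")
  }
  if (length(fraction) != 1L || !fraction %in% samples$fraction) {
    abort(sprintf("Fraction '%s' is not present in the sample sheet.",
                  as.character(fraction)[1]),
          class = "polystate_validation_error")
  }
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  assert_scalar_number(detection_threshold, "detection_threshold", lower = 0)

  sel <- function(stage) {
    ids <- samples$sample_id[samples$stage == stage &
                               samples$fraction == fraction]
    as.matrix(abundance[ids])
  }
  xa <- sel(stages[1]); xb <- sel(stages[2])
  row_test <- if (method == "welch") row_welch else row_moderated
  w <- row_test(log2(xa + pseudocount), log2(xb + pseudocount))

  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  q <- bh_adjust(w$p_value)
  direction <- dplyr::if_else(
    q <= alpha & log2fc != 0,
    dplyr::if_else(log2fc > 0, "up", "down"),
    "none")

  res <- tibble(
    isoform_id = abundance$isoform_id,
    log2fc = log2fc,
    statistic = w$statistic,
    df = w$df,
    p_value = w$p_value,
    q_value = q,
    detected_A = mean_a >= detection_threshold,
    detected_B = mean_b >= detection_threshold,
    direction = direction,
    degenerate = w$degenerate
  )
  attr(res, "fraction") <- fraction
  attr(res, "stages") <- stages
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  class(res) <- c("polystate_contrast", class(res))
  res
}

#' Detection flags per stage for one fraction
#'
#' An isoform is detected at a stage if its mean abundance across that
#' stage's replicates in the chosen fraction reaches `threshold`.
#'
#' @inheritParams test_contrast
#' @param threshold Non-negative detection threshold.
#' @return Tibble with `isoform_id`, `detected_A`, `detected_B`.
#' @export
detection_filter <- function(abundance, samples, fraction, threshold = 1,
                             stages = NULL) {
  res <- test_contrast(abundance, samples, fraction,
                       detection_threshold = threshold, stages = stages)
  tibble(isoform_id = res$isoform_id,
         detected_A = res$detected_A,
         detected_B = res$detected_B)
}

#' @exportS3Method generics::tidy
tidy.polystate_contrast <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "polystate_contrast")
  out
}

#' @exportS3Method generics::glance
glance.polystate_contrast <- function(x, ...) {
  tibble(
    fraction = attr(x, "fraction"),
    stage_A = attr(x, "stages")[1],
    stage_B = attr(x, "stages")[2],
    alpha = attr(x, "alpha"),
    n_isoforms = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down")
  )
}
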