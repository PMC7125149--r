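#' Configuration for a simulated polysome-profiling experiment
#'
#' Builds and validates the parameter set for [simulate_polysome_experiment()].
#' The default design mirrors a two-stage developmental comparison profiled in
#' three RNA fractions (input/total, monosome, polysome) with three biological
#' replicates per stage and fraction.
#'
#' @param n_isoforms Number of simulated mRNA isoforms.
#' @param n_replicates Replicates per (stage, fraction) cell; at least 2.
#' @param baseline_mean Baseline mean abundance (FPKM-like units) shared by all
#'   unaffected (stage, fraction) cells.
#' @param dispersion Negative-binomial dispersion; the simulated variance is
#'   `mu + dispersion * mu^2`. `0` gives Poisson noise.
#' @param state_proportions Named numeric vector mapping each planted state to
#'   the fraction of isoforms carrying it. Names must come from
#'   `c("steady", "transcription_up", "transcription_down", "repressed",
#'   "derepressed", "monosome_shift")`; values must sum to 1.
#' @param effect_fold Multiplicative fold (> 1) applied to the affected
#'   fraction(s) at stage B for planted non-steady states.
#' @param detection_fraction Fraction of derepressed isoforms planted with
#'   input abundance below `detection_threshold` at both stages, emulating
#'   transcripts visible in the polysome fraction but not in total RNA.
#' @param detection_threshold Detection threshold (mean abundance) used when
#'   planting below-detection isoforms; keep equal to the threshold passed to
#'   [test_contrast()] downstream.
#' @param noise_model `"nb"` (negative binomial, default) or `"lognormal"`
#'   (log-normal with matched coefficient of variation).
#' @param mass_conserving If `TRUE`, planted polysome gains/losses are
#'   mirrored by opposite monosome changes (truncated at zero mean), emulating
#'   mRNA moving between the monosome and polysome pools. Default `FALSE`:
#'   repression/derepression acts on the polysome fraction only.
#' @param stage_labels Length-2 character vector naming the earlier and later
#'   stage, in that order.
#' @param seed Integer RNG seed; required.
#'
#' @return A `simulation_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(n_isoforms = 100, seed = 1)
#' sim <- simulate_polysome_experiment(cfg)
#' dplyr::count(sim$truth, state)
simulation_config <- function(n_isoforms,
                              n_replicates = 3,
                              baseline_mean = 50,
                              dispersion = 0.1,
                              state_proportions = c(steady = 1),
                              effect_fold = 4,
                              detection_fraction = 0,
                              detection_threshold = 1,
                              noise_model = c("nb", "lognormal"),
                              mass_conserving = FALSE,
                              stage_labels = c("A", "B"),
                              seed = NULL) {
  n_isoforms <- assert_count(n_isoforms, "n_isoforms", minimum = 1L)
  n_replicates <- assert_count(n_replicates, "n_replicates", minimum = 2L)
  assert_scalar_number(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  assert_scalar_number(effect_fold, "effect_fold", lower = 1, strict_lower = TRUE)
  assert_scalar_number(detection_fraction, "detection_fraction", lower = 0, upper = 1)
  assert_scalar_number(detection_threshold, "detection_threshold", lower = 0)
  noise_model <- match.arg(noise_model)
  seed <- assert_seed(seed)

  # YAML/JSON configs deliver proportions as a named list
  if (is.list(state_proportions)) {
    state_proportions <- unlist(state_proportions)
  }
  if (is.null(names(state_proportions)) ||
      !all(names(state_proportions) %in% .states)) {
    abort(paste0("`state_proportions` must be named with states from: ",
                 paste(.states, collapse = ", ")),
          class = "polystate_validation_error")
  }
  if (any(state_proportions < 0) ||
      abs(sum(state_proportions) - 1) > 1e-9) {
    abort("`state_proportions` must be non-negative and sum to 1.",
          class = "polystate_validation_error")
  }
  if (length(stage_labels) != 2L || anyDuplicated(stage_labels)) {
    abort("`stage_labels` must be two distinct labels (earlier, later).",
          class = "polystate_validation_error")
  }

  structure(
    list(
      n_isoforms = n_isoforms, n_replicates = n_replicates,
      baseline_mean = baseline_mean, dispersion = dispersion,
      state_proportions = state_proportions, effect_fold = effect_fold,
      detection_fraction = detection_fraction,
      detection_threshold = detection_threshold,
      noise_model = noise_model, mass_conserving = mass_conserving,
      stage_labels = as.character(stage_labels), seed = seed
    ),
    class = "simulation_config"
  )
}

# Largest-remainder allocation of n isoforms to states; deterministic.
allocate_states <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  remainder <- n - sum(counts)
  if (remainder > 0) {
    order_idx <- order(raw - counts, decreasing = TRUE)
    counts[order_idx[seq_len(remainder)]] <- counts[order_idx[seq_len(remainder)]] + 1
  }
  rep(names(proportions), times = counts)
}

draw_noise <- function(n, mu, dispersion, noise_model) {
  if (noise_model == "nb") {
    if (dispersion == 0) rpois(n, lambda = mu) else
      rnbinom(n, mu = mu, size = 1 / dispersion)
  } else {
    # log-normal with the same coefficient of variation as NB's
    # extra-Poisson term: CV^2 = dispersion
    sdlog <- sqrt(log1p(dispersion))
    mu * exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  }
}

#' Simulate a two-stage, three-fraction polysome-profiling experiment
#'
#' Generates an isoform-by-sample abundance table for 2 stages x 3 fractions
#' (input, monosome, polysome) x `n_replicates`, with translational-regulation
#' states planted per isoform and recorded in a ground-truth table. Planted
#' effects act at stage B relative to stage A: `transcription_up`/`_down`
#' scale all three fractions, `repressed`/`derepressed` scale the polysome
#' fraction only (down/up), and `monosome_shift` scales the monosome fraction.
#' Below-detection derepressed isoforms get input means well under the
#' detection threshold at both stages.
#'
#' @param config A [simulation_config()] object.
#' @return A list with three tibbles:
#'   \describe{
#'     \item{abundance}{`isoform_id` plus one column per sample.}
#'     \item{samples}{`sample_id`, `stage`, `fraction`, `replicate`.}
#'     \item{truth}{`isoform_id`, planted `state`, applied `fold` (multiplier
#'       on the affected means; 1 for steady), `below_detection` flag.}
#'   }
#' @export
simulate_polysome_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created by `simulation_config()`.",
          class = "polystate_validation_error")
  }
  n <- config$n_isoforms
  isoform_id <- sprintf("iso%05d", seq_len(n))
  state <- allocate_states(config$state_proportions, n)

  fold_up <- config$effect_fold
  fold_down <- 1 / config$effect_fold
  applied_fold <- dplyr::case_match(
    state,
    c("transcription_up", "derepressed", "monosome_shift") ~ fold_up,
    c("transcription_down", "repressed") ~ fold_down,
    "steady" ~ 1
  )

  below_detection <- rep(FALSE, n)
  derep_idx <- which(state == "derepressed")
  n_below <- round(config$detection_fraction * length(derep_idx))
  if (n_below > 0) below_detection[derep_idx[seq_len(n_below)]] <- TRUE

  samples <- tidyr::expand_grid(
    stage = factor(config$stage_labels, levels = config$stage_labels),
    fraction = factor(.fractions, levels = .fractions),
    replicate = seq_len(config$n_replicates)
  )
  samples <- dplyr::mutate(
    samples,
    sample_id = paste(.data$stage, .data$fraction, .data$replicate, sep = "_"),
    .before = 1
  )

  # Mean matrix: isoform x (stage, fraction) cell, before replicate noise.
  mu <- config$baseline_mean
  cell_means <- matrix(mu, nrow = n, ncol = 6,
                       dimnames = list(isoform_id, c(
                         "A_input", "A_monosome", "A_polysome",
                         "B_input", "B_monosome", "B_polysome")))
  b_cols <- c("B_input", "B_monosome", "B_polysome")
  is_tx <- state %in% c("transcription_up", "transcription_down")
  cell_means[is_tx, b_cols] <- mu * applied_fold[is_tx]
  is_trans <- state %in% c("repressed", "derepressed")
  cell_means[is_trans, "B_polysome"] <- mu * applied_fold[is_trans]
  is_mono <- state == "monosome_shift"
  cell_means[is_mono, "B_monosome"] <- mu * applied_fold[is_mono]
  if (config$mass_conserving) {
    delta <- cell_means[is_trans, "B_polysome"] - mu
    cell_means[is_trans, "B_monosome"] <- pmax(mu - delta, 0)
  }
  cell_means[below_detection, c("A_input", "B_input")] <-
    config$detection_threshold * 0.05

  role <- ifelse(samples$stage == config$stage_labels[1], "A", "B")
  cell_of_sample <- paste(role, samples$fraction, sep = "_")

  values <- with_seed_(config$seed, {
    vapply(seq_len(nrow(samples)), function(j) {
      draw_noise(n, cell_means[, cell_of_sample[j]],
                 config$dispersion, config$noise_model)
    }, numeric(n))
  })
  colnames(values) <- samples$sample_id

  abundance <- dplyr::bind_cols(
    tibble(isoform_id = isoform_id),
    as_tibble(values)
  )
  truth <- tibble(
    isoform_id = isoform_id,
    state = state,
    fold = applied_fold,
    below_detection = below_detection
  )
  list(abundance = abundance,
       samples = dplyr::mutate(samples,
                               stage = as.character(.data$stage),
                               fraction = as.character(.data$fraction)),
       truth = truth)
}

#' Simulate sucrose-gradient fraction profiles for two conditions
#'
#' Generates per-replicate raw abundance profiles over the four gradient
#' groups F (free), M (40S-60S-80S monosome), LP (light polysome) and
#' HP (heavy polysome). Condition 2 shifts `shift_delta` of mass from F to HP
#' before multiplicative (log-normal) noise is applied, emulating increased
#' heavy-polysome loading of a transcript.
#'
#' @param n_replicates Replicates per condition (>= 2).
#' @param baseline_composition Non-negative numeric vector of length 4,
#'   ordered (F, M, LP, HP); need not sum to 1.
#' @param shift_delta Mass moved from F to HP in condition 2; must not exceed
#'   the baseline F component.
#' @param noise_sd Standard deviation of the multiplicative log-normal noise
#'   on the natural-log scale; 0 gives noiseless profiles.
#' @param seed Integer RNG seed; required.
#' @param condition_labels Labels for the two conditions.
#' @return A tibble with columns `condition`, `replicate`, `F`, `M`, `LP`, `HP`.
#' @export
#' @examples
#' simulate_fraction_profiles(3, c(0.4, 0.3, 0.2, 0.1),
#'                            shift_delta = 0.2, noise_sd = 0, seed = 1)
simulate_fraction_profiles <- function(n_replicates,
                                       baseline_composition,
                                       shift_delta = 0,
                                       noise_sd = 0.05,
                                       seed = NULL,
                                       condition_labels = c("ctrl", "shifted")) {
  n_replicates <- assert_count(n_replicates, "n_replicates", minimum = 2L)
  if (length(baseline_composition) != 4L || any(baseline_composition < 0) ||
      !all(is.finite(baseline_composition))) {
    abort("`baseline_composition` must be 4 non-negative finite values (F, M, LP, HP).",
          class = "polystate_validation_error")
  }
  assert_scalar_number(shift_delta, "shift_delta",
                       lower = 0, upper = baseline_composition[1])
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  seed <- assert_seed(seed)

  means <- rbind(
    baseline_composition,
    baseline_composition + c(-shift_delta, 0, 0, shift_delta)
  )
  with_seed_(seed, {
    rows <- tidyr::expand_grid(
      condition = factor(condition_labels, levels = condition_labels),
      replicate = seq_len(n_replicates)
    )
    noise <- matrix(exp(rnorm(nrow(rows) * 4, sd = noise_sd)),
                    nrow = nrow(rows))
    raw <- means[as.integer(rows$condition), , drop = FALSE] * noise
    colnames(raw) <- .gradient_fractions
    dplyr::bind_cols(
      dplyr::mutate(rows, condition = as.character(.data$condition)),
      as_tibble(raw)
    )
  })
}

#' Simulate a gene universe with a planted set overlap
#'
#' Draws an input set and a target set from a common background universe with
#' an exactly planted overlap, providing ground truth for the permutation
#' enrichment test.
#'
#' @param n_universe Background universe size.
#' @param n_input,n_target Sizes of the input and target sets.
#' @param planted_overlap Exact size of the input-target intersection.
#' @param seed Integer RNG seed; required.
#' @return A list with character vectors `universe`, `input_set`, `target_set`.
#' @export
simulate_gene_sets <- function(n_universe, n_input, n_target,
                               planted_overlap, seed = NULL) {
  n_universe <- assert_count(n_universe, "n_universe", minimum = 1L)
  n_input <- assert_count(n_input, "n_input", minimum = 0L)
  n_target <- assert_count(n_target, "n_target", minimum = 0L)
  planted_overlap <- assert_count(planted_overlap, "planted_overlap")
  if (n_input > n_universe || n_target > n_universe) {
    abort("Set sizes cannot exceed the universe size.",
          class = "polystate_validation_error")
  }
  if (planted_overlap > min(n_input, n_target) ||
      n_input - planted_overlap > n_universe - n_target) {
    abort("`planted_overlap` is infeasible for the given sizes.",
          class = "polystate_validation_error")
  }
  seed <- assert_seed(seed)

  universe <- sprintf("g%05d", seq_len(n_universe))
  with_seed_(seed, {
    target_set <- sample(universe, n_target)
    inside <- sample(target_set, planted_overlap)
    outside <- sample(setdiff(universe, target_set), n_input - planted_overlap)
    input_set <- sample(c(inside, outside))
    list(universe = universe, input_set = input_set, target_set = target_set)
  })
}
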