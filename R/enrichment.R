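# Permutation gene-set enrichment: the empirical null is built by drawing
# gene lists of the input-set size from the background universe without
# replacement and counting how often their overlap with the target set is at
# least the observed overlap. The exact hypergeometric tail is provided as an
# analytic oracle for the same null.

#' Exact hypergeometric tail probability of an overlap
#'
#' Probability that two fixed-size sets drawn from a finite universe overlap
#' in at least `k` elements:
#' `sum_{j >= k} C(n_target, j) C(n_background - n_target, n_input - j) /
#' C(n_background, n_input)`.
#'
#' @param k Observed overlap (non-negative integer).
#' @param n_input,n_target,n_background Set and universe sizes.
#' @return The exact upper-tail probability.
#' @export
#' @examples
#' hypergeometric_tail(5, 5, 8, 20) # 56 / 15504
hypergeometric_tail <- function(k, n_input, n_target, n_background) {
  k <- assert_count(k, "k")
  n_input <- assert_count(n_input, "n_input")
  n_target <- assert_count(n_target, "n_target")
  n_background <- assert_count(n_background, "n_background", minimum = 1L)
  if (n_input > n_background || n_target > n_background ||
      k > min(n_input, n_target)) {
    abort("Infeasible arguments: need k <= min(n_input, n_target) <= n_background.",
          class = "polystate_validation_error")
  }
  if (k == 0) return(1)
  phyper(k - 1, m = n_target, n = n_background - n_target, k = n_input,
         lower.tail = FALSE)
}

draw_overlaps <- function(n_background, n_input, target_flag, n_permutations) {
  vapply(seq_len(n_permutations), function(i) {
    sum(target_flag[sample.int(n_background, n_input)])
  }, integer(1))
}

#' Permutation test for gene-set overlap enrichment
#'
#' Samples `n_permutations` gene lists of size `|input_set|` from `universe`
#' without replacement and computes the empirical p-value as the fraction of
#' sampled lists whose overlap with `target_set` is at least the observed
#' overlap. With `pseudocount = TRUE` the p-value is `(count + 1) /
#' (n_permutations + 1)` instead, which can never be exactly zero.
#'
#' `neg_log10_p` is computed from the pseudocounted p-value so it stays
#' finite when no permutation reaches the observed overlap; the literal
#' permutation p and the raw exceedance count are always reported alongside.
#'
#' @param input_set,target_set Character vectors of gene identifiers; must be
#'   subsets of `universe` unless `clip_to_universe = TRUE`.
#' @param universe Character vector: the background universe.
#' @param n_permutations Number of permutation draws (>= 1).
#' @param seed Integer RNG seed; required.
#' @param pseudocount If `TRUE`, report `(count + 1) / (n + 1)` as `p_perm`.
#' @param clip_to_universe If `TRUE`, members outside the universe are dropped
#'   with a warning instead of raising an error.
#' @param input_name,target_name Labels carried into the result.
#' @return A one-row `polystate_enrichment` tibble: set names and sizes,
#'   `n_background`, `overlap`, `n_exceed` (raw exceedance count),
#'   `n_permutations`, `p_perm`, `neg_log10_p`, `seed`.
#' @export
permutation_enrichment <- function(input_set, target_set, universe,
                                   n_permutations = 10000, seed = NULL,
                                   pseudocount = FALSE,
                                   clip_to_universe = FALSE,
                                   input_name = "input",
                                   target_name = "target") {
  n_permutations <- assert_count(n_permutations, "n_permutations", minimum = 1L)
  seed <- assert_seed(seed)
  universe <- unique(as.character(universe))
  input_set <- unique(as.character(input_set))
  target_set <- unique(as.character(target_set))
  outside <- c(setdiff(input_set, universe), setdiff(target_set, universe))
  if (length(outside)) {
    if (clip_to_universe) {
      warn(paste0("Dropping ", length(outside),
                  " member(s) outside the universe."))
      input_set <- intersect(input_set, universe)
      target_set <- intersect(target_set, universe)
    } else {
      abort(paste0("Members outside the universe: ",
                   paste(head(outside, 10), collapse = ", "),
                   if (length(outside) > 10) ", ..." else ""),
            class = "polystate_validation_error")
    }
  }

  n_background <- length(universe)
  n_input <- length(input_set)
  n_target <- length(target_set)
  observed <- length(intersect(input_set, target_set))

  target_flag <- universe %in% target_set
  overlaps <- with_seed_(seed, {
    draw_overlaps(n_background, n_input, target_flag, n_permutations)
  })
  n_exceed <- sum(overlaps >= observed)
  p_literal <- n_exceed / n_permutations
  p_pseudo <- (n_exceed + 1) / (n_permutations + 1)
  p_perm <- if (pseudocount) p_pseudo else p_literal

  res <- tibble(
    input_set = input_name, target_set = target_name,
    n_input = n_input, n_target = n_target, n_background = n_background,
    overlap = observed,
    n_exceed = n_exceed, n_permutations = n_permutations,
    p_perm = p_perm,
    neg_log10_p = -log10(p_pseudo),
    seed = seed
  )
  class(res) <- c("polystate_enrichment", class(res))
  res
}

#' Enrichment grid over input-set and target-set collections
#'
#' Runs [permutation_enrichment()] for every (input set, target set) pair,
#' e.g. RNA-binding-protein target lists against disease gene lists. Each
#' pair gets an independent sub-seed derived deterministically from the
#' master seed, so results do not depend on the order in which pairs are
#' computed.
#'
#' @param input_collections,target_collections Named lists of character
#'   vectors (e.g. from [read_gmt()]).
#' @param universe Background universe (character vector).
#' @inheritParams permutation_enrichment
#' @return A `polystate_enrichment` tibble with one row per pair, sorted by
#'   (input_set, target_set).
#' @export
enrichment_grid <- function(input_collections, target_collections, universe,
                            n_permutations = 10000, seed = NULL,
                            pseudocount = FALSE, clip_to_universe = FALSE) {
  seed <- assert_seed(seed)
  if (is.null(names(input_collections)) || is.null(names(target_collections))) {
    abort("Input and target collections must be named lists.",
          class = "polystate_validation_error")
  }
  input_names <- sort(names(input_collections))
  target_names <- sort(names(target_collections))
  pairs <- tidyr::expand_grid(input_set = input_names,
                              target_set = target_names)
  rows <- purrr::pmap(pairs, function(input_set, target_set) {
    pair_index <- (match(input_set, input_names) - 1L) * length(target_names) +
      match(target_set, target_names)
    permutation_enrichment(
      input_collections[[input_set]], target_collections[[target_set]],
      universe,
      n_permutations = n_permutations,
      seed = derive_seed(seed, pair_index),
      pseudocount = pseudocount, clip_to_universe = clip_to_universe,
      input_name = input_set, target_name = target_set)
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "master_seed") <- seed
  class(res) <- c("polystate_enrichment", class(res))
  res
}

#' @exportS3Method generics::tidy
tidy.polystate_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "polystate_enrichment")
  attr(out, "master_seed") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.polystate_enrichment <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_permutations = x$n_permutations[1],
    min_p = min(x$p_perm),
    max_overlap = max(x$overlap)
  )
}
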