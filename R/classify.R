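# Partition of isoforms into regulation states from the three per-fraction
# contrasts. Rules, applied in order, per isoform:
#   1. input changed            -> transcription_up / transcription_down
#   2. else polysome down       -> repressed
#   3. else polysome up         -> derepressed
#   4. else monosome changed    -> monosome_shift
#   5. else                     -> steady
# A transcriptional change disqualifies the translational labels: the
# repressed/derepressed sets are, by construction, isoforms with steady total
# abundance. Isoforms undetected in total RNA remain eligible for the
# polysome rules (polysome calls are made whether or not the isoform is
# detected in input); they just carry detected_in_input = FALSE.

#' Classify isoforms into regulation states
#'
#' Combines the input, monosome and polysome stage contrasts into one state
#' per isoform. Directions are re-derived from each contrast's q-values at
#' `alpha`, so one classification level applies across all three fractions.
#'
#' @param input_res,monosome_res,polysome_res `polystate_contrast` tibbles
#'   from [test_contrast()] covering identical isoform sets.
#' @param alpha FDR level at which a direction counts as a change.
#' @return A `polystate_states` tibble: `isoform_id`, `input_direction`,
#'   `monosome_direction`, `polysome_direction`, `detected_in_input`, `state`.
#' @export
classify_states <- function(input_res, monosome_res, polysome_res,
                            alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  ids <- input_res$isoform_id
  for (other in list(monosome_res, polysome_res)) {
    if (!setequal(ids, other$isoform_id)) {
      off <- c(setdiff(ids, other$isoform_id),
               setdiff(other$isoform_id, ids))
      abort(paste0("Contrasts cover different isoform sets; offending ids: ",
                   paste(head(off, 10), collapse = ", ")),
            class = "polystate_validation_error")
    }
  }
  direction_at <- function(res) {
    res <- res[match(ids, res$isoform_id), ]
    dplyr::if_else(res$q_value <= alpha & res$log2fc != 0,
                   dplyr::if_else(res$log2fc > 0, "up", "down"),
                   "none")
  }
  input_dir <- direction_at(input_res)
  mono_dir <- direction_at(monosome_res)
  poly_dir <- direction_at(polysome_res)
  detected <- input_res$detected_A | input_res$detected_B

  state <- dplyr::case_when(
    input_dir == "up" ~ "transcription_up",
    input_dir == "down" ~ "transcription_down",
    poly_dir == "down" ~ "repressed",
    poly_dir == "up" ~ "derepressed",
    mono_dir != "none" ~ "monosome_shift",
    .default = "steady"
  )
  res <- tibble(
    isoform_id = ids,
    input_direction = input_dir,
    monosome_direction = mono_dir,
    polysome_direction = poly_dir,
    detected_in_input = detected,
    state = state
  )
  attr(res, "alpha") <- alpha
  class(res) <- c("polystate_states", class(res))
  res
}

#' Count isoforms per regulation state
#'
#' Tallies a state table into one row of per-state counts plus the derived
#' totals: `translationally_altered` (repressed + derepressed) and
#' `below_detection_derepressed` (derepressed isoforms not detected in the
#' input fraction at either stage).
#'
#' @param state_table A `polystate_states` tibble from [classify_states()],
#'   or any tibble with `state` (and optionally `detected_in_input`) columns.
#' @return A one-row `polystate_state_summary` tibble.
#' @export
summarize_states <- function(state_table) {
  if (!is.data.frame(state_table) || !"state" %in% names(state_table)) {
    abort("`state_table` must be a data frame with a `state` column.",
          class = "polystate_validation_error")
  }
  bad <- setdiff(unique(state_table$state), .states)
  if (length(bad)) {
    abort(paste0("Unknown state label(s): ", paste(bad, collapse = ", ")),
          class = "polystate_validation_error")
  }
  counts <- vapply(.states, function(s) sum(state_table$state == s),
                   integer(1))
  below <- if ("detected_in_input" %in% names(state_table)) {
    sum(state_table$state == "derepressed" & !state_table$detected_in_input)
  } else {
    NA_integer_
  }
  res <- dplyr::bind_cols(
    as_tibble(as.list(counts)),
    tibble(
      n_isoforms = nrow(state_table),
      translationally_altered = counts[["repressed"]] + counts[["derepressed"]],
      below_detection_derepressed = below
    )
  )
  class(res) <- c("polystate_state_summary", class(res))
  res
}

#' Cross-reference an isoform/gene list with an annotation set
#'
#' Case-sensitive exact intersection with duplicates collapsed, e.g. for
#' crossing a derepressed gene list with a disease gene set.
#'
#' @param ids Character vector of identifiers (e.g. a state-table subset).
#' @param annotation_set Character vector of annotation identifiers.
#' @return A one-row tibble: `n_ids`, `n_set`, `n_overlap`, and `members`
#'   (list-column with the sorted intersected identifiers).
#' @export
#' @examples
#' crossref_sets(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
crossref_sets <- function(ids, annotation_set) {
  ids <- unique(as.character(ids))
  annotation_set <- unique(as.character(annotation_set))
  members <- sort(intersect(ids, annotation_set))
  tibble(
    n_ids = length(ids),
    n_set = length(annotation_set),
    n_overlap = length(members),
    members = list(members)
  )
}

#' @exportS3Method generics::tidy
tidy.polystate_states <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "polystate_states")
  out
}

#' @exportS3Method generics::glance
glance.polystate_states <- function(x, ...) {
  s <- summarize_states(x)
  class(s) <- setdiff(class(s), "polystate_state_summary")
  dplyr::bind_cols(tibble(alpha = attr(x, "alpha") %||% NA_real_), s)
}
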