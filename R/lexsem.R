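#' Unique-verb dispersion
#'
#' Number of distinct related-verb lemmas produced for each noun, a dispersion
#' measure of the response distribution. By default counted per noun within
#' each cohort ("for each noun and for each cohort"); `by = "subject"` counts
#' distinct related verbs per subject instead.
#'
#' @param trials Coded trial tibble (one cohort or several; `group` is kept).
#' @param by `"noun"` (default) or `"subject"`.
#' @return A tibble with `group`, the unit column, and `n_unique_verbs`
#'   (zero rows appear for units with no related responses when the unit is
#'   present in `trials`).
#' @export
unique_verb_counts <- function(trials, by = c("noun", "subject")) {
  by <- match.arg(by)
  unit <- if (by == "noun") "noun" else "subject_id"
  units <- distinct(trials, .data$group, !!rlang::sym(unit))
  counts <- trials %>%
    filter(.data$response_code == "related_verb",
           !is.na(.data$response_lemma)) %>%
    group_by(.data$group, !!rlang::sym(unit)) %>%
    summarise(n_unique_verbs = dplyr::n_distinct(.data$response_lemma),
              .groups = "drop")
  units %>%
    left_join(counts, by = c("group", unit)) %>%
    mutate(n_unique_verbs = dplyr::coalesce(.data$n_unique_verbs, 0L)) %>%
    arrange(.data$group, !!rlang::sym(unit))
}

#' Light-verb percentage per subject
#'
#' Percentage of a subject's related-verb responses whose head lemma is a
#' "light" verb (semantically impoverished high-frequency predicates such as
#' *do*, *take*, *get*); phrasal responses match on their head ("take out"
#' counts as *take*). Subjects with zero related responses get `NA`, dropped
#' from group statistics.
#'
#' @param trials Coded trial tibble.
#' @param light Character vector of light-verb lemmas (default
#'   [light_verbs()]).
#' @return Tibble with `subject_id`, `group`, `n_related`, `pct_light_verbs`.
#' @export
light_verb_pct <- function(trials, light = light_verbs()) {
  trials %>%
    group_by(.data$subject_id, .data$group) %>%
    summarise(
      n_related = sum(.data$response_code == "related_verb"),
      pct_light_verbs = if (.data$n_related > 0) {
        100 * sum(.data$response_code == "related_verb" &
                    .data$response_lemma %in% light) / .data$n_related
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Cosine similarity between two vectors
#'
#' `dot(a, b) / (|a| * |b|)`; symmetric and invariant to positive rescaling
#' of either argument.
#'
#' @param a,b Numeric vectors of equal length, both nonzero.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine similarity is undefined for a zero vector",
      class = "verbgen_domain_error"
    )
  }
  sum(a * b) / (na * nb)
}

vg_lookup_vec <- function(emb, word) {
  i <- match(word, rownames(emb))
  if (is.na(i)) NULL else emb[i, ]
}

#' Stimulus-response similarities for not-a-verb trials
#'
#' For every non-repetition not-a-verb response, the embedding cosine
#' similarity between the response token and the stimulus noun. Trials whose
#' noun or response is absent from the embedding table are flagged
#' `covered = FALSE` (similarity `NA`) rather than dropped silently.
#'
#' @param trials Coded trial tibble.
#' @param emb An `embedding_table` (see [read_embeddings()]).
#' @return Tibble with `subject_id`, `group`, `noun`, `response_lemma`,
#'   `repetition`, `covered`, `similarity`.
#' @export
notverb_similarities <- function(trials, emb) {
  nv <- trials %>%
    filter(.data$response_code == "not_a_verb") %>%
    mutate(repetition = .data$response_lemma == .data$noun)
  sims <- purrr::map2_dbl(nv$noun, nv$response_lemma, function(noun, resp) {
    va <- vg_lookup_vec(emb, noun)
    vb <- vg_lookup_vec(emb, resp)
    if (is.null(va) || is.null(vb)) NA_real_ else cosine_similarity(va, vb)
  })
  nv %>%
    mutate(
      covered = .data$repetition | !is.na(sims),
      similarity = dplyr::if_else(.data$repetition, NA_real_, sims)
    ) %>%
    select(
      "subject_id", "group", "noun", "response_lemma",
      "repetition", "covered", "similarity"
    )
}

#' Decompose not-a-verb errors per subject
#'
#' Splits each subject's not-a-verb responses into (1) simple repetitions of
#' the stimulus noun and (2) semantically related nouns, defined as a
#' non-repetition response whose embedding cosine similarity to the stimulus
#' is strictly greater than `threshold`. Non-repetition trials without
#' embedding coverage are counted in `n_uncovered` and reported with a
#' warning. For every subject
#' `n_repetitions + n_semantically_related + n_other + n_uncovered` equals the
#' subject's total not-a-verb count.
#'
#' @inheritParams notverb_similarities
#' @param threshold Similarity cut-off (default 0.3, the conventional value;
#'   see [calibrate_threshold()] for a data-driven choice).
#' @return Tibble with `subject_id`, `group`, `n_not_verb`, `n_repetitions`,
#'   `n_semantically_related`, `n_other`, `n_uncovered`, `threshold_used`.
#' @export
not_verb_decomposition <- function(trials, emb, threshold = 0.3) {
  sims <- notverb_similarities(trials, emb)
  if (any(!sims$covered)) {
    warn(sprintf(
      "%d not-a-verb response(s) lack embedding coverage and were skipped",
      sum(!sims$covered)
    ))
  }
  subjects <- distinct(trials, .data$subject_id, .data$group)
  out <- sims %>%
    group_by(.data$subject_id, .data$group) %>%
    summarise(
      n_not_verb = dplyr::n(),
      n_repetitions = sum(.data$repetition),
      n_semantically_related = sum(!.data$repetition & .data$covered &
                                     .data$similarity > threshold),
      n_uncovered = sum(!.data$covered),
      .groups = "drop"
    ) %>%
    mutate(n_other = .data$n_not_verb - .data$n_repetitions -
             .data$n_semantically_related - .data$n_uncovered)
  subjects %>%
    left_join(out, by = c("subject_id", "group")) %>%
    mutate(
      across(
        c("n_not_verb", "n_repetitions", "n_semantically_related",
          "n_uncovered", "n_other"),
        ~ as.integer(dplyr::coalesce(.x, 0L))
      ),
      threshold_used = threshold
    ) %>%
    select(
      "subject_id", "group", "n_not_verb", "n_repetitions",
      "n_semantically_related", "n_other", "n_uncovered", "threshold_used"
    ) %>%
    arrange(.data$subject_id)
}

#' Calibrate the semantic-relatedness threshold
#'
#' The median of the pooled stimulus-response similarity values across all
#' cohorts' non-repetition not-a-verb responses, the data-driven analogue of
#' the conventional 0.3 cut-off.
#'
#' @param similarities Numeric vector of cosine similarities (NAs dropped).
#' @return The median similarity.
#' @export
calibrate_threshold <- function(similarities) {
  similarities <- similarities[!is.na(similarities)]
  if (length(similarities) == 0) {
    abort("no similarity values to calibrate a threshold from",
      class = "verbgen_state_error"
    )
  }
  median(similarities)
}

#' Per-subject lexico-semantic profile
#'
#' Convenience wrapper combining [light_verb_pct()] and
#' [not_verb_decomposition()].
#'
#' @inheritParams not_verb_decomposition
#' @param light Light-verb lemmas.
#' @return One row per subject.
#' @export
lexsem_profiles <- function(trials, emb, threshold = 0.3,
                            light = light_verbs()) {
  left_join(
    light_verb_pct(trials, light = light),
    not_verb_decomposition(trials, emb, threshold = threshold),
    by = c("subject_id", "group")
  )
}
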