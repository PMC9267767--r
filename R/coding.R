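#' Build a set of response-coding rules
#'
#' The rule-based auto-coder mirrors human rating practice on a verb
#' generation task: a response is *related_verb* when its head-verb lemma is
#' acceptable for the stimulus noun, *unrelated_verb* when it is a known verb
#' that is not acceptable for that noun, *not_a_verb* when it is not a verb
#' at all, and *missing* when empty. Per-item exception lists override the
#' lexicon in either direction, mirroring rater adjudications such as
#' rejecting "to be careful" for knife while accepting "to do" for laundry.
#'
#' @param lexicon Named list: noun -> character vector of acceptable verb
#'   lemmas. The default reference lexicon in practice is the set of verbs
#'   produced by at least one control for that noun (see
#'   [reference_lexicon()]).
#' @param accept_phrasal Match phrasal responses ("take out") on their head
#'   verb. Default `TRUE`.
#' @param rejected_phrases Tibble/data frame with columns `noun`, `phrase`:
#'   responses always coded `unrelated_verb` for that noun.
#' @param accepted_exceptions Tibble with columns `noun`, `phrase`: responses
#'   always coded `related_verb` for that noun. Must be disjoint from
#'   `rejected_phrases`.
#' @param extra_verbs Additional verb lemmas that count as verbs for the
#'   not-a-verb decision (the global verb vocabulary is the lexicon union the
#'   light-verb list union this).
#' @param inflections Optional named vector of extra surface-form-to-lemma
#'   mappings (see [lemmatize()]).
#'
#' @return A `coding_rules` object.
#' @export
coding_rules <- function(lexicon,
                         accept_phrasal = TRUE,
                         rejected_phrases = NULL,
                         accepted_exceptions = NULL,
                         extra_verbs = character(),
                         inflections = NULL) {
  stopifnot(is.list(lexicon), !is.null(names(lexicon)))
  names(lexicon) <- vg_norm_token(names(lexicon))
  lexicon <- lapply(lexicon, function(v) unique(vg_norm_token(v)))
  rej <- vg_pair_keys(rejected_phrases)
  acc <- vg_pair_keys(accepted_exceptions)
  overlap <- intersect(rej, acc)
  if (length(overlap) > 0) {
    abort(
      sprintf(
        "rejected and accepted exception sets overlap: %s",
        paste(overlap, collapse = "; ")
      ),
      class = "verbgen_config_error"
    )
  }
  verb_vocab <- unique(c(
    unlist(lexicon, use.names = FALSE), light_verbs(),
    vg_norm_token(extra_verbs)
  ))
  structure(
    list(
      lexicon = lexicon, accept_phrasal = accept_phrasal,
      rejected = rej, accepted = acc,
      verb_vocab = verb_vocab, inflections = inflections
    ),
    class = "coding_rules"
  )
}

vg_pair_keys <- function(pairs) {
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0) {
    return(character())
  }
  pairs <- as.data.frame(pairs)
  vg_assert_cols(pairs, c("noun", "phrase"), "exception table")
  paste(vg_norm_token(pairs$noun), vg_norm_token(pairs$phrase), sep = "\r")
}

#' Derive a reference lexicon from coded control trials
#'
#' The default acceptability standard: every verb lemma produced by at least
#' one control (as a related or, optionally, any verb response) for a noun is
#' acceptable for that noun.
#'
#' @param hc_trials Coded control trials.
#' @param codes Response codes that contribute lemmas (default related only).
#' @return Named list noun -> character vector of lemmas.
#' @export
reference_lexicon <- function(hc_trials, codes = "related_verb") {
  keep <- hc_trials %>%
    filter(.data$response_code %in% codes, !is.na(.data$response_lemma))
  split(keep$response_lemma, keep$noun) %>% lapply(unique)
}

#' Code raw responses with the four-way error taxonomy
#'
#' Applies [coding_rules()] to every trial that lacks a pre-assigned
#' `response_code`; pre-assigned codes (e.g., from human raters, or upstream
#' handling of articulatory errors and phonological paraphasias) are never
#' overwritten. Coding is deterministic and idempotent.
#'
#' Decision order per trial: empty response -> `missing`; per-item rejected
#' phrase -> `unrelated_verb`; per-item accepted exception -> `related_verb`;
#' head lemma acceptable for the noun -> `related_verb`; head lemma in the
#' global verb vocabulary -> `unrelated_verb`; otherwise `not_a_verb`.
#' `response_lemma` is filled with the head lemma (the normalized token
#' itself for non-verbs, so repetitions stay detectable).
#'
#' @param trials Trial tibble (see [read_trials()]).
#' @param rules A `coding_rules` object covering every noun in `trials`.
#' @return The trials tibble with `response_code` and `response_lemma` filled.
#' @export
code_responses <- function(trials, rules) {
  stopifnot(inherits(rules, "coding_rules"))
  uncovered <- setdiff(unique(trials$noun), names(rules$lexicon))
  if (length(uncovered) > 0) {
    abort(
      sprintf(
        "noun(s) absent from the reference lexicon: %s",
        paste(uncovered, collapse = ", ")
      ),
      class = "verbgen_config_error"
    )
  }
  resp <- vg_norm_token(trials$response_raw)
  lemma <- head_lemma(resp,
    accept_phrasal = rules$accept_phrasal,
    extra = rules$inflections
  )
  pairkey <- paste(trials$noun, resp, sep = "\r")
  in_lex <- mapply(
    function(l, noun) l %in% rules$lexicon[[noun]],
    lemma, trials$noun,
    USE.NAMES = FALSE
  )
  auto <- dplyr::case_when(
    resp == "" ~ "missing",
    pairkey %in% rules$rejected ~ "unrelated_verb",
    pairkey %in% rules$accepted ~ "related_verb",
    in_lex ~ "related_verb",
    lemma %in% rules$verb_vocab ~ "unrelated_verb",
    TRUE ~ "not_a_verb"
  )
  trials %>%
    mutate(
      response_code = dplyr::coalesce(.data$response_code, auto),
      response_lemma = dplyr::coalesce(
        .data$response_lemma,
        dplyr::if_else(resp == "", NA_character_, lemma)
      )
    )
}

#' Per-subject accuracy, error-pattern and consistency profiles
#'
#' For every subject: percentage of trials in each of the four response
#' categories (closing to 100 exactly); error consistency (percentage of
#' stimulus pairs — nouns presented twice — with both presentations
#' incorrect); error-type consistency (percentage of those consistently-erred
#' pairs in which both errors share a type; `NA` when a subject has no
#' consistently-erred pairs); and mean reaction time.
#'
#' @param trials Coded trial tibble (every `response_code` assigned).
#' @param rt_trials Which trials enter `mean_rt_s`: `"correct"` (default) or
#'   `"all"` non-missing trials.
#' @return A tibble, one row per subject.
#' @export
subject_profiles <- function(trials, rt_trials = c("correct", "all")) {
  rt_trials <- match.arg(rt_trials)
  if (anyNA(trials$response_code)) {
    abort("trials must be coded before profiling (uncoded response_code)",
      class = "verbgen_state_error"
    )
  }
  base <- trials %>%
    group_by(.data$subject_id, .data$group) %>%
    summarise(
      n_trials = dplyr::n(),
      pct_correct = 100 * mean(.data$response_code == "related_verb"),
      pct_not_verb = 100 * mean(.data$response_code == "not_a_verb"),
      pct_unrelated_verb = 100 * mean(.data$response_code == "unrelated_verb"),
      pct_missing = 100 * mean(.data$response_code == "missing"),
      mean_rt_s = if (rt_trials == "correct") {
        mean(.data$rt_s[.data$response_code == "related_verb"], na.rm = TRUE)
      } else {
        mean(.data$rt_s[.data$response_code != "missing"], na.rm = TRUE)
      },
      .groups = "drop"
    ) %>%
    mutate(mean_rt_s = dplyr::if_else(is.nan(.data$mean_rt_s),
      NA_real_, .data$mean_rt_s
    ))

  cons <- trials %>%
    group_by(.data$subject_id, .data$noun) %>%
    filter(dplyr::n() == 2) %>%
    summarise(
      both_wrong = all(.data$response_code != "related_verb"),
      same_type = .data$both_wrong &&
        dplyr::n_distinct(.data$response_code) == 1,
      .groups = "drop_last"
    ) %>%
    summarise(
      n_pairs = dplyr::n(),
      pct_error_consistency = 100 * mean(.data$both_wrong),
      pct_error_type_consistency = if (any(.data$both_wrong)) {
        100 * sum(.data$same_type) / sum(.data$both_wrong)
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  left_join(base, cons, by = "subject_id") %>%
    select(
      "subject_id", "group", "n_trials", "n_pairs", "pct_correct",
      "pct_not_verb", "pct_unrelated_verb", "pct_missing",
      "pct_error_consistency", "pct_error_type_consistency", "mean_rt_s"
    )
}

#' Exclude accuracy outliers from a cohort
#'
#' Single-pass two-standard-deviation rule on percentage correct: a subject is
#' excluded when its accuracy lies strictly outside mean +/- 2 SD of its
#' reference cohort, with mean and SD computed once on the full cohort (never
#' iterated). In the default mode the reference cohorts are (a) all patient
#' groups pooled and (b) controls, the usual practice when patient subgroup
#' sizes are small; `per_group` uses each diagnostic group as its own
#' reference. A zero-variance cohort excludes any deviating subject.
#'
#' @param profiles Subject profile tibble (see [subject_profiles()]).
#' @param mode `"pooled_patients_and_hc"` (default) or `"per_group"`.
#' @param n_sd Width of the exclusion band in SD units (default 2).
#' @return An `outlier_report`: list with `kept` (subject ids), `excluded`
#'   (tibble of id, group, pct_correct), `cohorts` (tibble of reference
#'   cohort, mean, sd, bounds) and the filtered `profiles`. Has [tidy()] and
#'   [glance()] methods.
#' @export
exclude_outliers <- function(profiles,
                             mode = c("pooled_patients_and_hc", "per_group"),
                             n_sd = 2) {
  mode <- match.arg(mode)
  cohort <- if (mode == "pooled_patients_and_hc") {
    dplyr::if_else(profiles$group == "HC", "HC", "patients")
  } else {
    profiles$group
  }
  sizes <- table(cohort)
  if (any(sizes < 3)) {
    abort(
      sprintf(
        "reference cohort(s) with fewer than 3 subjects: %s",
        paste(names(sizes)[sizes < 3], collapse = ", ")
      ),
      class = "verbgen_state_error"
    )
  }
  stats_tbl <- tibble(cohort = cohort, pct_correct = profiles$pct_correct) %>%
    group_by(.data$cohort) %>%
    summarise(
      mean = mean(.data$pct_correct), sd = sd(.data$pct_correct),
      .groups = "drop"
    ) %>%
    mutate(lower = .data$mean - n_sd * .data$sd,
           upper = .data$mean + n_sd * .data$sd)
  ref <- stats_tbl[match(cohort, stats_tbl$cohort), ]
  # strictly outside the band; sd == 0 => any deviation from the mean excludes
  out <- abs(profiles$pct_correct - ref$mean) > n_sd * ref$sd
  report <- list(
    mode = mode, n_sd = n_sd,
    kept = profiles$subject_id[!out],
    excluded = profiles[out, c("subject_id", "group", "pct_correct")],
    cohorts = stats_tbl,
    profiles = profiles[!out, , drop = FALSE]
  )
  class(report) <- "outlier_report"
  report
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Outlier exclusion (%s, %g SD): %d kept, %d excluded\n",
    x$mode, x$n_sd, length(x$kept), nrow(x$excluded)
  ))
  if (nrow(x$excluded) > 0) print(x$excluded)
  invisible(x)
}

#' @export
tidy.outlier_report <- function(x, ...) {
  tibble(
    subject_id = c(x$kept, x$excluded$subject_id),
    excluded = c(
      rep(FALSE, length(x$kept)),
      rep(TRUE, nrow(x$excluded))
    )
  )
}

#' @export
glance.outlier_report <- function(x, ...) {
  tibble(
    mode = x$mode, n_sd = x$n_sd,
    n_kept = length(x$kept), n_excluded = nrow(x$excluded)
  )
}
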