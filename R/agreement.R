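#' Per-noun control response distributions
#'
#' Pools the verb responses the control cohort produced for each noun into a
#' count table, the raw material for the agreement indices. By default both
#' presentations are pooled (a subject answering twice counts twice) and all
#' verb responses (related and unrelated) enter; missing and not-a-verb
#' trials never do.
#'
#' @param trials Coded trial tibble.
#' @param groups Groups whose responses form the distribution (default
#'   `"HC"`).
#' @param include_unrelated Include `unrelated_verb` responses (default
#'   `TRUE`).
#' @param responses `"all"` pools both presentations; `"first"` keeps one
#'   response per subject (presentation 1), the per-subject mode.
#' @return A tibble with columns `noun`, `lemma`, `n` (count >= 1).
#' @export
response_distributions <- function(trials, groups = "HC",
                                   include_unrelated = TRUE,
                                   responses = c("all", "first")) {
  responses <- match.arg(responses)
  codes <- if (include_unrelated) {
    c("related_verb", "unrelated_verb")
  } else {
    "related_verb"
  }
  keep <- trials %>%
    filter(.data$group %in% .env$groups, .data$response_code %in% codes,
           !is.na(.data$response_lemma))
  if (responses == "first") keep <- filter(keep, .data$presentation == 1L)
  keep %>%
    count(.data$noun, lemma = .data$response_lemma, name = "n") %>%
    arrange(.data$noun, dplyr::desc(.data$n), .data$lemma)
}

#' Shannon response entropy of a count distribution
#'
#' `E = sum_i p_i * log2(1 / p_i)` over the k distinct verbs with
#' `p_i = count_i / n`. Zero means perfect agreement (a single verb); 1 bit
#' means two verbs produced with equal frequency.
#'
#' @param counts Positive integer counts, one per distinct verb.
#' @return Entropy in bits.
#' @export
response_entropy <- function(counts) {
  counts <- counts[counts > 0]
  stopifnot(length(counts) >= 1)
  p <- counts / sum(counts)
  sum(p * log2(1 / p))
}

#' Association Strength Index
#'
#' Percentage of responses that are the modal (most common) verb: a proxy for
#' retrieval demand — the stronger the noun-verb association, the higher the
#' ASI.
#'
#' @inheritParams response_entropy
#' @return Percent in (0, 100].
#' @export
asi <- function(counts) {
  counts <- counts[counts > 0]
  stopifnot(length(counts) >= 1)
  100 * max(counts) / sum(counts)
}

#' Competition Strength Index
#'
#' Ratio of the modal response percentage to the second most common one: a
#' proxy for selection/competition demand — the wider the gap between the top
#' two verbs, the higher the CSI. When only one distinct verb was produced the
#' second percentage is imputed as one hypothetical dissenter
#' (`100 / n_responses`), keeping the index finite.
#'
#' @inheritParams response_entropy
#' @return Ratio >= 1.
#' @export
csi <- function(counts) {
  counts <- counts[counts > 0]
  stopifnot(length(counts) >= 1)
  n <- sum(counts)
  p <- sort(100 * counts / n, decreasing = TRUE)
  p2 <- if (length(p) >= 2) p[2] else 100 / n
  p[1] / p2
}

#' Per-noun agreement profiles from control trials
#'
#' Builds the control response distribution for every noun and computes the
#' distinct-verb count `k`, response entropy, ASI and CSI, plus the modal verb
#' (ties broken lexicographically for reporting only; the indices themselves
#' are order-independent).
#'
#' @inheritParams response_distributions
#' @return A tibble with columns `noun`, `k`, `n_responses`, `modal_verb`,
#'   `entropy`, `asi`, `csi`.
#' @export
agreement_profiles <- function(trials, groups = "HC",
                               include_unrelated = TRUE,
                               responses = c("all", "first")) {
  dist <- response_distributions(
    trials,
    groups = groups, include_unrelated = include_unrelated,
    responses = responses
  )
  empty <- setdiff(
    unique(trials$noun[trials$group %in% groups]),
    unique(dist$noun)
  )
  if (length(empty) > 0) {
    abort(
      sprintf(
        "no verb responses for noun(s): %s",
        paste(empty, collapse = ", ")
      ),
      class = "verbgen_state_error"
    )
  }
  dist %>%
    group_by(.data$noun) %>%
    summarise(
      k = dplyr::n(),
      n_responses = sum(.data$n),
      modal_verb = .data$lemma[order(-.data$n, .data$lemma)][1],
      entropy = response_entropy(.data$n),
      asi = asi(.data$n),
      csi = csi(.data$n),
      .groups = "drop"
    )
}
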