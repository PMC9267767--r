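#' One-way between-groups ANOVA
#'
#' Classical fixed-effects ANOVA, `F = MS_between / MS_within`, on a long
#' table of values and group labels. When every value is identical across all
#' groups the F statistic is undefined and reported as `NA`.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the grouping
#'   factor.
#' @return A `vg_anova` object; [tidy()] gives the effect table.
#' @export
oneway_anova <- function(data, value, group) {
  df <- tibble(
    y = as.numeric(data[[value]]),
    g = factor(data[[group]])
  ) %>% filter(!is.na(.data$y))
  if (dplyr::n_distinct(df$g) < 2) {
    abort("need at least 2 groups", class = "verbgen_state_error")
  }
  if (any(table(df$g) < 2)) {
    abort("each group needs n >= 2", class = "verbgen_state_error")
  }
  fit <- aov(y ~ g, data = df)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  pval <- tab[["Pr(>F)"]][1]
  if (var(df$y) == 0) {
    fstat <- NA_real_
    pval <- NA_real_
  }
  structure(
    list(
      design = "one_way",
      effects = tibble(
        term = group,
        df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
        statistic = fstat, p.value = pval
      ),
      fit = fit, data = df
    ),
    class = "vg_anova"
  )
}

#' Group-by-error-type ANOVA on subject profiles
#'
#' Compares patient variants on their error patterns: each subject contributes
#' its three error-type percentages (not-a-verb, unrelated verb, missing), so
#' the design is mixed — diagnostic group between subjects, error type within
#' subjects — and the effects of interest are group, error type, and their
#' interaction. Subjects with any missing error percentage are excluded with a
#' warning. A single-group input degenerates to a within-subject one-way
#' design (error type only).
#'
#' @param profiles Subject profile tibble (see [subject_profiles()]); HC rows,
#'   if present, are dropped.
#' @param design `"mixed"` (default, error type within-subject) or
#'   `"between"`, a fully-between long-format variant for comparison.
#' @return A `vg_anova` object.
#' @export
group_by_errortype_anova <- function(profiles, design = c("mixed", "between")) {
  design <- match.arg(design)
  pats <- filter(profiles, .data$group != "HC")
  bad <- !complete.cases(
    pats[, c("pct_not_verb", "pct_unrelated_verb", "pct_missing")]
  )
  if (any(bad)) {
    warn(sprintf("excluding %d subject(s) with missing error percentages",
                 sum(bad)))
    pats <- pats[!bad, , drop = FALSE]
  }
  long <- pats %>%
    select("subject_id", "group", "pct_not_verb", "pct_unrelated_verb",
           "pct_missing") %>%
    tidyr::pivot_longer(
      cols = c("pct_not_verb", "pct_unrelated_verb", "pct_missing"),
      names_to = "error_type", values_to = "pct"
    ) %>%
    mutate(
      subject_id = factor(.data$subject_id),
      group = factor(.data$group),
      error_type = factor(.data$error_type)
    )
  one_group <- dplyr::n_distinct(long$group) == 1
  if (design == "between") {
    form <- if (one_group) pct ~ error_type else pct ~ group * error_type
    fit <- aov(form, data = long)
    tab <- summary(fit)[[1]]
    effects <- tibble(
      term = stringr::str_trim(rownames(tab)[-nrow(tab)]),
      df1 = tab[["Df"]][-nrow(tab)],
      df2 = tab[["Df"]][nrow(tab)],
      statistic = tab[["F value"]][-nrow(tab)],
      p.value = tab[["Pr(>F)"]][-nrow(tab)]
    )
  } else {
    form <- if (one_group) {
      pct ~ error_type + Error(subject_id)
    } else {
      pct ~ group * error_type + Error(subject_id)
    }
    fit <- aov(form, data = long)
    effects <- purrr::map_dfr(summary(fit), function(stratum) {
      tab <- stratum[[1]]
      keep <- stringr::str_trim(rownames(tab)) != "Residuals"
      tibble(
        term = stringr::str_trim(rownames(tab))[keep],
        df1 = tab[["Df"]][keep],
        df2 = tab[["Df"]][!keep][1],
        statistic = tab[["F value"]][keep],
        p.value = tab[["Pr(>F)"]][keep]
      )
    })
  }
  structure(
    list(design = paste0("group_by_errortype_", design),
         effects = effects, fit = fit, data = long),
    class = "vg_anova"
  )
}

#' @export
print.vg_anova <- function(x, ...) {
  cat(sprintf("ANOVA (%s)\n", x$design))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.vg_anova <- function(x, ...) x$effects

#' @export
glance.vg_anova <- function(x, ...) {
  tibble(design = x$design, n_terms = nrow(x$effects))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted pairwise mean differences using the pooled
#' within-group mean square, the standard post hoc companion to
#' [oneway_anova()].
#'
#' @inheritParams oneway_anova
#' @return A tibble with `group_a`, `group_b`, `estimate` (mean difference
#'   a - b), and `adj.p.value`; every unordered pair appears once.
#' @export
tukey_hsd <- function(data, value, group) {
  res <- oneway_anova(data, value, group)
  tk <- TukeyHSD(res$fit)$g
  labels <- stringr::str_split_fixed(rownames(tk), "-", 2)
  tibble(
    group_a = labels[, 1], group_b = labels[, 2],
    estimate = tk[, "diff"],
    conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
    adj.p.value = tk[, "p adj"]
  )
}

vg_cor_table <- function(df, outcome, predictors, m, alpha = 0.05) {
  purrr::map_dfr(predictors, function(pr) {
    keep <- complete.cases(df[[outcome]], df[[pr]])
    x <- df[[pr]][keep]
    y <- df[[outcome]][keep]
    if (length(x) < 4 || sd(x) == 0 || sd(y) == 0) {
      return(tibble(
        predictor = pr, n = length(x), r = NA_real_, p.value = NA_real_,
        adj.p.value = NA_real_, m = m, survives = NA
      ))
    }
    ct <- cor.test(x, y, method = "pearson")
    padj <- min(1, m * ct$p.value)
    tibble(
      predictor = pr, n = length(x),
      r = unname(ct$estimate), p.value = ct$p.value,
      adj.p.value = padj, m = m, survives = padj < alpha
    )
  })
}

#' By-item correlations of accuracy with stimulus properties
#'
#' Pools percentage-correct scores across the subjects of one variant, item by
#' item, and correlates them (Pearson) with six per-noun predictors: log
#' corpus frequency, phoneme count, semantic neighborhood density, and the
#' control-derived ASI, CSI and response entropy. Bonferroni correction over
#' the family of six.
#'
#' @param item_accuracy Tibble with `noun` and `pct_correct` (see
#'   [item_accuracy()]).
#' @param norms Per-noun norms with `freq_log`, `n_phonemes`,
#'   `semantic_neighborhood`.
#' @param agreement Per-noun agreement profiles with `asi`, `csi`, `entropy`
#'   (see [agreement_profiles()]).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble, one row per predictor, with raw and Bonferroni-adjusted
#'   p-values and a `survives` flag.
#' @export
by_item_correlations <- function(item_accuracy, norms, agreement,
                                 alpha = 0.05) {
  df <- item_accuracy %>%
    left_join(norms, by = "noun") %>%
    left_join(agreement, by = "noun")
  preds <- c("freq_log", "n_phonemes", "semantic_neighborhood",
             "asi", "csi", "entropy")
  vg_assert_cols(df, c("pct_correct", preds), "by-item correlation input")
  if (sum(complete.cases(df[, c("pct_correct", preds)])) < 4) {
    abort("need at least 4 items with complete data",
      class = "verbgen_state_error"
    )
  }
  vg_cor_table(df, "pct_correct", preds, m = length(preds), alpha = alpha)
}

#' By-subject correlations of accuracy with neuropsychological measures
#'
#' Correlates per-subject accuracy with three neuropsychological measures
#' (single-word comprehension `ppvt`, the phonemic/semantic fluency ratio,
#' and `trails_time`), Bonferroni-corrected over the family of three.
#' Missing scores are handled pairwise-complete; subjects with zero semantic
#' fluency are excluded from the ratio.
#'
#' @param profiles Subject profiles with `pct_correct`.
#' @param subjects Subject records with `ppvt`, `phonemic_fluency`,
#'   `semantic_fluency`, `trails_time`.
#' @inheritParams by_item_correlations
#' @return A tibble, one row per measure.
#' @export
by_subject_correlations <- function(profiles, subjects, alpha = 0.05) {
  vg_assert_cols(
    subjects,
    c("subject_id", "ppvt", "phonemic_fluency", "semantic_fluency",
      "trails_time"),
    "subjects table"
  )
  df <- profiles %>%
    select("subject_id", "pct_correct") %>%
    left_join(subjects, by = "subject_id") %>%
    mutate(fluency_ratio = dplyr::if_else(
      !is.na(.data$semantic_fluency) & .data$semantic_fluency != 0,
      .data$phonemic_fluency / .data$semantic_fluency,
      NA_real_
    ))
  vg_cor_table(df, "pct_correct", c("ppvt", "fluency_ratio", "trails_time"),
               m = 3, alpha = alpha)
}

#' Per-noun accuracy pooled across subjects
#'
#' Percentage of correct (related-verb) responses per noun, pooled over the
#' subjects of the given group(s) and, by default, both presentations.
#'
#' @param trials Coded trial tibble.
#' @param groups Group labels to pool over (default all present).
#' @param presentations Presentation indices to include (default both).
#' @return Tibble with `noun`, `n_trials`, `pct_correct`.
#' @export
item_accuracy <- function(trials, groups = unique(trials$group),
                          presentations = c(1L, 2L)) {
  trials %>%
    filter(.data$group %in% .env$groups,
           .data$presentation %in% .env$presentations) %>%
    group_by(.data$noun) %>%
    summarise(
      n_trials = dplyr::n(),
      pct_correct = 100 * mean(.data$response_code == "related_verb"),
      .groups = "drop"
    )
}
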