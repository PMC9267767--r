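# From-definition sums-of-squares oracle for the one-way F statistic.
oracle_f <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_b <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- length(unique(groups))
  n <- length(values)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

test_that("one-way ANOVA matches hand computation and handles degeneracy", {
  df <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6),
                       g = rep(c("a", "b"), each = 3))
  res <- oneway_anova(df, "y", "g")
  eff <- tidy(res)
  expect_equal(eff$statistic, 13.5)
  expect_equal(c(eff$df1, eff$df2), c(1, 4))

  # all values identical across groups: F undefined, reported as NA
  const <- tibble::tibble(y = rep(5, 9), g = rep(c("a", "b", "c"), 3))
  expect_true(is.na(tidy(oneway_anova(const, "y", "g"))$statistic))

  # a single zero-variance group among others is fine
  zv <- tibble::tibble(y = c(5, 5, 5, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_gt(tidy(oneway_anova(zv, "y", "g"))$statistic, 0)
})

test_that("one-way F agrees with the sums-of-squares oracle", {
  withr::with_seed(21, {
    for (i in 1:25) {
      k <- sample(2:4, 1)
      ns <- sample(3:7, k, replace = TRUE)
      df <- tibble::tibble(
        y = rnorm(sum(ns), mean = rep(rnorm(k, sd = 2), ns)),
        g = rep(letters[1:k], ns)
      )
      expect_equal(tidy(oneway_anova(df, "y", "g"))$statistic,
                   oracle_f(df$y, df$g),
                   tolerance = 1e-9)
    }
  })
})

test_that("ANOVA p-values are uniform under the null", {
  pvals <- withr::with_seed(31, {
    vapply(1:1000, function(i) {
      df <- tibble::tibble(y = rnorm(24), g = rep(c("a", "b", "c"), each = 8))
      tidy(oneway_anova(df, "y", "g"))$p.value
    }, numeric(1))
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  withr::with_seed(41, {
    df <- tibble::tibble(y = rnorm(14, rep(c(0, 1), each = 7)),
                         g = rep(c("a", "b"), each = 7))
  })
  tk <- tukey_hsd(df, "y", "g")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(nrow(tk), 1)
  expect_equal(tk$adj.p.value, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey HSD separates distinct groups and not identical ones", {
  withr::with_seed(42, {
    sep <- tibble::tibble(
      y = c(rnorm(10, 0, 0.5), rnorm(10, 5, 0.5), rnorm(10, 10, 0.5)),
      g = rep(c("a", "b", "c"), each = 10)
    )
  })
  tk <- tukey_hsd(sep, "y", "g")
  expect_equal(nrow(tk), 3) # every unordered pair once
  expect_true(all(tk$adj.p.value < 0.05))

  same <- tibble::tibble(y = rep(c(1, 2, 3), 3),
                         g = rep(c("a", "b", "c"), each = 3))
  expect_true(all(tukey_hsd(same, "y", "g")$adj.p.value > 0.999))

  # Tukey adjusted p is never below the unadjusted pairwise comparison
  # computed with the same pooled within-group mean square
  withr::with_seed(43, {
    df <- tibble::tibble(y = rnorm(30, rep(c(0, 0.5, 1), each = 10)),
                         g = rep(c("a", "b", "c"), each = 10))
  })
  tk <- tukey_hsd(df, "y", "g")
  ms_w <- sum(tapply(df$y, df$g, function(v) sum((v - mean(v))^2))) / 27
  for (i in seq_len(nrow(tk))) {
    se <- sqrt(ms_w * (1 / 10 + 1 / 10))
    praw <- 2 * pt(-abs(tk$estimate[i]) / se, df = 27)
    expect_gte(tk$adj.p.value[i] + 1e-12, praw)
  }
})

make_profiles <- function(n_per_group, mixes, seed, sds = NULL) {
  # mixes: named list group -> c(correct, not_verb, unrelated, missing)
  if (is.null(sds)) sds <- rep(4, 4)
  withr::with_seed(seed, {
    purrr::imap_dfr(mixes, function(mix, g) {
      raw <- matrix(pmax(rnorm(n_per_group * 4, rep(mix, each = n_per_group),
                               rep(sds, each = n_per_group)), 0),
                    ncol = 4)
      raw <- 100 * raw / rowSums(raw)
      tibble::tibble(
        subject_id = sprintf("%s%02d", g, seq_len(n_per_group)),
        group = g,
        pct_correct = raw[, 1], pct_not_verb = raw[, 2],
        pct_unrelated_verb = raw[, 3], pct_missing = raw[, 4]
      )
    })
  })
}

test_that("group-by-errortype ANOVA detects variant-specific patterns", {
  # identical error mixes: interaction well above 0.05
  null_mix <- list(lvPPA = c(60, 20, 10, 10), svPPA = c(60, 20, 10, 10),
                   nfvPPA = c(60, 20, 10, 10))
  res0 <- group_by_errortype_anova(make_profiles(20, null_mix, seed = 51))
  eff0 <- tidy(res0)
  expect_gt(eff0$p.value[eff0$term == "group:error_type"], 0.05)

  # published variant profiles at n = 20/group: strong interaction
  alt_mix <- list(lvPPA = c(45.1, 37.9, 3.9, 13.1),
                  svPPA = c(63.9, 17.3, 7.6, 11.2),
                  nfvPPA = c(79.2, 7.8, 2.1, 10.9))
  res1 <- group_by_errortype_anova(
    make_profiles(20, alt_mix, seed = 52, sds = c(10, 8, 3, 5))
  )
  eff1 <- tidy(res1)
  expect_lt(eff1$p.value[eff1$term == "group:error_type"], 0.001)
  expect_setequal(eff1$term, c("group", "error_type", "group:error_type"))

  # a single group degenerates to a within-subject one-way design
  res2 <- group_by_errortype_anova(
    make_profiles(10, alt_mix["lvPPA"], seed = 53)
  )
  expect_equal(tidy(res2)$term, "error_type")
})

test_that("subjects with missing error percentages are excluded with warning", {
  profs <- make_profiles(6, list(lvPPA = c(60, 20, 10, 10),
                                 svPPA = c(70, 15, 5, 10),
                                 nfvPPA = c(80, 10, 5, 5)), seed = 54)
  profs$pct_missing[3] <- NA
  expect_warning(res <- group_by_errortype_anova(profs), "excluding 1")
  expect_equal(dplyr::n_distinct(res$data$subject_id), 17)
})

test_that("by-item correlations recover planted effects with Bonferroni", {
  withr::with_seed(61, {
    n <- 40
    norms <- tibble::tibble(
      noun = sprintf("n%02d", 1:n),
      freq_log = runif(n, 3.4, 8.3),
      n_phonemes = sample(2:6, n, replace = TRUE),
      semantic_neighborhood = runif(n, 30, 360)
    )
    agreement <- tibble::tibble(
      noun = norms$noun,
      asi = runif(n, 30, 95), csi = runif(n, 1, 20),
      entropy = runif(n, 0.1, 2.7)
    )
    acc <- tibble::tibble(
      noun = norms$noun,
      # perfectly linear in freq_log; independent of everything else
      pct_correct = 10 * norms$freq_log
    )
  })
  ct <- by_item_correlations(acc, norms, agreement)
  expect_equal(nrow(ct), 6)
  expect_equal(ct$m, rep(6, 6))
  freq_row <- ct[ct$predictor == "freq_log", ]
  expect_equal(freq_row$r, 1)
  expect_true(freq_row$survives)
  # Bonferroni arithmetic and the survives rule
  expect_equal(ct$adj.p.value, pmin(1, 6 * ct$p.value))
  expect_equal(ct$survives, ct$adj.p.value < 0.05)
  # independent predictors do not survive
  expect_false(any(ct$survives[ct$predictor %in%
                                 c("n_phonemes", "semantic_neighborhood")]))
})

test_that("a planted frequency effect in svPPA yields a positive item r", {
  cfg <- generator_config(n_nouns = 50, n_controls = 10, seed = 62)
  stim <- generate_stimuli(cfg)
  spec <- default_cohort_specs()$svPPA
  spec$n_subjects <- 28
  sv <- generate_patient_cohort(spec, stim, cfg, seed = 63)
  acc <- item_accuracy(sv)
  hc <- generate_hc_responses(stim, cfg, seed = 64)
  ct <- by_item_correlations(acc, stimulus_norms(stim),
                             agreement_profiles(hc))
  r <- ct$r[ct$predictor == "freq_log"]
  expect_gt(r, 0.2)
  # and a zero-effect cohort shows no such association
  spec0 <- spec
  spec0$frequency_effect <- 0
  sv0 <- generate_patient_cohort(spec0, stim, cfg, seed = 65)
  ct0 <- by_item_correlations(item_accuracy(sv0), stimulus_norms(stim),
                              agreement_profiles(hc))
  expect_lt(abs(ct0$r[ct0$predictor == "freq_log"]), 0.5)
  expect_false(ct0$survives[ct0$predictor == "freq_log"])
})

test_that("by-subject correlations use the fluency ratio pairwise-complete", {
  profs <- tibble::tibble(
    subject_id = sprintf("p%02d", 1:12),
    pct_correct = seq(20, 86, length.out = 12)
  )
  subj <- tibble::tibble(
    subject_id = profs$subject_id,
    group = "svPPA",
    ppvt = profs$pct_correct / 5, # perfectly collinear
    phonemic_fluency = rep(10, 12),
    semantic_fluency = rep(c(10, 0), 6), # zero denominators excluded
    trails_time = 100 - profs$pct_correct # perfectly anti-correlated
  )
  subj$trails_time[1:2] <- NA # pairwise-complete handling
  ct <- by_subject_correlations(profs, subj)
  expect_equal(nrow(ct), 3)
  expect_equal(ct$m, rep(3, 3))
  expect_equal(ct$r[ct$predictor == "ppvt"], 1)
  expect_equal(ct$r[ct$predictor == "trails_time"], -1)
  expect_equal(ct$n[ct$predictor == "trails_time"], 10)
  expect_equal(ct$n[ct$predictor == "fluency_ratio"], 6)
})

test_that("planted anti-correlated trails times are recovered from the
           generator", {
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:30),
    group = rep(c("lvPPA", "svPPA", "nfvPPA"), each = 10)
  )
  acc <- withr::with_seed(71, runif(30, 20, 90))
  gen <- generate_subjects(subjects, seed = 72, accuracy = acc,
                           trails_coupling = -3)
  profs <- tibble::tibble(subject_id = subjects$subject_id, pct_correct = acc)
  ct <- by_subject_correlations(profs, gen)
  expect_lt(ct$r[ct$predictor == "trails_time"], -0.5)
})

test_that("item accuracy pools subjects and presentations", {
  tr <- make_trials(
    subject_id = rep(c("a", "b"), each = 4),
    group = "svPPA",
    noun = rep(c("n1", "n1", "n2", "n2"), 2),
    presentation = rep(c(1L, 2L), 4),
    response_raw = "x",
    response_code = c("related_verb", "related_verb", "missing",
                      "related_verb", "not_a_verb", "related_verb",
                      "related_verb", "related_verb")
  )
  acc <- item_accuracy(tr)
  expect_equal(acc$pct_correct[acc$noun == "n1"], 75)
  expect_equal(acc$pct_correct[acc$noun == "n2"], 75)
  acc1 <- item_accuracy(tr, presentations = 1L)
  expect_equal(acc1$pct_correct[acc1$noun == "n1"], 50)
})
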