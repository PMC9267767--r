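test_that("auto-coder applies the four-way taxonomy with exceptions", {
  rules <- toy_rules()
  tr <- make_trials(
    subject_id = "s1", group = "svPPA",
    noun = c("ball", "ball", "ball", "ball", "knife", "laundry", "house"),
    presentation = c(1L, 2L, 3L, 4L, 1L, 1L, 1L),
    response_raw = c("throw", "baseball", "eat", "", "to be careful",
                     "to do", "to go in")
  )
  coded <- code_responses(tr, rules)
  expect_equal(
    coded$response_code,
    c("related_verb", "not_a_verb", "unrelated_verb", "missing",
      "unrelated_verb", "related_verb", "unrelated_verb")
  )
  expect_equal(coded$response_lemma[1:3], c("throw", "baseball", "eat"))
  expect_true(is.na(coded$response_lemma[4]))
})

test_that("phrasal responses match on their head verb", {
  rules <- toy_rules()
  tr <- make_trials("s1", "HC", "trash", 1, "take out")
  expect_equal(code_responses(tr, rules)$response_code, "related_verb")
  expect_equal(code_responses(tr, rules)$response_lemma, "take")
  # inflected head: "took away" lemmatizes to "take"
  tr2 <- make_trials("s1", "HC", "trash", 1, "took away")
  expect_equal(code_responses(tr2, rules)$response_code, "related_verb")
  # with phrasal matching off, the full phrase must match verbatim
  rules_np <- coding_rules(toy_lexicon(), accept_phrasal = FALSE)
  expect_equal(code_responses(tr, rules_np)$response_code, "not_a_verb")
})

test_that("pre-assigned codes are never overwritten and coding is idempotent", {
  rules <- toy_rules()
  tr <- make_trials("s1", "HC", "ball", 1, "throw",
                    response_code = "missing", response_lemma = NA)
  coded <- code_responses(tr, rules)
  expect_equal(coded$response_code, "missing")
  tr2 <- make_trials("s1", "HC", c("ball", "ball"), c(1, 2),
                     c("throw", "baseball"))
  once <- code_responses(tr2, rules)
  twice <- code_responses(once, rules)
  expect_identical(once, twice)
})

test_that("coding a noun absent from the lexicon is a configuration error", {
  tr <- make_trials("s1", "HC", "comet", 1, "fly")
  expect_error(code_responses(tr, toy_rules()), "comet",
               class = "verbgen_config_error")
})

test_that("rejected and accepted exception sets must be disjoint", {
  expect_error(
    coding_rules(
      toy_lexicon(),
      rejected_phrases = tibble::tibble(noun = "house", phrase = "to go in"),
      accepted_exceptions = tibble::tibble(noun = "house", phrase = "to go in")
    ),
    class = "verbgen_config_error"
  )
})

test_that("subject profiles compute percentages and consistency", {
  codes <- rep("related_verb", 100)
  codes[1:55] <- c(rep("not_a_verb", 25), rep("unrelated_verb", 15),
                   rep("missing", 15))
  tr <- coded_subject(codes = sample(codes))
  prof <- subject_profiles(tr)
  expect_equal(prof$pct_correct, 45)
  expect_equal(prof$pct_correct + prof$pct_not_verb +
                 prof$pct_unrelated_verb + prof$pct_missing, 100)

  # 50 pairs; 10 both-wrong, 7 of those with matching error type
  codes <- rep("related_verb", 100)
  pair_codes <- c(
    rep(list(c("not_a_verb", "not_a_verb")), 7),
    rep(list(c("not_a_verb", "missing")), 3)
  )
  for (i in seq_along(pair_codes)) {
    codes[(2 * i - 1):(2 * i)] <- pair_codes[[i]]
  }
  prof <- subject_profiles(coded_subject(codes = codes))
  expect_equal(prof$pct_error_consistency, 20)
  expect_equal(prof$pct_error_type_consistency, 70)

  # no consistently-erred pairs: type consistency undefined
  codes <- rep(c("not_a_verb", "related_verb"), 50)
  prof <- subject_profiles(coded_subject(codes = codes))
  expect_equal(prof$pct_error_consistency, 0)
  expect_true(is.na(prof$pct_error_type_consistency))
})

test_that("percentage closure holds for random coded subjects", {
  withr::with_seed(11, {
    for (i in 1:20) {
      codes <- sample(c("related_verb", "not_a_verb", "unrelated_verb",
                        "missing"), 100, replace = TRUE)
      prof <- subject_profiles(coded_subject(id = paste0("s", i),
                                             codes = codes))
      total <- prof$pct_correct + prof$pct_not_verb +
        prof$pct_unrelated_verb + prof$pct_missing
      expect_equal(total, 100, tolerance = 1e-12)
    }
  })
})

test_that("mean RT defaults to correct trials only", {
  tr <- make_trials(
    "s1", "HC", c("a", "a", "b", "b"), c(1, 2, 1, 2),
    c("x", "y", "z", ""),
    response_code = c("related_verb", "not_a_verb", "related_verb",
                      "missing"),
    response_lemma = c("x", "y", "z", NA),
    rt_s = c(1, 10, 3, NA)
  )
  expect_equal(subject_profiles(tr)$mean_rt_s, 2)
  expect_equal(subject_profiles(tr, rt_trials = "all")$mean_rt_s, 14 / 3)
})

test_that("uncoded trials cannot be profiled", {
  tr <- make_trials("s1", "HC", "ball", 1, "throw")
  expect_error(subject_profiles(tr), class = "verbgen_state_error")
})

test_that("outlier exclusion is strict, single-pass and handles zero SD", {
  # a low scorer well over 2 cohort SDs below the mean is excluded
  vals <- c(rep(84, 5), rep(76, 5), 80, 65)
  profs <- tibble::tibble(
    subject_id = sprintf("p%02d", seq_along(vals)),
    group = "svPPA", pct_correct = vals
  )
  m <- mean(vals)
  s <- sd(vals)
  expect_gt(abs(65 - m), 2 * s) # fixture sanity
  rep_pg <- exclude_outliers(profs, mode = "per_group")
  expect_setequal(
    rep_pg$excluded$subject_id,
    profs$subject_id[abs(vals - m) > 2 * s]
  )
  expect_equal(rep_pg$excluded$subject_id, "p12")

  # boundary: exclusion needs strictly more than 2 SD, so a subject just
  # inside the band stays and one just outside goes (the band itself moves
  # only second-order under the nudge)
  base <- c(rep(80, 5), 90)
  boundary <- uniroot(function(v) {
    vv <- c(base, v)
    (mean(vv) - 2 * sd(vv)) - v
  }, c(0, 79), tol = 1e-12)$root
  for (nudge in c(0.05, -0.05)) {
    b <- tibble::tibble(subject_id = letters[1:7], group = "HC",
                        pct_correct = c(base, boundary + nudge))
    rep_b <- exclude_outliers(b, mode = "per_group")
    if (nudge > 0) {
      expect_true("g" %in% rep_b$kept)
    } else {
      expect_true("g" %in% rep_b$excluded$subject_id)
    }
  }

  # near-degenerate cohort: an otherwise constant cohort still excludes its
  # single deviator (cohort SD comes almost entirely from that subject)
  z <- tibble::tibble(subject_id = letters[1:10], group = "HC",
                      pct_correct = c(rep(90, 9), 89))
  expect_equal(exclude_outliers(z, mode = "per_group")$excluded$subject_id,
               "j")
})

test_that("default mode pools patients and references HC separately", {
  profs <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:12),
    group = c(rep("HC", 4), rep("lvPPA", 4), rep("svPPA", 4)),
    pct_correct = c(95, 94, 96, 60, 50, 55, 45, 5, 70, 65, 60, 75)
  )
  rep <- exclude_outliers(profs)
  expect_setequal(rep$cohorts$cohort, c("HC", "patients"))
  pat <- profs$pct_correct[5:12]
  expected_pat <- profs$subject_id[5:12][
    abs(pat - mean(pat)) > 2 * sd(pat)
  ]
  hc <- profs$pct_correct[1:4]
  expected_hc <- profs$subject_id[1:4][abs(hc - mean(hc)) > 2 * sd(hc)]
  expect_setequal(rep$excluded$subject_id, c(expected_pat, expected_hc))
  expect_length(intersect(rep$kept, rep$excluded$subject_id), 0)
  expect_equal(nrow(glance(rep)), 1)
  expect_equal(sum(tidy(rep)$excluded), nrow(rep$excluded))
})

test_that("planted extremes in a synthetic cohort are exactly the exclusions", {
  cfg <- generator_config(n_nouns = 20, n_controls = 12, seed = 202)
  stim <- generate_stimuli(cfg)
  hc <- generate_hc_responses(stim, cfg)
  profs <- subject_profiles(hc)
  # plant two extreme subjects far outside the control band
  planted <- tibble::tibble(
    subject_id = c("lowA", "lowB"), group = "HC",
    n_trials = 40L, n_pairs = 20L,
    pct_correct = c(20, 25), pct_not_verb = c(40, 35),
    pct_unrelated_verb = c(20, 20), pct_missing = c(20, 20),
    pct_error_consistency = 50, pct_error_type_consistency = 50,
    mean_rt_s = 2
  )
  all_profs <- dplyr::bind_rows(profs, planted)
  report <- exclude_outliers(all_profs, mode = "per_group")
  m <- mean(all_profs$pct_correct)
  s <- sd(all_profs$pct_correct)
  recomputed <- all_profs$subject_id[abs(all_profs$pct_correct - m) > 2 * s]
  expect_setequal(report$excluded$subject_id, recomputed)
  expect_setequal(report$excluded$subject_id, c("lowA", "lowB"))
})
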