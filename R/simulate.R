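#' Configuration for the synthetic study generator
#'
#' Defaults emulate a typical auditory verb generation study: 50 nouns
#' presented twice to 29 controls, with control verb-choice distributions
#' whose response entropies span roughly 0.1 to 2.7 bits.
#'
#' @param n_nouns Number of stimulus nouns (default 50).
#' @param presentations Presentations per noun (default 2).
#' @param n_controls Number of control subjects (default 29).
#' @param agreement_range Target span of per-noun response entropy, in bits
#'   (default `c(0.1, 2.7)`).
#' @param n_verbs_per_noun Size of each noun's latent verb inventory
#'   (default 10).
#' @param hc_missing_rate Probability a control trial is missing
#'   (default 0.02).
#' @param hc_rt_mean,hc_rt_sd Control reaction-time mean and SD in seconds.
#' @param embedding_dim Dimension of generated embedding vectors (default 50).
#' @param seed Integer seed; mandatory, every stochastic call is a pure
#'   function of (config, seed).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_nouns = 50, presentations = 2,
                             n_controls = 29,
                             agreement_range = c(0.1, 2.7),
                             n_verbs_per_noun = 10,
                             hc_missing_rate = 0.02,
                             hc_rt_mean = 1.5, hc_rt_sd = 0.35,
                             embedding_dim = 50, seed) {
  stopifnot(
    n_nouns >= 1, presentations %in% 1:2, n_controls >= 1,
    length(agreement_range) == 2, agreement_range[1] >= 0,
    agreement_range[2] <= log2(n_verbs_per_noun),
    hc_missing_rate >= 0, hc_missing_rate < 1,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      n_nouns = n_nouns, presentations = presentations,
      n_controls = n_controls, agreement_range = agreement_range,
      n_verbs_per_noun = n_verbs_per_noun,
      hc_missing_rate = hc_missing_rate,
      hc_rt_mean = hc_rt_mean, hc_rt_sd = hc_rt_sd,
      embedding_dim = embedding_dim, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Specification of one synthetic patient cohort
#'
#' `error_mix` and `error_sd` give the cohort mean and SD of the four response
#' percentages (correct, not-a-verb, unrelated verb, missing); per-subject
#' mixes are drawn truncated-normal and renormalized to 100.
#'
#' @param group Diagnostic label (`"lvPPA"`, `"svPPA"` or `"nfvPPA"`).
#' @param n_subjects Cohort size.
#' @param error_mix,error_sd Length-4 numeric vectors (percent): correct,
#'   not-a-verb, unrelated verb, missing. Means must sum to 100.
#' @param dispersion Verb-choice spread: related responses are drawn from the
#'   noun's popularity vector raised to `1 / dispersion` (1 = control-like;
#'   larger = flatter, more unique verbs).
#' @param light_verb_rate Probability a related response is replaced by a
#'   light verb.
#' @param repetition_rate Probability a not-a-verb response repeats the
#'   stimulus noun.
#' @param related_noun_rate Probability a non-repetition not-a-verb response
#'   is a semantically related noun (planted near the stimulus in the
#'   embedding space).
#' @param frequency_effect Logistic slope tying item-level correctness to the
#'   noun's (centered) log frequency.
#' @param rt_mean,rt_sd Reaction-time mean and SD in seconds.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group, n_subjects, error_mix, error_sd,
                        dispersion = 1, light_verb_rate = 0.02,
                        repetition_rate = 0.25, related_noun_rate = 0.3,
                        frequency_effect = 0, rt_mean = 2, rt_sd = 0.5) {
  stopifnot(
    length(error_mix) == 4, length(error_sd) == 4,
    abs(sum(error_mix) - 100) < 1e-6, all(error_sd >= 0),
    dispersion > 0,
    light_verb_rate >= 0, light_verb_rate <= 1,
    repetition_rate >= 0, repetition_rate <= 1,
    related_noun_rate >= 0, related_noun_rate <= 1
  )
  structure(
    list(
      group = group, n_subjects = n_subjects,
      error_mix = setNames(
        error_mix, c("correct", "not_verb", "unrelated_verb", "missing")
      ),
      error_sd = setNames(
        error_sd, c("correct", "not_verb", "unrelated_verb", "missing")
      ),
      dispersion = dispersion, light_verb_rate = light_verb_rate,
      repetition_rate = repetition_rate,
      related_noun_rate = related_noun_rate,
      frequency_effect = frequency_effect,
      rt_mean = rt_mean, rt_sd = rt_sd
    ),
    class = "cohort_spec"
  )
}

#' Default synthetic patient cohorts
#'
#' Error-mix means/SDs, cohort sizes and reaction times follow the published
#' variant profiles for analyzed cohorts (lvPPA n 19: 45.1/37.9/3.9/13.1;
#' svPPA n 28: 63.9/17.3/7.6/11.3; nfvPPA n 24: 79.2/7.8/2.1/11.0, with the
#' error-mix remainder assigned so means close to 100). Structural knobs
#' mirror the reported contrasts: svPPA gets the widest verb dispersion and
#' highest light-verb rate; lvPPA the highest semantically-related-noun rate;
#' only svPPA a frequency effect.
#'
#' @return Named list of three `cohort_spec`s.
#' @export
default_cohort_specs <- function() {
  list(
    lvPPA = cohort_spec(
      "lvPPA", 19,
      error_mix = c(45.1, 37.9, 3.9, 13.1),
      error_sd = c(23.1, 21.2, 3.0, 12.0),
      dispersion = 1.0, light_verb_rate = 0.019,
      repetition_rate = 0.25, related_noun_rate = 0.5,
      frequency_effect = 0, rt_mean = 2.20, rt_sd = 0.47
    ),
    svPPA = cohort_spec(
      "svPPA", 28,
      error_mix = c(63.9, 17.3, 7.6, 11.2),
      error_sd = c(22.8, 19.6, 7.0, 9.9),
      dispersion = 2.0, light_verb_rate = 0.087,
      repetition_rate = 0.25, related_noun_rate = 0.25,
      frequency_effect = 0.12, rt_mean = 2.03, rt_sd = 0.59
    ),
    nfvPPA = cohort_spec(
      "nfvPPA", 24,
      error_mix = c(79.2, 7.8, 2.1, 10.9),
      error_sd = c(15.2, 7.9, 2.5, 12.4),
      dispersion = 0.8, light_verb_rate = 0.023,
      repetition_rate = 0.25, related_noun_rate = 0.25,
      frequency_effect = 0, rt_mean = 1.86, rt_sd = 0.40
    )
  )
}

# Entropy (bits) of a truncated-geometric popularity vector with ratio q.
vg_geom_entropy <- function(q, k) {
  p <- q^(0:(k - 1))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Invert entropy -> decay ratio q on (0, 1] for a k-verb inventory.
vg_decay_for_entropy <- function(target, k) {
  if (target <= 1e-9) return(1e-9)
  hi <- log2(k)
  if (target >= hi - 1e-9) return(1)
  uniroot(
    function(q) vg_geom_entropy(q, k) - target,
    interval = c(1e-9, 1), tol = 1e-10
  )$root
}

#' Generate synthetic stimuli with norms and latent verb popularity
#'
#' Draws per-noun psycholinguistic norms uniformly within the ranges typical
#' of verb-generation stimulus sets (letters 3-8, syllables 1-2, phonemes
#' 2-6, log frequency 3.4-8.3, semantic neighborhood 28.7-362.9,
#' concreteness 3.78-6.88, familiarity 4.49-6.94, imageability 3.81-6.92,
#' age of acquisition 1.49-4.17), and assigns each noun a latent verb
#' popularity vector: a truncated geometric whose decay is solved so the
#' implied response entropy is uniform over `cfg$agreement_range`.
#'
#' @param cfg A [generator_config()].
#' @param seed Seed (default `cfg$seed`).
#' @return A tibble with `noun`, the norm columns, `target_entropy`, and a
#'   `popularity` list-column of named probability vectors.
#' @export
generate_stimuli <- function(cfg, seed = cfg$seed) {
  n <- cfg$n_nouns
  k <- cfg$n_verbs_per_noun
  withr::with_seed(seed, {
    noun <- sprintf("noun%02d", seq_len(n))
    target_entropy <- runif(n, cfg$agreement_range[1], cfg$agreement_range[2])
    popularity <- lapply(seq_len(n), function(i) {
      q <- vg_decay_for_entropy(target_entropy[i], k)
      p <- q^(0:(k - 1))
      setNames(p / sum(p), sprintf("%s_v%02d", noun[i], seq_len(k)))
    })
    tibble(
      noun = noun,
      n_letters = sample(3:8, n, replace = TRUE),
      n_syllables = sample(1:2, n, replace = TRUE),
      n_phonemes = sample(2:6, n, replace = TRUE),
      freq_log = runif(n, 3.4, 8.3),
      semantic_neighborhood = runif(n, 28.7, 362.9),
      concreteness = runif(n, 3.78, 6.88),
      familiarity = runif(n, 4.49, 6.94),
      imageability = runif(n, 3.81, 6.92),
      age_of_acquisition = runif(n, 1.49, 4.17),
      target_entropy = target_entropy,
      popularity = popularity
    )
  })
}

#' Drop generator-internal columns, keeping the norms table
#' @param stimuli Output of [generate_stimuli()].
#' @return A norms tibble suitable for [write_stimulus_norms()].
#' @export
stimulus_norms <- function(stimuli) {
  select(stimuli, -dplyr::any_of(c("target_entropy", "popularity")))
}

vg_rlnorm <- function(n, mean, sd) {
  sigma2 <- log(1 + sd^2 / mean^2)
  rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate coded control trials
#'
#' Each control samples a verb per presentation from the noun's latent
#' popularity vector; a small configurable fraction of trials is missing.
#' Output trials arrive already coded (`related_verb` / `missing`).
#'
#' @param stimuli Output of [generate_stimuli()].
#' @param cfg A [generator_config()].
#' @param seed Seed (default `cfg$seed + 1`).
#' @return A coded trial tibble.
#' @export
generate_hc_responses <- function(stimuli, cfg, seed = cfg$seed + 1) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      subject_id = sprintf("hc%02d", seq_len(cfg$n_controls)),
      noun = stimuli$noun,
      presentation = seq_len(cfg$presentations)
    )
    pop <- setNames(stimuli$popularity, stimuli$noun)
    verb <- vapply(grid$noun, function(nn) {
      p <- pop[[nn]]
      sample(names(p), 1, prob = p)
    }, character(1), USE.NAMES = FALSE)
    missing <- runif(nrow(grid)) < cfg$hc_missing_rate
    grid %>%
      mutate(
        group = "HC",
        response_raw = dplyr::if_else(missing, "", verb),
        response_code = dplyr::if_else(missing, "missing", "related_verb"),
        response_lemma = dplyr::if_else(missing, NA_character_, verb),
        rt_s = dplyr::if_else(
          missing, NA_real_,
          vg_rlnorm(nrow(grid), cfg$hc_rt_mean, cfg$hc_rt_sd)
        )
      ) %>%
      select(
        "subject_id", "group", "noun", "presentation",
        "response_raw", "response_code", "response_lemma", "rt_s"
      )
  })
}

# Location parameter of a normal truncated at zero whose post-truncation
# mean equals `target` — keeps the realized cohort moments at the planted
# values instead of letting the truncation inflate small error components.
vg_tn_location <- function(target, sd) {
  if (sd == 0 || target <= 0) return(target)
  tn_mean <- function(mu) mu + sd * stats::dnorm(mu / sd) / pnorm(mu / sd)
  if (tn_mean(target) <= target + 1e-12) return(target)
  uniroot(function(mu) tn_mean(mu) - target,
          interval = c(target - 10 * sd, target), tol = 1e-9)$root
}

# One subject's error mix: truncated normal matching the cohort moments,
# renormalized to sum 100. Bounded resampling, then clamping, keeps
# degenerate parameter choices safe.
vg_draw_mix <- function(means, sds, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    x <- rnorm(4, means, sds)
    if (all(x >= 0)) return(100 * x / sum(x))
  }
  x <- pmax(rnorm(4, means, sds), 0)
  if (sum(x) == 0) x <- means
  100 * x / sum(x)
}

#' Generate one coded synthetic patient cohort
#'
#' Per subject, an error-mix vector is drawn around the cohort profile; trial
#' outcomes are then assigned by that mix, with item-level correctness
#' modulated through a logistic link by `frequency_effect * (freq_log -
#' mean)`. Related responses are drawn from the noun's popularity vector
#' sharpened/flattened by the cohort `dispersion` and replaced by a random
#' light verb at `light_verb_rate`; not-a-verb responses are stimulus
#' repetitions, planted related nouns (`<noun>_rel`), or filler nouns;
#' unrelated-verb responses borrow a verb from a different noun's inventory.
#'
#' @param spec A [cohort_spec()].
#' @param stimuli Output of [generate_stimuli()].
#' @param cfg A [generator_config()].
#' @param seed Seed (mandatory; pass distinct seeds per cohort).
#' @return A coded trial tibble.
#' @export
generate_patient_cohort <- function(spec, stimuli, cfg, seed) {
  k <- cfg$n_verbs_per_noun
  n_fillers <- max(20, cfg$n_nouns)
  fillers <- sprintf("filler%02d", seq_len(n_fillers))
  pop <- setNames(stimuli$popularity, stimuli$noun)
  freq_c <- stimuli$freq_log - mean(stimuli$freq_log)
  names(freq_c) <- stimuli$noun
  light <- light_verbs()
  mix_loc <- mapply(vg_tn_location, spec$error_mix, spec$error_sd)

  withr::with_seed(seed, {
    rows <- lapply(seq_len(spec$n_subjects), function(s) {
      sid <- sprintf("%s%02d", tolower(spec$group), s)
      mix <- vg_draw_mix(mix_loc, spec$error_sd) / 100
      grid <- tidyr::expand_grid(
        noun = stimuli$noun, presentation = seq_len(cfg$presentations)
      )
      p0 <- min(max(mix[1], 0.01), 0.99)
      p_item <- unname(plogis(qlogis(p0) +
                                spec$frequency_effect * freq_c[grid$noun]))
      correct <- runif(nrow(grid)) < p_item
      err_w <- mix[2:4]
      if (sum(err_w) == 0) err_w <- c(0, 0, 1)
      outcome <- ifelse(
        correct, "related_verb",
        sample(c("not_a_verb", "unrelated_verb", "missing"),
               nrow(grid), replace = TRUE, prob = err_w)
      )
      response <- character(nrow(grid))
      for (i in seq_len(nrow(grid))) {
        nn <- grid$noun[i]
        response[i] <- switch(outcome[i],
          related_verb = {
            if (runif(1) < spec$light_verb_rate) {
              sample(light, 1)
            } else {
              p <- pop[[nn]]^(1 / spec$dispersion)
              sample(names(pop[[nn]]), 1, prob = p / sum(p))
            }
          },
          not_a_verb = {
            u <- runif(1)
            if (u < spec$repetition_rate) {
              nn
            } else if (runif(1) < spec$related_noun_rate) {
              paste0(nn, "_rel")
            } else {
              sample(fillers, 1)
            }
          },
          unrelated_verb = {
            other <- sample(setdiff(stimuli$noun, nn), 1)
            sample(names(pop[[other]]), 1)
          },
          missing = ""
        )
      }
      tibble(
        subject_id = sid, group = spec$group,
        noun = grid$noun, presentation = grid$presentation,
        response_raw = response,
        response_code = outcome,
        response_lemma = dplyr::if_else(response == "", NA_character_,
                                        response),
        rt_s = dplyr::if_else(
          outcome == "missing", NA_real_,
          vg_rlnorm(nrow(grid), spec$rt_mean, spec$rt_sd)
        )
      )
    })
    bind_rows(rows)
  })
}

#' Generate a toy word-embedding table with planted similarities
#'
#' Random unit vectors (so unplanted pairs concentrate near zero cosine in
#' high dimension); each planted pair `(a, b, s)` rebuilds `b` as
#' `s * a + sqrt(1 - s^2) * u` with `u` a unit vector orthogonal to `a`, so
#' the realized cosine equals the target up to floating-point error.
#'
#' @param vocab Character vector of words.
#' @param cfg A [generator_config()] (supplies `embedding_dim`).
#' @param planted_pairs Optional tibble with columns `word_a`, `word_b`,
#'   `target` in `[-1, 1]`. A pair listed twice with conflicting targets is a
#'   configuration error.
#' @param seed Seed (default `cfg$seed + 2`).
#' @return An `embedding_table`.
#' @export
generate_embeddings <- function(vocab, cfg, planted_pairs = NULL,
                                seed = cfg$seed + 2) {
  vocab <- unique(vg_norm_token(vocab))
  d <- cfg$embedding_dim
  if (!is.null(planted_pairs)) {
    planted_pairs <- as_tibble(planted_pairs)
    vg_assert_cols(planted_pairs, c("word_a", "word_b", "target"),
                   "planted_pairs")
    stopifnot(all(planted_pairs$target >= -1 & planted_pairs$target <= 1))
    key <- paste(
      pmin(planted_pairs$word_a, planted_pairs$word_b),
      pmax(planted_pairs$word_a, planted_pairs$word_b)
    )
    agg <- tapply(planted_pairs$target, key, function(v) length(unique(v)))
    if (any(agg > 1)) {
      abort("conflicting targets for a planted pair",
        class = "verbgen_config_error"
      )
    }
    planted_pairs <- planted_pairs[!duplicated(key), , drop = FALSE]
    missing_words <- setdiff(
      c(planted_pairs$word_a, planted_pairs$word_b), vocab
    )
    vocab <- c(vocab, missing_words)
  }
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(vocab) * d), nrow = length(vocab))
    m <- m / sqrt(rowSums(m^2))
    rownames(m) <- vocab
    if (!is.null(planted_pairs)) {
      for (i in seq_len(nrow(planted_pairs))) {
        a <- m[planted_pairs$word_a[i], ]
        s <- planted_pairs$target[i]
        u <- rnorm(d)
        u <- u - sum(u * a) * a
        u <- u / sqrt(sum(u^2))
        m[planted_pairs$word_b[i], ] <- s * a + sqrt(1 - s^2) * u
      }
    }
    structure(m, dimension = d, class = c("embedding_table", "matrix"))
  })
}

#' Generate per-subject neuropsychological covariates
#'
#' Draws the four scores used in by-subject correlations (single-word
#' comprehension `ppvt`, phonemic and semantic fluency, `trails_time`) from
#' group-typical normal distributions (PPA neuropsychological batteries;
#' semantic fluency truncated at 1 so the fluency ratio stays defined).
#' Optionally plants an association between trails time and task accuracy.
#'
#' @param subjects Tibble with `subject_id` and `group`.
#' @param seed Seed.
#' @param accuracy Optional numeric vector (same order as `subjects`) of
#'   per-subject percentage correct.
#' @param trails_coupling Slope (seconds per accuracy percentage point) added
#'   to `trails_time` as `trails_coupling * (accuracy - mean(accuracy))`;
#'   negative values plant the usual worse-performance-slower-trails pattern.
#' @return A tibble suitable for [by_subject_correlations()].
#' @export
generate_subjects <- function(subjects, seed, accuracy = NULL,
                              trails_coupling = 0) {
  params <- list(
    HC = list(ppvt = c(15.6, 0.5), phon = c(17.4, 5.3),
              sem = c(23.0, 4.4), trails = c(23.1, 11.3)),
    lvPPA = list(ppvt = c(14.2, 2.2), phon = c(8.4, 4.0),
                 sem = c(9.8, 6.4), trails = c(86.2, 37.0)),
    svPPA = list(ppvt = c(8.8, 4.2), phon = c(8.7, 4.2),
                 sem = c(9.3, 5.7), trails = c(46.0, 28.2)),
    nfvPPA = list(ppvt = c(15.1, 1.2), phon = c(7.0, 4.3),
                  sem = c(13.7, 6.0), trails = c(48.3, 27.2))
  )
  stopifnot(all(subjects$group %in% names(params)))
  if (!is.null(accuracy)) stopifnot(length(accuracy) == nrow(subjects))
  withr::with_seed(seed, {
    draw <- function(field) {
      vapply(subjects$group, function(g) {
        p <- params[[g]][[field]]
        rnorm(1, p[1], p[2])
      }, numeric(1), USE.NAMES = FALSE)
    }
    out <- tibble(
      subject_id = subjects$subject_id,
      group = subjects$group,
      ppvt = pmax(draw("ppvt"), 0),
      phonemic_fluency = pmax(draw("phon"), 0),
      semantic_fluency = pmax(draw("sem"), 1),
      trails_time = pmax(draw("trails"), 1)
    )
    if (!is.null(accuracy) && trails_coupling != 0) {
      out$trails_time <- pmax(
        out$trails_time + trails_coupling * (accuracy - mean(accuracy)), 1
      )
    }
    out
  })
}

#' Simulate a complete synthetic verb-generation study
#'
#' Runs every generator with seeds derived from `cfg$seed`: stimuli with
#' norms and latent popularity, coded control and patient trials, subject
#' covariates, and an embedding table over all noun-like tokens with each
#' `<noun>_rel` pair planted above the relatedness threshold and fillers left
#' unplanted.
#'
#' @param cfg A [generator_config()].
#' @param specs List of [cohort_spec()]s (default [default_cohort_specs()]).
#' @param related_similarity Planted cosine for `(noun, noun_rel)` pairs
#'   (default 0.6).
#' @return List with `trials`, `stimuli`, `norms`, `subjects`, `embeddings`,
#'   `lexicon`, `cfg`, `specs`.
#' @export
simulate_study <- function(cfg, specs = default_cohort_specs(),
                           related_similarity = 0.6) {
  stimuli <- generate_stimuli(cfg, seed = cfg$seed)
  hc <- generate_hc_responses(stimuli, cfg, seed = cfg$seed + 1)
  patients <- purrr::imap(
    specs,
    function(spec, i) {
      offset <- 10 + match(i, names(specs))
      generate_patient_cohort(spec, stimuli, cfg, seed = cfg$seed + offset)
    }
  )
  trials <- bind_rows(c(list(hc), unname(patients)))
  subj_tbl <- distinct(trials, .data$subject_id, .data$group)
  profiles_acc <- trials %>%
    group_by(.data$subject_id) %>%
    summarise(acc = 100 * mean(.data$response_code == "related_verb"),
              .groups = "drop")
  accuracy <- profiles_acc$acc[match(subj_tbl$subject_id,
                                     profiles_acc$subject_id)]
  subjects <- generate_subjects(subj_tbl, seed = cfg$seed + 20,
                                accuracy = accuracy, trails_coupling = -0.5)
  n_fillers <- max(20, cfg$n_nouns)
  vocab <- c(
    stimuli$noun, paste0(stimuli$noun, "_rel"),
    sprintf("filler%02d", seq_len(n_fillers))
  )
  planted <- tibble(
    word_a = stimuli$noun,
    word_b = paste0(stimuli$noun, "_rel"),
    target = related_similarity
  )
  embeddings <- generate_embeddings(vocab, cfg, planted_pairs = planted,
                                    seed = cfg$seed + 30)
  list(
    trials = trials, stimuli = stimuli, norms = stimulus_norms(stimuli),
    subjects = subjects, embeddings = embeddings,
    lexicon = reference_lexicon(hc), cfg = cfg, specs = specs
  )
}
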