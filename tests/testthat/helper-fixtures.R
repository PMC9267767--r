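# Shared in-code fixtures: trial tables, a toy lexicon and embeddings.

make_trials <- function(subject_id, group, noun, presentation, response_raw,
                        response_code = NA_character_,
                        response_lemma = NA_character_, rt_s = NA_real_) {
  tibble::tibble(
    subject_id = subject_id, group = group, noun = noun,
    presentation = as.integer(presentation), response_raw = response_raw,
    response_code = response_code, response_lemma = response_lemma,
    rt_s = rt_s
  )
}

# One subject's coded trials over `n_nouns` nouns x 2 presentations with the
# given codes (recycled).
coded_subject <- function(id = "s1", group = "svPPA", codes,
                          n_nouns = length(codes) / 2, rt = 2) {
  stopifnot(length(codes) == 2 * n_nouns)
  nouns <- sprintf("n%03d", seq_len(n_nouns))
  make_trials(
    subject_id = id, group = group,
    noun = rep(nouns, each = 2), presentation = rep(1:2, n_nouns),
    response_raw = ifelse(codes == "missing", "", "resp"),
    response_code = codes,
    response_lemma = ifelse(codes == "missing", NA, "resp"),
    rt_s = ifelse(codes == "missing", NA, rt)
  )
}

toy_lexicon <- function() {
  list(
    ball = c("throw", "kick", "bounce"),
    trash = c("take", "throw", "empty"),
    knife = c("cut", "slice"),
    laundry = c("fold", "wash"),
    house = c("build", "live")
  )
}

toy_rules <- function(...) {
  coding_rules(
    toy_lexicon(),
    rejected_phrases = tibble::tibble(
      noun = c("knife", "house"),
      phrase = c("to be careful", "to go in")
    ),
    accepted_exceptions = tibble::tibble(noun = "laundry", phrase = "to do"),
    extra_verbs = c("eat", "sleep", "run"),
    ...
  )
}

# Embedding table with hand-set rows (named list word -> numeric vector).
toy_embeddings <- function(vectors) {
  m <- do.call(rbind, vectors)
  rownames(m) <- names(vectors)
  structure(m, dimension = ncol(m), class = c("embedding_table", "matrix"))
}

# Counts of every distribution over at most `max_k` verbs with per-verb
# counts 1..max_count (unordered, so nondecreasing sequences enumerate all).
all_count_distributions <- function(max_k = 5, max_count = 6) {
  out <- list()
  for (k in seq_len(max_k)) {
    grid <- do.call(expand.grid, rep(list(seq_len(max_count)), k))
    keep <- apply(grid, 1, function(r) all(diff(r) >= 0))
    rows <- grid[keep, , drop = FALSE]
    out <- c(out, lapply(seq_len(nrow(rows)), function(i) as.numeric(rows[i, ])))
  }
  out
}
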