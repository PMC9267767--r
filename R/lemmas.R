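#' The default light-verb list
#'
#' Fourteen semantically impoverished, high-frequency "light" verbs commonly
#' contrasted with specific "heavy" verbs in aphasia research.
#'
#' @return A character vector of lowercase verb lemmas.
#' @export
light_verbs <- function() {
  c(
    "be", "bring", "come", "do", "get", "give", "go", "have",
    "make", "move", "put", "see", "take", "use"
  )
}

# Bundled inflection lookup: surface form -> lemma. Covers the light-verb
# list exhaustively plus frequent task verbs; anything absent maps to itself.
# Deliberately a lookup, not a morphological analyzer.
vg_inflections <- local({
  irregular <- c(
    # be
    am = "be", is = "be", are = "be", was = "be", were = "be",
    been = "be", being = "be",
    bring = "bring", brings = "bring", bringing = "bring", brought = "bring",
    come = "come", comes = "come", coming = "come", came = "come",
    do = "do", does = "do", doing = "do", did = "do", done = "do",
    get = "get", gets = "get", getting = "get", got = "get", gotten = "get",
    give = "give", gives = "give", giving = "give", gave = "give",
    given = "give",
    go = "go", goes = "go", going = "go", went = "go", gone = "go",
    have = "have", has = "have", having = "have", had = "have",
    make = "make", makes = "make", making = "make", made = "make",
    move = "move", moves = "move", moving = "move", moved = "move",
    put = "put", puts = "put", putting = "put",
    see = "see", sees = "see", seeing = "see", saw = "see", seen = "see",
    take = "take", takes = "take", taking = "take", took = "take",
    taken = "take",
    use = "use", uses = "use", using = "use", used = "use",
    # frequent task verbs
    throw = "throw", throws = "throw", throwing = "throw", threw = "throw",
    thrown = "throw",
    eat = "eat", eats = "eat", eating = "eat", ate = "eat", eaten = "eat",
    drive = "drive", drives = "drive", driving = "drive", drove = "drive",
    driven = "drive",
    read = "read", reads = "read", reading = "read",
    write = "write", writes = "write", writing = "write", wrote = "write",
    written = "write",
    sleep = "sleep", sleeps = "sleep", sleeping = "sleep", slept = "sleep",
    run = "run", runs = "run", running = "run", ran = "run",
    fold = "fold", folds = "fold", folding = "fold", folded = "fold",
    spend = "spend", spends = "spend", spending = "spend", spent = "spend",
    kick = "kick", kicks = "kick", kicking = "kick", kicked = "kick",
    hit = "hit", hits = "hit", hitting = "hit",
    cut = "cut", cuts = "cut", cutting = "cut"
  )
  irregular
})

#' Reduce a verb surface form to its lemma
#'
#' Lookup against a bundled inflection table (exhaustive for the light-verb
#' list); forms not in the table are returned unchanged. No suffix stripping
#' or POS tagging is attempted.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param extra Optional named character vector of additional
#'   surface-form-to-lemma mappings; takes precedence over the bundled table.
#' @return Character vector of lemmas.
#' @export
lemmatize <- function(tokens, extra = NULL) {
  table <- vg_inflections
  if (!is.null(extra)) table <- c(extra, table)
  hit <- table[tokens]
  out <- ifelse(is.na(hit), tokens, hit)
  unname(out)
}

#' Extract the head-verb lemma of a (possibly phrasal) response
#'
#' Strips a leading infinitive marker ("to throw" -> "throw"), takes the
#' first remaining token as the head when phrasal responses are accepted
#' ("take out" -> "take"), and lemmatizes it. With `accept_phrasal = FALSE`
#' multi-word responses keep the full normalized phrase, so they can only
#' match the lexicon verbatim.
#'
#' @param responses Character vector of normalized responses.
#' @param accept_phrasal Match phrasal responses on their head verb?
#' @param extra Passed to [lemmatize()].
#' @return Character vector of head lemmas ("" for empty responses).
#' @export
head_lemma <- function(responses, accept_phrasal = TRUE, extra = NULL) {
  x <- vg_norm_token(responses)
  x <- stringr::str_remove(x, "^to\\s+")
  multi <- stringr::str_detect(x, "\\s")
  head_tok <- ifelse(
    multi & accept_phrasal,
    stringr::str_extract(x, "^\\S+"),
    x
  )
  ifelse(
    multi & !accept_phrasal,
    head_tok,
    lemmatize(head_tok, extra = extra)
  )
}
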