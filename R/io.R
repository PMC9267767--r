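#' Read a long-format trial table
#'
#' Reads one row per stimulus presentation with columns `subject_id`, `group`,
#' `noun`, `presentation`, `response_raw` and optionally `response_code`,
#' `response_lemma` and `rt_s`. Tokens (`noun`, `response_raw`) are case-folded
#' and whitespace-squished on ingest; internal spaces are kept so phrasal
#' verbs ("take out") survive. Empty response cells become `""` (they are
#' coded `missing` later, never at read time).
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter. `NULL` (default) auto-detects from the file
#'   extension: `.tsv` reads tab-separated, anything else comma-separated.
#'
#' @return A tibble of trials, one row per (subject, noun, presentation).
#' @export
read_trials <- function(path, delim = NULL) {
  delim <- delim %||% vg_guess_delim(path)
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  vg_assert_cols(
    raw, c("subject_id", "group", "noun", "presentation", "response_raw"),
    "trials file"
  )
  out <- tibble(
    subject_id = stringr::str_trim(raw$subject_id),
    group = stringr::str_trim(raw$group),
    noun = vg_norm_token(raw$noun),
    presentation = vg_parse_int(raw$presentation, "presentation"),
    response_raw = vg_norm_token(raw$response_raw),
    response_code = if ("response_code" %in% names(raw)) {
      dplyr::na_if(stringr::str_trim(raw$response_code), "")
    } else {
      NA_character_
    },
    response_lemma = if ("response_lemma" %in% names(raw)) {
      dplyr::na_if(vg_norm_token(raw$response_lemma), "")
    } else {
      NA_character_
    },
    rt_s = if ("rt_s" %in% names(raw)) {
      vg_parse_num(raw$rt_s, "rt_s")
    } else {
      NA_real_
    }
  )
  validate_trials(out)
}

#' Validate a trial table
#'
#' Checks group labels, presentation indices, response codes and the
#' uniqueness of the (subject, noun, presentation) key. Called by
#' [read_trials()]; exposed so programmatically built tables can be checked.
#'
#' @param trials A trial tibble as produced by [read_trials()].
#' @return `trials`, invisibly unchanged, or an error.
#' @export
validate_trials <- function(trials) {
  bad_group <- setdiff(unique(trials$group), VG_GROUPS)
  if (length(bad_group) > 0) {
    abort(
      sprintf("unknown group label(s): %s", paste(bad_group, collapse = ", ")),
      class = "verbgen_format_error"
    )
  }
  if (!all(trials$presentation %in% c(1L, 2L))) {
    abort("presentation must be 1 or 2", class = "verbgen_format_error")
  }
  bad_code <- setdiff(stats::na.omit(unique(trials$response_code)), VG_CODES)
  if (length(bad_code) > 0) {
    abort(
      sprintf("unknown response_code(s): %s", paste(bad_code, collapse = ", ")),
      class = "verbgen_format_error"
    )
  }
  key <- paste(trials$subject_id, trials$noun, trials$presentation, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(
      sprintf(
        "duplicate (subject, noun, presentation) triple: %s",
        gsub("\r", ", ", dup, fixed = TRUE)
      ),
      class = "verbgen_integrity_error"
    )
  }
  trials
}

#' Write a trial table
#'
#' Inverse of [read_trials()]: writing then re-reading reproduces every field
#' (text bit-identically, numerics to full double precision).
#'
#' @inheritParams read_trials
#' @param trials Trial tibble.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, delim = NULL) {
  delim <- delim %||% vg_guess_delim(path)
  readr::write_delim(trials, path, delim = delim, na = "")
  invisible(path)
}

#' Read per-noun psycholinguistic norms
#'
#' One row per noun; numeric columns (letter/syllable/phoneme counts,
#' log frequency, semantic neighborhood density, Glasgow-style rating scales)
#' are parsed as doubles, blank cells as `NA`.
#'
#' @param path Path to a CSV (or TSV) file with a `noun` column.
#' @inheritParams read_trials
#' @return A tibble keyed by `noun`.
#' @export
read_stimulus_norms <- function(path, delim = NULL) {
  delim <- delim %||% vg_guess_delim(path)
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  vg_assert_cols(raw, "noun", "norms file")
  out <- raw %>%
    mutate(noun = vg_norm_token(.data$noun)) %>%
    mutate(across(-"noun", ~ vg_parse_num(.x, dplyr::cur_column())))
  if (anyDuplicated(out$noun)) {
    abort(
      sprintf(
        "duplicate noun row(s) in norms file: %s",
        paste(unique(out$noun[duplicated(out$noun)]), collapse = ", ")
      ),
      class = "verbgen_integrity_error"
    )
  }
  out
}

#' Write per-noun psycholinguistic norms
#' @param norms Norms tibble with a `noun` column.
#' @inheritParams write_trials
#' @return `path`, invisibly.
#' @export
write_stimulus_norms <- function(norms, path, delim = NULL) {
  delim <- delim %||% vg_guess_delim(path)
  readr::write_delim(norms, path, delim = delim, na = "")
  invisible(path)
}

#' Read per-subject records
#'
#' One row per subject with `subject_id`, `group` and any neuropsychological
#' score columns (by-subject correlations expect `ppvt`, `phonemic_fluency`,
#' `semantic_fluency`, `trails_time`). Blank score cells become `NA`.
#'
#' @inheritParams read_stimulus_norms
#' @return A tibble keyed by `subject_id`.
#' @export
read_subjects <- function(path, delim = NULL) {
  delim <- delim %||% vg_guess_delim(path)
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  vg_assert_cols(raw, c("subject_id", "group"), "subjects file")
  out <- raw %>%
    mutate(
      subject_id = stringr::str_trim(.data$subject_id),
      group = stringr::str_trim(.data$group)
    ) %>%
    mutate(across(
      -c("subject_id", "group"),
      ~ vg_parse_num(.x, dplyr::cur_column())
    ))
  if (anyDuplicated(out$subject_id)) {
    abort("duplicate subject_id in subjects file",
      class = "verbgen_integrity_error"
    )
  }
  out
}

#' Write per-subject records
#' @param subjects Subjects tibble.
#' @inheritParams write_trials
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path, delim = NULL) {
  delim <- delim %||% vg_guess_delim(path)
  readr::write_delim(subjects, path, delim = delim, na = "")
  invisible(path)
}

#' Read a plain-text word-embedding table
#'
#' Expects the common "word then D whitespace-separated floats, one word per
#' line" format. All vectors must share one dimension; a duplicated word keeps
#' its first vector and emits a warning.
#'
#' @param path Path to the embedding text file.
#' @return An `embedding_table`: a numeric matrix with words as row names and
#'   a `dimension` attribute.
#' @export
read_embeddings <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    abort("embedding file is empty", class = "verbgen_format_error")
  }
  parts <- stringr::str_split(stringr::str_trim(lines), "\\s+")
  words <- vg_norm_token(vapply(parts, `[[`, character(1), 1))
  dims <- lengths(parts) - 1L
  dim0 <- dims[1]
  if (dim0 < 1) {
    abort("embedding line 1 has no vector components",
      class = "verbgen_format_error"
    )
  }
  bad <- which(dims != dim0)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "embedding line %d has %d components, expected %d",
        bad[1], dims[bad[1]], dim0
      ),
      class = "verbgen_format_error"
    )
  }
  vecs <- matrix(
    as.numeric(unlist(lapply(parts, `[`, -1))),
    ncol = dim0, byrow = TRUE
  )
  if (anyNA(vecs)) {
    abort("non-numeric vector component in embedding file",
      class = "verbgen_format_error"
    )
  }
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    warn(sprintf(
      "duplicate word(s) in embedding file, keeping first occurrence: %s",
      paste(dup, collapse = ", ")
    ))
    keep <- !duplicated(words)
    words <- words[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  rownames(vecs) <- words
  structure(vecs, dimension = dim0, class = c("embedding_table", "matrix"))
}

#' Write a plain-text word-embedding table
#' @param emb An `embedding_table` (or numeric matrix with row names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(is.matrix(emb), !is.null(rownames(emb)))
  lines <- vapply(
    seq_len(nrow(emb)),
    function(i) {
      paste(
        rownames(emb)[i],
        paste(format(emb[i, ], digits = 17, scientific = TRUE, trim = TRUE),
          collapse = " "
        )
      )
    },
    character(1)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

vg_guess_delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

vg_parse_int <- function(x, col) {
  out <- suppressWarnings(as.integer(x))
  if (any(!is.na(x) & nzchar(x) & is.na(out))) {
    abort(sprintf("non-integer value in column '%s'", col),
      class = "verbgen_format_error"
    )
  }
  out
}

vg_parse_num <- function(x, col) {
  blank <- is.na(x) | !nzchar(stringr::str_trim(x))
  out <- suppressWarnings(as.numeric(x))
  if (any(!blank & is.na(out))) {
    abort(sprintf("non-numeric value in column '%s'", col),
      class = "verbgen_format_error"
    )
  }
  out[blank] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
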