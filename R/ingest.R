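#' Parse coded property-listing transcripts
#'
#' Reads a delimited UTF-8 file of coded property-listing responses, one row
#' per listed property. Required columns: `participant_id`, `group`,
#' `concept`, `property_index`, `text`, `validity_tag`. Optional columns
#' `lemma_seq` and `pos_seq` (semicolon-joined) carry pre-tagged content
#' tokens and, when present, bypass the tagger in
#' [extract_content_tokens()].
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter (default `","`).
#' @return A tibble of property records, ordered as in the file, with one row
#'   per property and a `tokens` list-column (unpopulated until
#'   [extract_content_tokens()] is called, unless pre-tagged columns are
#'   present).
#' @export
parse_responses <- function(path, delim = ",") {
  if (!file.exists(path)) abort_schema(paste0("transcript file not found: ", path))
  df <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    locale = readr::locale(encoding = "UTF-8"),
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("participant_id", "group", "concept", "property_index", "text", "validity_tag")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort_schema(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  df$property_index <- as.integer(df$property_index)

  bad_group <- which(!df$group %in% GROUP_LEVELS)
  if (length(bad_group) > 0L) {
    abort_validation(paste0(
      "unknown group label(s) ", paste(unique(df$group[bad_group]), collapse = ", "),
      " in row(s): ", paste(head(bad_group, 20L), collapse = ", ")
    ))
  }
  bad_tag <- which(!df$validity_tag %in% VALIDITY_TAGS)
  if (length(bad_tag) > 0L) {
    abort_validation(paste0(
      "unknown validity_tag value(s) ", paste(unique(df$validity_tag[bad_tag]), collapse = ", "),
      " in row(s): ", paste(head(bad_tag, 20L), collapse = ", ")
    ))
  }

  # production order must be strictly increasing within (participant, concept)
  ord_ok <- df |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$participant_id, .data$concept) |>
    dplyr::summarise(ok = all(diff(.data$property_index) > 0), .groups = "drop")
  if (any(!ord_ok$ok)) {
    bad <- ord_ok[!ord_ok$ok, ]
    abort_validation(paste0(
      "property_index not strictly increasing for: ",
      paste(paste0(bad$participant_id, "/", bad$concept), collapse = ", ")
    ))
  }

  records <- tibble::as_tibble(df)
  records$tokens <- vector("list", nrow(records))
  if (all(c("lemma_seq", "pos_seq") %in% names(records))) {
    records$tokens <- parse_token_columns(records$lemma_seq, records$pos_seq)
  }
  records
}

# Parse semicolon-joined lemma/pos columns into token tibbles.
parse_token_columns <- function(lemma_seq, pos_seq) {
  lemma_seq[is.na(lemma_seq)] <- ""
  pos_seq[is.na(pos_seq)] <- ""
  lem <- strsplit(lemma_seq, ";", fixed = TRUE)
  pos <- strsplit(pos_seq, ";", fixed = TRUE)
  if (any(lengths(lem) != lengths(pos))) {
    abort_validation("lemma_seq and pos_seq lengths differ within a row")
  }
  bad <- setdiff(unique(unlist(pos, use.names = FALSE)), CONTENT_POS)
  if (length(bad) > 0L) {
    abort_validation(paste0("pos_seq contains non-content tag(s): ",
                            paste(bad, collapse = ", ")))
  }
  purrr::map2(lem, pos, function(l, p) {
    tibble::new_tibble(list(surface = l, lemma = fold_word(l), pos = p),
                       nrow = length(l))
  })
}

#' Serialize property records back to the transcript format
#'
#' Writes the canonical delimited schema; populated tokens are serialized into
#' the `lemma_seq`/`pos_seq` columns so that a write/parse round trip is the
#' identity.
#'
#' @param records Tibble from [parse_responses()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path, delim = ",") {
  out <- records
  out$lemma_seq <- purrr::map_chr(records$tokens, function(tk) {
    if (is.null(tk) || nrow(tk) == 0L) "" else paste(tk$lemma, collapse = ";")
  })
  out$pos_seq <- purrr::map_chr(records$tokens, function(tk) {
    if (is.null(tk) || nrow(tk) == 0L) "" else paste(tk$pos, collapse = ";")
  })
  out$tokens <- NULL
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Drop non-valid properties
#'
#' Removes records whose `validity_tag` is not `"valid"`: statements directed
#' to the examiner, personal life experiences, and metacognitive comments.
#' Repetitions and factually incorrect but on-task properties carry the tag
#' `"valid"` and are retained. Exclusion counts per tag are attached as the
#' `"exclusions"` attribute (see [exclusion_counts()]).
#'
#' @param records Tibble of property records.
#' @return Filtered tibble with an `"exclusions"` attribute (named integer
#'   vector over the three non-valid tags).
#' @export
filter_valid <- function(records) {
  excl_tags <- setdiff(VALIDITY_TAGS, "valid")
  counts <- vapply(excl_tags, function(tg) sum(records$validity_tag == tg), integer(1))
  out <- records[records$validity_tag == "valid", , drop = FALSE]
  attr(out, "exclusions") <- counts
  out
}

#' @rdname filter_valid
#' @export
exclusion_counts <- function(records) attr(records, "exclusions")

#' Isolate lemmatized content words
#'
#' Populates the `tokens` list-column of each record with its lemmatized
#' content words (nouns, verbs, adjectives, adverbs) in surface order;
#' function words are dropped. Rows whose tokens were already populated from
#' pre-tagged columns pass through untouched. The tagger is pluggable: any
#' function mapping a character vector of surface tokens to a tibble with
#' columns `surface`, `lemma`, `pos` (pos in the content 4-class set, or
#' another tagset convertible via [map_pos()]); tokens the tagger cannot
#' handle are skipped with a warning, never an error.
#'
#' @param records Tibble of property records.
#' @param tagger A `function(words) -> tibble(surface, lemma, pos)`, e.g. from
#'   [make_dictionary_tagger()]. Required for rows without pre-tagged tokens.
#' @return Records with `tokens` populated.
#' @export
extract_content_tokens <- function(records, tagger = NULL) {
  needs <- purrr::map_lgl(records$tokens, is.null)
  if (!any(needs)) return(records)
  if (is.null(tagger)) {
    abort_validation("records lack pre-tagged tokens and no tagger was supplied")
  }
  records$tokens[needs] <- purrr::map(records$text[needs], function(txt) {
    words <- tokenize_text(txt)
    if (length(words) == 0L) {
      return(tibble::tibble(surface = character(), lemma = character(), pos = character()))
    }
    tagged <- tryCatch(tagger(words), error = function(e) {
      warning("tagger failed on '", txt, "': ", conditionMessage(e), call. = FALSE)
      tibble::tibble(surface = character(), lemma = character(), pos = character())
    })
    tagged$pos <- map_pos(tagged$pos)
    tagged <- tagged[!is.na(tagged$pos) & !is.na(tagged$lemma) & tagged$lemma != "", , drop = FALSE]
    tibble::tibble(surface = tagged$surface, lemma = fold_word(tagged$lemma), pos = tagged$pos)
  })
  records
}

#' Tokenize a short response on Unicode word boundaries
#'
#' Splits on anything that is not a letter, digit, apostrophe or hyphen;
#' hyphenated forms stay as one token.
#'
#' @param text Character scalar.
#' @return Character vector of surface tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- stringr::str_split(text, "[^\\p{L}\\p{N}'\\-]+")[[1]]
  toks <- gsub("^[-']+|[-']+$", "", toks)
  toks[nzchar(toks)]
}

# Fixed mapping from common tagger tagsets (universal POS, TreeTagger-style
# Spanish prefixes) to the 4-class content set; proper nouns count as nouns;
# everything else (function words, punctuation) maps to NA and is dropped.
POS_MAP <- c(
  noun = "noun", verb = "verb", adjective = "adjective", adverb = "adverb",
  NOUN = "noun", PROPN = "noun", VERB = "verb", ADJ = "adjective", ADV = "adverb",
  NC = "noun", NP = "noun", NMEA = "noun", VLfin = "verb", VLinf = "verb",
  VLger = "verb", VLadj = "verb", ADJv = "adjective", ADV2 = "adverb"
)

#' Map a tagger's POS labels onto the content 4-class set
#'
#' @param pos Character vector of tags.
#' @return Character vector in `{noun, verb, adjective, adverb}` or `NA` for
#'   non-content tags.
#' @export
map_pos <- function(pos) unname(POS_MAP[pos])

#' Build a dictionary-backed tagger
#'
#' A minimal pluggable tagger for pre-lemmatized workflows and testing: looks
#' each case-folded surface token up in a dictionary tibble (`surface`,
#' `lemma`, `pos`); unknown tokens are skipped with a warning.
#'
#' @param dictionary Tibble with columns `surface`, `lemma`, `pos`.
#' @return A tagger function usable with [extract_content_tokens()].
#' @export
make_dictionary_tagger <- function(dictionary) {
  stopifnot(all(c("surface", "lemma", "pos") %in% names(dictionary)))
  key <- fold_word(dictionary$surface)
  function(words) {
    idx <- match(fold_word(words), key)
    unknown <- words[is.na(idx)]
    if (length(unknown) > 0L) {
      warning("tokens not in tagger dictionary, skipped: ",
              paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    keep <- !is.na(idx)
    tibble::tibble(
      surface = words[keep],
      lemma = dictionary$lemma[idx[keep]],
      pos = dictionary$pos[idx[keep]]
    )
  }
}
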