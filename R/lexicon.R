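#' Load a psycholinguistic norms table
#'
#' Reads a UTF-8 CSV with columns `word`, `concreteness`, `imageability`,
#' `familiarity` (1-7 rating scales), `log_frequency` (log10 occurrences per
#' million) and `length` (phoneme count). Rows with out-of-range values are
#' rejected and reported via the `"rejected"` attribute; duplicate words
#' (after case folding) are an error.
#'
#' @param path CSV path.
#' @return A `plt_norms` tibble keyed by case-folded word.
#' @export
load_norms <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        locale = readr::locale(encoding = "UTF-8"))
  required <- c("word", "concreteness", "imageability", "familiarity", "log_frequency", "length")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort_schema(paste0("norms file missing column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in required[-1]) {
    if (nrow(df) == 0L) df[[col]] <- numeric()
    if (!is.numeric(df[[col]])) {
      abort_validation(paste0("non-numeric values in norms column '", col, "'"))
    }
  }
  scales <- c("concreteness", "imageability", "familiarity")
  in_range <- rep(TRUE, nrow(df))
  for (col in scales) in_range <- in_range & df[[col]] >= 1 & df[[col]] <= 7
  in_range <- in_range & df$length >= 1
  in_range[is.na(in_range)] <- FALSE
  rejected <- df[!in_range, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " norms row(s) rejected (out-of-range values): ",
            paste(head(rejected$word, 10L), collapse = ", "), call. = FALSE)
  }
  df <- df[in_range, , drop = FALSE]
  df$word <- fold_word(df$word)
  dup <- df$word[duplicated(df$word)]
  if (length(dup) > 0L) {
    abort_validation(paste0("duplicate word(s) in norms after case folding: ",
                            paste(unique(dup), collapse = ", ")))
  }
  out <- tibble::as_tibble(df[required])
  class(out) <- c("plt_norms", class(out))
  attr(out, "rejected") <- rejected
  out
}

#' Look up norm values for lemmas
#'
#' Lemma-based, case-folded, accent-preserving lookup. Out-of-vocabulary
#' lemmas yield `NA` rows (skip-with-warning policy is applied by callers).
#'
#' @param norms A `plt_norms` table.
#' @param lemmas Character vector.
#' @return Tibble with one row per lemma and the five norm columns.
#' @export
lookup_norms <- function(norms, lemmas) {
  idx <- match(fold_word(lemmas), norms$word)
  norms[idx, c("concreteness", "imageability", "familiarity", "log_frequency", "length")]
}

#' Load a word-vector lexicon in word2vec text format
#'
#' First line is a `"vocab_size dim"` header; each following line is a word
#' and `dim` floats. A line with the wrong number of fields is an error naming
#' the line; duplicated words keep the first occurrence with a warning.
#'
#' @param path File path.
#' @return A `plt_vectors` object: list with `vectors` (matrix, words in
#'   rownames), `dim`, and `oov_policy = "skip_with_warning"`.
#' @export
load_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) abort_schema("empty vector file")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    abort_schema("first line must be a 'vocab_size dim' header")
  }
  d <- as.integer(header[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  lens <- lengths(parts)
  bad <- which(lens != d + 1L)
  if (length(bad) > 0L) {
    abort_validation(paste0("line ", bad[1] + 1L, ": expected ", d,
                            " vector components, found ", lens[bad[1]] - 1L))
  }
  words <- fold_word(vapply(parts, `[[`, character(1), 1L))
  mat <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))), ncol = d, byrow = TRUE)
  if (anyNA(mat)) abort_validation("non-numeric vector component in vector file")
  dup <- duplicated(words)
  if (any(dup)) {
    warning("duplicate word(s) in vector file, keeping first: ",
            paste(unique(words[dup]), collapse = ", "), call. = FALSE)
    mat <- mat[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  norms2 <- sqrt(rowSums(mat^2))
  if (any(norms2 == 0)) abort_validation("zero-length vector(s) in vector file")
  rownames(mat) <- words
  structure(list(vectors = mat, dim = d, oov_policy = "skip_with_warning"),
            class = "plt_vectors")
}

#' Look up vectors for lemmas
#'
#' Total function: returns a matrix with one row per lemma, `NA` rows for
#' out-of-vocabulary lemmas (the OOV signal).
#'
#' @param lexicon A `plt_vectors` object.
#' @param lemmas Character vector.
#' @return Numeric matrix `length(lemmas) x dim`.
#' @export
lookup_vectors <- function(lexicon, lemmas) {
  idx <- match(fold_word(lemmas), rownames(lexicon$vectors))
  out <- matrix(NA_real_, nrow = length(lemmas), ncol = lexicon$dim)
  hit <- !is.na(idx)
  out[hit, ] <- lexicon$vectors[idx[hit], , drop = FALSE]
  out
}

#' @export
print.plt_vectors <- function(x, ...) {
  cat("<plt_vectors> ", nrow(x$vectors), " words, dim ", x$dim, "\n", sep = "")
  invisible(x)
}

#' Load a noun taxonomy rooted at 'entity'
#'
#' Reads a child-parent TSV edge list and a word-node mapping TSV
#' (multi-valued for polysemous words). The taxonomy must be acyclic, contain
#' the root `entity` (which has no parent), and every retained node must
#' reach `entity` via parent edges; unreachable nodes are reported and
#' dropped. Node depths (shortest parent-path edge counts to the root) are
#' precomputed.
#'
#' @param edges_path TSV with columns `child`, `parent`.
#' @param mapping_path TSV with columns `word`, `node`.
#' @return A `plt_taxonomy` object: list with `graph` (igraph, edges
#'   child->parent), `depths` (named numeric), `mapping` (tibble), `dropped`
#'   (character vector of unreachable nodes).
#' @export
load_taxonomy <- function(edges_path, mapping_path) {
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE, progress = FALSE,
                           locale = readr::locale(encoding = "UTF-8"))
  if (!all(c("child", "parent") %in% names(edges)) || nrow(edges) == 0L) {
    abort_schema("taxonomy edge list must be a nonempty TSV with columns child, parent")
  }
  mapping <- readr::read_tsv(mapping_path, show_col_types = FALSE, progress = FALSE,
                             locale = readr::locale(encoding = "UTF-8"))
  if (!all(c("word", "node") %in% names(mapping))) {
    abort_schema("taxonomy mapping must be a TSV with columns word, node")
  }
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")], directed = TRUE)
  if (!"entity" %in% igraph::V(g)$name) abort_validation("root node 'entity' absent from taxonomy")
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle(edges$child, edges$parent)
    abort_validation(paste0("taxonomy contains a cycle: ", paste(cyc, collapse = " -> ")))
  }
  if (igraph::degree(g, "entity", mode = "out") > 0L) {
    abort_validation("root 'entity' must have no parent")
  }
  depths <- igraph::distances(g, to = "entity", mode = "out")[, 1]
  unreachable <- names(depths)[!is.finite(depths)]
  if (length(unreachable) > 0L) {
    warning("dropping ", length(unreachable), " node(s) not reaching 'entity': ",
            paste(head(unreachable, 10L), collapse = ", "), call. = FALSE)
    g <- igraph::delete_vertices(g, unreachable)
    depths <- depths[is.finite(depths)]
  }
  mapping$word <- fold_word(mapping$word)
  mapping <- mapping[mapping$node %in% names(depths), , drop = FALSE]
  structure(list(graph = g, depths = depths, mapping = tibble::as_tibble(mapping),
                 dropped = unreachable),
            class = "plt_taxonomy")
}

# Locate one directed cycle in a child->parent edge list by iterative DFS.
find_cycle <- function(child, parent) {
  adj <- split(parent, child)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- get0(v, envir = state, ifnotfound = "white")
    if (st == "grey") {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == "black") return()
    assign(v, "grey", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) visit(w)
    path <<- path[-length(path)]
    assign(v, "black", envir = state)
  }
  for (v in unique(child)) visit(v)
  found
}

#' Taxonomy depth of word senses
#'
#' Depth of a word is the shortest parent-path edge count from its node to
#' the root `entity`, resolved over polysemous senses by the `sense` policy
#' (minimum depth by default: the least specific defensible sense).
#'
#' @param taxonomy A `plt_taxonomy` object.
#' @param words Character vector of noun lemmas.
#' @param sense `"min"` (default) or `"mean"` over a word's senses.
#' @return Numeric vector of depths; `NA` for unmapped words.
#' @export
taxonomy_depth <- function(taxonomy, words, sense = c("min", "mean")) {
  sense <- match.arg(sense)
  agg <- if (sense == "min") min else mean
  vapply(fold_word(words), function(w) {
    nodes <- taxonomy$mapping$node[taxonomy$mapping$word == w]
    if (length(nodes) == 0L) return(NA_real_)
    agg(taxonomy$depths[nodes])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count syllables of a Spanish word
#'
#' Orthographic syllable-nucleus counting: strong vowels (a, e, o, accented
#' or not) each nucleate; unaccented weak vowels (i, u) attach to an adjacent
#' nucleus (diphthong) while accented weak vowels (í, ú) break the diphthong
#' (hiatus); the silent `u` of `qu`/`gu` before `e`/`i` contributes nothing
#' (but `gü` does).
#'
#' @param word Lowercase Spanish word(s), letters only.
#' @return Integer vector of syllable counts.
#' @export
syllabify <- function(word) {
  vapply(word, function(w) {
    w <- tolower(w)
    if (!grepl("^[a-záéíóúüñ]+$", w)) {
      abort_validation(paste0("syllabify expects alphabetic Spanish input, got: '", w, "'"))
    }
    # silent u: que/qui, gue/gui; diaeresis u is a real vowel
    w <- gsub("qu([eiéí])", "q\\1", w)
    w <- gsub("gu([eiéí])", "g\\1", w)
    w <- gsub("ü", "u", w)
    chars <- strsplit(w, "")[[1]]
    strong <- chars %in% c("a", "e", "o", "á", "é", "ó")
    weak_acc <- chars %in% c("í", "ú")
    weak <- chars %in% c("i", "u")
    vowel <- strong | weak_acc | weak
    # within each maximal vowel run: nuclei = strong + accented weak,
    # or one nucleus if the run holds only unaccented weak vowels
    runs <- rle(vowel)
    count <- 0L
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      if (runs$values[k]) {
        seg <- pos:(pos + len - 1L)
        nuc <- sum(strong[seg]) + sum(weak_acc[seg])
        count <- count + max(nuc, 1L)
      }
      pos <- pos + len
    }
    as.integer(count)
  }, integer(1), USE.NAMES = FALSE)
}

#' The ten stimulus words
#'
#' Common concrete Spanish nouns (one to three syllables) used to cue the
#' property-listing task, shipped as a validated fixture.
#'
#' @return Tibble with columns `word` (Spanish) and `gloss` (English).
#' @export
plt_stimuli <- function() {
  path <- system.file("extdata", "stimuli.csv", package = "pltmarkers")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  locale = readr::locale(encoding = "UTF-8"))
}
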