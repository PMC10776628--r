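# The ten word-property features: five psycholinguistic norm means,
# semantic variability, granularity, property distance flow, and the
# relevance/distinctiveness pair derived from production frequencies.

#' Pairwise vector distance
#'
#' @param x,y Numeric vectors of equal length.
#' @param metric `"cosine"` (1 - cosine similarity; default, standard for
#'   word embeddings) or `"euclidean"`.
#' @return Scalar distance.
#' @export
vector_distance <- function(x, y, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "cosine") {
    1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
  } else {
    sqrt(sum((x - y)^2))
  }
}

# Distances between consecutive rows of a vector matrix.
consecutive_distances <- function(mat, metric = "cosine") {
  n <- nrow(mat)
  if (n < 2L) return(numeric())
  if (metric == "cosine") {
    u <- mat / sqrt(rowSums(mat^2))
    1 - rowSums(u[-n, , drop = FALSE] * u[-1, , drop = FALSE])
  } else {
    sqrt(rowSums((mat[-n, , drop = FALSE] - mat[-1, , drop = FALSE])^2))
  }
}

# Distances from each row of mat to a single vector v.
distances_to <- function(mat, v, metric = "cosine") {
  if (metric == "cosine") {
    u <- mat / sqrt(rowSums(mat^2))
    w <- v / sqrt(sum(v^2))
    1 - as.numeric(u %*% w)
  } else {
    sqrt(rowSums((mat - matrix(v, nrow(mat), length(v), byrow = TRUE))^2))
  }
}

#' Semantic variability of a token sequence
#'
#' Distances between the embedding vectors of consecutive produced content
#' words form a time series; semantic variability is the variance of that
#' series. Low values indicate staying within a semantic field. Tokens must be
#' in production order; out-of-vocabulary tokens are dropped before pairing.
#' Undefined (`NA`) with fewer than two distances (fewer than three usable
#' tokens).
#'
#' @param lemmas Character vector of content lemmas in production order, or a
#'   numeric matrix of vectors (one row per token).
#' @param lexicon A `plt_vectors` object (ignored when `lemmas` is a matrix).
#' @param metric Distance metric, see [vector_distance()].
#' @param var_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Scalar variance (>= 0) or `NA`.
#' @export
semantic_variability <- function(lemmas, lexicon = NULL, metric = c("cosine", "euclidean"),
                                 var_type = c("sample", "population")) {
  metric <- match.arg(metric)
  var_type <- match.arg(var_type)
  mat <- token_matrix(lemmas, lexicon)
  seq_variance(consecutive_distances(mat, metric), var_type)
}

#' Property distance flow for one concept
#'
#' Each property is summarized as the mean of its in-vocabulary content-word
#' vectors; the distances from these property vectors to the cue concept's
#' vector are collected and their variance returned. Undefined (`NA`) when
#' the concept word is out of vocabulary or fewer than two properties have a
#' usable vector.
#'
#' @param concept Concept cue word.
#' @param properties List of character vectors (content lemmas per property).
#' @param lexicon A `plt_vectors` object.
#' @inheritParams semantic_variability
#' @return Scalar variance (>= 0) or `NA`.
#' @export
property_distance_flow <- function(concept, properties, lexicon,
                                   metric = c("cosine", "euclidean"),
                                   var_type = c("sample", "population")) {
  metric <- match.arg(metric)
  var_type <- match.arg(var_type)
  cvec <- lookup_vectors(lexicon, concept)[1, ]
  if (anyNA(cvec)) return(NA_real_)
  pvecs <- lapply(properties, function(lem) {
    m <- lookup_vectors(lexicon, lem)
    m <- m[!is.na(m[, 1]), , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    colMeans(m)
  })
  pvecs <- pvecs[!vapply(pvecs, is.null, logical(1))]
  if (length(pvecs) < 2L) return(NA_real_)
  pm <- do.call(rbind, pvecs)
  seq_variance(distances_to(pm, cvec, metric), var_type)
}

#' Granularity of a concept's nouns
#'
#' Each noun's granularity is the edge-count distance from its taxonomy node
#' to the root `entity` (minimum over senses by default); larger depth means
#' a more specific concept. The concept score is the mean depth over nouns
#' that map into the taxonomy; `NA` if none do.
#'
#' @param nouns Character vector of noun lemmas.
#' @param taxonomy A `plt_taxonomy` object.
#' @param sense Polysemy policy, see [taxonomy_depth()].
#' @return List with `score` (mean depth or `NA`) and `depths` (per-noun
#'   depth vector, `NA` for unmapped nouns).
#' @export
granularity_score <- function(nouns, taxonomy, sense = "min") {
  depths <- taxonomy_depth(taxonomy, nouns, sense = sense)
  list(score = mean_defined(depths), depths = depths)
}

# Resolve lemmas to an in-vocabulary vector matrix (rows = usable tokens).
token_matrix <- function(lemmas, lexicon) {
  if (is.matrix(lemmas)) return(lemmas[stats::complete.cases(lemmas), , drop = FALSE])
  m <- lookup_vectors(lexicon, lemmas)
  m[!is.na(m[, 1]), , drop = FALSE]
}

#' Norm feature means for one concept
#'
#' Arithmetic mean of each of the five psycholinguistic norms over all
#' in-vocabulary content lemmas pooled across the concept's properties;
#' a norm is `NA` when no lemma is in vocabulary.
#'
#' @param lemmas Character vector of content lemmas (pooled across the
#'   concept's properties).
#' @param norms A `plt_norms` table.
#' @return Named numeric vector of the five means.
#' @export
norm_feature_means <- function(lemmas, norms) {
  vals <- lookup_norms(norms, lemmas)
  c(
    concreteness = mean_defined(vals$concreteness),
    imageability = mean_defined(vals$imageability),
    familiarity = mean_defined(vals$familiarity),
    log_frequency = mean_defined(vals$log_frequency),
    length = mean_defined(vals$length)
  )
}

#' Relevance and distinctiveness from production frequencies
#'
#' For a concept-by-property production-frequency table, the relevance of
#' property j for concept i is \eqn{k_{ij} = x_{ij} \log(I / I_j)}, where
#' \eqn{x_{ij}} is the production frequency of property j over concept i,
#' \eqn{I} the total number of concepts, and \eqn{I_j} the number of concepts
#' for which property j was listed. \eqn{\log(I/I_j)} is the property's
#' distinctiveness: 0 when every concept shares it.
#'
#' @param counts Tibble with columns `concept`, `property_key`, `x`
#'   (non-negative integer production frequencies).
#' @param n_concepts Total number of concepts `I`; defaults to the number of
#'   distinct concepts in `counts`.
#' @param log_base Base of the logarithm (natural log by default; the base
#'   only rescales globally).
#' @return A `plt_relevance` tibble with columns `concept`, `property_key`,
#'   `x`, `I_j`, `distinctiveness`, `k`; attribute `I` holds the concept
#'   count.
#' @export
relevance_distinctiveness <- function(counts, n_concepts = NULL, log_base = exp(1)) {
  stopifnot(all(c("concept", "property_key", "x") %in% names(counts)))
  if (any(counts$x < 0)) abort_validation("negative production frequency")
  I <- n_concepts %||% dplyr::n_distinct(counts$concept)
  tab <- counts |>
    dplyr::group_by(.data$property_key) |>
    dplyr::mutate(I_j = dplyr::n_distinct(.data$concept[.data$x > 0])) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$I_j > 0L)
  if (any(tab$I_j > I)) abort_validation("I_j exceeds the number of concepts I")
  tab$distinctiveness <- log(I / tab$I_j, base = log_base)
  tab$k <- ifelse(tab$x > 0, tab$x * tab$distinctiveness, 0)
  out <- tab[, c("concept", "property_key", "x", "I_j", "distinctiveness", "k")]
  attr(out, "I") <- I
  class(out) <- c("plt_relevance", class(out))
  out
}

# Canonical identity of a property for production-frequency counting:
# the sorted multiset of its content lemmas.
property_key <- function(lemmas) {
  vapply(lemmas, function(l) paste(sort(l), collapse = " "), character(1),
         USE.NAMES = FALSE)
}

#' Build the production-frequency table from tokenized records
#'
#' Pools production frequencies over all participants in the analysis set
#' (repetitions counted), keyed by the sorted lemma multiset of each
#' property. Properties with no content lemmas are skipped.
#'
#' @param records Filtered, tokenized property records.
#' @return Tibble with columns `concept`, `property_key`, `x`.
#' @export
production_counts <- function(records) {
  keys <- property_key(lapply(records$tokens, function(tk) tk$lemma))
  keep <- nzchar(keys)
  tibble::tibble(concept = records$concept[keep], property_key = keys[keep]) |>
    dplyr::count(.data$concept, .data$property_key, name = "x")
}

#' Per-concept feature extraction
#'
#' Computes the ten word-property features for every (participant, concept)
#' cell of a filtered, tokenized record set. Relevance and distinctiveness
#' are means, over the properties the participant listed for that concept, of
#' the pooled-table values of \eqn{k_{ij}} and \eqn{\log(I/I_j)}.
#'
#' @param records Filtered, tokenized property records.
#' @param norms A `plt_norms` table.
#' @param lexicon A `plt_vectors` object.
#' @param taxonomy A `plt_taxonomy` object (or `NULL` to leave granularity
#'   `NA`).
#' @param metric Distance metric, see [vector_distance()].
#' @param var_type Variance convention, see [semantic_variability()].
#' @param adjacency `"concat"` (default): the semantic-variability token
#'   sequence concatenates a concept's properties in production order;
#'   `"reset"`: consecutive distances are computed within each property and
#'   pooled before taking the variance.
#' @param log_base Log base for relevance/distinctiveness.
#' @param sense Taxonomy polysemy policy.
#' @return Tibble with one row per (participant, concept) and the ten feature
#'   columns.
#' @export
concept_features <- function(records, norms, lexicon, taxonomy = NULL,
                             metric = "cosine", var_type = "sample",
                             adjacency = c("concat", "reset"),
                             log_base = exp(1), sense = "min") {
  adjacency <- match.arg(adjacency)
  records <- dplyr::arrange(records, .data$participant_id, .data$concept,
                            .data$property_index)
  rel <- relevance_distinctiveness(production_counts(records), log_base = log_base)
  rel_key <- paste(rel$concept, rel$property_key, sep = "\r")

  # flat token table in production order, with one global lookup per resource
  ntok <- vapply(records$tokens, nrow, integer(1))
  tok <- tibble::tibble(
    row = rep(seq_len(nrow(records)), ntok),
    lemma = unlist(lapply(records$tokens, `[[`, "lemma"), use.names = FALSE) %||% character(),
    pos = unlist(lapply(records$tokens, `[[`, "pos"), use.names = FALSE) %||% character()
  )
  tok$participant_id <- records$participant_id[tok$row]
  tok$concept <- records$concept[tok$row]
  cell <- paste(tok$participant_id, tok$concept, sep = "\r")

  nv <- lookup_norms(norms, tok$lemma)
  vec_idx <- match(fold_word(tok$lemma), rownames(lexicon$vectors))
  depth_tbl <- NULL
  if (!is.null(taxonomy)) {
    uw <- unique(tok$lemma[tok$pos == "noun"])
    depth_tbl <- setNames(taxonomy_depth(taxonomy, uw, sense = sense), uw)
  }

  cells <- split(seq_len(nrow(tok)), factor(cell, levels = unique(cell)))
  vmat <- lexicon$vectors
  nc <- length(cells)
  fvals <- matrix(NA_real_, nc, 10, dimnames = list(NULL, feature_names()))
  pid_out <- cpt_out <- character(nc)

  for (ci in seq_len(nc)) {
    ti <- cells[[ci]]
    pid_out[ci] <- tok$participant_id[ti[1]]
    cpt <- tok$concept[ti[1]]
    cpt_out[ci] <- cpt
    idx <- vec_idx[ti]
    usable <- idx[!is.na(idx)]

    sv <- if (adjacency == "concat") {
      seq_variance(consecutive_distances(vmat[usable, , drop = FALSE], metric), var_type)
    } else {
      ok <- !is.na(idx)
      dists <- unlist(lapply(split(idx[ok], tok$row[ti][ok]), function(pi) {
        consecutive_distances(vmat[pi, , drop = FALSE], metric)
      }), use.names = FALSE)
      seq_variance(dists, var_type)
    }

    gran <- if (is.null(depth_tbl)) NA_real_ else {
      mean_defined(depth_tbl[tok$lemma[ti][tok$pos[ti] == "noun"]])
    }

    # property distance flow: mean vector per property, distance to the cue
    cvi <- match(fold_word(cpt), rownames(vmat))
    pdf_ <- NA_real_
    if (!is.na(cvi)) {
      props <- split(idx, tok$row[ti])
      pvecs <- lapply(props, function(pi) {
        pi <- pi[!is.na(pi)]
        if (length(pi) == 0L) NULL else colMeans(vmat[pi, , drop = FALSE])
      })
      pvecs <- pvecs[!vapply(pvecs, is.null, logical(1))]
      if (length(pvecs) >= 2L) {
        pdf_ <- seq_variance(distances_to(do.call(rbind, pvecs),
                                          vmat[cvi, ], metric), var_type)
      }
    }

    keys <- vapply(split(tok$lemma[ti], tok$row[ti]), function(l) {
      paste(sort(l), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    ridx <- match(paste(cpt, keys, sep = "\r"), rel_key)

    fvals[ci, ] <- c(
      mean_defined(nv$concreteness[ti]), mean_defined(nv$imageability[ti]),
      mean_defined(nv$familiarity[ti]), mean_defined(nv$log_frequency[ti]),
      mean_defined(nv$length[ti]), sv, gran, pdf_,
      mean_defined(rel$k[ridx]), mean_defined(rel$distinctiveness[ridx])
    )
  }
  out <- dplyr::bind_cols(
    tibble::tibble(participant_id = pid_out, concept = cpt_out),
    tibble::as_tibble(fvals)
  )

  # (participant, concept) cells whose every property had zero content tokens
  # still appear, with all features undefined
  all_cells <- dplyr::distinct(records, .data$participant_id, .data$group, .data$concept)
  out <- dplyr::left_join(all_cells, out, by = c("participant_id", "concept"))
  for (f in feature_names()) if (!f %in% names(out)) out[[f]] <- NA_real_
  dplyr::as_tibble(out)
}

#' Aggregate concept features into the participant feature matrix
#'
#' Per participant and feature, the mean over concepts where the feature is
#' defined; a cell is missing only when the feature was undefined for every
#' concept. Education (and any other participant-level covariates) are joined
#' from `participants`.
#'
#' @param cfeats Output of [concept_features()].
#' @param participants Optional tibble with `participant_id` and covariate
#'   columns (e.g. `education`).
#' @return A `plt_feature_matrix` tibble: `participant_id`, `group`,
#'   covariates, then the ten feature columns.
#' @export
aggregate_participants <- function(cfeats, participants = NULL) {
  fm <- cfeats |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feature_names()), mean_defined),
                     .groups = "drop")
  if (!is.null(participants)) {
    participants <- participants[, setdiff(names(participants), "group"), drop = FALSE]
    fm <- dplyr::left_join(fm, participants, by = "participant_id")
    fm <- fm[, c("participant_id", "group",
                 setdiff(names(participants), c("participant_id", "group")),
                 feature_names())]
  }
  class(fm) <- c("plt_feature_matrix", class(fm))
  fm
}

#' End-to-end feature extraction
#'
#' Convenience wrapper: filter validity, (optionally) tag tokens, compute
#' per-concept features, and aggregate per participant.
#'
#' @param records Parsed property records.
#' @param norms,lexicon,taxonomy Lexical resources.
#' @param participants Participant covariate table (see
#'   [aggregate_participants()]).
#' @param tagger Optional tagger for non-pre-tagged rows.
#' @param ... Feature options passed to [concept_features()].
#' @return A `plt_feature_matrix` tibble.
#' @export
build_feature_matrix <- function(records, norms, lexicon, taxonomy = NULL,
                                 participants = NULL, tagger = NULL, ...) {
  records <- filter_valid(records)
  records <- extract_content_tokens(records, tagger = tagger)
  cf <- concept_features(records, norms, lexicon, taxonomy, ...)
  aggregate_participants(cf, participants)
}
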