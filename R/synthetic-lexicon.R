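# Toy lexical resources: a clustered unit-norm vector lexicon, a stratified
# norms table, and a chain taxonomy, all in the pipeline's input formats.

#' Generate a clustered toy vector lexicon
#'
#' Draws unit-norm vectors around cluster centroids (random orthonormal
#' centroids by default). With zero dispersion every member equals its
#' centroid; with small dispersion, within-cluster cosine distances are much
#' smaller than between-cluster ones, which is what gives the cluster-stay
#' Markov chain of [simulate_cohort()] its handle on semantic variability.
#'
#' @param vocab_size Number of words (must be >= `n_clusters`).
#' @param dim Vector dimension (>= 2).
#' @param n_clusters Number of clusters (>= 2).
#' @param within_sd Per-coordinate Gaussian dispersion around the centroid
#'   before renormalization.
#' @param seed Integer seed (fixes everything).
#' @param centroids Optional `n_clusters x dim` matrix of centroids.
#' @param words Optional character vector of words (default `w0001`, ...).
#' @return List with `lexicon` (a `plt_vectors`) and `clusters` (named
#'   integer vector of cluster assignments).
#' @export
make_toy_lexicon <- function(vocab_size = 480, dim = 8, n_clusters = 4,
                             within_sd = 0.15, seed = 1, centroids = NULL,
                             words = NULL) {
  stopifnot(n_clusters >= 2, dim >= 2)
  if (vocab_size < n_clusters) abort_validation("vocab_size smaller than cluster count")
  set.seed(derive_seed(seed, "toy-lexicon"))
  if (is.null(centroids)) {
    if (n_clusters <= dim) {
      centroids <- qr.Q(qr(matrix(rnorm(dim * dim), dim)))[, seq_len(n_clusters), drop = FALSE]
      centroids <- t(centroids)
    } else {
      centroids <- matrix(rnorm(n_clusters * dim), n_clusters)
      centroids <- centroids / sqrt(rowSums(centroids^2))
    }
  }
  words <- words %||% sprintf("w%04d", seq_len(vocab_size))
  cluster <- rep_len(seq_len(n_clusters), vocab_size)
  noise <- matrix(rnorm(vocab_size * dim, sd = within_sd), vocab_size)
  mat <- centroids[cluster, , drop = FALSE] + noise
  mat <- mat / sqrt(rowSums(mat^2))
  rownames(mat) <- fold_word(words)
  lexicon <- structure(list(vectors = mat, dim = dim,
                            oov_policy = "skip_with_warning"),
                       class = "plt_vectors")
  list(lexicon = lexicon, clusters = setNames(cluster, words),
       centroids = centroids)
}

#' Write a vector lexicon in word2vec text format
#'
#' @param lexicon A `plt_vectors` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(lexicon, path) {
  mat <- lexicon$vectors
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(mat), ncol(mat)), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(rownames(mat)[i], paste(formatC(mat[i, ], format = "g", digits = 10),
                                  collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

# Build the response-vocabulary word table: cluster x concreteness-stratum x
# imageability-stratum cells crossed with content POS classes. Strata are the
# effect-injection handle: high strata draw norms from [5,7], low from [1,3].
make_word_table <- function(vocab_size, n_clusters, seed) {
  set.seed(derive_seed(seed, "toy-word-table"))
  words <- sprintf("w%04d", seq_len(vocab_size))
  cluster <- rep_len(seq_len(n_clusters), vocab_size)
  # balanced quadrants within each cluster
  quadrant <- unlist(lapply(split(seq_len(vocab_size), cluster), function(idx) {
    rep_len(1:4, length(idx))
  }))[order(unlist(split(seq_len(vocab_size), cluster)))]
  conc_high <- quadrant %in% c(1, 2)
  imag_high <- quadrant %in% c(1, 3)
  pos <- sample(CONTENT_POS, vocab_size, replace = TRUE,
                prob = c(0.60, 0.20, 0.12, 0.08))
  tibble::tibble(word = words, cluster = cluster,
                 conc_high = conc_high, imag_high = imag_high, pos = pos)
}

# Norms drawn uniformly within stratum-specific ranges on the 1-7 scales.
make_toy_norms <- function(word_table, seed) {
  set.seed(derive_seed(seed, "toy-norms"))
  n <- nrow(word_table)
  runif_range <- function(hi) ifelse(hi, runif(n, 5, 7), runif(n, 1, 3))
  tibble::tibble(
    word = word_table$word,
    concreteness = runif_range(word_table$conc_high),
    imageability = runif_range(word_table$imag_high),
    familiarity = runif(n, 3, 7),
    log_frequency = runif(n, 0, 2.5),
    length = sample(2:8, n, replace = TRUE)
  )
}

# A taxonomy of parallel chains under 'entity', with noun words mapped to
# nodes at depths 2..8; a small fraction of nouns are polysemous (two senses).
make_toy_taxonomy <- function(word_table, seed, n_chains = 5, max_depth = 8,
                              polysemy_frac = 0.05) {
  set.seed(derive_seed(seed, "toy-taxonomy"))
  edges <- purrr::map_dfr(seq_len(n_chains), function(ch) {
    nodes <- c("entity", sprintf("n%d_%d", ch, seq_len(max_depth)))
    tibble::tibble(child = nodes[-1], parent = nodes[-length(nodes)])
  })
  nouns <- word_table$word[word_table$pos == "noun"]
  mapping <- tibble::tibble(
    word = nouns,
    node = sprintf("n%d_%d", sample(n_chains, length(nouns), replace = TRUE),
                   sample(2:max_depth, length(nouns), replace = TRUE))
  )
  poly <- nouns[runif(length(nouns)) < polysemy_frac]
  if (length(poly) > 0L) {
    mapping <- dplyr::bind_rows(mapping, tibble::tibble(
      word = poly,
      node = sprintf("n%d_%d", sample(n_chains, length(poly), replace = TRUE),
                     sample(2:max_depth, length(poly), replace = TRUE))
    ))
  }
  list(edges = edges, mapping = mapping)
}
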