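# Tiny in-code fixtures shared across test files.

write_tiny_transcripts <- function(path = tempfile(fileext = ".csv"),
                                   rows = NULL) {
  rows <- rows %||% c(
    "participant_id,group,concept,property_index,text,validity_tag",
    "S001,PD,árbol,1,tiene hojas,valid",
    "S001,PD,árbol,2,es verde,valid",
    "S001,PD,sol,1,el tuyo es muy bonito,examiner_directed"
  )
  writeLines(rows, path, useBytes = TRUE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tiny_norms <- function(path = tempfile(fileext = ".csv"),
                             extra = character()) {
  writeLines(c(
    "word,concreteness,imageability,familiarity,log_frequency,length",
    "sol,6.1,6.5,6.8,1.7,3",
    "hoja,5.5,6.0,6.2,1.2,4",
    "verde,4.0,5.0,6.0,1.5,5",
    "tener,2.0,2.5,6.9,2.4,4",
    extra
  ), path, useBytes = TRUE)
  path
}

write_tiny_vectors <- function(path = tempfile(fileext = ".vec"),
                               lines = NULL) {
  lines <- lines %||% c("3 2", "sol 1 0", "hoja 0 1", "verde 0.6 0.8")
  writeLines(lines, path, useBytes = TRUE)
  path
}

write_tiny_taxonomy <- function(edges = NULL, mapping = NULL) {
  edges <- edges %||% c("child\tparent", "animal\tentity", "dog\tanimal",
                        "bulldog\tdog", "plant\tentity", "tree\tplant")
  mapping <- mapping %||% c("word\tnode", "bulldog\tbulldog", "perro\tdog",
                            "árbol\ttree", "animal\tanimal")
  ep <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".tsv")
  writeLines(edges, ep, useBytes = TRUE)
  writeLines(mapping, mp, useBytes = TRUE)
  list(edges = ep, mapping = mp)
}

# A deterministic lexicon of explicit vectors for hand-computed oracles.
fixed_lexicon <- function(words, mat) {
  rownames(mat) <- words
  structure(list(vectors = mat, dim = ncol(mat), oov_policy = "skip_with_warning"),
            class = "plt_vectors")
}

# Independent oracle: cosine / euclidean distance computed element by element.
oracle_distance <- function(x, y, metric = "cosine") {
  if (metric == "cosine") {
    num <- 0; nx <- 0; ny <- 0
    for (i in seq_along(x)) {
      num <- num + x[i] * y[i]; nx <- nx + x[i]^2; ny <- ny + y[i]^2
    }
    1 - num / (sqrt(nx) * sqrt(ny))
  } else {
    s <- 0
    for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
    sqrt(s)
  }
}

# Independent oracle: two-pass sample variance.
oracle_variance <- function(v) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  m <- sum(v) / n
  s <- 0
  for (i in seq_len(n)) s <- s + (v[i] - m)^2
  s / (n - 1)
}

# Independent oracle: breadth-first shortest-path depth in a child->parent
# edge list, never touching igraph.
oracle_bfs_depth <- function(child, parent, from, to = "entity") {
  adj <- split(parent, child)
  frontier <- from
  depth <- 0
  seen <- character()
  while (length(frontier) > 0) {
    if (to %in% frontier) return(depth)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    depth <- depth + 1
  }
  Inf
}

# A small simulated cohort reused by several test files (cached per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(group_sizes = c(PD = 8L, bvFTD = 7L, HC = 9L), seed = 7)
      cache <<- simulate_cohort(spec)
    }
    cache
  }
})
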