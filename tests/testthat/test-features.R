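test_that("norm feature means average pooled in-vocabulary lemmas", {
  norms <- load_norms(write_tiny_norms())
  # {4.0, 6.0} -> 5.0 via verde (4.0) and a 6.0-concreteness word
  n2 <- load_norms(write_tiny_norms(extra = "seis,6,6,6,1,3"))
  out <- norm_feature_means(c("verde", "seis"), n2)
  expect_equal(unname(out["concreteness"]), 5.0)
  # single in-vocabulary lemma -> verbatim norms
  one <- norm_feature_means("sol", norms)
  expect_equal(unname(one), c(6.1, 6.5, 6.8, 1.7, 3))
  # all OOV -> undefined
  expect_true(all(is.na(norm_feature_means(c("xx", "yy"), norms))))
  # OOV lemmas are simply skipped
  expect_equal(unname(norm_feature_means(c("sol", "xx"), norms)["concreteness"]), 6.1)
})

test_that("semantic variability matches the hand-computed distance-variance oracle", {
  lex <- fixed_lexicon(c("a", "b", "c"),
                       matrix(c(1, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE))
  # (1,0),(1,0),(0,1): cosine distances (0,1) -> sample variance 0.5
  expect_equal(semantic_variability(c("a", "b", "c"), lex), 0.5)
  # three identical vectors -> variance 0
  expect_equal(semantic_variability(c("a", "a", "a"), lex), 0)
  # two usable tokens -> one distance -> undefined
  expect_true(is.na(semantic_variability(c("a", "c"), lex)))
  # OOV dropped before pairing: a, OOV, a, c == a, a, c
  expect_equal(semantic_variability(c("a", "zz", "a", "c"), lex),
               semantic_variability(c("a", "a", "c"), lex))
  # population variance convention halves the two-distance case
  expect_equal(semantic_variability(c("a", "b", "c"), lex, var_type = "population"), 0.25)
})

test_that("property distance flow matches its hand-computed oracle", {
  lex <- fixed_lexicon(c("sol", "p1", "p2"),
                       matrix(c(1, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE))
  # property vectors (1,0) and (0,1) vs concept (1,0): distances (0,1) -> var 0.5
  expect_equal(property_distance_flow("sol", list("p1", "p2"), lex), 0.5)
  # every property equals the concept vector -> variance 0
  expect_equal(property_distance_flow("sol", list("p1", "p1", "p1"), lex), 0)
  # single usable property -> undefined
  expect_true(is.na(property_distance_flow("sol", list("p1", "zz"), lex)))
  # concept OOV -> undefined
  expect_true(is.na(property_distance_flow("luna", list("p1", "p2"), lex)))
})

test_that("random vector sequences agree with element-wise oracles", {
  set.seed(42)
  for (metric in c("cosine", "euclidean")) {
    for (rep in 1:50) {
      n <- sample(3:12, 1); d <- sample(2:6, 1)
      mat <- matrix(rnorm(n * d), n)
      lex <- fixed_lexicon(sprintf("w%d", 1:n), mat)
      dists <- vapply(seq_len(n - 1), function(i) {
        oracle_distance(mat[i, ], mat[i + 1, ], metric)
      }, numeric(1))
      expect_equal(semantic_variability(sprintf("w%d", 1:n), lex, metric = metric),
                   oracle_variance(dists), tolerance = 1e-12)
    }
  }
})

test_that("cosine-metric features are invariant to orthogonal maps and rescaling", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(4:10, 1); d <- sample(3:6, 1)
    mat <- matrix(rnorm(n * d), n)
    Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    scales <- runif(n, 0.2, 5)
    words <- sprintf("w%d", 1:n)
    sv1 <- semantic_variability(words, fixed_lexicon(words, mat))
    sv2 <- semantic_variability(words, fixed_lexicon(words, (mat %*% Q) * scales))
    expect_equal(sv1, sv2, tolerance = 1e-8)

    pf1 <- property_distance_flow(words[1], as.list(words[-1]), fixed_lexicon(words, mat))
    pf2 <- property_distance_flow(words[1], as.list(words[-1]),
                                  fixed_lexicon(words, mat %*% Q))
    expect_equal(pf1, pf2, tolerance = 1e-8)
  }
})

test_that("granularity equals BFS depth, with min-depth polysemy resolution", {
  tx <- write_tiny_taxonomy(
    mapping = c("word\tnode", "bulldog\tbulldog", "animal\tanimal",
                "entity\tentity", "ambiguo\tbulldog", "ambiguo\tplant")
  )
  taxo <- load_taxonomy(tx$edges, tx$mapping)
  # chain entity <- animal <- dog <- bulldog
  expect_equal(granularity_score("bulldog", taxo)$score, 3)
  expect_equal(granularity_score("entity", taxo)$score, 0)
  # senses at depths {3, 1}: min policy picks 1, mean policy 2
  expect_equal(granularity_score("ambiguo", taxo)$score, 1)
  expect_equal(granularity_score("ambiguo", taxo, sense = "mean")$score, 2)
  # mean over mapped nouns, unmapped nouns skipped
  g <- granularity_score(c("bulldog", "animal", "nada"), taxo)
  expect_equal(g$score, 2)
  expect_equal(g$depths, c(3, 1, NA))
  expect_true(is.na(granularity_score("nada", taxo)$score))
})

test_that("random taxonomies agree with an independent BFS oracle", {
  set.seed(44)
  for (rep in 1:25) {
    n_nodes <- sample(6:15, 1)
    nodes <- c("entity", sprintf("n%d", seq_len(n_nodes - 1)))
    # random DAG: each non-root node gets 1-2 parents among earlier nodes
    child <- character(); parent <- character()
    for (i in 2:n_nodes) {
      k <- sample(1:min(2, i - 1), 1)
      for (p in sample(seq_len(i - 1), k)) {
        child <- c(child, nodes[i]); parent <- c(parent, nodes[p])
      }
    }
    tx <- write_tiny_taxonomy(
      edges = c("child\tparent", paste(child, parent, sep = "\t")),
      mapping = c("word\tnode", paste(nodes, nodes, sep = "\t"))
    )
    taxo <- load_taxonomy(tx$edges, tx$mapping)
    for (nd in nodes) {
      expect_equal(taxonomy_depth(taxo, nd),
                   oracle_bfs_depth(child, parent, nd))
    }
  }
})

test_that("relevance/distinctiveness implement the production-frequency weighting", {
  counts <- tibble::tibble(
    concept = rep(sprintf("c%d", 1:10), each = 2),
    property_key = rep(c("shared", "rare"), 10),
    x = c(rbind(rep(5, 10), c(3, rep(0, 8), 1)))
  )
  rel <- relevance_distinctiveness(counts)
  # property listed for all I concepts -> k = 0 despite x = 5
  expect_equal(rel$k[rel$property_key == "shared"], rep(0, 10))
  # x = 0 -> k = 0
  expect_equal(rel$k[rel$property_key == "rare" & rel$x == 0], rep(0, 8))
  # x = 3, I = 10, I_j = 2 -> k = 3 ln 5
  expect_equal(rel$k[rel$property_key == "rare" & rel$x == 3], 3 * log(5),
               tolerance = 1e-12)
  expect_equal(rel$distinctiveness[rel$property_key == "rare"][1], log(5))
  expect_error(relevance_distinctiveness(tibble::tibble(
    concept = "a", property_key = "p", x = -1)), "negative")
})

test_that("relevance table matches a brute-force recount on random tables", {
  set.seed(45)
  for (rep in 1:40) {
    I <- sample(3:8, 1); J <- sample(2:6, 1)
    counts <- expand.grid(concept = sprintf("c%d", 1:I),
                          property_key = sprintf("p%d", 1:J),
                          stringsAsFactors = FALSE)
    counts$x <- rpois(nrow(counts), 1.2)
    counts <- tibble::as_tibble(counts)
    rel <- relevance_distinctiveness(counts)
    for (r in sample(nrow(rel), min(10, nrow(rel)))) {
      cj <- rel$property_key[r]
      I_j <- length(unique(counts$concept[counts$property_key == cj & counts$x > 0]))
      if (I_j == 0) next
      expect_equal(rel$I_j[r], I_j)
      expect_equal(rel$k[r], rel$x[r] * log(I / I_j), tolerance = 1e-12)
    }
    listed <- rel[rel$x > 0, ]
    # monotone in x at fixed I_j; zero iff x = 0 or I_j = I; bounded distinctiveness
    expect_true(all(rel$distinctiveness >= 0 & rel$distinctiveness <= log(I) + 1e-12))
    expect_true(all((rel$k == 0) == (rel$x == 0 | rel$I_j == I)))
  }
})

test_that("participant aggregation averages defined concepts only", {
  cf <- tibble::tibble(
    participant_id = "S1", group = "PD", concept = c("a", "b"),
    concreteness = c(2, 4), imageability = c(NA, 5), familiarity = c(3, 3),
    log_frequency = c(1, 2), length = c(4, 6), semantic_variability = c(NA, NA),
    granularity = c(2, 4), property_distance_flow = c(0.1, 0.3),
    relevance = c(1, 2), distinctiveness = c(0.5, 0.7)
  )
  fm <- aggregate_participants(cf)
  expect_equal(fm$concreteness, 3)
  expect_equal(fm$imageability, 5)          # skip-missing mean
  expect_true(is.na(fm$semantic_variability))  # undefined everywhere
  # single concept -> row equals that concept's features
  fm1 <- aggregate_participants(cf[2, ])
  expect_equal(fm1$concreteness, 4)
  expect_equal(fm1$imageability, 5)
})

test_that("feature extraction is a pure function of its inputs", {
  sim <- small_cohort()
  fm1 <- simulated_feature_matrix(sim)
  fm2 <- simulated_feature_matrix(sim)
  expect_identical(fm1, fm2)
  expect_equal(sum(duplicated(fm1$participant_id)), 0L)
  expect_named(fm1, c("participant_id", "group", "education", feature_names()))
})
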