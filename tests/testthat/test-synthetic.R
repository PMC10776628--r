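test_that("toy lexicon is deterministic, unit-norm, and cluster-separated", {
  t1 <- make_toy_lexicon(vocab_size = 60, dim = 6, n_clusters = 3, seed = 3)
  t2 <- make_toy_lexicon(vocab_size = 60, dim = 6, n_clusters = 3, seed = 3)
  expect_identical(t1$lexicon$vectors, t2$lexicon$vectors)
  expect_equal(unname(sqrt(rowSums(t1$lexicon$vectors^2))), rep(1, 60))

  # mean within-cluster cosine distance < mean between-cluster
  m <- t1$lexicon$vectors
  cl <- t1$clusters
  sims <- m %*% t(m)
  same <- outer(cl, cl, "==") & upper.tri(sims)
  diff <- !outer(cl, cl, "==") & upper.tri(sims)
  expect_lt(mean(1 - sims[same]), mean(1 - sims[diff]))
})

test_that("zero dispersion collapses members onto centroids; orthogonal centroids separate fully", {
  cents <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  t0 <- make_toy_lexicon(vocab_size = 20, dim = 4, n_clusters = 2,
                         within_sd = 0, seed = 4, centroids = cents)
  m <- t0$lexicon$vectors
  within <- 1 - m[1, ] %*% m[3, ]   # same cluster (round-robin assignment)
  between <- 1 - m[1, ] %*% m[2, ]
  expect_equal(as.numeric(within), 0)
  expect_equal(as.numeric(between), 1)
  expect_error(make_toy_lexicon(vocab_size = 2, n_clusters = 4), "smaller")
})

test_that("generated bundles round-trip through every loader", {
  sim <- small_cohort()
  dir <- withr::local_tempdir()
  spec <- cohort_spec(group_sizes = c(PD = 8L, bvFTD = 7L, HC = 9L), seed = 7)
  simulate_cohort(spec, dir = dir)

  rec <- parse_responses(file.path(dir, "transcripts.csv"))
  expect_gt(nrow(rec), 0)
  norms <- load_norms(file.path(dir, "norms.csv"))
  expect_gt(nrow(norms), 0)
  lex <- load_vectors(file.path(dir, "vectors.vec"))
  expect_equal(lex$dim, spec$dim)
  taxo <- load_taxonomy(file.path(dir, "taxonomy_edges.tsv"),
                        file.path(dir, "taxonomy_mapping.tsv"))
  expect_equal(unname(taxo$depths["entity"]), 0)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$seed, 7)
  # ground truth re-derives the injected effects without re-reading transcripts
  expect_equal(gt$effects$d_concreteness$PD, 0.78)
  expect_length(gt$traits$stay, sum(spec$group_sizes))
})

test_that("same seed gives byte-identical files; different seeds differ", {
  spec <- cohort_spec(group_sizes = c(PD = 4L, bvFTD = 4L, HC = 4L), seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  simulate_cohort(spec, dir = d1)
  simulate_cohort(spec, dir = d2)
  spec3 <- cohort_spec(group_sizes = c(PD = 4L, bvFTD = 4L, HC = 4L), seed = 12)
  simulate_cohort(spec3, dir = d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  expect_false(identical(readLines(file.path(d1, "transcripts.csv"), warn = FALSE),
                         readLines(file.path(d3, "transcripts.csv"), warn = FALSE)))
})

test_that("valid-property counts track the group means", {
  sim <- simulate_cohort(cohort_spec(seed = 31))
  rec <- filter_valid(sim$records)
  per <- dplyr::count(rec, group, participant_id, concept)
  means <- tapply(per$n, per$group, mean)
  expect_equal(unname(means["HC"]), 8.3, tolerance = 0.15)
  expect_equal(unname(means["PD"]), 6.3, tolerance = 0.2)
  # non-valid properties present with correct tags
  excl <- exclusion_counts(rec)
  expect_gt(sum(excl), 0)
})

test_that("raising the cluster-stay probability lowers semantic variability", {
  grid <- c(0.55, 0.7, 0.85)
  mean_sv <- vapply(seq_along(grid), function(i) {
    svs <- vapply(1:4, function(r) {
      spec <- cohort_spec(group_sizes = c(PD = 2L, bvFTD = 2L, HC = 8L),
                          base_stay = grid[i],
                          d_semantic_variability = c(PD = 0, bvFTD = 0),
                          d_concreteness = c(PD = 0, bvFTD = 0),
                          d_imageability = c(PD = 0, bvFTD = 0),
                          seed = 300 + 10 * i + r)
      fm <- simulated_feature_matrix(simulate_cohort(spec))
      mean(fm$semantic_variability[fm$group == "HC"], na.rm = TRUE)
    }, numeric(1))
    mean(svs)
  }, numeric(1))
  expect_true(all(diff(mean_sv) < 0))
})

test_that("zero injected effects leave group means equal within Monte-Carlo error", {
  # Quick version of the replicate experiment run in full in the acceptance
  # suite: per-replicate d has SD ~0.3, so a 6-replicate mean is bounded by
  # 0.2 + 2 * 0.3/sqrt(6) ~= 0.45; assert a 0.35 working bound here.
  ds <- sapply(1:6, function(r) {
    spec <- cohort_spec(seed = 400 + r,
                        d_concreteness = c(PD = 0, bvFTD = 0),
                        d_imageability = c(PD = 0, bvFTD = 0),
                        d_semantic_variability = c(PD = 0, bvFTD = 0))
    fm <- simulated_feature_matrix(simulate_cohort(spec))
    vapply(c("concreteness", "imageability", "semantic_variability"), function(f) {
      a <- fm[[f]][fm$group == "PD"]; b <- fm[[f]][fm$group == "HC"]
      (mean(a) - mean(b)) / sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                                   (length(a) + length(b) - 2))
    }, numeric(1))
  })
  expect_true(all(abs(rowMeans(ds)) < 0.35))
})
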