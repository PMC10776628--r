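# Synthetic cohort generation with parameterized group effects.
#
# Group shifts in concreteness/imageability are injected by biasing token
# sampling toward high- vs low-norm vocabulary strata; reduced semantic
# variability is injected by raising the probability of staying in the
# current vector cluster between consecutive tokens. The generator's
# contract is that the injected standardized shifts (Cohen's d at the
# participant level) are realized in the resulting feature matrix, so the
# mapping from d to sampling parameters is calibrated internally
# (analytically for the norm strata, by short Monte Carlo for the
# cluster-stay chain).

#' Specify a synthetic property-listing cohort
#'
#' Defaults emulate the study design this package validates against: three
#' groups of 20/16/26 participants (PD, bvFTD, HC), ten concrete Spanish cue
#' concepts, group means of 6.3/6.0/8.3 valid properties per concept, and
#' standardized group shifts of +0.78 (concreteness, PD), +0.74
#' (imageability, PD) and -1.04 (semantic variability, both patient groups)
#' relative to healthy controls. Signs follow the direction of the effects:
#' patients produce more concrete/imageable words and show reduced semantic
#' variability.
#'
#' @param group_sizes Named integer vector over `PD`, `bvFTD`, `HC` (each
#'   >= 2).
#' @param concepts Character vector of cue concepts (default: the ten
#'   stimulus words).
#' @param props_mean Named means of the per-concept valid-property counts.
#' @param props_size Negative-binomial size (overdispersion) of those counts.
#' @param tokens_per_prop_mean Mean content tokens per property is
#'   `1 + tokens_per_prop_mean` (Poisson shifted to a 1 minimum).
#' @param d_concreteness,d_imageability,d_semantic_variability Named (PD,
#'   bvFTD) signed standardized shifts vs HC.
#' @param base_conc_high,base_imag_high HC probability of sampling a token
#'   from the high-norm stratum.
#' @param base_stay HC cluster-stay probability (must exceed 0.5 so the
#'   stay-variability relation is monotone).
#' @param trait_sd_p,trait_sd_stay Between-participant SD of the stratum
#'   probabilities / stay probability.
#' @param edu_share Fraction of within-group feature-trait variance explained
#'   by education (capped by trait capacity).
#' @param edu_mean,edu_sd Education (years) distribution, common to all
#'   groups by default so the covariate adjustment leaves the injected group
#'   contrasts unbiased; `edu_mean` may be a named per-group vector.
#' @param invalid_frac Expected non-valid properties as a fraction of valid
#'   ones (tagged examiner_directed / personal_experience / metacognitive).
#' @param vocab_size,dim,n_clusters,within_sd Toy lexicon geometry.
#' @param seed Integer seed fixing all randomness.
#' @return A `plt_cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c(PD = 20L, bvFTD = 16L, HC = 26L),
                        concepts = NULL,
                        props_mean = c(PD = 6.3, bvFTD = 6.0, HC = 8.3),
                        props_size = 8,
                        tokens_per_prop_mean = 1.3,
                        d_concreteness = c(PD = 0.78, bvFTD = 0),
                        d_imageability = c(PD = 0.74, bvFTD = 0),
                        d_semantic_variability = c(PD = -1.04, bvFTD = -1.04),
                        base_conc_high = 0.5, base_imag_high = 0.5,
                        base_stay = 0.6,
                        trait_sd_p = 0.10, trait_sd_stay = 0.05,
                        edu_share = 0.3,
                        edu_mean = 12.4, edu_sd = 4.5,
                        invalid_frac = 0.08,
                        vocab_size = 480, dim = 8, n_clusters = 4,
                        within_sd = 0.15,
                        seed = 1) {
  stopifnot(all(group_sizes >= 2), base_stay > 0.5, base_stay < 1)
  stopifnot(all(is.finite(c(d_concreteness, d_imageability, d_semantic_variability))))
  concepts <- concepts %||% plt_stimuli()$word
  structure(list(
    group_sizes = group_sizes, concepts = concepts,
    props_mean = props_mean, props_size = props_size,
    tokens_per_prop_mean = tokens_per_prop_mean,
    d_concreteness = d_concreteness, d_imageability = d_imageability,
    d_semantic_variability = d_semantic_variability,
    base_conc_high = base_conc_high, base_imag_high = base_imag_high,
    base_stay = base_stay, trait_sd_p = trait_sd_p,
    trait_sd_stay = trait_sd_stay, edu_share = edu_share,
    edu_mean = edu_mean, edu_sd = edu_sd, invalid_frac = invalid_frac,
    vocab_size = vocab_size, dim = dim, n_clusters = n_clusters,
    within_sd = within_sd, seed = seed
  ), class = "plt_cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# --- calibration ------------------------------------------------------------

# Monte-Carlo draw of content-token counts per concept under the design
# (truncated negative-binomial property counts, shifted-Poisson lengths).
draw_concept_tokens <- function(spec, group, n = 4000) {
  props <- pmax(1L, rnbinom(n, size = spec$props_size, mu = spec$props_mean[[group]]))
  vapply(props, function(k) k + sum(stats::rpois(k, spec$tokens_per_prop_mean)),
         numeric(1))
}

# Stratum means are 6 (high, uniform 5-7) and 2 (low, uniform 1-3): a token's
# expected norm is 2 + 4p, so a probability shift of dp moves the feature by
# 4*dp. Feature variance has a trait part (4*trait_sd)^2 and a sampling part:
# the participant feature averages per-concept means with very unequal token
# counts, so the sampling term is v_tok * E[1/m] / n_concepts (not v_tok over
# the total count -- E[1/m] is Jensen-inflated by short property lists).
calibrate_strata <- function(spec, d_target, base_p, label) {
  set.seed(derive_seed(spec$seed, paste0("calibrate-strata-", label)))
  v_tok <- base_p * (1 - base_p) * 16 + 1 / 3  # mixture + within-stratum uniform
  inv_m <- vapply(names(spec$props_mean), function(g) {
    mean(1 / draw_concept_tokens(spec, g))
  }, numeric(1))
  sig2 <- (4 * spec$trait_sd_p)^2 + v_tok * inv_m / length(spec$concepts)
  pooled <- sqrt((sig2[c("PD", "bvFTD")] + sig2["HC"]) / 2)
  dp <- d_target[c("PD", "bvFTD")] * pooled / 4
  gamma <- min(sqrt(spec$edu_share * sig2[["HC"]]) / 4, 0.85 * spec$trait_sd_p)
  list(shift = dp, gamma = gamma,
       resid_sd = sqrt(spec$trait_sd_p^2 - gamma^2), sigma_F = sqrt(sig2))
}

# Cluster membership index for calibration chains over the actual lexicon.
cluster_pools <- function(lexicon, clusters) {
  mat <- lexicon$vectors
  list(mat = mat, by_cluster = split(seq_len(nrow(mat)), clusters[rownames(mat)]))
}

# Distance-series variance of one simulated cluster-stay token chain over
# the actual lexicon (consecutive distances share a token, so no iid mixture
# shortcut is taken).
chain_variance <- function(s, m, pools) {
  n_cl <- length(pools$by_cluster)
  cl <- integer(m)
  cur <- sample.int(n_cl, 1)
  stay <- runif(m) < s
  for (t in seq_len(m)) {
    if (!stay[t]) cur <- sample(setdiff(seq_len(n_cl), cur), 1)
    cl[t] <- cur
  }
  tok <- vapply(cl, function(k) {
    p <- pools$by_cluster[[k]]
    p[sample.int(length(p), 1)]
  }, integer(1))
  v <- pools$mat[tok, , drop = FALSE]
  var(1 - rowSums(v[-m, , drop = FALSE] * v[-1, , drop = FALSE]))
}

# Participant-level semantic-variability features for pseudo-participants at
# mean stay probability s_mean: trait noise, design-drawn token counts and
# the real chain process, so mean and SD need no analytic composition.
sim_sv_participants <- function(s_mean, spec, pools, group, n_part,
                                sigma = spec$trait_sd_stay) {
  s_i <- clamp(rnorm(n_part, s_mean, sigma), 0.05, 0.95)
  n_c <- length(spec$concepts)
  vapply(s_i, function(s) {
    m <- pmax(3, round(draw_concept_tokens(spec, group, n = n_c)))
    mean(vapply(m, function(mi) chain_variance(s, mi, pools), numeric(1)))
  }, numeric(1))
}

# Solve the stay-probability shift realizing the target standardized SV
# shift (participant-level Cohen's d), by secant iteration on the simulated
# participant-level response.
calibrate_stay <- function(spec, pools, group) {
  d <- spec$d_semantic_variability[[group]]
  s0 <- spec$base_stay
  set.seed(derive_seed(spec$seed, paste0("calibrate-stay-", group)))
  FH <- sim_sv_participants(s0, spec, pools, "HC", n_part = 150)
  if (d == 0) {
    return(list(shift = 0, sigma_F = sd(FH), secant = NA_real_))
  }
  ds <- 0.10 * sign(-d)
  secant <- NA_real_
  for (iter in 1:2) {
    FP <- sim_sv_participants(clamp(s0 + ds, 0.05, 0.95), spec, pools, group,
                              n_part = 100)
    secant <- (mean(FP) - mean(FH)) / ds
    pooled <- sqrt((var(FH) + var(FP)) / 2)
    ds <- clamp(d * pooled / secant, -(s0 - 0.52), 0.95 - s0)
  }
  list(shift = ds, sigma_F = sd(FH), secant = secant)
}

# --- generation -------------------------------------------------------------

#' Simulate a complete synthetic property-listing dataset
#'
#' Generates the full input bundle — coded transcripts (pre-tagged), norms
#' table, word-vector lexicon, taxonomy edge list and word-node mapping,
#' participant covariates and clinical scores — in the pipeline's input
#' formats, plus a `ground_truth.json` recording every injected parameter.
#' Clinical scores are linear in the participant's latent traits with
#' Gaussian noise, signed to the reported correlation directions (MoCA
#' decreasing in concreteness/imageability; Hayling increasing in the
#' cluster-stay trait, i.e. decreasing in semantic variability).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed); `NULL` returns the
#'   in-memory bundle without writing files.
#' @return Invisibly, a list with `files` (paths or `NULL`), `records`
#'   (transcript tibble), `participants`, `clinical`, `resources` (lexicon,
#'   norms tibble, taxonomy edge/mapping tibbles, word table), and
#'   `ground_truth`.
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "plt_cohort_spec"))

  word_table <- make_word_table(spec$vocab_size, spec$n_clusters, spec$seed)
  toy <- make_toy_lexicon(spec$vocab_size, spec$dim, spec$n_clusters,
                          spec$within_sd, spec$seed, words = word_table$word)
  norms_tbl <- make_toy_norms(word_table, spec$seed)
  taxo <- make_toy_taxonomy(word_table, spec$seed)

  # concept cue words get their own vectors near a home centroid
  set.seed(derive_seed(spec$seed, "concept-vectors"))
  home <- rep_len(seq_len(spec$n_clusters), length(spec$concepts))
  cmat <- toy$centroids[home, , drop = FALSE] +
    matrix(rnorm(length(spec$concepts) * spec$dim, sd = spec$within_sd),
           length(spec$concepts))
  cmat <- cmat / sqrt(rowSums(cmat^2))
  rownames(cmat) <- fold_word(spec$concepts)
  lexicon <- toy$lexicon
  lexicon$vectors <- rbind(lexicon$vectors, cmat)
  clusters <- toy$clusters

  # calibrated effect-injection parameters
  cal_c <- calibrate_strata(spec, spec$d_concreteness, spec$base_conc_high, "conc")
  cal_i <- calibrate_strata(spec, spec$d_imageability, spec$base_imag_high, "imag")
  pools <- cluster_pools(toy$lexicon, clusters)
  cal_s <- list(PD = calibrate_stay(spec, pools, "PD"),
                bvFTD = calibrate_stay(spec, pools, "bvFTD"))
  gamma_s <- min(sqrt(spec$edu_share * (cal_s$PD$sigma_F^2)) /
                   max(abs(cal_s$PD$secant), 1e-9),
                 0.8 * spec$trait_sd_stay)
  if (!is.finite(gamma_s)) gamma_s <- 0
  resid_s <- sqrt(spec$trait_sd_stay^2 - gamma_s^2)
  # education raises semantic variability, i.e. lowers the stay probability
  gamma_s <- -gamma_s

  # participants: education and latent traits
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  set.seed(derive_seed(spec$seed, "participants"))
  edu_mean <- if (length(spec$edu_mean) == 1L) {
    setNames(rep(spec$edu_mean, 3), names(spec$group_sizes))
  } else spec$edu_mean
  education <- round(clamp(rnorm(n, edu_mean[groups], spec$edu_sd), 0, 22))
  z_edu <- (education - mean(unlist(edu_mean))) / spec$edu_sd

  shift_of <- function(cal, g) if (g == "HC") 0 else cal$shift[[g]]
  p_conc <- clamp(spec$base_conc_high +
                    vapply(groups, shift_of, numeric(1), cal = cal_c) -
                    cal_c$gamma * z_edu + rnorm(n, 0, cal_c$resid_sd),
                  0.02, 0.98)
  p_imag <- clamp(spec$base_imag_high +
                    vapply(groups, shift_of, numeric(1), cal = cal_i) -
                    cal_i$gamma * z_edu + rnorm(n, 0, cal_i$resid_sd),
                  0.02, 0.98)
  stay <- clamp(spec$base_stay +
                  vapply(groups, function(g) if (g == "HC") 0 else cal_s[[g]]$shift,
                         numeric(1)) +
                  gamma_s * z_edu + rnorm(n, 0, resid_s),
                0.05, 0.95)

  # token pools by cluster x (conc stratum, imag stratum)
  pool_key <- paste(word_table$cluster,
                    ifelse(word_table$conc_high, "H", "L"),
                    ifelse(word_table$imag_high, "H", "L"), sep = "/")
  pool_idx <- split(seq_len(nrow(word_table)), pool_key)

  set.seed(derive_seed(spec$seed, "transcripts"))
  invalid_tags <- setdiff(VALIDITY_TAGS, "valid")
  rows <- vector("list", n * length(spec$concepts))
  ri <- 0L
  for (i in seq_len(n)) {
    g <- groups[i]
    for (ci in seq_along(spec$concepts)) {
      n_valid <- max(1L, rnbinom(1, size = spec$props_size, mu = spec$props_mean[[g]]))
      lens <- 1L + stats::rpois(n_valid, spec$tokens_per_prop_mean)
      m <- sum(lens)
      # cluster-stay Markov chain, concatenated across the concept's properties
      cl <- integer(m)
      cur <- home[ci]
      for (t in seq_len(m)) {
        if (runif(1) >= stay[i]) {
          cur <- sample(setdiff(seq_len(spec$n_clusters), cur), 1)
        }
        cl[t] <- cur
      }
      strat <- paste(cl,
                     ifelse(runif(m) < p_conc[i], "H", "L"),
                     ifelse(runif(m) < p_imag[i], "H", "L"), sep = "/")
      widx <- vapply(strat, function(k) {
        pool <- pool_idx[[k]]
        pool[sample.int(length(pool), 1)]
      }, integer(1), USE.NAMES = FALSE)
      lemmas <- word_table$word[widx]
      poss <- word_table$pos[widx]
      prop_of <- rep(seq_len(n_valid), lens)

      n_inv <- rbinom(1, n_valid, spec$invalid_frac)
      n_tot <- n_valid + n_inv
      tag_slots <- sample(n_tot, n_inv)
      valid_slots <- setdiff(seq_len(n_tot), tag_slots)

      texts <- tags <- lemseq <- posseq <- character(n_tot)
      for (p in seq_len(n_valid)) {
        sl <- valid_slots[p]
        tk <- which(prop_of == p)
        texts[sl] <- paste(lemmas[tk], collapse = " ")
        tags[sl] <- "valid"
        lemseq[sl] <- paste(lemmas[tk], collapse = ";")
        posseq[sl] <- paste(poss[tk], collapse = ";")
      }
      if (n_inv > 0L) {
        for (sl in tag_slots) {
          wi <- sample(nrow(word_table), 2)
          texts[sl] <- paste(word_table$word[wi], collapse = " ")
          tags[sl] <- sample(invalid_tags, 1)
          lemseq[sl] <- paste(word_table$word[wi], collapse = ";")
          posseq[sl] <- paste(word_table$pos[wi], collapse = ";")
        }
      }
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        participant_id = ids[i], group = g, concept = spec$concepts[ci],
        property_index = seq_len(n_tot), text = texts, validity_tag = tags,
        lemma_seq = lemseq, pos_seq = posseq
      )
    }
  }
  transcripts <- dplyr::bind_rows(rows)

  # clinical scores linked to the latent traits
  set.seed(derive_seed(spec$seed, "clinical"))
  z_pc <- (p_conc - spec$base_conc_high) / spec$trait_sd_p
  z_pi <- (p_imag - spec$base_imag_high) / spec$trait_sd_p
  z_st <- (stay - spec$base_stay) / spec$trait_sd_stay
  moca_base <- c(PD = 20.05, bvFTD = 22.07, HC = 24.33)
  hayling_base <- c(PD = 14.9, bvFTD = 15.8, HC = 8.0)
  moca <- round(clamp(moca_base[groups] - 1.3 * z_pc - 1.3 * z_pi +
                        rnorm(n, 0, 3.2), 0, 30))
  hayling <- round(clamp(hayling_base[groups] + 3.0 * z_st + rnorm(n, 0, 8), 0, 40))
  pdq_total <- ifelse(groups == "PD",
                      round(clamp(rnorm(n, 72.2, 24.7), 0, 156)), NA_real_)
  pdq_mob <- ifelse(groups == "PD",
                    round(clamp(rnorm(n, 19.5, 9.7), 0, 40)), NA_real_)

  participants <- tibble::tibble(participant_id = ids, group = groups,
                                 education = education)
  clinical <- tibble::tibble(participant_id = ids, moca = as.numeric(moca),
                             hayling = as.numeric(hayling),
                             pdq39_total = pdq_total, pdq39_mobility = pdq_mob)

  ground_truth <- list(
    seed = spec$seed,
    group_sizes = as.list(spec$group_sizes),
    effects = list(d_concreteness = as.list(spec$d_concreteness),
                   d_imageability = as.list(spec$d_imageability),
                   d_semantic_variability = as.list(spec$d_semantic_variability)),
    calibration = list(
      conc = list(shift = as.list(cal_c$shift), gamma_edu = cal_c$gamma,
                  sigma_F = as.list(cal_c$sigma_F)),
      imag = list(shift = as.list(cal_i$shift), gamma_edu = cal_i$gamma,
                  sigma_F = as.list(cal_i$sigma_F)),
      stay = list(shift = list(PD = cal_s$PD$shift, bvFTD = cal_s$bvFTD$shift),
                  gamma_edu = gamma_s, sigma_F = cal_s$PD$sigma_F,
                  base = spec$base_stay)
    ),
    traits = list(participant_id = ids, group = groups,
                  education = education, p_conc_high = p_conc,
                  p_imag_high = p_imag, stay = stay)
  )

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      transcripts = file.path(dir, "transcripts.csv"),
      norms = file.path(dir, "norms.csv"),
      vectors = file.path(dir, "vectors.vec"),
      taxonomy_edges = file.path(dir, "taxonomy_edges.tsv"),
      taxonomy_mapping = file.path(dir, "taxonomy_mapping.tsv"),
      participants = file.path(dir, "participants.csv"),
      clinical = file.path(dir, "clinical.csv"),
      ground_truth = file.path(dir, "ground_truth.json")
    )
    readr::write_csv(transcripts, files$transcripts)
    readr::write_csv(norms_tbl, files$norms)
    write_vectors(lexicon, files$vectors)
    readr::write_tsv(taxo$edges, files$taxonomy_edges)
    readr::write_tsv(taxo$mapping, files$taxonomy_mapping)
    readr::write_csv(participants, files$participants)
    readr::write_csv(clinical, files$clinical)
    jsonlite::write_json(ground_truth, files$ground_truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  invisible(list(
    files = files, records = transcripts, participants = participants,
    clinical = clinical,
    resources = list(lexicon = lexicon, norms = norms_tbl,
                     taxonomy_edges = taxo$edges,
                     taxonomy_mapping = taxo$mapping,
                     word_table = word_table, clusters = clusters),
    ground_truth = ground_truth
  ))
}

# In-memory resource coercion used by the pipeline and tests: the generator's
# tibbles, validated through the same loaders as on-disk inputs would be.
load_synthetic_resources <- function(sim, dir = tempfile("pltres")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  norms_path <- file.path(dir, "norms.csv")
  readr::write_csv(sim$resources$norms, norms_path)
  edges_path <- file.path(dir, "edges.tsv")
  map_path <- file.path(dir, "map.tsv")
  readr::write_tsv(sim$resources$taxonomy_edges, edges_path)
  readr::write_tsv(sim$resources$taxonomy_mapping, map_path)
  list(norms = load_norms(norms_path),
       lexicon = sim$resources$lexicon,
       taxonomy = load_taxonomy(edges_path, map_path))
}

#' Feature matrix straight from a simulated cohort
#'
#' Convenience wrapper used by validation experiments: runs the in-memory
#' simulated bundle through the standard ingest and feature modules.
#'
#' @param sim Result of [simulate_cohort()].
#' @param resources Optional pre-loaded resources (from repeated calls with
#'   the same spec geometry).
#' @param ... Passed to [concept_features()].
#' @return A `plt_feature_matrix` tibble.
#' @export
simulated_feature_matrix <- function(sim, resources = NULL, ...) {
  res <- resources %||% load_synthetic_resources(sim)
  records <- sim$records
  records$tokens <- parse_token_columns(records$lemma_seq, records$pos_seq)
  records <- filter_valid(records)
  cf <- concept_features(records, res$norms, res$lexicon, res$taxonomy, ...)
  aggregate_participants(cf, sim$participants)
}
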