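# Group-level inference: IQR outlier fencing, one-way ANCOVA with an
# education covariate, Tukey-Kramer post hocs with Cohen's d, and
# distribution-gated clinical correlations.

#' Fence outliers by a multiple of the interquartile range
#'
#' Retains values x with `Q1 - k*IQR <= x <= Q3 + k*IQR`, with quartiles
#' computed by linear interpolation (type 7) on the full input, in a single
#' pass (no re-fencing after removal). A constant vector has IQR 0 and loses
#' nothing.
#'
#' @param values Numeric vector (>= 4 finite values).
#' @param k Fence multiplier (default 3).
#' @return List with `values` (retained), `removed` (integer indices into the
#'   input), and `fences` (length-2 numeric).
#' @export
remove_outliers <- function(values, k = 3) {
  finite <- is.finite(values)
  if (sum(finite) < 4L) abort_validation("remove_outliers needs at least 4 finite values")
  q <- quantile(values[finite], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  out <- finite & (values < fences[1] | values > fences[2])
  list(values = values[!out], removed = which(out), fences = fences)
}

#' One-way ANCOVA with a single covariate
#'
#' Tests the group factor adjusting for the covariate via the standard
#' linear-model decomposition: the group sum of squares is the residual
#' sum-of-squares drop from adding group to the covariate-only model, and
#' partial eta squared is `SS_group / (SS_group + SS_error)`.
#'
#' @param values Numeric outcome.
#' @param group Group labels (factor or character).
#' @param covariate Numeric covariate (e.g. years of education); `NULL` for a
#'   plain one-way ANOVA.
#' @return List of class `plt_ancova`: `F`, `p`, `eta_p2`, `df` (numerator,
#'   denominator), `ss_group`, `ss_error`, `n`.
#' @export
ancova_oneway <- function(values, group, covariate = NULL) {
  group <- factor(group)
  keep <- is.finite(values) & !is.na(group)
  if (!is.null(covariate)) {
    if (any(!is.finite(covariate[keep]))) abort_validation("covariate must be finite")
    keep <- keep & is.finite(covariate)
  }
  y <- values[keep]; g <- droplevels(group[keep])
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    abort_validation("ancova_oneway needs >= 2 groups with >= 2 observations each")
  }
  if (is.null(covariate)) {
    fit0 <- lm(y ~ 1)
    fit1 <- lm(y ~ g)
  } else {
    x <- covariate[keep]
    fit0 <- lm(y ~ x)
    fit1 <- lm(y ~ x + g)
    # a covariate collinear with the group indicators makes the group
    # effect unidentifiable
    if (fit1$rank < nlevels(g) + 1L) {
      abort_validation("covariate is collinear with the group indicator")
    }
  }
  ss_group <- sum(fit0$residuals^2) - sum(fit1$residuals^2)
  ss_error <- sum(fit1$residuals^2)
  df1 <- nlevels(g) - 1L
  df2 <- fit1$df.residual
  Fstat <- (ss_group / df1) / (ss_error / df2)
  structure(list(
    F = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE),
    eta_p2 = ss_group / (ss_group + ss_error),
    df = c(df1, df2), ss_group = ss_group, ss_error = ss_error,
    n = length(y)
  ), class = "plt_ancova")
}

#' Tukey-Kramer post hoc comparisons with Cohen's d
#'
#' All pairwise group comparisons via the studentized range distribution with
#' unequal-n (Tukey-Kramer) standard errors, plus Cohen's d with the pooled
#' (two-group) SD, uncorrected for small samples. Pairs involving a
#' singleton group are flagged undefined.
#'
#' @param values Numeric outcome.
#' @param group Group labels.
#' @return Tibble with columns `pair`, `diff`, `p`, `d`, `n1`, `n2`.
#' @export
tukey_posthoc_effects <- function(values, group) {
  group <- factor(group)
  keep <- is.finite(values) & !is.na(group)
  y <- values[keep]; g <- droplevels(group[keep])
  lev <- levels(g)
  if (length(lev) < 2L) abort_validation("tukey_posthoc_effects needs >= 2 groups")
  ns <- tapply(y, g, length)
  ms <- tapply(y, g, mean)
  vs <- tapply(y, g, var)
  df_err <- length(y) - length(lev)
  mse <- sum((ns - 1) * vs, na.rm = TRUE) / df_err
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    if (ns[a] < 2L || ns[b] < 2L) {
      return(tibble::tibble(pair = paste(a, b, sep = "-"), diff = NA_real_,
                            p = NA_real_, d = NA_real_,
                            n1 = as.integer(ns[a]), n2 = as.integer(ns[b])))
    }
    dmean <- ms[a] - ms[b]
    se <- sqrt((mse / 2) * (1 / ns[a] + 1 / ns[b]))
    p <- ptukey(abs(dmean) / se, nmeans = length(lev), df = df_err, lower.tail = FALSE)
    sp <- sqrt(((ns[a] - 1) * vs[a] + (ns[b] - 1) * vs[b]) / (ns[a] + ns[b] - 2))
    tibble::tibble(pair = paste(a, b, sep = "-"), diff = unname(dmean), p = unname(p),
                   d = unname(dmean / sp), n1 = as.integer(ns[a]), n2 = as.integer(ns[b]))
  })
}

#' Group comparison for one feature
#'
#' Outlier fencing on the pooled sample, ANCOVA omnibus, and (always
#' computed, flagged by the omnibus) Tukey-Kramer post hocs with Cohen's d.
#'
#' @param values Feature values per participant.
#' @param group Group labels.
#' @param covariate Covariate (education), aligned with `values`.
#' @param k Outlier fence multiplier.
#' @param feature Feature name carried into the result.
#' @return List of class `plt_group_comparison`: `feature`, `omnibus`
#'   (`plt_ancova`), `posthoc` (tibble), `n_removed`, `removed`.
#' @export
compare_groups <- function(values, group, covariate = NULL, k = 3, feature = "feature") {
  fence <- remove_outliers(values, k = k)
  keep <- setdiff(seq_along(values), fence$removed)
  y <- values[keep]; g <- group[keep]
  cv <- if (is.null(covariate)) NULL else covariate[keep]
  omnibus <- ancova_oneway(y, g, cv)
  posthoc <- tukey_posthoc_effects(y, g)
  structure(list(feature = feature, omnibus = omnibus, posthoc = posthoc,
                 n_removed = length(fence$removed), removed = fence$removed),
            class = "plt_group_comparison")
}

#' Feature-wise group comparisons over a feature matrix
#'
#' @param fm A `plt_feature_matrix` tibble.
#' @param covariate Name of the covariate column (default `"education"`;
#'   `NULL` for plain ANOVA).
#' @param k Outlier fence multiplier.
#' @param alpha Significance level used to flag features.
#' @return Tibble with one row per feature: omnibus F, p, partial eta
#'   squared, n removed, significance flag, and a `posthoc` list-column.
#' @export
compare_all_features <- function(fm, covariate = "education", k = 3, alpha = 0.05) {
  cv <- if (is.null(covariate)) NULL else fm[[covariate]]
  purrr::map_dfr(feature_names(), function(f) {
    gc <- compare_groups(fm[[f]], fm$group, cv, k = k, feature = f)
    tibble::tibble(
      feature = f, F = gc$omnibus$F, p = gc$omnibus$p, eta_p2 = gc$omnibus$eta_p2,
      df1 = gc$omnibus$df[1], df2 = gc$omnibus$df[2],
      n_removed = gc$n_removed, significant = gc$omnibus$p < alpha,
      posthoc = list(gc$posthoc)
    )
  })
}

#' Distribution-gated (partial) correlation with a clinical score
#'
#' Normality of both variables is assessed by Shapiro-Wilk at `alpha`;
#' Pearson's r is used when both pass, Spearman's rho otherwise. With a
#' covariate, a partial correlation is computed by residualizing both
#' variables on the covariate (after rank-transforming all three when the
#' gate selects Spearman).
#'
#' @param feature Numeric vector (participant feature values).
#' @param clinical Numeric vector (clinical scores), same length.
#' @param covariate Optional numeric covariate to partial out.
#' @param tandem Label for the pooled sample (e.g. `"PD-HC"`).
#' @param alpha Shapiro-Wilk significance level for the normality gate.
#' @return One-row tibble: `tandem`, `method`, `estimate`, `p`, `n`,
#'   `partial`.
#' @export
correlate_clinical <- function(feature, clinical, covariate = NULL,
                               tandem = NA_character_, alpha = 0.05) {
  keep <- is.finite(feature) & is.finite(clinical)
  if (!is.null(covariate)) keep <- keep & is.finite(covariate)
  x <- feature[keep]; y <- clinical[keep]
  cv <- if (is.null(covariate)) NULL else covariate[keep]
  if (length(x) < 4L) abort_validation("correlate_clinical needs >= 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(tandem = tandem, method = NA_character_,
                          estimate = NA_real_, p = NA_real_, n = length(x),
                          partial = !is.null(cv)))
  }
  normal <- shapiro.test(x)$p.value > alpha && shapiro.test(y)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  if (is.null(cv)) {
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    est <- unname(ct$estimate); p <- ct$p.value
  } else {
    if (method == "spearman") {
      x <- rank(x); y <- rank(y); cv <- rank(cv)
    }
    rx <- lm(x ~ cv)$residuals
    ry <- lm(y ~ cv)$residuals
    ct <- suppressWarnings(cor.test(rx, ry, method = "pearson"))
    est <- unname(ct$estimate); p <- ct$p.value
  }
  tibble::tibble(tandem = tandem, method = method, estimate = est, p = p,
                 n = length(x), partial = !is.null(cv))
}

#' Clinical correlations over patient-control tandems
#'
#' For each feature flagged by the group comparisons and each clinical score,
#' pools the patient group with healthy controls (PD-HC and bvFTD-HC
#' tandems) to increase variance and power, then applies
#' [correlate_clinical()].
#'
#' @param fm A `plt_feature_matrix` tibble.
#' @param clinical Tibble with `participant_id` and clinical score columns.
#' @param features Character vector of feature names to test.
#' @param scores Character vector of clinical column names.
#' @param covariate Optional name of a covariate column in `fm` to partial
#'   out.
#' @param alpha Normality-gate level.
#' @return Tibble with one row per (tandem, feature, score).
#' @export
correlate_tandems <- function(fm, clinical, features, scores,
                              covariate = NULL, alpha = 0.05) {
  dat <- dplyr::left_join(fm, clinical, by = "participant_id")
  tandems <- list("PD-HC" = c("PD", "HC"), "bvFTD-HC" = c("bvFTD", "HC"))
  purrr::map_dfr(names(tandems), function(tn) {
    sub <- dat[dat$group %in% tandems[[tn]], , drop = FALSE]
    purrr::map_dfr(features, function(f) {
      purrr::map_dfr(scores, function(s) {
        cv <- if (is.null(covariate)) NULL else sub[[covariate]]
        n_pairs <- sum(is.finite(sub[[f]]) & is.finite(sub[[s]]))
        res <- if (n_pairs < 4L) {
          # e.g. a patient-only instrument in the other tandem
          tibble::tibble(tandem = tn, method = NA_character_,
                         estimate = NA_real_, p = NA_real_, n = n_pairs,
                         partial = !is.null(cv))
        } else {
          correlate_clinical(sub[[f]], sub[[s]], covariate = cv,
                             tandem = tn, alpha = alpha)
        }
        dplyr::bind_cols(tibble::tibble(feature = f, score = s), res)
      })
    })
  })
}

#' @export
print.plt_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA: F(%d,%d) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$eta_p2))
  invisible(x)
}
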