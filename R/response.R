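# Per-individual glucose response and empirical-Bayes moderated tests.
#
# The response of individual i at gene k is Delta_{i,k} = HG_{i,k} - SG_{i,k}
# after collapsing biological replicates to per-(individual, condition)
# means. Gene-wise variances are shrunk toward a common prior value using
# the standard scaled-inverse-chi-square empirical-Bayes model, giving
# moderated t-statistics with d0 + d degrees of freedom.

#' Filter genes by detection p-values
#'
#' Keeps genes detected (`detection_p < alpha`) in at least
#' `min_fraction` of samples (at minimum one sample). When no detection
#' p-values are attached the input is returned unchanged with a warning.
#'
#' @param expr an `expression_matrix`.
#' @param alpha detection p-value cutoff, default 0.01.
#' @param min_fraction minimum fraction of samples in which a gene must be
#'   detected; the default 0 keeps any gene detected in at least one sample.
#' @return filtered `expression_matrix`.
#' @export
filter_detected_genes <- function(expr, alpha = 0.01, min_fraction = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  check_prob(alpha, "alpha")
  if (min_fraction < 0 || min_fraction > 1) {
    stopf("glucoMR_parameter_error", "min_fraction must be in [0, 1]")
  }
  if (is.null(expr$detection_p)) {
    warning("no detection p-values attached; returning input unchanged")
    return(expr)
  }
  n <- ncol(expr$values)
  need <- max(1L, ceiling(min_fraction * n))
  keep <- rowSums(expr$detection_p < alpha) >= need
  log_msg("info", "detection filter: %d of %d genes retained", sum(keep),
          length(keep))
  expression_matrix(expr$values[keep, , drop = FALSE], expr$samples,
                    expr$detection_p[keep, , drop = FALSE])
}

#' Per-individual glucose response matrix
#'
#' Collapses replicates to per-(individual, condition) means, then computes
#' Delta = mean(HG) - mean(SG) per gene and individual. Individuals missing
#' either condition are dropped with a log entry.
#'
#' @param expr an `expression_matrix`.
#' @return object of class `response_matrix`: list with `delta`
#'   (gene x individual) and `groups` (named character).
#' @export
compute_response <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  s <- expr$samples
  key <- paste(s$individual, s$condition, sep = "|")
  # replicate means per (individual, condition)
  agg <- vapply(split(seq_len(ncol(expr$values)), key), function(ix) {
    rowMeans(expr$values[, ix, drop = FALSE])
  }, numeric(nrow(expr$values)))
  if (!is.matrix(agg)) {           # single-gene input: vapply drops to vector
    agg <- matrix(agg, nrow = 1L,
                  dimnames = list(rownames(expr$values), names(agg)))
  }
  inds <- unique(s$individual)
  has_both <- vapply(inds, function(i)
    all(paste(i, c("SG", "HG"), sep = "|") %in% colnames(agg)), logical(1))
  if (!any(has_both)) {
    stopf("glucoMR_data_error", "no individual has both SG and HG samples")
  }
  if (any(!has_both)) {
    log_msg("info", "dropping %d individual(s) missing a condition: %s",
            sum(!has_both), paste(inds[!has_both], collapse = ", "))
  }
  inds <- inds[has_both]
  delta <- agg[, paste(inds, "HG", sep = "|"), drop = FALSE] -
    agg[, paste(inds, "SG", sep = "|"), drop = FALSE]
  colnames(delta) <- inds
  groups <- s$group[match(inds, s$individual)]
  names(groups) <- inds
  structure(list(delta = delta, groups = groups), class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d genes x %d individuals (%s)\n",
              nrow(x$delta), ncol(x$delta),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

# Newton inversion of the trigamma function: solve trigamma(x) = y.
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < tol) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment-matching on e_g = log(s_g^2): with s_g^2 ~ s0^2 * F(df, d0), the
#' spread of e_g in excess of trigamma(df/2) identifies d0 through
#' trigamma(d0/2), solved by Newton iteration; s0^2 follows from the mean of
#' e_g after digamma corrections. When the observed spread does not exceed
#' the sampling floor, d0 = Inf (complete shrinkage to the common value).
#'
#' @param sample_variances gene-wise residual variances s_g^2.
#' @param residual_df residual degrees of freedom (scalar).
#' @return object of class `moderation_prior`: list with `d0`, `s0_sq`.
#' @export
fit_moderation_prior <- function(sample_variances, residual_df) {
  if (length(residual_df) != 1L || residual_df <= 0) {
    stopf("glucoMR_parameter_error", "residual_df must be a positive scalar")
  }
  s2 <- sample_variances[is.finite(sample_variances) & sample_variances > 0]
  if (length(s2) == 0L) {
    stopf("glucoMR_degenerate_error", "all sample variances are zero")
  }
  if (length(s2) < 10L) {
    stopf("glucoMR_parameter_error",
          "need >= 10 genes with positive variance, got %d", length(s2))
  }
  e <- log(s2)
  df2 <- residual_df / 2
  ebar <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df2)
  if (excess <= 0) {
    # no spread beyond sampling noise: complete shrinkage, and the common
    # value is the geometric mean of the observed variances
    d0 <- Inf
    s0_sq <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar - digamma(df2) + log(df2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

# posterior (moderated) variance; d0 = 0 reduces to s2, d0 = Inf to s0_sq
posterior_var <- function(s2, df, prior) {
  if (is.infinite(prior$d0)) return(rep(prior$s0_sq, length(s2)))
  (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
}

moderated_result <- function(gene_id, effect, s2, df, se_scale, prior) {
  effect <- unname(effect)
  s2 <- unname(s2)
  s2_post <- posterior_var(s2, df, prior)
  df_total <- prior$d0 + df
  tt <- effect / (sqrt(s2_post) * se_scale)
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  out <- data.frame(gene_id = gene_id, log2fc = effect, t = tt,
                    pvalue = p, qvalue = bh_adjust(p), s2_post = s2_post,
                    df_resid = df, df_total = df_total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Moderated one-sample test of the overall glucose response
#'
#' Per gene, tests whether the mean response Delta across all individuals
#' differs from zero: t = mean(Delta) / (s_tilde / sqrt(n)) with
#' s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d) and d0 + d degrees of freedom.
#'
#' @param resp a `response_matrix`.
#' @param prior a `moderation_prior`; fitted from the data when `NULL`.
#' @return data frame with gene_id, log2fc, t, pvalue, qvalue (BH),
#'   s2_post, df_resid, df_total.
#' @export
test_response_all <- function(resp, prior = NULL) {
  stopifnot(inherits(resp, "response_matrix"))
  n <- ncol(resp$delta)
  if (n < 3L) stopf("glucoMR_data_error", "need >= 3 individuals, got %d", n)
  mu <- rowMeans(resp$delta)
  s2 <- apply(resp$delta, 1, stats::var)
  df <- n - 1
  if (is.null(prior)) prior <- fit_moderation_prior(s2, df)
  moderated_result(rownames(resp$delta), mu, s2, df, 1 / sqrt(n), prior)
}

#' Moderated test of group-differential glucose response
#'
#' Unpaired mode (default): two-sample moderated t on Delta between groups
#' with pooled variance. Paired mode: one-sample moderated t on per-pair
#' differences. The reported effect is the difference of mean log2
#' responses, `group_a - group_b`.
#'
#' @param resp a `response_matrix`.
#' @param group_a,group_b group labels (e.g. "PDR" and "nDR").
#' @param prior optional `moderation_prior`; fitted from the data if `NULL`.
#' @param pairing optional named character vector mapping each `group_a`
#'   individual to its matched `group_b` individual; switches to paired mode.
#' @return data frame as in [test_response_all()].
#' @export
test_differential_response <- function(resp, group_a = "PDR", group_b = "nDR",
                                       prior = NULL, pairing = NULL) {
  stopifnot(inherits(resp, "response_matrix"))
  g <- resp$groups
  if (!group_a %in% g || !group_b %in% g) {
    stopf("glucoMR_data_error", "unknown group label(s): %s / %s",
          group_a, group_b)
  }
  a <- names(g)[g == group_a]
  b <- names(g)[g == group_b]
  if (!is.null(pairing)) {
    if (!all(names(pairing) %in% a) || !all(pairing %in% b)) {
      stopf("glucoMR_data_error", "pairing references unknown individuals")
    }
    if (length(pairing) < 3L) {
      stopf("glucoMR_data_error", "need >= 3 pairs, got %d", length(pairing))
    }
    d <- resp$delta[, names(pairing), drop = FALSE] -
      resp$delta[, pairing, drop = FALSE]
    n <- ncol(d)
    mu <- rowMeans(d)
    s2 <- apply(d, 1, stats::var)
    df <- n - 1
    if (is.null(prior)) prior <- fit_moderation_prior(s2, df)
    return(moderated_result(rownames(resp$delta), mu, s2, df, 1 / sqrt(n),
                            prior))
  }
  if (length(a) < 3L || length(b) < 3L) {
    stopf("glucoMR_data_error", "need >= 3 individuals per group (have %d, %d)",
          length(a), length(b))
  }
  da <- resp$delta[, a, drop = FALSE]
  db <- resp$delta[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  eff <- rowMeans(da) - rowMeans(db)
  s2 <- ((na - 1) * apply(da, 1, stats::var) +
           (nb - 1) * apply(db, 1, stats::var)) / (na + nb - 2)
  df <- na + nb - 2
  if (is.null(prior)) prior <- fit_moderation_prior(s2, df)
  moderated_result(rownames(resp$delta), eff, s2, df,
                   sqrt(1 / na + 1 / nb), prior)
}

#' Inter- vs intra-individual response variability test
#'
#' Builds replicate-level response profiles by pairing HG replicate r with
#' SG replicate r within each individual, computes all pairwise Pearson
#' correlations between profiles, and compares within-individual versus
#' between-individual correlations with a one-sided Wilcoxon rank-sum test
#' (within greater). A small p-value indicates that an individual's response
#' is reproducible across replicates relative to other individuals, i.e.
#' interindividual response variance exceeds the intraindividual one.
#'
#' @param expr an `expression_matrix` with >= 2 replicates per condition for
#'   >= 2 individuals.
#' @return list with `statistic` (Wilcoxon W), `p.value`, `n_within`,
#'   `n_between`.
#' @export
interindividual_variance_test <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  s <- expr$samples
  inds <- unique(s$individual)
  profiles <- list()
  owner <- character(0)
  for (i in inds) {
    hg <- s$sample_id[s$individual == i & s$condition == "HG"]
    sg <- s$sample_id[s$individual == i & s$condition == "SG"]
    k <- min(length(hg), length(sg))
    if (k < 2L) next
    hg <- sort(hg); sg <- sort(sg)
    for (r in seq_len(k)) {
      profiles[[length(profiles) + 1L]] <-
        expr$values[, hg[r]] - expr$values[, sg[r]]
      owner <- c(owner, i)
    }
  }
  if (length(unique(owner)) < 2L) {
    stopf("glucoMR_data_error",
          "need >= 2 replicates per condition for >= 2 individuals")
  }
  P <- do.call(cbind, profiles)
  cm <- stats::cor(P)
  same <- outer(owner, owner, "==")
  ut <- upper.tri(cm)
  within <- cm[ut & same]
  between <- cm[ut & !same]
  wt <- stats::wilcox.test(within, between, alternative = "greater",
                           exact = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_within = length(within), n_between = length(between))
}

#' Associate response principal components with covariates
#'
#' PCA of the gene x individual response matrix (genes centered); each of
#' the first `k` PCs is tested against each covariate by linear model
#' (numeric covariates) or one-way ANOVA (categorical). Covariates with a
#' single level are skipped with a warning.
#'
#' @param resp a `response_matrix`.
#' @param covariates data frame (or list) of per-individual covariates,
#'   aligned to `colnames(resp$delta)` by rownames/names when present.
#' @param k number of PCs to test (default 5, capped by availability).
#' @return data frame with columns PC, covariate, p.
#' @export
pca_covariate_association <- function(resp, covariates, k = 5L) {
  stopifnot(inherits(resp, "response_matrix"))
  n <- ncol(resp$delta)
  if (n < 3L) stopf("glucoMR_data_error", "need >= 3 individuals")
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (!is.null(rownames(covariates)) &&
      all(colnames(resp$delta) %in% rownames(covariates))) {
    covariates <- covariates[colnames(resp$delta), , drop = FALSE]
  } else if (nrow(covariates) != n) {
    stopf("glucoMR_data_error", "covariates not aligned to individuals")
  }
  pc <- stats::prcomp(t(resp$delta), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x), n - 1L)
  out <- list()
  for (cv in names(covariates)) {
    v <- covariates[[cv]]
    if (length(unique(v)) < 2L) {
      warning(sprintf("covariate '%s' has a single level; skipped", cv))
      next
    }
    for (j in seq_len(k)) {
      y <- pc$x[, j]
      p <- if (is.numeric(v)) {
        f <- stats::lm(y ~ v)
        stats::anova(f)[["Pr(>F)"]][1]
      } else {
        f <- stats::aov(y ~ factor(v))
        summary(f)[[1]][["Pr(>F)"]][1]
      }
      out[[length(out) + 1L]] <- data.frame(PC = j, covariate = cv, p = p,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(PC = integer(0), covariate = character(0),
                      p = numeric(0)))
  }
  do.call(rbind, out)
}
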