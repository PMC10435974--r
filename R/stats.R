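#' ln(x + 1) transform
#'
#' The standard variance-stabilizing transform applied to nematode
#' abundances before ANOVA.
#'
#' @param x Non-negative values.
#' @return `log(x + 1)` (computed as `log1p`).
#' @export
ln_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    nf_error("abundances must be non-negative", "nemafauna_domain_error")
  }
  log1p(x)
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance,
#' `F = MSB / MSW` on `(k - 1, N - k)` degrees of freedom, fitted via
#' [stats::aov()].
#'
#' @param x Numeric response vector.
#' @param g Group labels (coerced to factor); at least 2 groups with at
#'   least 2 observations each.
#' @return An `anova_result` list: `F`, `df_between`, `df_within`, `p`,
#'   `group_means`, `group_n`, `MSW` (the within-group mean square, needed
#'   by [duncan_mrt()]).
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(x, g) {
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- droplevels(as.factor(g[keep]))
  sizes <- table(g)
  if (nlevels(g) < 2L || any(sizes < 2L)) {
    nf_error(
      "one-way ANOVA needs >= 2 groups with >= 2 observations each",
      "nemafauna_domain_error"
    )
  }
  if (all(tapply(x, g, stats::var) == 0)) {
    nf_error(
      "zero within-group variance in every group; F statistic undefined",
      "nemafauna_domain_error"
    )
  }
  fit <- stats::aov(x ~ g)
  tab <- summary(fit)[[1L]]
  gm <- tapply(x, g, mean)
  structure(
    list(
      F = tab[1L, "F value"],
      df_between = tab[1L, "Df"],
      df_within = tab["Residuals", "Df"],
      p = tab[1L, "Pr(>F)"],
      group_means = setNames(as.numeric(gm), names(gm)),
      group_n = as.integer(sizes),
      MSW = tab["Residuals", "Mean Sq"]
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$df_between, x$df_within, x$F, x$p
  ))
  invisible(x)
}

#' Duncan's multiple range test with letter display
#'
#' Stepwise studentized-range post hoc test. Group means are sorted in
#' descending order; two means `p` positions apart are compared against the
#' least significant range
#' `R_p = q(1 - alpha_p, p, df_within) * sqrt(MSW / n_h)`, where `q` is the
#' studentized-range quantile, `alpha_p = 1 - (1 - alpha)^(p - 1)` is
#' Duncan's protection level, and `n_h` the harmonic mean of the group
#' sizes (the exact common size when groups are balanced). A difference is
#' declared non-significant if its own range fails, or if it lies inside
#' any wider range that failed; letters then mark the maximal runs of
#' mutually non-separated means, `a` starting at the largest mean.
#'
#' For two groups `alpha_2 = alpha` and the decision coincides with
#' Fisher's LSD. Quantiles come from [stats::qtukey()], not printed tables.
#'
#' @param x Numeric response vector.
#' @param g Group labels.
#' @param alpha Significance level (default 0.05).
#' @return A `duncan_mrt` list: `letters` (named character vector, one
#'   letter string per group, ordered by descending mean), `means`,
#'   `anova` (the underlying [one_way_anova()] result), `ranges` (the
#'   critical values `R_p` by span), `alpha`.
#' @examples
#' set.seed(1)
#' y <- c(rnorm(3, 10), rnorm(3, 10.2), rnorm(3, 15))
#' duncan_mrt(y, rep(c("CK", "C2", "C4"), each = 3))$letters
#' @export
duncan_mrt <- function(x, g, alpha = 0.05) {
  fit <- one_way_anova(x, g)
  means <- sort(fit$group_means, decreasing = TRUE)
  k <- length(means)
  nh <- length(fit$group_n) / sum(1 / fit$group_n) # harmonic mean
  spans <- 2:max(2L, k)
  ranges <- vapply(spans, function(p) {
    stats::qtukey((1 - alpha)^(p - 1), p, fit$df_within) *
      sqrt(fit$MSW / nh)
  }, numeric(1))
  names(ranges) <- spans
  nonsig <- duncan_nonsig(as.numeric(means), ranges)
  letters <- range_letters(nonsig)
  names(letters) <- names(means)
  structure(
    list(
      letters = letters, means = means, anova = fit,
      ranges = ranges, alpha = alpha
    ),
    class = "duncan_mrt"
  )
}

# Non-significance matrix for means sorted in descending order, under the
# protection rule: a pair is not separated if its own range test fails or
# if it is contained in a wider pair that is not separated.
duncan_nonsig <- function(means, ranges) {
  k <- length(means)
  nonsig <- diag(TRUE, k)
  if (k < 2L) {
    return(nonsig)
  }
  for (p in k:2) { # widest spans first so containment propagates
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      fails_own <- (means[i] - means[j]) <= ranges[[as.character(p)]]
      contained <- FALSE
      if (p < k) {
        if (i > 1L && nonsig[i - 1L, j]) contained <- TRUE
        if (j < k && nonsig[i, j + 1L]) contained <- TRUE
      }
      if (fails_own || contained) {
        nonsig[i, j] <- nonsig[j, i] <- TRUE
      }
    }
  }
  nonsig
}

# Letter display from an interval-closed non-significance matrix over
# descending-sorted means: maximal all-non-significant runs become letters.
range_letters <- function(nonsig) {
  k <- nrow(nonsig)
  reach <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    j
  }, integer(1))
  out <- character(k)
  letter <- 0L
  last_end <- 0L
  for (i in seq_len(k)) {
    if (reach[i] > last_end) { # maximal run not covered by a previous letter
      letter <- letter + 1L
      idx <- i:reach[i]
      out[idx] <- paste0(out[idx], letters[letter])
      last_end <- reach[i]
    }
  }
  out
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf(
    "Duncan's multiple range test (alpha = %g)\n", x$alpha
  ))
  df <- data.frame(
    group = names(x$means), mean = as.numeric(x$means),
    letters = unname(x$letters)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum(|x_ik - x_jk|) / sum(x_ik + x_jk)` over genera `k`,
#' computed with [vegan::vegdist()]. Values lie in `[0, 1]` for
#' non-negative data; a pair of all-zero samples has no defined
#' dissimilarity and triggers an error.
#'
#' @param comm Community matrix, genera in rows, samples in columns (>= 2).
#' @return A [stats::dist] object over samples.
#' @export
bray_curtis <- function(comm) {
  if (ncol(comm) < 2L) {
    nf_error("need at least 2 samples", "nemafauna_domain_error")
  }
  if (any(colSums(comm) == 0)) {
    nf_error(
      "all-zero sample(s): Bray-Curtis dissimilarity undefined",
      "nemafauna_domain_error"
    )
  }
  vegan::vegdist(t(comm), method = "bray")
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric multidimensional scaling: the squared dissimilarities
#' are double-centred (Gower) and eigendecomposed; coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but excluded from the coordinates, and the
#' explained fractions are taken over the positive eigenvalues;
#' `correction = "lingoes"` instead adds the Lingoes constant to the
#' off-diagonal squared dissimilarities to make the matrix Euclidean.
#'
#' @param d A [stats::dist] object or square symmetric matrix with zero
#'   diagonal and non-negative entries.
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return A `pcoa_result` list: `coordinates` (samples x axes,
#'   `Axis1`, `Axis2`, ...), `eigenvalues` (all, descending), `explained`
#'   (fraction per retained axis), `correction`, `negative_sum` (sum of
#'   negative eigenvalues before any correction).
#' @export
pcoa <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    nf_error("distance matrix must be square and symmetric",
      "nemafauna_validation_error")
  }
  if (any(diag(D) != 0) || any(D < 0)) {
    nf_error("distances must be non-negative with a zero diagonal",
      "nemafauna_validation_error")
  }
  n <- nrow(D)
  eig0 <- gower_eigen(D)
  negative_sum <- sum(eig0$values[eig0$values < 0])
  if (correction == "lingoes" && negative_sum < 0) {
    c1 <- -min(eig0$values)
    D2 <- D^2 + 2 * c1
    diag(D2) <- 0
    eig0 <- gower_eigen(sqrt(D2))
  }
  vals <- eig0$values
  tol <- max(abs(vals)) * sqrt(.Machine$double.eps)
  pos <- which(vals > tol)
  coords <- eig0$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  colnames(coords) <- paste0("Axis", seq_along(pos))
  rownames(coords) <- rownames(D)
  structure(
    list(
      coordinates = coords,
      eigenvalues = vals,
      explained = vals[pos] / sum(vals[pos]),
      correction = correction,
      negative_sum = negative_sum
    ),
    class = "pcoa_result"
  )
}

gower_eigen <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eigen((G + t(G)) / 2, symmetric = TRUE)
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf(
    "PCoA: %d positive axes; axis 1-2 explain %s%% (correction: %s)\n",
    ncol(x$coordinates),
    paste(round(100 * x$explained[seq_len(min(2, length(x$explained)))], 2),
      collapse = " + "
    ),
    x$correction
  ))
  invisible(x)
}

#' Permutation Mantel test
#'
#' Correlation between the lower triangles of two distance matrices, with
#' significance from permutations of the object labels of the second
#' matrix. The p-value is one-sided for positive association: one plus the
#' number of permuted statistics at least as large as the observed one,
#' divided by `n_perm + 1` — so its floor is `1 / (n_perm + 1)`. Spearman
#' (default, rank-based as for the network edge tests) or Pearson
#' correlation.
#'
#' @param d1,d2 Conformable square symmetric matrices or [stats::dist]
#'   objects over the same >= 4 objects.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer making the permutation stream reproducible;
#'   the global RNG state is restored afterwards.
#' @return A `mantel_result` list: `r`, `p`, `n_perm`, `method`, `n` (number
#'   of objects).
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999L, seed = NULL) {
  method <- match.arg(method)
  M1 <- as.matrix(d1)
  M2 <- as.matrix(d2)
  if (!identical(dim(M1), dim(M2)) || nrow(M1) != ncol(M1)) {
    nf_error("distance matrices must be square and conformable",
      "nemafauna_validation_error")
  }
  n <- nrow(M1)
  if (n < 4L) {
    nf_error("Mantel test needs at least 4 objects", "nemafauna_domain_error")
  }
  lower <- which(lower.tri(M1), arr.ind = TRUE)
  ii <- lower[, 1L]
  jj <- lower[, 2L]
  v1 <- M1[lower]
  v2 <- M2[lower]
  if (method == "spearman") {
    v1 <- rank(v1)
    v2 <- rank(v2)
    # Symmetric matrix of triangle ranks: label permutations rearrange the
    # same multiset of entries, so ranks can be permuted by indexing.
    S2 <- matrix(0, n, n)
    S2[lower] <- v2
    S2 <- S2 + t(S2)
  } else {
    S2 <- M2
  }
  r_obs <- stats::cor(v1, v2)
  # Means/sds of both triangles are permutation-invariant, so only the dot
  # product varies across permutations.
  c1 <- v1 - mean(v1)
  obs_dot <- sum(c1 * v2)
  perm_dot <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pi <- sample.int(n)
      sum(c1 * S2[cbind(pi[ii], pi[jj])])
    }, numeric(1))
  })
  count <- sum(perm_dot >= obs_dot - 1e-12 * max(1, abs(obs_dot)))
  structure(
    list(
      r = r_obs,
      p = (1 + count) / (n_perm + 1),
      n_perm = n_perm,
      method = method,
      n = n
    ),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test (%s, %d objects): r = %.4f, p = %.4g (%d permutations)\n",
    x$method, x$n, x$r, x$p, x$n_perm
  ))
  invisible(x)
}

#' Euclidean distances on standardized covariates
#'
#' Builds the covariate distance matrix conventionally paired with a
#' community dissimilarity in a Mantel test: each covariate column is
#' centred and scaled to unit variance, then Euclidean distances are taken
#' between samples.
#'
#' @param metadata Data frame of samples; `columns` selects the covariates.
#' @param columns Character vector of covariate column names (default: all
#'   numeric columns except `replicate` and `dry_mass_g`).
#' @return A [stats::dist] object over samples.
#' @export
covariate_distance <- function(metadata, columns = NULL) {
  if (is.null(columns)) {
    numcols <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
    columns <- setdiff(numcols, c("replicate", "dry_mass_g"))
  }
  miss <- setdiff(columns, names(metadata))
  if (length(miss) > 0) {
    nf_error(
      sprintf("covariate column(s) not found: %s", paste(miss, collapse = ", ")),
      "nemafauna_format_error"
    )
  }
  m <- scale(as.matrix(metadata[, columns, drop = FALSE]))
  m[, attr(m, "scaled:scale") == 0] <- 0 # constant covariates carry nothing
  d <- stats::dist(m)
  attr(d, "Labels") <- if ("sample_id" %in% names(metadata)) {
    metadata$sample_id
  } else {
    rownames(metadata)
  }
  d
}
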