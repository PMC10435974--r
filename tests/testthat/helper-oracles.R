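# Independent literal-loop oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: every quantity is accumulated
# taxon by taxon from first definitions.

make_traits <- function(genus, group, cp, w = 1, predator = FALSE) {
  df <- data.frame(
    genus = genus,
    trophic_group = group,
    cp_value = as.integer(cp),
    fresh_weight_ug = rep_len(w, length(genus)),
    predator = rep_len(predator, length(genus)),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("trait_table", "data.frame"))
}

oracle_trait_row <- function(traits, genus) {
  row <- traits[tolower(traits$genus) == tolower(genus), , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  row
}

oracle_weighted_cp <- function(x, traits, groups, cp_min = 1) {
  num <- 0
  den <- 0
  for (g in names(x)) {
    tr <- oracle_trait_row(traits, g)
    if (tr$trophic_group %in% groups && tr$cp_value >= cp_min) {
      num <- num + tr$cp_value * x[[g]]
      den <- den + x[[g]]
    }
  }
  if (den <= 0) {
    return(NA_real_)
  }
  num / den
}

oracle_group_sums <- function(x, traits) {
  out <- c(Ba = 0, Fu = 0, Pp = 0, Op = 0)
  for (g in names(x)) {
    tr <- oracle_trait_row(traits, g)
    out[tr$trophic_group] <- out[tr$trophic_group] + x[[g]]
  }
  out
}

oracle_components <- function(x, traits) {
  e <- 0
  b <- 0
  s <- 0
  struct_w <- c("3" = 1.8, "4" = 3.2, "5" = 5.0)
  for (g in names(x)) {
    tr <- oracle_trait_row(traits, g)
    a <- x[[g]]
    if (tr$trophic_group == "Ba" && tr$cp_value == 1) e <- e + 3.2 * a
    if (tr$trophic_group == "Fu" && tr$cp_value == 2) e <- e + 0.8 * a
    if (tr$trophic_group == "Ba" && tr$cp_value == 2) b <- b + 0.8 * a
    if (tr$trophic_group == "Fu" && tr$cp_value == 2) b <- b + 0.8 * a
    if (tr$trophic_group %in% c("Ba", "Fu", "Op") && tr$cp_value >= 3) {
      s <- s + struct_w[[as.character(tr$cp_value)]] * a
    }
    if (isTRUE(tr$predator) && tr$cp_value == 2) s <- s + 0.8 * a
  }
  c(e = e, b = b, s = s)
}

oracle_footprint <- function(x, traits) {
  total <- 0
  by_group <- c(Ba = 0, Fu = 0, Pp = 0, Op = 0)
  fe <- 0
  fs <- 0
  for (g in names(x)) {
    tr <- oracle_trait_row(traits, g)
    f <- x[[g]] *
      (0.1 * tr$fresh_weight_ug / tr$cp_value +
        0.273 * tr$fresh_weight_ug^0.75)
    total <- total + f
    by_group[tr$trophic_group] <- by_group[tr$trophic_group] + f
    if (tr$cp_value <= 2) fe <- fe + f else fs <- fs + f
  }
  list(NMF = total, by_group = by_group, Fe = fe, Fs = fs)
}

# A random community sample over the packaged trait fixture: a random subset
# of genera with lognormal abundances. Some draws drop whole trophic groups,
# exercising the undefined-index (NA) paths.
random_sample <- function(traits) {
  n <- sample(3:nrow(traits), 1L)
  genera <- sample(traits$genus, n)
  stats::setNames(round(stats::rlnorm(n, meanlog = 3, sdlog = 1), 3), genera)
}

# Spearman correlation from first definitions: mid-ranks by counting, then
# the Pearson formula accumulated elementwise.
oracle_rank <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v)) {
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Duncan separation oracle: a pair of sorted means (i < j, descending order)
# is significantly separated iff EVERY range containing it (including
# itself) exceeds its critical value.
oracle_duncan_separated <- function(means_sorted, ranges) {
  k <- length(means_sorted)
  sep <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- TRUE
      for (a in seq_len(i)) {
        for (b in j:k) {
          p <- b - a + 1
          if (means_sorted[a] - means_sorted[b] <= ranges[[as.character(p)]]) {
            ok <- FALSE
          }
        }
      }
      sep[i, j] <- sep[j, i] <- ok
    }
  }
  sep
}

# Orthogonal Procrustes residual from first principles: centre both
# configurations, find the optimal rotation/reflection by SVD, and return
# the root sum of squared residuals.
oracle_procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$v %*% t(s$u)
  sqrt(sum((Yc %*% R - Xc)^2))
}

# Fisher's LSD decision for two groups from first principles.
oracle_lsd_separated <- function(x, g, alpha = 0.05) {
  g <- as.factor(g)
  stopifnot(nlevels(g) == 2L)
  sp <- split(x, g)
  n1 <- length(sp[[1]])
  n2 <- length(sp[[2]])
  df <- n1 + n2 - 2
  msw <- (sum((sp[[1]] - mean(sp[[1]]))^2) + sum((sp[[2]] - mean(sp[[2]]))^2)) / df
  tcrit <- stats::qt(1 - alpha / 2, df)
  abs(mean(sp[[1]]) - mean(sp[[2]])) > tcrit * sqrt(msw * (1 / n1 + 1 / n2))
}

# TRUE iff two groups share at least one letter in a letter display.
shares_letter <- function(letters_vec, g1, g2) {
  a <- strsplit(letters_vec[[g1]], "")[[1]]
  b <- strsplit(letters_vec[[g2]], "")[[1]]
  length(intersect(a, b)) > 0
}
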