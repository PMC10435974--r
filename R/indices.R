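#' Default guild weights for the enrichment/structure indices
#'
#' The enrichment index (EI) and structure index (SI) weight functional
#' guilds — (trophic group, c-p class) combinations — before summing them
#' into the enrichment (e), basal (b) and structure (s) components:
#'
#' * enrichment `e`: Ba1 (weight 3.2) and Fu2 (0.8);
#' * basal `b`: Ba2 and Fu2 (both 0.8);
#' * structure `s`: Ba3-5, Fu3-5 and Op3-5 at weights 1.8 (c-p 3),
#'   3.2 (c-p 4) and 5.0 (c-p 5), plus predatory c-p 2 taxa
#'   (trait-table `predator` flag) at 0.8.
#'
#' These are the canonical faunal-profile weights. Note that Fu2
#' deliberately contributes to *both* `e` and `b`, following the standard
#' definition of the faunal profile. Override any weight with
#' [load_guild_weights()] or by editing the returned data frame.
#'
#' @return Data frame with columns `component` (`"e"`, `"b"`, `"s"`),
#'   `group` (`"Ba"`, `"Fu"`, `"Op"` or `"pred"` for the predator flag),
#'   `cp` and `weight`.
#' @export
default_guild_weights <- function() {
  rbind(
    data.frame(
      component = "e", group = c("Ba", "Fu"), cp = c(1L, 2L),
      weight = c(3.2, 0.8)
    ),
    data.frame(
      component = "b", group = c("Ba", "Fu"), cp = c(2L, 2L),
      weight = c(0.8, 0.8)
    ),
    data.frame(
      component = "s",
      group = c(rep(c("Ba", "Fu", "Op"), each = 3L), "pred"),
      cp = c(rep(3:5, times = 3L), 2L),
      weight = c(rep(c(1.8, 3.2, 5.0), times = 3L), 0.8)
    )
  )
}

#' Load guild weights from a delimited file
#'
#' Columns `component`, `group`, `cp`, `weight`; same semantics as
#' [default_guild_weights()].
#'
#' @param path Path to the file.
#' @return A guild-weight data frame.
#' @export
load_guild_weights <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = detect_sep(path), comment.char = "#",
    stringsAsFactors = FALSE
  )
  required <- c("component", "group", "cp", "weight")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    nf_error(
      sprintf(
        "guild weight table missing column(s): %s",
        paste(missing, collapse = ", ")
      ),
      "nemafauna_format_error"
    )
  }
  if (any(df$weight <= 0)) {
    nf_error("guild weights must be positive", "nemafauna_validation_error")
  }
  df[, required]
}

#' Maturity index (MI)
#'
#' Abundance-weighted mean c-p value of the free-living nematodes (Ba, Fu,
#' Op): `MI = sum(v_i * f_i)` where `v_i` is the c-p value of taxon `i` and
#' `f_i` its proportion of the total free-living abundance. Low MI indicates
#' a disturbed, enrichment-dominated community; high MI a stable one. By
#' default all c-p classes (1-5) enter; `cp_min = 2` gives the MI(2-5)
#' variant that drops the enrichment opportunists.
#'
#' @param x Named genus-abundance vector for one sample.
#' @param traits A `trait_table`.
#' @param cp_min Minimum c-p class included (1 by default).
#' @return MI in `[1, 5]`, or `NA_real_` if the sample holds no free-living
#'   individuals in the included c-p range (undefined, never coerced to 0).
#' @examples
#' maturity_index(
#'   c(Rhabditis = 40, Acrobeloides = 40, Eudorylaimus = 20),
#'   default_traits()
#' ) # 1*0.4 + 2*0.4 + 4*0.2 = 2
#' @export
maturity_index <- function(x, traits, cp_min = 1L) {
  weighted_cp_mean(x, traits, groups = FREE_LIVING_GROUPS, cp_min = cp_min)
}

#' Plant-parasite index (PPI)
#'
#' The same c-p weighted mean as [maturity_index()], restricted to
#' plant-parasitic (Pp) taxa with proportions normalized within the Pp
#' abundance.
#'
#' @inheritParams maturity_index
#' @return PPI in `[1, 5]`, or `NA_real_` when no plant parasites occur.
#' @export
plant_parasite_index <- function(x, traits, cp_min = 1L) {
  weighted_cp_mean(x, traits, groups = "Pp", cp_min = cp_min)
}

weighted_cp_mean <- function(x, traits, groups, cp_min) {
  if (length(x) == 0L) {
    return(NA_real_)
  }
  idx <- resolve_genera(traits, names(x))
  keep <- traits$trophic_group[idx] %in% groups & traits$cp_value[idx] >= cp_min
  a <- as.numeric(x)[keep]
  tot <- sum(a)
  if (tot <= 0) {
    return(NA_real_)
  }
  sum(traits$cp_value[idx][keep] * a) / tot
}

#' Wasilewska index (WI)
#'
#' `(Ba + Fu) / Pp`: the ratio of microbial-feeding to plant-feeding
#' nematode abundance, an indirect descriptor of the organic-matter
#' mineralization pathway.
#'
#' @param Ba,Fu,Pp Trophic-group abundances (see [aggregate_trophic()]).
#' @return WI (>= 0), or `NA_real_` when `Pp` is 0 (undefined).
#' @export
wasilewska_index <- function(Ba, Fu, Pp) {
  ifelse(Pp > 0, (Ba + Fu) / Pp, NA_real_)
}

#' Nematode channel ratio (NCR)
#'
#' `Ba / (Ba + Fu)`: the share of the bacterial decomposition channel; 1 is
#' a purely bacterial channel, 0 purely fungal.
#'
#' @param Ba,Fu Trophic-group abundances.
#' @return NCR in `[0, 1]`, or `NA_real_` when `Ba + Fu` is 0.
#' @export
nematode_channel_ratio <- function(Ba, Fu) {
  ifelse(Ba + Fu > 0, Ba / (Ba + Fu), NA_real_)
}

#' Enrichment, basal and structure components
#'
#' Computes the weighted guild sums `e`, `b` and `s` that the enrichment and
#' structure indices are built from (see [default_guild_weights()] for the
#' guild membership and weights). A genus enters the predator (`"pred"`)
#' structure guild when its trait-table `predator` flag is set and its c-p
#' value matches; Op taxa of c-p 3-5 enter the structure component through
#' the Op guilds.
#'
#' @param x Named genus-abundance vector for one sample.
#' @param traits A `trait_table`.
#' @param weights Guild-weight data frame (default
#'   [default_guild_weights()]).
#' @return Numeric vector `c(e = , b = , s = )`.
#' @export
enrichment_structure_components <- function(x, traits,
                                            weights = default_guild_weights()) {
  out <- c(e = 0, b = 0, s = 0)
  if (length(x) == 0L) {
    return(out)
  }
  idx <- resolve_genera(traits, names(x))
  a <- as.numeric(x)
  grp <- traits$trophic_group[idx]
  cp <- traits$cp_value[idx]
  pred <- traits$predator[idx]
  for (r in seq_len(nrow(weights))) {
    comp <- weights$component[r]
    if (weights$group[r] == "pred") {
      sel <- pred & cp == weights$cp[r]
    } else {
      sel <- grp == weights$group[r] & cp == weights$cp[r]
    }
    out[comp] <- out[comp] + weights$weight[r] * sum(a[sel])
  }
  out
}

#' Enrichment index (EI) and structure index (SI)
#'
#' `EI = 100 * e / (e + b)` and `SI = 100 * s / (s + b)`. EI tracks
#' nutrient enrichment (opportunist response); SI tracks food-web structure
#' (persistence of higher c-p taxa). Both live in `[0, 100]` and together
#' locate a sample in the faunal profile (see [classify_quadrat()]).
#'
#' @param e,b,s Component values from
#'   [enrichment_structure_components()].
#' @return The index value, or `NA_real_` when its denominator is 0.
#' @examples
#' enrichment_index(e = 40, b = 16) # 71.43
#' @export
enrichment_index <- function(e, b) {
  ifelse(e + b > 0, 100 * e / (e + b), NA_real_)
}

#' @rdname enrichment_index
#' @export
structure_index <- function(s, b) {
  ifelse(s + b > 0, 100 * s / (s + b), NA_real_)
}

#' All ecological indices for every sample of a community table
#'
#' Convenience wrapper computing MI, PPI, WI, NCR, EI, SI and the e/b/s
#' components per sample. Undefined indices (zero denominators) are `NA`,
#' never 0, and should be excluded from downstream testing.
#'
#' @param comm Community matrix, genera in rows, samples in columns.
#' @param traits A `trait_table`.
#' @param weights Guild weights (default [default_guild_weights()]).
#' @param cp_min Minimum c-p class for MI (see [maturity_index()]).
#' @return Data frame with one row per sample and columns `sample_id`, `MI`,
#'   `PPI`, `WI`, `NCR`, `EI`, `SI`, `e`, `b`, `s`.
#' @export
nema_indices <- function(comm, traits, weights = default_guild_weights(),
                         cp_min = 1L) {
  samples <- colnames(comm)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(comm)))
  rows <- lapply(seq_len(ncol(comm)), function(j) {
    x <- comm[, j]
    x <- x[x > 0]
    groups <- aggregate_trophic(x, traits)
    ebs <- enrichment_structure_components(x, traits, weights)
    data.frame(
      sample_id = samples[j],
      MI = maturity_index(x, traits, cp_min = cp_min),
      PPI = plant_parasite_index(x, traits),
      WI = wasilewska_index(groups[["Ba"]], groups[["Fu"]], groups[["Pp"]]),
      NCR = nematode_channel_ratio(groups[["Ba"]], groups[["Fu"]]),
      EI = enrichment_index(ebs[["e"]], ebs[["b"]]),
      SI = structure_index(ebs[["s"]], ebs[["b"]]),
      e = ebs[["e"]], b = ebs[["b"]], s = ebs[["s"]]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
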