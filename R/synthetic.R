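#' Scenario configuration for the synthetic community generator
#'
#' Bundles everything the generator needs to emulate a replicated
#' cover-crop field design: four treatments (no cover crop `CK`, and two-,
#' four- and eight-species mixtures `C2`/`C4`/`C8`) with three plots each,
#' a 46-genus pool (19 bacterivores, 6 fungivores, 9 plant parasites, 12
#' omnivores/predators — the composition of a typical orchard survey),
#' negative-binomial abundance noise around per-genus baselines,
#' multiplicative treatment effects per trophic group, a plot-level
#' lognormal heterogeneity factor, a 100-individual identification
#' subsample, and a soil-covariate model coupled to the trophic-group
#' abundances.
#'
#' Default treatment effects plant the qualitative field pattern the
#' pipeline is meant to detect: fungivores x1.6 under C4 and C8, plant
#' parasites x1.5 under C2 and C8, bacterivores x1.5 under C4 (x1.2 under
#' C2/C8), omnivores/predators mildly elevated (x1.15) under C4/C8 — so
#' total abundance is elevated under every cover treatment.
#'
#' @param treatments Ordered treatment labels.
#' @param replicates Plots per treatment (>= 2).
#' @param traits Trait table defining the genus pool.
#' @param baseline Named per-genus baseline mean abundance (individuals per
#'   100 g dry soil) under `CK`; defaults to a community of ~760
#'   individuals per 100 g dominated by Aphelenchoides, Eucephalobus and
#'   Rhabditis.
#' @param effects Numeric matrix of multiplicative treatment effects,
#'   trophic groups in rows (`Ba`, `Fu`, `Pp`, `Op`), treatments in
#'   columns; all entries > 0.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson); default 15, moderate field overdispersion.
#' @param poisson Use Poisson counts instead of negative binomial (for
#'   exact-variance checks).
#' @param plot_sd Standard deviation (log scale) of the lognormal
#'   plot-level heterogeneity factor; default 0.12.
#' @param subsample_size Identification subsample size; default 100.
#' @param covariates Covariate model, a data frame as returned by
#'   [default_covariate_model()].
#' @param seed Integer seed; every stochastic step of the scenario derives
#'   its stream from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(treatments = c("CK", "C2", "C4", "C8"),
                            replicates = 3L,
                            traits = default_traits(),
                            baseline = default_baseline(traits),
                            effects = default_effects(treatments),
                            dispersion = 15,
                            poisson = FALSE,
                            plot_sd = 0.12,
                            subsample_size = 100L,
                            covariates = default_covariate_model(treatments),
                            seed = NULL) {
  if (replicates < 2L) {
    nf_error("need >= 2 replicates per treatment for ANOVA testability",
      "nemafauna_validation_error")
  }
  if (any(effects <= 0)) {
    nf_error("treatment effect multipliers must be positive",
      "nemafauna_validation_error")
  }
  if (!setequal(rownames(effects), TROPHIC_GROUPS) ||
    !setequal(colnames(effects), treatments)) {
    nf_error(
      "effects must have trophic groups as rows and treatments as columns",
      "nemafauna_validation_error"
    )
  }
  if (is.null(names(baseline)) ||
    !all(tolower(names(baseline)) %in% tolower(traits$genus))) {
    nf_error("baseline must be named by genera present in the trait table",
      "nemafauna_validation_error")
  }
  if (any(baseline < 0)) {
    nf_error("baseline abundances must be non-negative",
      "nemafauna_validation_error")
  }
  structure(
    list(
      treatments = treatments, replicates = as.integer(replicates),
      traits = traits, baseline = baseline, effects = effects,
      dispersion = dispersion, poisson = poisson, plot_sd = plot_sd,
      subsample_size = as.integer(subsample_size), covariates = covariates,
      seed = seed
    ),
    class = "scenario_config"
  )
}

#' @rdname scenario_config
#' @export
default_baseline <- function(traits = default_traits()) {
  base <- setNames(
    c(Ba = 12, Fu = 25, Pp = 15, Op = 8)[traits$trophic_group],
    traits$genus
  )
  dominant <- c(Aphelenchoides = 80, Eucephalobus = 60, Rhabditis = 60)
  base[names(dominant)] <- dominant
  base
}

#' @rdname scenario_config
#' @export
default_effects <- function(treatments = c("CK", "C2", "C4", "C8")) {
  eff <- matrix(1, nrow = 4L, ncol = length(treatments),
    dimnames = list(TROPHIC_GROUPS, treatments)
  )
  set_if <- function(group, treatment, value) {
    hit <- treatments %in% treatment
    eff[group, hit] <<- value
  }
  set_if("Ba", c("C2", "C8"), 1.2)
  set_if("Ba", "C4", 1.5)
  set_if("Fu", c("C4", "C8"), 1.6)
  set_if("Pp", c("C2", "C8"), 1.5)
  set_if("Op", c("C4", "C8"), 1.15)
  eff
}

#' Default soil-covariate model
#'
#' One row per covariate: a baseline level, per-treatment additive shifts,
#' a coupling coefficient applied to the standardized abundance of one
#' trophic group (0 for uncoupled covariates), and a Gaussian noise SD.
#' The default couples microbial biomass carbon (MBC) to bacterivores and
#' MBN, SOC, nitrate and moisture to fungivores, with pH weakly tracking
#' omnivores/predators — the association structure a cover-crop survey
#' typically reports. Units are conventional (SMC %, pH units, SOC and TN
#' g/kg, mineral N and microbial biomass mg/kg, biomasses g/m^2).
#'
#' @param treatments Treatment labels the shift columns refer to.
#' @return Data frame with columns `covariate`, `baseline`,
#'   `shift_<treatment>` ..., `coupling_group`, `coupling`, `noise_sd`,
#'   `nonneg`.
#' @export
default_covariate_model <- function(treatments = c("CK", "C2", "C4", "C8")) {
  df <- data.frame(
    covariate = c(
      "SMC", "pH", "SOC", "NO3_N", "NH4_N", "TN", "CN", "MBC", "MBN",
      "cover_crop_biomass", "weed_biomass"
    ),
    baseline = c(20, 8.1, 6.7, 10, 5, 0.44, 15, 150, 25, 0, 200),
    coupling_group = c(
      "Fu", "Op", "Fu", "Fu", "", "", "", "Ba", "Fu", "", ""
    ),
    coupling = c(0.4, 0.02, 0.3, 0.5, 0, 0, 0, 15, 3, 0, 0),
    noise_sd = c(0.5, 0.03, 0.3, 0.5, 0.4, 0.02, 0.5, 10, 2, 20, 15),
    nonneg = c(
      TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE
    ),
    stringsAsFactors = FALSE
  )
  shifts <- rbind(
    SMC = c(0, 1, 1, 1.2), pH = c(0, 0.11, 0.12, 0.18),
    SOC = c(0, 0.3, 0.9, 1.0), NO3_N = c(0, 2, 2, 2.4),
    NH4_N = c(0, 0.2, 0.3, 0.6), TN = c(0, 0.02, 0.04, 0.08),
    CN = c(0, 0.2, 0.5, 0.5), MBC = c(0, 75, 90, 95),
    MBN = c(0, 12, 15, 17), cover_crop_biomass = c(0, 300, 400, 600),
    weed_biomass = c(0, -120, -150, -180)
  )
  shifts <- shifts[, seq_along(treatments), drop = FALSE]
  colnames(shifts) <- paste0("shift_", treatments)
  cbind(df, as.data.frame(shifts))
}

#' Generate a synthetic community table
#'
#' Draws one community per plot: genus means are
#' `baseline * effect[group, treatment] * plot_factor` with a lognormal
#' plot-level factor, and counts come from a negative binomial (or Poisson)
#' around those means. Deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return List with `abundance` (genus x sample matrix, individuals per
#'   100 g dry soil) and `metadata` (data frame `sample_id`, `treatment`,
#'   `replicate`, `dry_mass_g`).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  traits <- config$traits
  genera <- names(config$baseline)
  grp <- traits$trophic_group[resolve_genera(traits, genera)]
  treatments <- rep(config$treatments, each = config$replicates)
  reps <- rep(seq_len(config$replicates), times = length(config$treatments))
  ids <- paste0(treatments, "_", reps)
  with_seed(config$seed, {
    counts <- matrix(0, nrow = length(genera), ncol = length(ids),
      dimnames = list(genera, ids)
    )
    for (j in seq_along(ids)) {
      plot_factor <- stats::rlnorm(1, meanlog = 0, sdlog = config$plot_sd)
      mu <- config$baseline * config$effects[cbind(grp, treatments[j])] *
        plot_factor
      counts[, j] <- if (config$poisson) {
        stats::rpois(length(mu), lambda = mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
      }
    }
    metadata <- data.frame(
      sample_id = ids, treatment = treatments, replicate = reps,
      dry_mass_g = round(stats::runif(length(ids), 45, 55), 1)
    )
    list(abundance = counts, metadata = metadata)
  })
}

#' Draw an identification subsample for one sample
#'
#' Multinomial draw of `n` identified individuals with probabilities
#' proportional to the genus abundances — the in-silico analogue of
#' identifying 100 randomly picked nematodes under the microscope.
#'
#' @param x Named genus-abundance vector with positive total.
#' @param n Subsample size (default 100).
#' @param seed Optional seed.
#' @return Named integer vector of counts summing to `n`.
#' @export
generate_identification_counts <- function(x, n = 100L, seed = NULL) {
  if (sum(x) <= 0) {
    nf_error("cannot subsample a sample with zero total abundance",
      "nemafauna_domain_error")
  }
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1L, size = n, prob = x))
    setNames(counts, names(x))
  })
}

#' Generate soil covariates coupled to the community
#'
#' Each covariate is `baseline + treatment shift + coupling *
#' standardized(trophic-group abundance) + Gaussian noise` per sample, so a
#' nonzero coupling makes the covariate distances co-vary with community
#' dissimilarity (detectable by a Mantel test). Covariates flagged
#' non-negative are truncated at zero.
#'
#' @param config A [scenario_config()].
#' @param community Output of [generate_community()].
#' @param seed Optional seed (defaults to a stream derived from
#'   `config$seed`).
#' @return The community `metadata` data frame with one column appended per
#'   covariate.
#' @export
generate_soil_covariates <- function(config, community, seed = NULL) {
  model <- config$covariates
  metadata <- community$metadata
  groups <- vapply(
    seq_len(ncol(community$abundance)),
    function(j) {
      x <- community$abundance[, j]
      aggregate_trophic(x[x > 0], config$traits)
    },
    numeric(4L)
  ) # 4 x samples
  zgroups <- t(apply(groups, 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  shift_cols <- paste0("shift_", config$treatments)
  with_seed(seed, {
    for (i in seq_len(nrow(model))) {
      shifts <- as.numeric(model[i, shift_cols])[
        match(metadata$treatment, config$treatments)
      ]
      coupled <- if (nzchar(model$coupling_group[i])) {
        model$coupling[i] * zgroups[model$coupling_group[i], ]
      } else {
        0
      }
      v <- model$baseline[i] + shifts + coupled +
        stats::rnorm(nrow(metadata), sd = model$noise_sd[i])
      if (model$nonneg[i]) v <- pmax(v, 0)
      metadata[[model$covariate[i]]] <- v
    }
    metadata
  })
}

#' Generate a complete synthetic scenario
#'
#' Runs [generate_community()], [generate_identification_counts()] (one
#' subsample per sample) and [generate_soil_covariates()] with seeds
#' derived from `config$seed`, so the whole scenario is reproducible from a
#' single integer.
#'
#' @param config A [scenario_config()].
#' @return A `nema_scenario` list: `abundance` (genus x sample),
#'   `identification` (genus x sample subsample counts), `metadata`
#'   (with covariates), `traits`, `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  seeds <- derive_seeds(config$seed, 3L)
  community <- generate_community(config)
  ident <- with_seed(seeds[[2L]], {
    vapply(
      seq_len(ncol(community$abundance)),
      function(j) {
        generate_identification_counts(
          community$abundance[, j], n = config$subsample_size
        )
      },
      integer(nrow(community$abundance))
    )
  })
  dimnames(ident) <- dimnames(community$abundance)
  metadata <- generate_soil_covariates(config, community, seed = seeds[[3L]])
  structure(
    list(
      abundance = community$abundance, identification = ident,
      metadata = metadata, traits = config$traits, config = config
    ),
    class = "nema_scenario"
  )
}

# Derive k reproducible sub-seeds (< 2^31) from one seed; NULL stays NULL.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) {
    return(vector("list", k))
  }
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Generate a community with planted correlation blocks
#'
#' Builds a genus x sample table whose genera fall into independent blocks;
#' within a block, latent Gaussian variables share pairwise correlation
#' `rho`, and abundances are a monotone (exponential) transform of the
#' latent values, so Spearman correlations inherit the block structure.
#' Used to validate co-occurrence network recovery: edges should appear
#' within blocks and not between them.
#'
#' @param n_samples Number of samples (columns).
#' @param block_sizes Integer vector of genera per block.
#' @param rho Within-block latent correlation (default 0.9).
#' @param base Median abundance scale (default 50).
#' @param sdlog Lognormal spread of the abundance transform (default 0.6).
#' @param seed Optional seed.
#' @return A genus x sample abundance matrix with genera named
#'   `B<block>_G<index>`.
#' @export
generate_block_community <- function(n_samples = 12L, block_sizes = c(6L, 6L),
                                     rho = 0.9, base = 50, sdlog = 0.6,
                                     seed = NULL) {
  if (rho < 0 || rho >= 1) {
    nf_error("rho must lie in [0, 1)", "nemafauna_validation_error")
  }
  with_seed(seed, {
    blocks <- lapply(seq_along(block_sizes), function(b) {
      m <- block_sizes[b]
      # Equicorrelated Gaussians via a shared factor:
      # z = sqrt(rho) f + sqrt(1 - rho) e.
      f <- stats::rnorm(n_samples)
      z <- sqrt(rho) * matrix(f, n_samples, m) +
        sqrt(1 - rho) * matrix(stats::rnorm(n_samples * m), n_samples, m)
      colnames(z) <- paste0("B", b, "_G", seq_len(m))
      z
    })
    z <- do.call(cbind, blocks)
    abund <- t(base * exp(sdlog * z)) # genera x samples, monotone in z
    colnames(abund) <- paste0("S", seq_len(n_samples))
    abund
  })
}

#' Write a scenario to delimited files
#'
#' Emits `community.csv` (per-100 g abundances), `identification.csv`
#' (subsample counts), `metadata.csv` and `traits.csv` into a directory,
#' in the formats [read_community()], [read_metadata()] and
#' [load_traits()] read back.
#'
#' @param scenario A `nema_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  write_community(scenario$abundance, file.path(dir, "community.csv"))
  write_community(scenario$identification, file.path(dir, "identification.csv"))
  utils::write.table(scenario$metadata, file.path(dir, "metadata.csv"),
    sep = ",", row.names = FALSE, quote = FALSE
  )
  write_traits(scenario$traits, file.path(dir, "traits.csv"))
  invisible(dir)
}

#' @export
print.nema_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic nematode scenario: %d genera x %d samples (%s; %d replicates)\n",
    nrow(x$abundance), ncol(x$abundance),
    paste(x$config$treatments, collapse = "/"), x$config$replicates
  ))
  invisible(x)
}
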