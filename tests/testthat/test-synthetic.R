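test_that("scenario generation is fully deterministic given a seed", {
  cfg <- scenario_config(seed = 123)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$identification, s2$identification)
  expect_identical(s1$metadata, s2$metadata)

  s3 <- generate_scenario(scenario_config(seed = 124))
  expect_false(identical(s1$abundance, s3$abundance))
})

test_that("scenario layout matches the configured design", {
  s <- generate_scenario(scenario_config(seed = 1))
  expect_equal(dim(s$abundance), c(46L, 12L))
  expect_equal(s$metadata$treatment, rep(c("CK", "C2", "C4", "C8"), each = 3))
  expect_true(all(s$abundance >= 0))
  expect_equal(colSums(s$identification), rep(100, 12), ignore_attr = TRUE)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(scenario_config(replicates = 1),
    class = "nemafauna_validation_error"
  )
  eff <- default_effects()
  eff["Fu", "C4"] <- -1
  expect_error(scenario_config(effects = eff),
    class = "nemafauna_validation_error"
  )
  expect_error(
    scenario_config(baseline = c(NotAGenus = 5)),
    class = "nemafauna_validation_error"
  )
})

test_that("identification subsampling is multinomial around abundance shares", {
  x <- c(OnlyGenus = 123)
  counts <- generate_identification_counts(x, n = 100, seed = 1)
  expect_equal(counts[["OnlyGenus"]], 100L)

  expect_error(
    generate_identification_counts(c(A = 0, B = 0)),
    class = "nemafauna_domain_error"
  )

  x <- c(A = 500, B = 300, C = 200)
  sums <- c(A = 0, B = 0, C = 0)
  n_draw <- 1000
  set.seed(31)
  for (i in seq_len(n_draw)) {
    counts <- generate_identification_counts(x, n = 100)
    expect_equal(sum(counts), 100L)
    sums <- sums + counts
  }
  p <- x / sum(x)
  se <- sqrt(100 * p * (1 - p) * n_draw)
  expect_true(all(abs(sums - n_draw * 100 * p) <= 3 * se))
})

test_that("null scenario keeps the ANOVA false-positive rate near alpha", {
  eff <- matrix(1, 4, 4, dimnames = list(c("Ba", "Fu", "Pp", "Op"),
    c("CK", "C2", "C4", "C8")))
  rejections <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- scenario_config(effects = eff, seed = 5000 + s)
    comm <- generate_community(cfg)
    fu <- vapply(seq_len(ncol(comm$abundance)), function(j) {
      x <- comm$abundance[, j]
      aggregate_trophic(x[x > 0], cfg$traits)[["Fu"]]
    }, numeric(1))
    fit <- one_way_anova(ln_transform(fu), comm$metadata$treatment)
    if (fit$p < 0.05) rejections <- rejections + 1L
  }
  # binomial(100, 0.05): 3 sd band around 5
  expect_lte(rejections, 12L)
})

test_that("planted trophic-group effects are recovered in direction", {
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- scenario_config(seed = 7000 + s)
    comm <- generate_community(cfg)
    fu <- vapply(seq_len(ncol(comm$abundance)), function(j) {
      x <- comm$abundance[, j]
      aggregate_trophic(x[x > 0], cfg$traits)[["Fu"]]
    }, numeric(1))
    trt <- comm$metadata$treatment
    if (mean(fu[trt %in% c("C4", "C8")]) > mean(fu[trt == "CK"])) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("soil covariates couple to the community and respect treatments", {
  s <- generate_scenario(scenario_config(seed = 42))
  meta <- s$metadata
  expect_true(all(c("SMC", "pH", "SOC", "MBC", "MBN", "cover_crop_biomass",
    "weed_biomass") %in% names(meta)))
  expect_true(all(meta$cover_crop_biomass[meta$treatment == "CK"] <=
    mean(meta$cover_crop_biomass[meta$treatment == "C8"])))
  expect_true(all(meta$MBC >= 0))

  # determinism of the covariate layer
  s2 <- generate_scenario(scenario_config(seed = 42))
  expect_identical(meta, s2$metadata)
})

test_that("block communities carry their planted rank correlation", {
  within_r <- numeric(5)
  between_r <- numeric(5)
  for (s in 1:5) {
    comm <- generate_block_community(
      n_samples = 40, block_sizes = c(5, 5), rho = 0.9, seed = 9 + s
    )
    cm <- correlation_matrix(comm, relative = FALSE)
    blocks <- sub("_.*", "", rownames(comm))
    same <- outer(blocks, blocks, "==") & upper.tri(cm$r)
    other <- outer(blocks, blocks, "!=") & upper.tri(cm$r)
    within_r[s] <- mean(cm$r[same])
    between_r[s] <- abs(mean(cm$r[other]))
  }
  # the block factors of any single draw can correlate by chance, so the
  # between-block level is judged on the average over seeds
  expect_gt(mean(within_r), 0.7)
  expect_lt(mean(between_r), 0.3)
  comm <- generate_block_community(
    n_samples = 40, block_sizes = c(5, 5), rho = 0.9, seed = 9
  )
  expect_identical(
    comm,
    generate_block_community(40, c(5, 5), rho = 0.9, seed = 9)
  )
})

test_that("the default scenario runs the whole pipeline within invariants", {
  s <- generate_scenario(scenario_config(seed = 2024))
  traits <- s$traits

  idx <- nema_indices(s$abundance, traits)
  ok <- !is.na(idx$MI)
  expect_true(all(idx$MI[ok] >= 1 & idx$MI[ok] <= 5))
  ok <- !is.na(idx$PPI)
  expect_true(all(idx$PPI[ok] >= 1 & idx$PPI[ok] <= 5))
  ok <- !is.na(idx$NCR)
  expect_true(all(idx$NCR[ok] >= 0 & idx$NCR[ok] <= 1))
  ok <- !is.na(idx$EI)
  expect_true(all(idx$EI[ok] >= 0 & idx$EI[ok] <= 100))
  ok <- !is.na(idx$SI)
  expect_true(all(idx$SI[ok] >= 0 & idx$SI[ok] <= 100))
  expect_true(all(idx$WI[!is.na(idx$WI)] >= 0))

  fp <- nema_footprints(s$abundance, traits)
  expect_equal(fp$Fe + fp$Fs, fp$NMF, tolerance = 1e-9)

  profile <- functional_footprint(
    EI = mean(idx$EI, na.rm = TRUE), SI = mean(idx$SI, na.rm = TRUE),
    Fe = mean(fp$Fe), Fs = mean(fp$Fs), k = 10
  )
  expect_s3_class(profile, "faunal_profile")
  expect_true(profile$quadrat %in% c("A", "B", "C", "D"))

  net <- suppressWarnings(
    build_network(correlation_matrix(s$abundance), traits = traits)
  )
  expect_s3_class(net, "cooccurrence_network")

  d <- bray_curtis(s$abundance)
  ord <- pcoa(d)
  expect_equal(nrow(ord$coordinates), 12L)

  mt <- mantel_test(d, covariate_distance(s$metadata), seed = 1)
  expect_true(mt$r >= -1 && mt$r <= 1)

  fit <- duncan_mrt(ln_transform(colSums(s$abundance)), s$metadata$treatment)
  expect_true(all(nchar(fit$letters) >= 1))
})

test_that("strongly coupled covariates are detectable by Mantel tests", {
  model <- default_covariate_model()
  model$coupling[model$covariate == "MBC"] <- 45 # triple the default coupling
  hits <- 0L
  n_seeds <- 30L
  for (s in seq_len(n_seeds)) {
    cfg <- scenario_config(covariates = model, seed = 8000 + s)
    scen <- generate_scenario(cfg)
    ba_rows <- cfg$traits$genus[cfg$traits$trophic_group == "Ba"]
    d_ba <- bray_curtis(scen$abundance[ba_rows, ])
    d_mbc <- covariate_distance(scen$metadata, columns = "MBC")
    mt <- mantel_test(d_ba, d_mbc, seed = s)
    if (mt$p < 0.05 && mt$r > 0) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("write_scenario emits files the readers load back", {
  s <- generate_scenario(scenario_config(seed = 77))
  dir <- withr::local_tempdir()
  write_scenario(s, dir)
  expect_equal(read_community(file.path(dir, "community.csv")), s$abundance)
  expect_equal(
    read_community(file.path(dir, "identification.csv")),
    s$identification + 0 # storage mode: files read back as double
  )
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(meta$sample_id, s$metadata$sample_id)
  expect_equal(meta$MBC, s$metadata$MBC, tolerance = 1e-6)
  back <- load_traits(file.path(dir, "traits.csv"))
  expect_equal(as.data.frame(back), as.data.frame(s$traits))
})
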