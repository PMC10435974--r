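test_that("Spearman correlation matrix matches rank definitions and cor.test", {
  set.seed(1)
  comm <- matrix(rlnorm(6 * 6), nrow = 6,
    dimnames = list(paste0("G", 1:6), paste0("S", 1:6))
  )
  cm <- correlation_matrix(comm, relative = FALSE)
  expect_equal(diag(cm$r), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))

  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(cm$r[i, j], oracle_spearman(comm[i, ], comm[j, ]),
        tolerance = 1e-12
      )
      ct <- suppressWarnings(
        cor.test(comm[i, ], comm[j, ], method = "spearman", exact = FALSE)
      )
      expect_equal(cm$p[i, j], unname(ct$p.value), tolerance = 1e-10)
    }
  }
})

test_that("monotone and reversed profiles give r = 1 and r = -1", {
  up <- c(1, 3, 8, 20, 50, 90)
  comm <- rbind(
    A = up,
    B = up^2, # strictly monotone transform: same ranks
    C = rev(up)
  )
  colnames(comm) <- paste0("S", 1:6)
  cm <- correlation_matrix(comm, relative = FALSE)
  expect_equal(cm$r["A", "B"], 1)
  expect_equal(cm$r["A", "C"], -1)
  expect_equal(cm$p["A", "B"], 0)
})

test_that("zero-variance genera are dropped with a warning", {
  comm <- rbind(
    A = c(1, 2, 3, 4, 5, 6),
    Flat = rep(4, 6),
    B = c(2, 1, 5, 3, 6, 4)
  )
  colnames(comm) <- paste0("S", 1:6)
  expect_warning(
    cm <- correlation_matrix(comm, relative = FALSE),
    "Flat"
  )
  expect_equal(rownames(cm$r), c("A", "B"))
})

test_that("network filtering honours both thresholds and keeps edge signs", {
  n <- 8
  genera <- paste0("G", 1:4)
  r <- diag(1, 4)
  dimnames(r) <- list(genera, genera)
  p <- matrix(0.5, 4, 4, dimnames = dimnames(r))
  diag(p) <- NA
  # strong significant positive, strong significant negative, strong but
  # non-significant, weak but significant
  r[1, 2] <- r[2, 1] <- 0.9
  p[1, 2] <- p[2, 1] <- 0.001
  r[1, 3] <- r[3, 1] <- -0.8
  p[1, 3] <- p[3, 1] <- 0.01
  r[2, 3] <- r[3, 2] <- 0.95
  p[2, 3] <- p[3, 2] <- 0.2
  r[3, 4] <- r[4, 3] <- 0.3
  p[3, 4] <- p[4, 3] <- 0.001

  net <- build_network(list(r = r, p = p, n = n))
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$sign, c("+", "-"))
  expect_true(all(abs(net$edges$r) > 0.6 & net$edges$p < 0.05))
  # G4 is isolated and dropped by default
  expect_false("G4" %in% net$nodes$genus)
  net_iso <- build_network(list(r = r, p = p, n = n), keep_isolated = TRUE)
  expect_true("G4" %in% net_iso$nodes$genus)

  # signed thresholding removes the negative edge
  net_pos <- build_network(list(r = r, p = p, n = n), signed_threshold = TRUE)
  expect_equal(net_pos$edges$sign, "+")

  # raising the threshold never adds edges
  for (thr in c(0.6, 0.7, 0.85, 0.95)) {
    e_lo <- nrow(build_network(list(r = r, p = p, n = n), r_threshold = thr)$edges)
    e_hi <- nrow(build_network(list(r = r, p = p, n = n), r_threshold = thr + 0.04)$edges)
    expect_lte(e_hi, e_lo)
  }
})

test_that("three perfectly correlated genera give a complete positive triangle", {
  up <- c(1, 4, 9, 16, 30, 55, 80, 120)
  comm <- rbind(A = up, B = 2 * up, C = up + 100)
  colnames(comm) <- paste0("S", 1:8)
  net <- build_network(correlation_matrix(comm, relative = FALSE))
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$sign == "+"))
  expect_equal(net$metrics$density, 1)
})

test_that("all sub-threshold correlations give an empty edge set", {
  r <- diag(1, 3)
  dimnames(r) <- list(letters[1:3], letters[1:3])
  r[upper.tri(r)] <- r[lower.tri(r)] <- 0.5
  p <- matrix(0.001, 3, 3, dimnames = dimnames(r))
  net <- build_network(list(r = r, p = p, n = 10))
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$metrics$n_edges, 0L)
  expect_true(is.na(net$metrics$positive_fraction))
})

test_that("network metrics follow the degree/density formulas", {
  # 4 nodes, 3 edges: density 0.5, average degree 1.5
  r <- diag(1, 4)
  g <- paste0("G", 1:4)
  dimnames(r) <- list(g, g)
  p <- matrix(1, 4, 4, dimnames = dimnames(r))
  for (pair in list(c(1, 2), c(2, 3), c(3, 4))) {
    r[pair[1], pair[2]] <- r[pair[2], pair[1]] <- 0.9
    p[pair[1], pair[2]] <- p[pair[2], pair[1]] <- 0.001
  }
  net <- build_network(list(r = r, p = p, n = 10))
  expect_equal(net$metrics$avg_degree, 1.5)
  expect_equal(net$metrics$density, 0.5)
  expect_equal(net$metrics$connectance_pct, 50)
  expect_equal(net$metrics$positive_fraction, 1)

  # cross-check against igraph on the same graph
  ig <- as_igraph(net)
  expect_equal(net$metrics$avg_degree, mean(igraph::degree(ig)))
  expect_equal(net$metrics$density, igraph::edge_density(ig))
})

test_that("metrics audit against brute-force edge counts on random graphs", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    g <- paste0("G", seq_len(n))
    r <- diag(1, n)
    dimnames(r) <- list(g, g)
    p <- matrix(runif(n * n), n, n, dimnames = dimnames(r))
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    rv <- runif(n * (n - 1) / 2, -1, 1)
    r[upper.tri(r)] <- rv
    r <- t(r)
    r[upper.tri(r)] <- rv
    net <- build_network(list(r = r, p = p, n = 20), keep_isolated = TRUE)
    manual_edges <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(r[i, j]) > 0.6 && p[i, j] < 0.05) manual_edges <- manual_edges + 1
      }
    }
    expect_equal(nrow(net$edges), manual_edges)
    expect_equal(net$metrics$avg_degree, 2 * manual_edges / n)
    expect_equal(sum(net$nodes$degree), 2 * manual_edges)
  }
})

test_that("planted two-block communities recover within-block edges only", {
  set.seed(88)
  within_rate <- numeric(10)
  between_rate <- numeric(10)
  for (s in 1:10) {
    comm <- generate_block_community(
      n_samples = 12, block_sizes = c(6, 6), rho = 0.9, seed = 1000 + s
    )
    net <- build_network(correlation_matrix(comm, relative = FALSE),
      keep_isolated = TRUE
    )
    block_of <- sub("_.*", "", net$edges$from) == sub("_.*", "", net$edges$to)
    within_rate[s] <- sum(block_of) / (2 * choose(6, 2))
    between_rate[s] <- sum(!block_of) / 36
  }
  expect_gte(mean(within_rate), 0.85)
  expect_lte(mean(between_rate), 0.10)
})

test_that("hub ranking prefers degree, then strength, then name", {
  g <- c("Hub", "S1", "S2", "S3", "S4")
  r <- diag(1, 5)
  dimnames(r) <- list(g, g)
  p <- matrix(1, 5, 5, dimnames = dimnames(r))
  for (j in 2:5) {
    r["Hub", g[j]] <- r[g[j], "Hub"] <- 0.9
    p["Hub", g[j]] <- p[g[j], "Hub"] <- 0.001
  }
  tt <- make_traits(g, rep("Ba", 5), rep(2, 5))
  net <- build_network(list(r = r, p = p, n = 10), traits = tt)
  hubs <- hub_taxa(net, top_n = 2)
  expect_equal(hubs$genus[1], "Hub")
  expect_equal(hubs$degree[1], 4)

  # equal degrees and strengths: alphabetical order decides
  r2 <- diag(1, 4)
  g2 <- c("Zeta", "Alpha", "Mu", "Beta")
  dimnames(r2) <- list(g2, g2)
  p2 <- matrix(1, 4, 4, dimnames = dimnames(r2))
  r2["Zeta", "Alpha"] <- r2["Alpha", "Zeta"] <- 0.9
  p2["Zeta", "Alpha"] <- p2["Alpha", "Zeta"] <- 0.001
  r2["Mu", "Beta"] <- r2["Beta", "Mu"] <- 0.9
  p2["Mu", "Beta"] <- p2["Beta", "Mu"] <- 0.001
  net2 <- build_network(list(r = r2, p = p2, n = 10))
  hubs2 <- hub_taxa(net2, top_n = 4)
  expect_equal(hubs2$genus, c("Alpha", "Beta", "Mu", "Zeta"))
})

test_that("few-sample networks trigger a power warning", {
  comm <- matrix(rlnorm(12), nrow = 4,
    dimnames = list(paste0("G", 1:4), paste0("S", 1:3))
  )
  cm <- correlation_matrix(comm, relative = FALSE)
  expect_warning(build_network(cm), "power")
})

test_that("edge lists and GraphML exports round-trip", {
  up <- c(1, 4, 9, 16, 30, 55, 80, 120)
  comm <- rbind(Rhabditis = up, Plectus = 2 * up, Aphelenchus = up + 3)
  colnames(comm) <- paste0("S", 1:8)
  net <- build_network(correlation_matrix(comm, relative = FALSE),
    traits = default_traits()
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(net, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(net$edges))
  expect_named(back, c("genus_a", "genus_b", "r", "p", "sign"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(net$nodes))
  expect_equal(igraph::gsize(ig), nrow(net$edges))
})
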