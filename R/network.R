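#' Genus-genus correlation matrix across samples
#'
#' Computes pairwise Spearman rank correlations between genera over samples,
#' on relative abundances by default (each sample divided by its total, the
#' conventional input for community co-occurrence networks). Two-sided
#' p-values use the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (the standard large-sample test of zero rank
#' correlation, matching `cor.test(..., exact = FALSE)`). Genera with zero
#' variance across samples carry no rank information and are dropped with a
#' warning.
#'
#' @param comm Community matrix, genera in rows, samples in columns; at
#'   least 3 samples.
#' @param method Correlation method; only `"spearman"` is implemented.
#' @param relative Convert each sample to relative abundance first
#'   (default `TRUE`).
#' @return A `cor_matrix` list: `r` (symmetric, unit diagonal), `p`
#'   (symmetric, `NA` diagonal), `n` (number of samples), `method`,
#'   `dropped` (zero-variance genera).
#' @export
correlation_matrix <- function(comm, method = "spearman", relative = TRUE) {
  method <- match.arg(method, "spearman")
  n <- ncol(comm)
  if (n < 3L) {
    nf_error(
      "at least 3 samples are needed for a correlation matrix",
      "nemafauna_domain_error"
    )
  }
  if (relative) {
    comm <- relative_abundance(comm)
  }
  x <- t(comm) # samples x genera
  vr <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[vr == 0]
  if (length(dropped) > 0) {
    warning(
      sprintf(
        "dropping %d genus/genera constant across samples: %s",
        length(dropped), paste(dropped, collapse = ", ")
      ),
      call. = FALSE
    )
    x <- x[, vr > 0, drop = FALSE]
  }
  r <- stats::cor(x, method = "spearman")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 0 # |r| = 1
  diag(p) <- NA_real_
  structure(
    list(r = r, p = p, n = n, method = method, dropped = dropped),
    class = "cor_matrix"
  )
}

#' Build a co-occurrence network from a thresholded correlation matrix
#'
#' Keeps the genus pairs whose correlation passes both filters — by default
#' `|r| > 0.6` and `p < 0.05`, the conventional screen for community
#' co-occurrence networks — and records each retained edge with its sign.
#' The absolute-value threshold admits negative (exclusion) edges; set
#' `signed_threshold = TRUE` to keep only `r > r_threshold`. Isolated nodes
#' are dropped by default, matching co-occurrence-network convention.
#'
#' Rank correlations at very small sample sizes are weakly powered: a
#' warning is emitted when fewer than 6 samples back the matrix.
#'
#' @param cormat A `cor_matrix` from [correlation_matrix()] (or a list with
#'   conformable symmetric `r` and `p` matrices).
#' @param r_threshold Minimum absolute correlation (default 0.6,
#'   exclusive).
#' @param p_threshold Maximum p-value (default 0.05, exclusive).
#' @param traits Optional `trait_table` used to attach a trophic-group
#'   attribute to each node.
#' @param keep_isolated Keep genera without any retained edge (default
#'   `FALSE`).
#' @param signed_threshold Threshold on `r` rather than `|r|`.
#' @param p_adjust Multiple-testing correction applied to the p-values
#'   before filtering (a `stats::p.adjust` method; default `"none"`, no
#'   correction).
#' @return A `cooccurrence_network` list: `nodes` (data frame `genus`,
#'   `trophic_group`, `degree`), `edges` (data frame `from`, `to`, `r`,
#'   `p`, `sign`), `n_samples`, `metrics` (see [network_metrics()]).
#' @export
build_network <- function(cormat, r_threshold = 0.6, p_threshold = 0.05,
                          traits = NULL, keep_isolated = FALSE,
                          signed_threshold = FALSE, p_adjust = "none") {
  r <- cormat$r
  p <- cormat$p
  stopifnot(identical(dim(r), dim(p)))
  n_samples <- if (!is.null(cormat$n)) cormat$n else NA_integer_
  if (!is.na(n_samples) && n_samples < 6L) {
    warning(
      sprintf(
        "only %d samples back this network; edge tests at |r| > %.2g have little power",
        n_samples, r_threshold
      ),
      call. = FALSE
    )
  }
  genera <- rownames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pv <- p[ut]
  if (p_adjust != "none") {
    pv <- stats::p.adjust(pv, method = p_adjust)
  }
  rv <- r[ut]
  strength <- if (signed_threshold) rv else abs(rv)
  keep <- !is.na(rv) & !is.na(pv) & strength > r_threshold & pv < p_threshold
  edges <- data.frame(
    from = genera[ut[keep, 1L]],
    to = genera[ut[keep, 2L]],
    r = rv[keep],
    p = pv[keep],
    sign = ifelse(rv[keep] >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  deg <- setNames(numeric(length(genera)), genera)
  tab <- table(c(edges$from, edges$to))
  deg[names(tab)] <- as.numeric(tab)
  nodes <- data.frame(
    genus = genera, degree = unname(deg), stringsAsFactors = FALSE
  )
  if (!is.null(traits)) {
    idx <- resolve_genera(traits, nodes$genus)
    nodes$trophic_group <- traits$trophic_group[idx]
  } else {
    nodes$trophic_group <- NA_character_
  }
  if (!keep_isolated) {
    nodes <- nodes[nodes$degree > 0, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  net <- structure(
    list(nodes = nodes, edges = edges, n_samples = n_samples,
         r_threshold = r_threshold, p_threshold = p_threshold),
    class = "cooccurrence_network"
  )
  net$metrics <- network_metrics(net)
  net
}

#' Summary metrics of a co-occurrence network
#'
#' Reports node and edge counts, average degree `2E / N`, density
#' `2E / (N (N - 1))`, the positive/negative edge fractions, and two
#' connectivity readings — `connectance_pct` (density x 100) and
#' `avg_degree` itself — since "connectivity" is used for either in the
#' community-network literature. An empty network yields zero counts and
#' `NA` for the degree-based metrics.
#'
#' @param net A `cooccurrence_network`.
#' @return Named list of metrics.
#' @export
network_metrics <- function(net) {
  n <- nrow(net$nodes)
  e <- nrow(net$edges)
  pos <- sum(net$edges$sign == "+")
  list(
    n_nodes = n,
    n_edges = e,
    avg_degree = if (n > 0) 2 * e / n else NA_real_,
    density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
    connectance_pct = if (n > 1) 200 * e / (n * (n - 1)) else NA_real_,
    positive_fraction = if (e > 0) pos / e else NA_real_,
    negative_fraction = if (e > 0) (e - pos) / e else NA_real_
  )
}

#' Highest-degree (hub) taxa per trophic group
#'
#' Ranks the network's genera by degree within each trophic group — the
#' taxa "controlling" the network in co-occurrence terms. Ties are broken
#' by the total absolute correlation strength of a genus's edges, then
#' alphabetically.
#'
#' @param net A `cooccurrence_network` built with `traits` so nodes carry
#'   trophic groups.
#' @param top_n Number of taxa reported per group.
#' @return Data frame `trophic_group`, `genus`, `degree`, `strength`,
#'   `rank`, ordered by group then rank.
#' @export
hub_taxa <- function(net, top_n = 3L) {
  nodes <- net$nodes
  if (nrow(nodes) == 0L) {
    nf_error("network has no nodes", "nemafauna_domain_error")
  }
  strength <- vapply(nodes$genus, function(g) {
    sum(abs(net$edges$r[net$edges$from == g | net$edges$to == g]))
  }, numeric(1))
  nodes$strength <- unname(strength)
  groups <- if (all(is.na(nodes$trophic_group))) {
    list(all = nodes)
  } else {
    split(nodes, nodes$trophic_group)
  }
  out <- lapply(names(groups), function(gname) {
    gdf <- groups[[gname]]
    ord <- order(-gdf$degree, -gdf$strength, gdf$genus)
    gdf <- gdf[ord, , drop = FALSE]
    k <- min(top_n, nrow(gdf))
    data.frame(
      trophic_group = gname,
      genus = gdf$genus[seq_len(k)],
      degree = gdf$degree[seq_len(k)],
      strength = gdf$strength[seq_len(k)],
      rank = seq_len(k),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Convert a co-occurrence network to an igraph object
#'
#' Nodes carry `trophic_group`; edges carry `r`, `p` and `sign`.
#'
#' @param net A `cooccurrence_network`.
#' @return An undirected [igraph::igraph] graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE, vertices = net$nodes
  )
}

#' Export a network as an edge list or GraphML
#'
#' `write_edge_list()` writes a delimited table (`genus_a`, `genus_b`, `r`,
#' `p`, `sign`); `write_graphml()` writes GraphML for external viewers
#' (Gephi, Cytoscape).
#'
#' @param net A `cooccurrence_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  edges <- net$edges
  names(edges)[1:2] <- c("genus_a", "genus_b")
  utils::write.table(edges, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Co-occurrence network: %d nodes, %d edges (|r| > %g, p < %g, n = %s samples)\n",
    m$n_nodes, m$n_edges, x$r_threshold, x$p_threshold,
    ifelse(is.na(x$n_samples), "?", x$n_samples)
  ))
  if (m$n_edges > 0) {
    cat(sprintf(
      "  avg degree %.3g, density %.3g, %d%% positive edges\n",
      m$avg_degree, m$density, round(100 * m$positive_fraction)
    ))
  }
  invisible(x)
}
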