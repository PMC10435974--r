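#' Metabolic footprint of one taxon
#'
#' Carbon utilization attributed to `N` individuals of a taxon with fresh
#' body weight `W` (micrograms) and c-p value `m`:
#' `N * (0.1 * W / m + 0.273 * W^0.75)`. The first term approximates carbon
#' lost to respiration (life-course scaled by the c-p class), the second
#' carbon fixed into production.
#'
#' @param N Abundance (individuals, typically per 100 g dry soil); >= 0.
#' @param W Fresh body weight in micrograms; > 0.
#' @param m c-p value in 1..5.
#' @return The footprint (same abundance basis as `N`). Vectorized.
#' @examples
#' taxon_footprint(100, 1, 2) # 32.3
#' @export
taxon_footprint <- function(N, W, m) {
  if (any(N < 0)) {
    nf_error("abundance must be non-negative", "nemafauna_domain_error")
  }
  if (any(W <= 0)) {
    nf_error("fresh weight must be positive", "nemafauna_domain_error")
  }
  if (any(m < 1 | m > 5)) {
    nf_error("c-p value must lie in 1..5", "nemafauna_domain_error")
  }
  N * (0.1 * W / m + 0.273 * W^0.75)
}

#' Metabolic footprints of one sample, by taxon and trophic group
#'
#' Sums [taxon_footprint()] within the four trophic groups (BaF, FuF, PpF,
#' OpF) and overall (the total nematode metabolic footprint, NMF). The four
#' group footprints partition NMF exactly.
#'
#' @param x Named genus-abundance vector for one sample.
#' @param traits A `trait_table`.
#' @return A `footprint_set` list: `per_taxon` (named vector), `BaF`, `FuF`,
#'   `PpF`, `OpF`, `NMF`.
#' @export
group_footprints <- function(x, traits) {
  groups <- setNames(numeric(4L), TROPHIC_GROUPS)
  per_taxon <- setNames(numeric(length(x)), names(x))
  if (length(x) > 0L) {
    idx <- resolve_genera(traits, names(x))
    per_taxon[] <- taxon_footprint(
      as.numeric(x), traits$fresh_weight_ug[idx], traits$cp_value[idx]
    )
    sums <- tapply(
      per_taxon, factor(traits$trophic_group[idx], TROPHIC_GROUPS), sum
    )
    groups[names(sums)[!is.na(sums)]] <- sums[!is.na(sums)]
  }
  structure(
    list(
      per_taxon = per_taxon,
      BaF = groups[["Ba"]], FuF = groups[["Fu"]],
      PpF = groups[["Pp"]], OpF = groups[["Op"]],
      NMF = sum(per_taxon)
    ),
    class = "footprint_set"
  )
}

#' @export
print.footprint_set <- function(x, ...) {
  cat(sprintf(
    "Metabolic footprints: NMF = %.4g (Ba %.4g, Fu %.4g, Pp %.4g, Op %.4g; %d taxa)\n",
    x$NMF, x$BaF, x$FuF, x$PpF, x$OpF, length(x$per_taxon)
  ))
  invisible(x)
}

#' Enrichment and structure footprints
#'
#' Partitions the metabolic footprint by life-history strategy: `Fe` sums
#' the footprints of c-p 1-2 taxa (fast-responding enrichment opportunists)
#' and `Fs` those of c-p 3-5 taxa (persisters indicating food-web
#' structure). With `free_living_only = FALSE` (default) every taxon is
#' included, so `Fe + Fs` equals the total NMF; with `TRUE`, plant
#' parasites are excluded from both and the partition identity no longer
#' refers to the all-taxa NMF.
#'
#' @param x Named genus-abundance vector for one sample.
#' @param traits A `trait_table`.
#' @param free_living_only Exclude plant-parasitic taxa (default `FALSE`).
#' @return Numeric vector `c(Fe = , Fs = )`.
#' @export
enrichment_structure_footprints <- function(x, traits,
                                            free_living_only = FALSE) {
  if (length(x) == 0L) {
    return(c(Fe = 0, Fs = 0))
  }
  idx <- resolve_genera(traits, names(x))
  keep <- if (free_living_only) {
    traits$trophic_group[idx] %in% FREE_LIVING_GROUPS
  } else {
    rep(TRUE, length(idx))
  }
  fp <- taxon_footprint(
    as.numeric(x), traits$fresh_weight_ug[idx], traits$cp_value[idx]
  )
  low <- traits$cp_value[idx] <= 2L
  c(Fe = sum(fp[keep & low]), Fs = sum(fp[keep & !low]))
}

#' Functional metabolic footprint (faunal-profile rhombus)
#'
#' Draws the rhombus centred on the faunal-profile point `(SI, EI)` with
#' horizontal half-diagonal `0.5 * Fs / k` and vertical half-diagonal
#' `0.5 * Fe / k`, i.e. the four vertices
#' `(SI - 0.5 Fs/k, EI)`, `(SI + 0.5 Fs/k, EI)`,
#' `(SI, EI - 0.5 Fe/k)`, `(SI, EI + 0.5 Fe/k)`.
#' Its area — computed by the shoelace formula over the polygon
#' left, bottom, right, top — is the functional metabolic footprint and
#' equals `Fe * Fs / (2 k^2)` in closed form.
#'
#' @param EI,SI Enrichment and structure indices, in `[0, 100]`.
#' @param Fe,Fs Enrichment and structure footprints (>= 0).
#' @param k Conversion constant (> 0) scaling footprint units onto the
#'   0-100 index axes; the default 1 leaves footprints unscaled. `k` only
#'   matters for cross-study comparability of the plotted rhombus.
#' @return A `faunal_profile` list: `EI`, `SI`, `Fe`, `Fs`, `k`, `vertices`
#'   (4 x 2 matrix, columns `SI`/`EI`, rows `left`, `right`, `bottom`,
#'   `top`), `area`, and `quadrat` (see [classify_quadrat()]).
#' @examples
#' fp <- functional_footprint(EI = 50, SI = 50, Fe = 2, Fs = 4, k = 1)
#' fp$area # 4
#' @export
functional_footprint <- function(EI, SI, Fe, Fs, k = 1) {
  if (k <= 0) {
    nf_error("conversion constant k must be positive", "nemafauna_domain_error")
  }
  if (EI < 0 || EI > 100 || SI < 0 || SI > 100) {
    nf_error("EI and SI must lie in [0, 100]", "nemafauna_domain_error")
  }
  if (Fe < 0 || Fs < 0) {
    nf_error("footprints must be non-negative", "nemafauna_domain_error")
  }
  hx <- 0.5 * Fs / k
  hy <- 0.5 * Fe / k
  vertices <- rbind(
    left   = c(SI - hx, EI),
    right  = c(SI + hx, EI),
    bottom = c(SI, EI - hy),
    top    = c(SI, EI + hy)
  )
  colnames(vertices) <- c("SI", "EI")
  poly <- vertices[c("left", "bottom", "right", "top"), , drop = FALSE]
  structure(
    list(
      EI = EI, SI = SI, Fe = Fe, Fs = Fs, k = k,
      vertices = vertices,
      area = shoelace_area(poly[, 1L], poly[, 2L]),
      quadrat = classify_quadrat(EI, SI)
    ),
    class = "faunal_profile"
  )
}

# Shoelace (surveyor's) formula for the area of a simple polygon given in
# traversal order.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(seq_len(n)[-1L], 1L)
  0.5 * abs(sum(x * y[j] - x[j] * y))
}

QUADRAT_MEANING <- c(
  A = paste(
    "Quadrat A: nutrient-enriched but disturbed soil;",
    "the food web is disturbed to some extent."
  ),
  B = paste(
    "Quadrat B: better soil nutrient status with low disturbance;",
    "the food web is mature and stable."
  ),
  C = paste(
    "Quadrat C: poor nutrient enrichment but small disturbance;",
    "the food web is in a structured state."
  ),
  D = paste(
    "Quadrat D: poor nutrient status and high disturbance;",
    "the environment is stressed and the food web degraded."
  )
)

#' Faunal-profile quadrat of a sample
#'
#' Classifies the `(EI, SI)` point into the four quadrats of the faunal
#' profile: A (`EI > 50`, `SI <= 50`), B (`EI > 50`, `SI > 50`),
#' C (`EI <= 50`, `SI > 50`), D (`EI <= 50`, `SI <= 50`). Points exactly on
#' an axis (EI or SI equal to 50) are assigned to the lower quadrat (the
#' `<=` side). The label's ecological reading is attached (attribute
#' `meaning`, also via [quadrat_interpretation()]).
#'
#' @param EI,SI Enrichment and structure indices in `[0, 100]`. Vectorized.
#' @return Factor with levels `A`, `B`, `C`, `D` and attribute `meaning`.
#' @examples
#' classify_quadrat(EI = 70, SI = 80) # B: mature, stable food web
#' @export
classify_quadrat <- function(EI, SI) {
  if (any(EI < 0 | EI > 100 | SI < 0 | SI > 100)) {
    nf_error("EI and SI must lie in [0, 100]", "nemafauna_domain_error")
  }
  lab <- ifelse(EI > 50,
    ifelse(SI > 50, "B", "A"),
    ifelse(SI > 50, "C", "D")
  )
  out <- factor(lab, levels = names(QUADRAT_MEANING))
  attr(out, "meaning") <- unname(QUADRAT_MEANING[lab])
  out
}

#' @rdname classify_quadrat
#' @param quadrat Quadrat label(s) (`"A"`-`"D"` or the factor returned by
#'   [classify_quadrat()]).
#' @export
quadrat_interpretation <- function(quadrat) {
  unname(QUADRAT_MEANING[as.character(quadrat)])
}

#' Per-sample footprint table
#'
#' Computes BaF, FuF, PpF, OpF, NMF, Fe and Fs for every sample of a
#' community matrix.
#'
#' @inheritParams nema_indices
#' @param free_living_only Passed to [enrichment_structure_footprints()].
#' @return Data frame, one row per sample.
#' @export
nema_footprints <- function(comm, traits, free_living_only = FALSE) {
  samples <- colnames(comm)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(comm)))
  rows <- lapply(seq_len(ncol(comm)), function(j) {
    x <- comm[, j]
    x <- x[x > 0]
    fp <- group_footprints(x, traits)
    fes <- enrichment_structure_footprints(x, traits,
      free_living_only = free_living_only
    )
    data.frame(
      sample_id = samples[j],
      BaF = fp$BaF, FuF = fp$FuF, PpF = fp$PpF, OpF = fp$OpF,
      NMF = fp$NMF, Fe = fes[["Fe"]], Fs = fes[["Fs"]]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.faunal_profile <- function(x, ...) {
  cat(sprintf(
    "Faunal profile: EI = %.2f, SI = %.2f (quadrat %s)\n",
    x$EI, x$SI, as.character(x$quadrat)
  ))
  cat(sprintf(
    "  Fe = %.4g, Fs = %.4g, k = %g; functional footprint area = %.4g\n",
    x$Fe, x$Fs, x$k, x$area
  ))
  cat(" ", quadrat_interpretation(x$quadrat), "\n")
  invisible(x)
}

#' Plot a faunal profile
#'
#' Draws the EI x SI plane (SI horizontal, EI vertical, quadrant lines at
#' 50) with the functional-metabolic-footprint rhombus and its centre.
#' Additional profiles can be overlaid with `add = TRUE`.
#'
#' @param x A `faunal_profile`.
#' @param add Overlay on an existing plot.
#' @param col Colour for the rhombus border and centre point.
#' @param ... Further arguments passed to [graphics::polygon()].
#' @return `x`, invisibly.
#' @export
plot.faunal_profile <- function(x, add = FALSE, col = "steelblue", ...) {
  poly <- x$vertices[c("left", "bottom", "right", "top"), , drop = FALSE]
  if (!add) {
    graphics::plot(NA,
      xlim = c(0, 100), ylim = c(0, 100),
      xlab = "Structure index (SI)", ylab = "Enrichment index (EI)",
      main = "Faunal profile"
    )
    graphics::abline(h = 50, v = 50, lty = 2, col = "grey50")
    graphics::text(
      c(25, 75, 75, 25), c(96, 96, 4, 4), c("A", "B", "C", "D"),
      col = "grey40"
    )
  }
  graphics::polygon(poly[, "SI"], poly[, "EI"], border = col, ...)
  graphics::points(x$SI, x$EI, pch = 19, col = col)
  invisible(x)
}
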