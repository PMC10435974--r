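#' Read a community table from delimited text
#'
#' Rows are genera, columns are samples; the first column holds the genus
#' name. Comma or tab separation is auto-detected and `#` comment lines are
#' skipped. Values are abundances (conventionally individuals per 100 g dry
#' soil); absences must be coded as 0, not left missing.
#'
#' @param path Path to the delimited file.
#' @return A numeric matrix, genera in rows (rownames), samples in columns.
#' @seealso [write_community()], [read_metadata()]
#' @export
read_community <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = detect_sep(path), comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE, quote = "\""
  )
  if (ncol(df) < 2L) {
    nf_error(
      "community table needs a genus column plus at least one sample column",
      "nemafauna_format_error"
    )
  }
  genera <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genera
  if (anyNA(mat)) {
    nf_error(
      "community table contains missing values; code absences as 0",
      "nemafauna_validation_error"
    )
  }
  if (any(mat < 0)) {
    nf_error("abundances must be non-negative", "nemafauna_validation_error")
  }
  mat
}

#' Write a community matrix to delimited text
#'
#' @param comm Numeric matrix, genera in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community <- function(comm, path) {
  df <- data.frame(genus = rownames(comm), comm,
    check.names = FALSE, row.names = NULL
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited text keyed by `sample_id`, with at least `treatment`,
#' `replicate` and `dry_mass_g` columns plus any number of free covariate
#' columns (soil moisture, pH, organic carbon, microbial biomass, plant
#' biomass, ...).
#'
#' @param path Path to the delimited file.
#' @return A data frame, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = detect_sep(path), comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE, quote = "\""
  )
  if (!"sample_id" %in% names(df)) {
    nf_error("metadata must have a sample_id column", "nemafauna_format_error")
  }
  df
}

#' Convert an extraction count to individuals per 100 g dry soil
#'
#' @param raw_count Individuals counted in the extract of one sample.
#' @param dry_mass Dry-soil mass of that sample in grams (> 0).
#' @return `raw_count * 100 / dry_mass`. Vectorized.
#' @examples
#' normalize_abundance(150, 50) # 300 per 100 g
#' @export
normalize_abundance <- function(raw_count, dry_mass) {
  if (any(dry_mass <= 0)) {
    nf_error("dry-soil mass must be positive", "nemafauna_domain_error")
  }
  if (any(raw_count < 0)) {
    nf_error("counts must be non-negative", "nemafauna_domain_error")
  }
  raw_count * 100 / dry_mass
}

#' Allocate a total abundance across genera from an identification subsample
#'
#' Field protocols count the total extract but identify only a fixed
#' subsample (typically 100 individuals) to genus. This expands the
#' subsample composition to per-genus abundances: each genus receives
#' `total_per100g * count / sum(counts)`, so the genus abundances sum
#' exactly to the total.
#'
#' @param total_per100g Total abundance of the sample (individuals per
#'   100 g dry soil).
#' @param identified_counts Named vector of genus counts in the
#'   identification subsample.
#' @return Named numeric vector of per-genus abundances.
#' @examples
#' expand_identification(300, c(Rhabditis = 25, Plectus = 75))
#' @export
expand_identification <- function(total_per100g, identified_counts) {
  if (total_per100g < 0) {
    nf_error("total abundance must be non-negative", "nemafauna_domain_error")
  }
  if (any(identified_counts < 0)) {
    nf_error("subsample counts must be non-negative", "nemafauna_domain_error")
  }
  n <- sum(identified_counts)
  if (total_per100g == 0) {
    return(setNames(numeric(length(identified_counts)), names(identified_counts)))
  }
  if (n <= 0) {
    nf_error(
      "empty identification subsample for a sample with positive abundance",
      "nemafauna_domain_error"
    )
  }
  total_per100g * identified_counts / n
}

#' Sum genus abundances into the four trophic groups
#'
#' @param x Named numeric vector of genus abundances for one sample.
#' @param traits A `trait_table`; every genus in `x` must resolve
#'   (case-insensitively), otherwise an error lists all missing genera.
#' @return Numeric vector `c(Ba = , Fu = , Pp = , Op = )`; the four entries
#'   sum to `sum(x)`.
#' @examples
#' aggregate_trophic(
#'   c(Rhabditis = 40, Aphelenchoides = 30, Pratylenchus = 30),
#'   default_traits()
#' )
#' @export
aggregate_trophic <- function(x, traits) {
  out <- setNames(numeric(4L), TROPHIC_GROUPS)
  if (length(x) == 0L) {
    return(out)
  }
  idx <- resolve_genera(traits, names(x))
  grp <- factor(traits$trophic_group[idx], levels = TROPHIC_GROUPS)
  sums <- tapply(as.numeric(x), grp, sum)
  out[names(sums)[!is.na(sums)]] <- sums[!is.na(sums)]
  out
}

#' Relative abundances per sample
#'
#' Divides each sample (column) by its total.
#'
#' @param comm Community matrix, genera in rows, samples in columns.
#' @return Matrix of the same shape with unit column sums.
#' @export
relative_abundance <- function(comm) {
  tot <- colSums(comm)
  if (any(tot <= 0)) {
    nf_error(
      sprintf(
        "sample(s) with zero total abundance: %s",
        paste(colnames(comm)[tot <= 0], collapse = ", ")
      ),
      "nemafauna_domain_error"
    )
  }
  sweep(comm, 2L, tot, "/")
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over positive entries, with `p_i` the relative
#' abundance. Natural-log based, so the maximum for `S` equally abundant
#' taxa is `ln(S)`.
#'
#' @param x Non-negative abundance (or proportion) vector with at least one
#'   positive entry.
#' @return `H` in nats.
#' @examples
#' shannon_index(rep(25, 4)) # log(4)
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) {
    nf_error("abundances must be non-negative", "nemafauna_domain_error")
  }
  tot <- sum(x)
  if (tot <= 0) {
    nf_error(
      "Shannon index undefined for an all-zero community",
      "nemafauna_domain_error"
    )
  }
  p <- x[x > 0] / tot
  -sum(p * log(p))
}
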