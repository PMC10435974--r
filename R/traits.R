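#' Load a genus trait table
#'
#' Reads a delimited text file (comma- or tab-separated, auto-detected; lines
#' starting with `#` are ignored) assigning each nematode genus its trophic
#' group, colonizer-persister (c-p) value and mean fresh body weight. These
#' traits are the classification backbone for every index and footprint in
#' the package.
#'
#' The file must have header columns `genus`, `trophic_group`, `cp_value` and
#' `fresh_weight_ug`; an optional logical `predator` column flags predatory
#' taxa so that c-p 2 predators can enter the structure component of the
#' enrichment/structure indices (see [enrichment_structure_components()]).
#'
#' @param path Path to the delimited trait file.
#' @return A `trait_table`: a data frame with one validated row per genus and
#'   columns `genus`, `trophic_group` (one of `"Ba"`, `"Fu"`, `"Pp"`, `"Op"`),
#'   `cp_value` (integer 1-5), `fresh_weight_ug` (positive, micrograms per
#'   individual) and `predator` (logical).
#' @seealso [default_traits()] for the packaged reference table,
#'   [trait_lookup()], [write_traits()].
#' @examples
#' traits <- default_traits()
#' head(traits)
#' @export
load_traits <- function(path) {
  if (!file.exists(path)) {
    nf_error(sprintf("trait file not found: %s", path), "nemafauna_format_error")
  }
  df <- utils::read.table(path,
    header = TRUE, sep = detect_sep(path), comment.char = "#",
    stringsAsFactors = FALSE, strip.white = TRUE, quote = "\""
  )
  required <- c("genus", "trophic_group", "cp_value", "fresh_weight_ug")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    nf_error(
      sprintf(
        "trait table is missing required column(s): %s",
        paste(missing, collapse = ", ")
      ),
      "nemafauna_format_error"
    )
  }
  if (!"predator" %in% names(df)) {
    df$predator <- rep(FALSE, nrow(df))
  }
  df <- df[, c(required, "predator")]
  df$genus <- as.character(df$genus)
  df$trophic_group <- as.character(df$trophic_group)
  df$cp_value <- as.integer(df$cp_value)
  df$fresh_weight_ug <- as.numeric(df$fresh_weight_ug)
  df$predator <- as.logical(df$predator)
  validate_traits(df)
  structure(df, class = c("trait_table", "data.frame"))
}

validate_traits <- function(df) {
  if (nrow(df) == 0L) {
    return(invisible(df))
  }
  dup <- duplicated(tolower(df$genus))
  if (any(dup)) {
    nf_error(
      sprintf(
        "duplicate genus name(s): %s",
        paste(unique(df$genus[dup]), collapse = ", ")
      ),
      "nemafauna_validation_error"
    )
  }
  bad_group <- !df$trophic_group %in% TROPHIC_GROUPS
  if (any(bad_group)) {
    nf_error(
      sprintf(
        "invalid trophic group for genus %s (must be one of %s)",
        paste(df$genus[bad_group], collapse = ", "),
        paste(TROPHIC_GROUPS, collapse = ", ")
      ),
      "nemafauna_validation_error"
    )
  }
  bad_cp <- is.na(df$cp_value) | !df$cp_value %in% 1:5
  if (any(bad_cp)) {
    nf_error(
      sprintf(
        "c-p value outside 1-5 for genus %s",
        paste(df$genus[bad_cp], collapse = ", ")
      ),
      "nemafauna_validation_error"
    )
  }
  bad_w <- is.na(df$fresh_weight_ug) | df$fresh_weight_ug <= 0
  if (any(bad_w)) {
    nf_error(
      sprintf(
        "fresh weight must be a positive number of micrograms (genus %s)",
        paste(df$genus[bad_w], collapse = ", ")
      ),
      "nemafauna_validation_error"
    )
  }
  invisible(df)
}

#' Packaged reference trait table
#'
#' Loads the trait table shipped with the package: 46 genera commonly
#' encountered in temperate orchard and arable soils (19 bacterivores, 6
#' fungivores, 9 plant parasites, 12 omnivores/predators). Trophic groups and
#' c-p values follow the standard Yeates/Bongers conventions; fresh weights
#' are representative literature-scale values (Nemaplex order of magnitude),
#' intended as sensible defaults. For publication-grade work supply your own
#' table via [load_traits()].
#'
#' @return A `trait_table` (see [load_traits()]).
#' @export
default_traits <- function() {
  load_traits(system.file("extdata", "nematode_traits.csv",
    package = "nemafauna", mustWork = TRUE
  ))
}

#' Write a trait table to delimited text
#'
#' Inverse of [load_traits()]: writes a CSV that [load_traits()] reads back
#' field-for-field.
#'
#' @param traits A `trait_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(as.data.frame(traits), path,
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Look up one genus in a trait table
#'
#' Matching is case-insensitive. An unknown genus is an explicit error (class
#' `nemafauna_lookup_error`), never a silent default.
#'
#' @param traits A `trait_table`.
#' @param genus Single genus name.
#' @return The one-row data frame for that genus.
#' @examples
#' trait_lookup(default_traits(), "Rhabditis")
#' @export
trait_lookup <- function(traits, genus) {
  stopifnot(length(genus) == 1L)
  i <- match(tolower(genus), tolower(traits$genus))
  if (is.na(i)) {
    nf_error(
      sprintf("genus not found in trait table: %s", genus),
      "nemafauna_lookup_error"
    )
  }
  as.data.frame(traits)[i, , drop = FALSE]
}

# Resolve a vector of genus names against the trait table, erroring with the
# full list of misses. Returns the matching row indices.
resolve_genera <- function(traits, genera) {
  idx <- match(tolower(genera), tolower(traits$genus))
  if (anyNA(idx)) {
    nf_error(
      sprintf(
        "genus not found in trait table: %s",
        paste(genera[is.na(idx)], collapse = ", ")
      ),
      "nemafauna_lookup_error"
    )
  }
  idx
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf(
    "Nematode trait table: %d genera (%s)\n", nrow(x),
    paste(sprintf(
      "%s %d", TROPHIC_GROUPS,
      as.integer(table(factor(x$trophic_group, TROPHIC_GROUPS)))
    ), collapse = ", ")
  ))
  print(as.data.frame(x), ...)
  invisible(x)
}
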