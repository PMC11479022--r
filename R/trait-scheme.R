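#' Trait descriptor schemes
#'
#' A trait scheme is the dictionary that drives every downstream step: one row
#' per trait, giving its name, the descriptor catalogue code it was taken
#' from, whether it is recorded as a categorical class or a raw number, the
#' ordered class labels (categorical traits), and measurement units
#' (quantitative traits). [cardamom_traits()] returns the default scheme of 17
#' IPGRI descriptors used to characterise cardamom (*Elettaria cardamomum*)
#' germplasm: 15 categorical traits plus two quantitative ones (cluster
#' internodal length in cm and capsules per cluster as a count).
#'
#' @param traits A data frame with columns `trait`, `ipgri_code`, `kind`
#'   (`"categorical"` or `"quantitative"`), `classes` (list column of ordered
#'   class labels; empty for quantitative traits) and `units` (empty for
#'   categorical traits).
#'
#' @return A tibble of class `germ_scheme`.
#' @examples
#' scheme <- cardamom_traits()
#' scheme
#' sum(lengths(scheme$classes))  # categorical class columns before binning
#' @export
trait_scheme <- function(traits) {
  df <- as_tibble(traits)
  needed <- c("trait", "ipgri_code", "kind", "classes", "units")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("trait scheme lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$trait)) {
    abort("trait names must be unique within a scheme")
  }
  if (!all(df$kind %in% c("categorical", "quantitative"))) {
    abort("trait kind must be 'categorical' or 'quantitative'")
  }
  for (i in seq_len(nrow(df))) {
    if (df$kind[i] == "categorical") {
      cls <- df$classes[[i]]
      if (length(cls) < 2 || anyDuplicated(cls)) {
        abort(paste0("categorical trait '", df$trait[i],
                     "' needs >= 2 distinct class labels"))
      }
    } else if (!nzchar(df$units[i])) {
      abort(paste0("quantitative trait '", df$trait[i], "' needs units"))
    }
  }
  structure(df, class = c("germ_scheme", class(df)))
}

#' @rdname trait_scheme
#' @export
cardamom_traits <- function() {
  cat_trait <- function(trait, code, classes) {
    tibble(trait = trait, ipgri_code = code, kind = "categorical",
           classes = list(classes), units = "")
  }
  num_trait <- function(trait, code, units) {
    tibble(trait = trait, ipgri_code = code, kind = "quantitative",
           classes = list(character()), units = units)
  }
  trait_scheme(bind_rows(
    cat_trait("plant_height", "7.1.4", c("<2 m", "2-3 m", ">3 m")),
    cat_trait("stems_per_plant", "7.1.5", c("<15", "16-30", "31-45", ">45")),
    cat_trait("stem_color", "7.1.6", c("Light green", "Green", "Yellow")),
    cat_trait("rhizome_color", "7.1.8",
              c("White", "Light purple", "Light green", "Dark green",
                "Pale light purple")),
    cat_trait("leaf_shape", "7.1.10", c("Lanceolate", "Oblong", "Oval")),
    cat_trait("leaf_pubescence", "7.1.12", c("Glabra", "Dense", "Spaced")),
    cat_trait("panicle_type", "7.2.4", c("Creeping", "Semi-erect", "Erect")),
    cat_trait("panicles_per_stem", "7.2.6", c("1", "2", ">3")),
    cat_trait("panicles_per_plant", "7.2.5",
              c("<10", "11-20", "21-30", ">31")),
    cat_trait("panicle_length", "7.2.7",
              c("<50 cm", "51-75 cm", "76-100 cm", ">100 cm")),
    cat_trait("clusters_per_panicle", "7.2.8", c("<20", "20-30", "30-40")),
    num_trait("internodal_length", "7.2.10", "cm"),
    cat_trait("panicle_branching", "7.2.11", c("Presence", "Absence")),
    cat_trait("branching_pattern", "7.2.11.1", c("Proximal", "Absent")),
    num_trait("capsules_per_cluster", "7.2.20", "count"),
    cat_trait("capsule_form", "7.2.21", c("Ellipsoid", "Globose", "Ovoid")),
    cat_trait("capsule_color", "7.2.23",
              c("Yellow", "Green", "Dark green", "Light green"))
  ))
}

scheme_categorical <- function(scheme) scheme$trait[scheme$kind == "categorical"]
scheme_quantitative <- function(scheme) scheme$trait[scheme$kind == "quantitative"]

scheme_classes <- function(scheme, trait) {
  scheme$classes[[match(trait, scheme$trait)]]
}

#' Validate an accession table against a trait scheme
#'
#' Checks that the table has an `accession` identifier column and one column
#' per scheme trait, that identifiers are unique, that every categorical value
#' is one of the trait's class labels, and that quantitative values are
#' finite, non-negative numbers. Offending values are reported with their row
#' and column so field data can be corrected at the source.
#'
#' @param df A data frame with an `accession` column and one column per trait.
#' @param scheme A [trait_scheme()].
#' @return The validated table as a tibble (invisibly usable in a pipe).
#' @export
validate_accessions <- function(df, scheme = cardamom_traits()) {
  df <- as_tibble(df)
  if (!"accession" %in% names(df)) {
    abort("accession table needs an 'accession' identifier column")
  }
  missing_traits <- setdiff(scheme$trait, names(df))
  if (length(missing_traits) > 0) {
    abort(paste0("accession table lacks trait column(s): ",
                 paste(missing_traits, collapse = ", ")), class = "germ_schema_error")
  }
  dup <- unique(df$accession[duplicated(df$accession)])
  if (length(dup) > 0) {
    abort(paste0("duplicate accession id(s): ", paste(dup, collapse = ", ")),
          class = "germ_validation_error")
  }
  for (tr in scheme$trait) {
    v <- df[[tr]]
    if (scheme$kind[match(tr, scheme$trait)] == "categorical") {
      cls <- scheme_classes(scheme, tr)
      bad <- which(!(as.character(v) %in% cls))
      if (length(bad) > 0) {
        abort(paste0("trait '", tr, "', row ", bad[1], ": value '",
                     as.character(v)[bad[1]], "' is not one of: ",
                     paste(cls, collapse = ", ")),
              class = "germ_validation_error")
      }
    } else {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.finite(vn) | vn < 0)
      if (length(bad) > 0) {
        abort(paste0("trait '", tr, "', row ", bad[1],
                     ": quantitative value '", as.character(v)[bad[1]],
                     "' must be a finite non-negative number"),
              class = "germ_validation_error")
      }
    }
  }
  df
}

#' Read an accession table from CSV or TSV
#'
#' The file must have a header row naming the traits and a first column of
#' accession identifiers (named `accession`). The delimiter is taken from the
#' file extension (`.tsv`/`.txt` tab, otherwise comma). The table is validated
#' against `scheme` before it is returned.
#'
#' @param path Path to a CSV/TSV file.
#' @inheritParams validate_accessions
#' @return A validated tibble, one row per accession.
#' @export
read_accessions <- function(path, scheme = cardamom_traits()) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  names(df)[1] <- "accession"
  df$accession <- as.character(df$accession)
  validate_accessions(df, scheme)
}
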