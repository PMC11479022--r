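#' One-hot encode an accession table
#'
#' Expands every trait into presence/absence indicator columns: categorical
#' traits get one column per descriptor class, quantitative traits are first
#' binned into ten sigma-levels (see [make_binning()]) and get one column per
#' level. Within each trait exactly one indicator per accession equals 1, so
#' row sums equal the number of traits. Column names are `trait|class`
#' compounds in scheme order, then class order.
#'
#' @inheritParams validate_accessions
#' @param bins Named list of `germ_binning` objects, one per quantitative
#'   trait. Defaults to binnings estimated from `df` itself via
#'   [trait_binnings()]; pass pre-computed binnings to encode new accessions
#'   on a fixed scale.
#' @return A tibble: `accession` plus 0/1 indicator columns. The trait/class
#'   layout is attached as attribute `"layout"` (a tibble with columns
#'   `trait`, `class`, `column`).
#' @examples
#' tab <- simulate_accessions(n = 20, seed = 1)
#' ind <- encode_indicators(tab)
#' all(rowSums(ind[-1]) == 17)
#' @export
encode_indicators <- function(df, scheme = cardamom_traits(), bins = NULL) {
  df <- validate_accessions(df, scheme)
  if (is.null(bins)) bins <- trait_binnings(df, scheme)
  qt <- scheme_quantitative(scheme)
  missing_bins <- setdiff(qt, names(bins))
  if (length(missing_bins) > 0) {
    abort(paste0("no binning provided for quantitative trait(s): ",
                 paste(missing_bins, collapse = ", ")))
  }
  blocks <- vector("list", nrow(scheme))
  layout <- vector("list", nrow(scheme))
  for (i in seq_len(nrow(scheme))) {
    tr <- scheme$trait[i]
    if (scheme$kind[i] == "categorical") {
      cls <- scheme$classes[[i]]
      lev <- match(as.character(df[[tr]]), cls)
    } else {
      cls <- bin_labels()
      lev <- assign_level(as.numeric(df[[tr]]), bins[[tr]])
    }
    m <- matrix(0L, nrow = nrow(df), ncol = length(cls))
    m[cbind(seq_len(nrow(df)), lev)] <- 1L
    colnames(m) <- paste0(tr, "|", cls)
    blocks[[i]] <- m
    layout[[i]] <- tibble(trait = tr, class = cls,
                          column = paste0(tr, "|", cls))
  }
  out <- bind_cols(tibble(accession = df$accession),
                   as_tibble(do.call(cbind, blocks)))
  attr(out, "layout") <- bind_rows(layout)
  out
}

#' @importFrom dplyr bind_cols
NULL

indicator_layout <- function(ind) {
  lay <- attr(ind, "layout")
  if (!is.null(lay)) return(lay)
  cols <- setdiff(names(ind), "accession")
  parts <- strsplit(cols, "|", fixed = TRUE)
  tibble(trait = vapply(parts, `[[`, "", 1),
         class = vapply(parts, function(p) paste(p[-1], collapse = "|"), ""),
         column = cols)
}

indicator_matrix <- function(ind) {
  m <- as.matrix(ind[setdiff(names(ind), "accession")])
  storage.mode(m) <- "double"
  rownames(m) <- ind$accession
  m
}

#' Recover class labels from an indicator matrix
#'
#' Inverts [encode_indicators()] by taking, per trait block, the class whose
#' indicator is 1. Quantitative traits decode to their level label
#' (`L01`..`L10`), not the original numeric value.
#'
#' @param ind An indicator tibble from [encode_indicators()].
#' @return A tibble with `accession` and one label column per trait.
#' @export
decode_indicators <- function(ind) {
  lay <- indicator_layout(ind)
  out <- tibble(accession = ind$accession)
  for (tr in unique(lay$trait)) {
    block <- lay[lay$trait == tr, ]
    m <- as.matrix(ind[block$column])
    out[[tr]] <- block$class[max.col(m, ties.method = "first")]
  }
  out
}
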