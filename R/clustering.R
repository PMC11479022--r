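#' Average-linkage (UPGMA) clustering of accessions on PC scores
#'
#' Builds a dendrogram from the pairwise Euclidean distances between
#' accessions on the selected principal-component score columns, merged by
#' unweighted between-groups average linkage (UPGMA): the distance between
#' two clusters is the mean of all between-cluster pairwise distances, so
#' merge heights are non-decreasing. Plain (not squared) Euclidean distance
#' is used; set `squared = TRUE` for software conventions that cluster on
#' squared distances.
#'
#' @param scores Score tibble from [component_scores()].
#' @param components Integer indices of the score columns to use.
#' @param squared Cluster on squared Euclidean distances instead.
#' @return An object of class `germ_dendro` wrapping the [stats::hclust()]
#'   tree (element `hclust`), with `labels` the accession ids.
#' @examples
#' ind <- simulate_accessions(n = 40, seed = 1) |> encode_indicators()
#' pca <- fit_pca(ind)
#' dend <- linkage_average(pca$scores, 1:3)
#' table(cut_k(dend, 4)$group)
#' @export
linkage_average <- function(scores, components, squared = FALSE) {
  if (nrow(scores) < 2) abort("clustering needs >= 2 accessions")
  cols <- paste0("PC", components)
  missing_cols <- setdiff(cols, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("score matrix lacks component(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(scores[cols])
  rownames(m) <- scores$accession
  d <- stats::dist(m, method = "euclidean")
  if (squared) d <- d^2
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, labels = scores$accession),
            class = "germ_dendro")
}

#' @export
print.germ_dendro <- function(x, ...) {
  cat("UPGMA dendrogram of", length(x$labels), "accessions",
      "(", length(x$hclust$height), "merges )\n")
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' Groups are labelled 1..k in order of first appearance in the accession
#' table, so labels do not depend on internal tree numbering.
#'
#' @param dend A `germ_dendro` from [linkage_average()].
#' @param k Number of groups (1..n).
#' @return A tibble: `accession`, `group` (integer 1..k).
#' @export
cut_k <- function(dend, k) {
  stopifnot(inherits(dend, "germ_dendro"))
  n <- length(dend$labels)
  if (k < 1 || k > n) abort(paste0("k must be in 1..", n))
  raw <- stats::cutree(dend$hclust, k = k)
  relab <- match(raw, unique(raw))  # 1..k by first appearance
  tibble(accession = dend$labels, group = as.integer(relab))
}

#' Characterise cluster groups by their dominant trait classes
#'
#' For every group and trait, the percentage of group members in each class
#' (quantitative traits over their sigma-levels); classes at or above the
#' dominance threshold are flagged as the group's defining features.
#'
#' @param partition Tibble from [cut_k()] (`accession`, `group`).
#' @param df The accession table the partition covers.
#' @inheritParams encode_indicators
#' @param dominance Percentage threshold for flagging a class (default 80).
#' @return A tibble: `group`, `n`, `trait`, `class`, `count`, `percent`,
#'   `dominant`.
#' @export
group_profile <- function(partition, df, scheme = cardamom_traits(),
                          bins = NULL, dominance = 80) {
  df <- validate_accessions(df, scheme)
  if (!all(df$accession %in% partition$accession)) {
    abort("partition does not cover every accession in the table")
  }
  if (is.null(bins)) bins <- trait_binnings(df, scheme)
  ind <- encode_indicators(df, scheme, bins = bins)
  lay <- indicator_layout(ind)
  joined <- left_join(partition, ind, by = "accession")
  out <- purrr::map(sort(unique(joined$group)), function(g) {
    rows <- joined[joined$group == g, ]
    cts <- colSums(rows[lay$column])
    tibble(group = g, n = nrow(rows), trait = lay$trait, class = lay$class,
           count = as.integer(unname(cts)),
           percent = unname(100 * cts / nrow(rows)))
  })
  out <- bind_rows(out)
  out$dominant <- out$percent >= dominance
  out
}

#' Export a dendrogram as Newick
#'
#' Converts the UPGMA tree to a `phylo` object (branch lengths from merge
#' heights) and writes it in Newick format.
#'
#' @param dend A `germ_dendro`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "germ_dendro"))
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
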