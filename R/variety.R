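#' Putative variety classification rules
#'
#' Cardamom germplasm is conventionally split into the putative foreign
#' cultivars 'Malabar' (short-statured) and 'Mysore'/'Vazhukka' (robust,
#' exceeding 3 m). Two visual rules are implemented: by plant height (classes
#' `<2 m` and `2-3 m` are Malabar, `>3 m` is Mysore/Vazhukka) and by capsule
#' color (`Light green` and `Yellow` are Malabar, `Green` and `Dark green`
#' Mysore/Vazhukka). Both are total on valid tables; their agreement on real
#' collections is an empirical question, so the agreement rate is reported,
#' never assumed.
#'
#' @inheritParams validate_accessions
#' @return A tibble: `accession`, `by_height`, `by_capsule` (both
#'   `"Malabar"` or `"MysoreVazhukka"`), and `agree` (logical).
#' @examples
#' simulate_accessions(n = 20, seed = 1) |> classify_varieties()
#' @export
classify_varieties <- function(df, scheme = cardamom_traits()) {
  df <- validate_accessions(df, scheme)
  tibble(accession = df$accession,
         by_height = classify_by_height(df, scheme),
         by_capsule = classify_by_capsule(df, scheme)) %>%
    mutate(agree = .data$by_height == .data$by_capsule)
}

#' @rdname classify_varieties
#' @export
classify_by_height <- function(df, scheme = cardamom_traits()) {
  h <- as.character(df$plant_height)
  ifelse(h == ">3 m", "MysoreVazhukka", "Malabar")
}

#' @rdname classify_varieties
#' @export
classify_by_capsule <- function(df, scheme = cardamom_traits()) {
  cc <- as.character(df$capsule_color)
  ifelse(cc %in% c("Light green", "Yellow"), "Malabar", "MysoreVazhukka")
}

# one full comprehensive-evaluation pass: encode -> PCA -> components ->
# membership -> F. Binnings are recomputed from `df` itself so a subset run
# is a genuinely fresh analysis.
composite_run <- function(df, scheme, threshold = 6, fallback_k = 3) {
  bins <- trait_binnings(df, scheme)
  ind <- encode_indicators(df, scheme, bins = bins)
  model <- fit_pca(ind)
  sel <- select_components(model, "min_contribution", threshold = threshold,
                           fallback_k = fallback_k)
  u <- membership_rescale(model$scores, sel)
  f <- f_value(u, model, sel)
  list(bins = bins, indicators = ind, model = model, components = sel,
       fscores = f)
}

#' Two-stage excellent-accession and conservation selection
#'
#' Stage 1 runs the full comprehensive evaluation (encoding, covariance PCA,
#' component selection, membership rescaling, F-value) on all accessions and
#' selects the top `k1` by F-value. Because stature dominates the first
#' component, stage-1 selections tend to concentrate in one putative variety;
#' stage 2 therefore re-runs the entire analysis from scratch (fresh
#' binnings, fresh PCA axes, fresh memberships) on the height-defined
#' Mysore/Vazhukka subset only, and adds the top `k2` subset accessions not
#' already selected in stage 1. The union of the two stages (exactly `k1 +
#' k2` accessions) is the proposed conservation set; its average trait
#' diversity and its representation across dendrogram groups are reported.
#'
#' @inheritParams validate_accessions
#' @param k1 Stage-1 selection size (default 14).
#' @param k2 Stage-2 addition size (default 12).
#' @param partition Optional [cut_k()] partition used to count how many
#'   selected accessions fall in each dendrogram group.
#' @param threshold,fallback_k Component-selection policy passed to
#'   [select_components()] in both stages.
#' @return An object of class `germ_conservation`: `stage1`/`stage2` id
#'   vectors (ordered by rank), `union`, `stage1_fscores` and
#'   `stage2_fscores` tibbles, `h_stage1` and `h_union` (average H' of the
#'   two sets, on the full table's binning scale), `group_counts` (tibble,
#'   when `partition` is given) and the stage sizes.
#' @export
two_stage_selection <- function(df, scheme = cardamom_traits(), k1 = 14,
                                k2 = 12, partition = NULL, threshold = 6,
                                fallback_k = 3) {
  df <- validate_accessions(df, scheme)
  n <- nrow(df)
  if (k1 + k2 > n) {
    abort(paste0("two_stage_selection: k1 + k2 = ", k1 + k2,
                 " exceeds the ", n, " available accessions"))
  }
  run1 <- composite_run(df, scheme, threshold, fallback_k)
  stage1 <- rank_and_select(run1$fscores, k1)

  tall <- classify_by_height(df, scheme)
  sub <- df[tall == "MysoreVazhukka", ]
  if (nrow(sub) == 0) {
    abort("stage 2 impossible: no accession exceeds 3 m (Mysore/Vazhukka subset is empty)")
  }
  run2 <- composite_run(sub, scheme, threshold, fallback_k)
  order2 <- rank_and_select(run2$fscores, nrow(sub))
  stage2 <- setdiff(order2, stage1)
  if (length(stage2) < k2) {
    abort(paste0("stage 2 impossible: only ", length(stage2),
                 " Mysore/Vazhukka accessions outside stage 1; need ", k2))
  }
  stage2 <- stage2[seq_len(k2)]
  union_ids <- c(stage1, stage2)

  bins_full <- trait_binnings(df, scheme)
  h1 <- subset_average_diversity(df, scheme, stage1, bins = bins_full)
  hu <- subset_average_diversity(df, scheme, union_ids, bins = bins_full)

  group_counts <- NULL
  if (!is.null(partition)) {
    group_counts <- partition %>%
      filter(.data$accession %in% union_ids) %>%
      count(.data$group, name = "n_selected")
  }
  structure(list(stage1 = stage1, stage2 = stage2, union = union_ids,
                 stage1_fscores = run1$fscores, stage2_fscores = run2$fscores,
                 h_stage1 = h1, h_union = hu, group_counts = group_counts,
                 k1 = k1, k2 = k2),
            class = "germ_conservation")
}

#' @export
print.germ_conservation <- function(x, ...) {
  cat("Two-stage conservation selection: ", x$k1, " + ", x$k2, " = ",
      length(x$union), " accessions\n", sep = "")
  cat("Average H': stage 1 =", format(x$h_stage1, digits = 3),
      " union =", format(x$h_union, digits = 3), "\n")
  invisible(x)
}

#' Check dendrogram-group coverage of a conservation set
#'
#' A conservation set should represent every germplasm group; this reports
#' how many selected accessions fall in each group of a partition and
#' whether all groups meet a minimum.
#'
#' @param report A `germ_conservation` from [two_stage_selection()], or a
#'   character vector of accession ids.
#' @param partition A [cut_k()] partition covering the selected ids.
#' @param min_per_group Minimum selected members per group (default 2).
#' @return A list: `ok` (logical), `counts` (tibble `group`, `n_selected`),
#'   and `failing_groups` (integer vector, empty when `ok`).
#' @export
coverage_check <- function(report, partition, min_per_group = 2) {
  ids <- if (inherits(report, "germ_conservation")) report$union else report
  counts <- partition %>%
    mutate(selected = .data$accession %in% ids) %>%
    group_by(.data$group) %>%
    summarise(n_selected = sum(.data$selected), .groups = "drop")
  failing <- counts$group[counts$n_selected < min_per_group]
  list(ok = length(failing) == 0, counts = counts,
       failing_groups = failing)
}
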