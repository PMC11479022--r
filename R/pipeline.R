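#' Run the full germplasm evaluation pipeline
#'
#' One call that chains every stage — diversity profile, indicator encoding,
#' covariance PCA, component selection, F-value ranking, stepwise selection
#' equation, UPGMA grouping, group characterisation, variety classification
#' and the two-stage conservation selection — and writes a report bundle of
#' plain-text artifacts mirroring the tables a germplasm characterisation
#' study reports.
#'
#' @param df An accession table; if `NULL` a synthetic collection of `n`
#'   accessions is simulated with `seed`.
#' @param n,seed Synthetic-collection size and seed (used when `df` is NULL).
#' @inheritParams validate_accessions
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing and just returns the results.
#' @param threshold,fallback_k Component selection policy (see
#'   [select_components()]).
#' @param k_groups Number of dendrogram groups (default 6).
#' @param k1,k2 Two-stage selection sizes (defaults 14 and 12).
#' @param entry_alpha,removal_alpha Stepwise thresholds (defaults 0.05, 0.10).
#' @param dominance Group-profile dominance threshold in percent (default 80).
#' @return (Invisibly) a list with every intermediate result: `table`,
#'   `diversity`, `indicators`, `pca`, `components`, `fscores`, `stepwise`,
#'   `dendrogram`, `partition`, `profile`, `varieties`, `conservation`,
#'   `coverage`, and `files` (paths written, if any).
#' @examples
#' res <- run_pipeline(n = 60, seed = 1, k1 = 5, k2 = 3, k_groups = 3)
#' length(res$conservation$union)
#' @export
run_pipeline <- function(df = NULL, n = 288, seed = NULL,
                         scheme = cardamom_traits(), out_dir = NULL,
                         threshold = 6, fallback_k = 3, k_groups = 6,
                         k1 = 14, k2 = 12, entry_alpha = 0.05,
                         removal_alpha = 0.10, dominance = 80) {
  if (is.null(df)) df <- simulate_accessions(n = n, seed = seed,
                                             scheme = scheme)
  df <- validate_accessions(df, scheme)
  if (k1 + k2 > nrow(df)) {
    abort(paste0("two_stage_selection: k1 + k2 = ", k1 + k2,
                 " exceeds the ", nrow(df), " available accessions"))
  }
  bins <- trait_binnings(df, scheme)
  diversity <- diversity_profile(df, scheme, bins = bins)
  ind <- encode_indicators(df, scheme, bins = bins)
  pca <- fit_pca(ind)
  sel <- select_components(pca, "min_contribution", threshold = threshold,
                           fallback_k = fallback_k)
  u <- membership_rescale(pca$scores, sel)
  fscores <- f_value(u, pca, sel)
  sw <- fit_stepwise(ind, fscores$f_value, entry_alpha, removal_alpha)
  dend <- linkage_average(pca$scores, sel)
  partition <- cut_k(dend, k_groups)
  profile <- group_profile(partition, df, scheme, bins = bins,
                           dominance = dominance)
  varieties <- classify_varieties(df, scheme)
  conservation <- two_stage_selection(df, scheme, k1 = k1, k2 = k2,
                                      partition = partition,
                                      threshold = threshold,
                                      fallback_k = fallback_k)
  coverage <- coverage_check(conservation, partition)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- function(x) file.path(out_dir, x)

    div_out <- diversity %>%
      mutate(counts = purrr::map_chr(
        .data$counts, ~ paste(names(.x), .x, sep = "=", collapse = "; ")))
    readr::write_csv(div_out, path("diversity.csv"))

    load_wide <- tidyr::pivot_wider(tidy(pca), names_from = "component",
                                    values_from = "loading")
    readr::write_csv(load_wide, path("loadings.csv"))
    readr::write_csv(glance(pca), path("eigenvalues.csv"))

    rk <- arrange(fscores, .data$rank, .data$accession)
    readr::write_csv(rk, path("ranking.csv"))

    readr::write_csv(profile, path("group_profile.csv"))

    cons_tab <- bind_rows(
      tibble(stage = 1L, accession = conservation$stage1),
      tibble(stage = 2L, accession = conservation$stage2)) %>%
      left_join(varieties[c("accession", "by_height")], by = "accession") %>%
      left_join(partition, by = "accession") %>%
      left_join(bind_rows(
        conservation$stage1_fscores[c("accession", "f_value")] %>%
          mutate(stage = 1L),
        conservation$stage2_fscores[c("accession", "f_value")] %>%
          mutate(stage = 2L)), by = c("accession", "stage")) %>%
      group_by(.data$stage) %>%
      mutate(rank_in_stage = row_number()) %>%
      ungroup()
    readr::write_csv(cons_tab, path("conservation.csv"))

    eq <- list(intercept = sw$intercept,
               terms = sw$terms[c("trait", "class", "coefficient")],
               r = sw$r, r2 = sw$r2)
    jsonlite::write_json(eq, path("equation.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    writeLines(utils::capture.output(print(sw)), path("equation.txt"))

    write_newick(dend, path("dendrogram.nwk"))

    log <- list(package = "germeval",
                version = as.character(utils::packageVersion("germeval")),
                r_version = paste(R.version$major, R.version$minor, sep = "."),
                seed = if (is.null(seed)) NA else seed,
                n_accessions = nrow(df),
                config = list(threshold = threshold, fallback_k = fallback_k,
                              k_groups = k_groups, k1 = k1, k2 = k2,
                              entry_alpha = entry_alpha,
                              removal_alpha = removal_alpha,
                              dominance = dominance))
    jsonlite::write_json(log, path("run_log.json"), auto_unbox = TRUE)
    files <- vapply(c("diversity.csv", "loadings.csv", "eigenvalues.csv",
                      "ranking.csv", "group_profile.csv", "conservation.csv",
                      "equation.json", "equation.txt", "dendrogram.nwk",
                      "run_log.json"), path, "")
  }

  invisible(list(table = df, diversity = diversity, indicators = ind,
                 pca = pca, components = sel, fscores = fscores,
                 stepwise = sw, dendrogram = dend, partition = partition,
                 profile = profile, varieties = varieties,
                 conservation = conservation, coverage = coverage,
                 files = files))
}
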