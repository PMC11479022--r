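#' Shannon-Wiener diversity index
#'
#' Entropy \eqn{H' = -\sum_i P_i \ln P_i} of a class-count vector, in nats,
#' with \eqn{P_i = n_i / \sum n_i}. Classes with zero count contribute
#' nothing (the usual \eqn{0 \ln 0 = 0} convention). \eqn{H'} ranges from 0
#' (all accessions in one class) to \eqn{\ln k} for k equally frequent
#' classes.
#'
#' @param counts Non-negative numeric vector of class counts; must sum to a
#'   positive total.
#' @return The index in nats.
#' @examples
#' shannon_index(c(2, 167, 119))   # plant height classes of 288 accessions
#' shannon_index(rep(72, 4))       # uniform: log(4)
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) abort("empty distribution: all counts are zero",
                        class = "germ_empty_distribution")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Per-trait diversity profile of an accession table
#'
#' Tabulates each trait's class counts over the accessions (quantitative
#' traits over their ten sigma-levels) and computes the Shannon-Wiener index
#' per trait. For quantitative traits the descriptive summary (mean, min,
#' max, SD, CV) is included.
#'
#' @inheritParams encode_indicators
#' @return A tibble with one row per trait: `trait`, `kind`, `counts` (list
#'   column, named class counts), `h_prime`, and for quantitative traits
#'   `mean`, `min`, `max`, `sd`, `cv_percent`. Profile-level `min`, `max` and
#'   `mean` of `h_prime` are attached as attribute `"summary"`.
#' @examples
#' simulate_accessions(n = 50, seed = 1) |> diversity_profile()
#' @export
diversity_profile <- function(df, scheme = cardamom_traits(), bins = NULL) {
  df <- validate_accessions(df, scheme)
  if (is.null(bins)) bins <- trait_binnings(df, scheme)
  rows <- purrr::map(seq_len(nrow(scheme)), function(i) {
    tr <- scheme$trait[i]
    if (scheme$kind[i] == "categorical") {
      cls <- scheme$classes[[i]]
      cts <- table(factor(as.character(df[[tr]]), levels = cls))
      tibble(trait = tr, kind = "categorical",
             counts = list(setNames(as.integer(cts), cls)),
             h_prime = shannon_index(as.integer(cts)),
             mean = NA_real_, min = NA_real_, max = NA_real_,
             sd = NA_real_, cv_percent = NA_real_)
    } else {
      v <- as.numeric(df[[tr]])
      lev <- assign_level(v, bins[[tr]])
      cts <- tabulate(lev, nbins = 10L)
      st <- if (length(v) >= 2) descriptive_stats(v) else
        tibble(mean = base::mean(v), min = base::min(v), max = base::max(v),
               sd = NA_real_, cv_percent = NA_real_)
      tibble(trait = tr, kind = "quantitative",
             counts = list(setNames(cts, bin_labels())),
             h_prime = shannon_index(cts),
             mean = st$mean, min = st$min, max = st$max,
             sd = st$sd, cv_percent = st$cv_percent)
    }
  })
  out <- bind_rows(rows)
  attr(out, "summary") <- tibble(min = min(out$h_prime),
                                 max = max(out$h_prime),
                                 mean = base::mean(out$h_prime))
  out
}

#' Average trait diversity of an accession subset
#'
#' Mean over the scheme's traits of the Shannon-Wiener index computed on the
#' given subset of accessions only. Used to compare the diversity captured by
#' a selected core set against the full collection. Quantitative traits are
#' binned on the full table's scale so subsets are compared on common levels.
#'
#' @inheritParams encode_indicators
#' @param subset Character vector of accession ids (non-empty, all present in
#'   `df`).
#' @return Mean H' over traits (nats).
#' @export
subset_average_diversity <- function(df, scheme = cardamom_traits(), subset,
                                     bins = NULL) {
  df <- validate_accessions(df, scheme)
  if (length(subset) == 0) abort("subset must be non-empty")
  unknown <- setdiff(subset, df$accession)
  if (length(unknown) > 0) {
    abort(paste0("unknown accession id(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(bins)) bins <- trait_binnings(df, scheme)
  sub <- df[df$accession %in% subset, ]
  prof <- diversity_profile(sub, scheme, bins = bins)
  base::mean(prof$h_prime)
}

#' Descriptive statistics with coefficient of variation
#'
#' @param values Numeric vector of length >= 2.
#' @return One-row tibble: `mean`, `min`, `max`, `sd` (n-1 denominator) and
#'   `cv_percent` = 100 sd / mean.
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 2) abort("need >= 2 values")
  m <- base::mean(values)
  s <- stats::sd(values)
  if (m == 0 && s > 0) abort("CV undefined: mean is zero")
  tibble(mean = m, min = base::min(values), max = base::max(values), sd = s,
         cv_percent = if (s == 0) 0 else 100 * s / m)
}
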