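#' Membership-function rescaling of component scores
#'
#' Converts each selected component's scores to fuzzy membership values in
#' \[0, 1\] by per-component min-max rescaling: \eqn{u_{ij} = (S_{ij} - \min_i
#' S_{ij}) / (\max_i S_{ij} - \min_i S_{ij})}. The accession with the lowest
#' score on a component gets membership 0, the highest gets 1, and ordering
#' within a component is preserved. A degenerate component (all scores equal)
#' maps to a constant 0.5 with a warning, so it carries no ranking
#' information but keeps the weight algebra intact.
#'
#' @param scores Score tibble from [component_scores()].
#' @param components Integer indices of the components to rescale (e.g. from
#'   [select_components()]).
#' @return A tibble: `accession` plus one membership column per selected
#'   component (same `PC<j>` names).
#' @export
membership_rescale <- function(scores, components) {
  if (nrow(scores) < 2) abort("membership rescaling needs >= 2 accessions")
  cols <- paste0("PC", components)
  missing_cols <- setdiff(cols, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("score matrix lacks component(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(accession = scores$accession)
  for (cl in cols) {
    s <- scores[[cl]]
    rng <- range(s)
    if (rng[1] == rng[2]) {
      warn(paste0("component ", cl, " is degenerate (constant scores); ",
                  "membership set to 0.5"))
      out[[cl]] <- rep(0.5, length(s))
    } else {
      out[[cl]] <- (s - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Morphological composite value (F-value)
#'
#' The comprehensive-evaluation score of each accession: a weighted sum of
#' its membership values over the selected components, \eqn{F_i = \sum_j w_j
#' u_{ij}}, with weights proportional to the components' contribution rates.
#' By default the weights are normalised over the *selected* components
#' (\eqn{w_j = c_j / \sum_{k \in \mathrm{sel}} c_k}), so they sum to 1 and F
#' spans \[0, 1\]; `normalize_over = "all"` divides by the total contribution
#' instead, reproducing analyses that keep the selected components' absolute
#' share. Higher F means a more favourable composite morphology.
#'
#' @param u Membership tibble from [membership_rescale()].
#' @param model The fitted [fit_pca()] model (source of contribution rates).
#' @param components Integer indices of the selected components (must match
#'   the membership columns).
#' @param normalize_over `"selected"` (default) or `"all"`.
#' @return A tibble of class `germ_fscore`: `accession`, `f_value`, `rank`
#'   (1 = highest F; ties share the smallest rank — dense ranking — and are
#'   broken by ascending accession id in orderings). Weights are attached as
#'   attribute `"weights"`.
#' @examples
#' ind <- simulate_accessions(n = 60, seed = 1) |> encode_indicators()
#' pca <- fit_pca(ind)
#' sel <- select_components(pca)
#' f <- membership_rescale(pca$scores, sel) |> f_value(pca, sel)
#' head(rank_and_select(f, 5))
#' @export
f_value <- function(u, model, components,
                    normalize_over = c("selected", "all")) {
  stopifnot(inherits(model, "germ_pca"))
  normalize_over <- match.arg(normalize_over)
  if (length(components) == 0) abort("empty component set")
  cols <- paste0("PC", components)
  if (!all(cols %in% names(u))) abort("membership matrix lacks selected components")
  cr <- model$contribution_rate[components]
  denom <- if (normalize_over == "selected") sum(cr) else
    sum(model$contribution_rate)
  w <- cr / denom
  f <- as.vector(as.matrix(u[cols]) %*% w)
  out <- tibble(accession = u$accession, f_value = f)
  # dense rank: equal F shares a rank, next distinct F gets rank + 1
  out$rank <- match(-out$f_value, sort(unique(-out$f_value)))
  attr(out, "weights") <- setNames(w, cols)
  structure(out, class = c("germ_fscore", class(out)))
}

#' Rank accessions by F-value and select the top k
#'
#' Orders accessions by decreasing F-value, breaking ties by ascending
#' accession id (so selection is deterministic and independent of input
#' order), and returns the ids of the first `k`.
#'
#' @param f A `germ_fscore` tibble from [f_value()].
#' @param k Number of accessions to select (1..n).
#' @return Character vector of `k` accession ids, best first.
#' @export
rank_and_select <- function(f, k) {
  n <- nrow(f)
  if (k < 1 || k > n) abort(paste0("k must be in 1..", n))
  ord <- order(-f$f_value, f$accession)
  f$accession[ord][seq_len(k)]
}

#' F-value distribution plot
#'
#' @param object A `germ_fscore` tibble.
#' @param k Optionally highlight the top-k selected accessions.
#' @param ... Ignored.
#' @return A ggplot of ranked F-values.
#' @method autoplot germ_fscore
#' @export
autoplot.germ_fscore <- function(object, k = NULL, ...) {
  ord <- order(-object$f_value, object$accession)
  d <- object[ord, ]
  d$position <- seq_len(nrow(d))
  d$selected <- if (is.null(k)) FALSE else d$position <= k
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$f_value,
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey50",
                                            "TRUE" = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "Accession rank", y = "F-value") +
    ggplot2::theme_minimal()
}
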