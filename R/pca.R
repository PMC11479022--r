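#' Covariance-matrix PCA of a trait indicator matrix
#'
#' Eigendecomposition of the sample covariance matrix (n-1 denominator) of
#' the raw 0/1 indicator columns — no correlation rescaling, so rare classes
#' contribute little variance, mirroring how descriptor data are usually
#' analysed with covariance PCA. Eigenvalues are sorted in decreasing order;
#' each eigenvector is scaled to unit norm and its sign fixed so that the
#' largest-absolute loading is positive, which makes results reproducible
#' across linear-algebra backends (signs of eigenvectors are otherwise
#' arbitrary).
#'
#' The contribution rate of component j is \eqn{100 \lambda_j / \sum_k
#' \lambda_k}; the cumulative rate is its running sum, ending at 100.
#'
#' @param ind Indicator tibble from [encode_indicators()] (or any data frame
#'   of numeric columns with an `accession` id column).
#' @return An object of class `germ_pca`: `eigenvalues`, `loadings` (columns
#'   x components), `center` (column means), `contribution_rate`,
#'   `cumulative_rate`, `total_variance`, and `scores` for the training
#'   accessions (see [component_scores()]).
#' @examples
#' ind <- simulate_accessions(n = 60, seed = 1) |> encode_indicators()
#' pca <- fit_pca(ind)
#' glance(pca)
#' @export
fit_pca <- function(ind) {
  m <- indicator_matrix(ind)
  if (nrow(m) < 2) abort("PCA needs >= 2 accessions")
  if (ncol(m) < 2) abort("PCA needs >= 2 indicator columns")
  cv <- stats::cov(m)
  eig <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  vec <- eig$vectors
  # deterministic sign: largest-|loading| entry of each eigenvector positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- colnames(m)
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))
  total <- sum(diag(cv))
  contrib <- 100 * lam / total
  model <- structure(
    list(eigenvalues = lam, loadings = vec, center = colMeans(m),
         contribution_rate = contrib, cumulative_rate = cumsum(contrib),
         total_variance = total, columns = colnames(m)),
    class = "germ_pca")
  model$scores <- component_scores(model, ind)
  model
}

#' Project accessions onto fitted principal components
#'
#' Scores are the centred indicator rows multiplied by the loading matrix;
#' on the training data each score column has mean zero and variance equal to
#' its eigenvalue.
#'
#' @param model A fitted [fit_pca()] object.
#' @param ind Indicator tibble with exactly the columns the model was fitted
#'   on.
#' @return A tibble: `accession` plus one `PC<j>` column per component.
#' @export
component_scores <- function(model, ind) {
  stopifnot(inherits(model, "germ_pca"))
  m <- indicator_matrix(ind)
  if (!identical(colnames(m), model$columns)) {
    abort("indicator columns do not match the fitted model")
  }
  sc <- sweep(m, 2, model$center) %*% model$loadings
  bind_cols(tibble(accession = ind$accession), as_tibble(sc))
}

#' Select principal components for downstream evaluation
#'
#' Two policies: `top_k` keeps the first k components; `min_contribution`
#' keeps the leading run of components whose individual contribution rate is
#' at or above `threshold` percent (once a component falls below the
#' threshold, later ones are not considered, keeping the selected set
#' contiguous from PC1).
#'
#' @param model A fitted [fit_pca()] object.
#' @param policy `"min_contribution"` or `"top_k"`.
#' @param threshold Contribution-rate cutoff in percent (policy
#'   `min_contribution`); default 6.
#' @param k Number of components (policy `top_k`).
#' @param fallback_k If `min_contribution` selects nothing, fall back to the
#'   first `fallback_k` components (default 3). Set `NULL` to error instead.
#' @return Integer vector of component indices (possibly empty).
#' @export
select_components <- function(model, policy = c("min_contribution", "top_k"),
                              threshold = 6, k = 3, fallback_k = 3) {
  stopifnot(inherits(model, "germ_pca"))
  policy <- match.arg(policy)
  p <- length(model$eigenvalues)
  if (policy == "top_k") {
    if (k < 1 || k > p) abort(paste0("k must be in 1..", p))
    return(seq_len(k))
  }
  run <- which(cumsum(model$contribution_rate < threshold) == 0)
  if (length(run) == 0) {
    if (is.null(fallback_k)) abort("no component reaches the contribution threshold")
    run <- seq_len(min(fallback_k, p))
  }
  run
}

#' @export
print.germ_pca <- function(x, ...) {
  cat("Covariance-matrix PCA of", length(x$columns), "trait indicators,",
      nrow(x$scores), "accessions\n")
  cat("Total variance:", format(x$total_variance, digits = 5), "\n")
  k <- min(5, length(x$eigenvalues))
  cat("First", k, "eigenvalues:",
      paste(format(x$eigenvalues[seq_len(k)], digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy methods for `germ_pca` objects
#'
#' `tidy()` returns the loadings in long form (`column`, `trait`, `class`,
#' `component`, `loading`); `glance()` returns one row per component with
#' eigenvalue, contribution rate and cumulative rate; `augment()` returns the
#' training scores.
#'
#' @param x,... A `germ_pca` object; further arguments are ignored.
#' @name germ_pca_tidiers
NULL

#' @rdname germ_pca_tidiers
#' @method tidy germ_pca
#' @export
tidy.germ_pca <- function(x, ...) {
  load <- as_tibble(x$loadings)
  load$column <- rownames(x$loadings)
  out <- tidyr::pivot_longer(load, -"column", names_to = "component",
                             values_to = "loading")
  parts <- strsplit(out$column, "|", fixed = TRUE)
  out$trait <- vapply(parts, `[[`, "", 1)
  out$class <- vapply(parts, function(p) paste(p[-1], collapse = "|"), "")
  out[c("column", "trait", "class", "component", "loading")]
}

#' @rdname germ_pca_tidiers
#' @method glance germ_pca
#' @export
glance.germ_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         contribution_rate = x$contribution_rate,
         cumulative_rate = x$cumulative_rate)
}

#' @rdname germ_pca_tidiers
#' @method augment germ_pca
#' @export
augment.germ_pca <- function(x, ...) x$scores

#' Scree plot of a fitted PCA
#'
#' @param object A `germ_pca` object.
#' @param n_components Number of leading components to show.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot germ_pca
#' @export
autoplot.germ_pca <- function(object, n_components = 14, ...) {
  d <- glance(object)[seq_len(min(n_components, length(object$eigenvalues))), ]
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = .data$contribution_rate)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "Contribution rate (%)") +
    ggplot2::theme_minimal()
}
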