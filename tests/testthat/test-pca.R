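make_ind <- function(m, ids = sprintf("A%03d", seq_len(nrow(m)))) {
  colnames(m) <- paste0("t|c", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(accession = ids), tibble::as_tibble(m))
}

test_that("a balanced two-column toy gives the hand-computed spectrum", {
  m <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  fit <- fit_pca(make_ind(m))
  expect_equal(unname(fit$eigenvalues), c(1 / 3, 1 / 3))
  expect_equal(fit$total_variance, 2 / 3)
  orc <- pca_svd_oracle(m)
  expect_equal(unname(fit$eigenvalues), orc$eigenvalues, tolerance = 1e-12)
  # the spectrum is tied, so individual axes are rotation-arbitrary; the
  # rotation-invariant per-accession score norms must still agree
  sc <- as.matrix(fit$scores[-1])
  expect_equal(sqrt(rowSums(sc^2)), sqrt(rowSums(orc$scores^2)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("eigenvalues and scores match an independent SVD oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 8, 1, runif(1, 0.2, 0.8)), nrow = 20)
    fit <- fit_pca(make_ind(m))
    orc <- pca_svd_oracle(m)
    expect_equal(unname(fit$eigenvalues), orc$eigenvalues, tolerance = 1e-10)
    expect_equal(sum(fit$eigenvalues), sum(diag(cov(m))), tolerance = 1e-10)
    sc <- as.matrix(fit$scores[-1])
    for (j in seq_len(ncol(m))) {
      if (orc$eigenvalues[j] < 1e-12) next
      expect_true(max(abs(sc[, j] - orc$scores[, j])) < 1e-8 ||
                  max(abs(sc[, j] + orc$scores[, j])) < 1e-8)
    }
  }
})

test_that("total variance equals the binomial variance identity for 0/1 columns", {
  ind <- encode_indicators(simulate_accessions(n = 50, seed = 7))
  m <- as.matrix(ind[-1])
  n <- nrow(m)
  phat <- colMeans(m)
  fit <- fit_pca(ind)
  expect_equal(sum(fit$eigenvalues),
               sum(phat * (1 - phat) * n / (n - 1)), tolerance = 1e-10)
})

test_that("all components reconstruct the centred data", {
  set.seed(33)
  m <- matrix(rbinom(15 * 6, 1, 0.5), nrow = 15)
  fit <- fit_pca(make_ind(m))
  centred <- sweep(m, 2, fit$center)
  recon <- as.matrix(fit$scores[-1]) %*% t(fit$loadings)
  expect_lt(max(abs(centred - recon)), 1e-9)
})

test_that("constant columns contribute zero variance without changing the total", {
  set.seed(34)
  m <- matrix(rbinom(12 * 4, 1, 0.5), nrow = 12)
  with_const <- cbind(m, 1L)
  f1 <- fit_pca(make_ind(m))
  f2 <- fit_pca(make_ind(with_const))
  expect_equal(f2$total_variance, f1$total_variance, tolerance = 1e-12)
  expect_equal(min(f2$eigenvalues), 0, tolerance = 1e-12)
})

test_that("training scores are centred with variance equal to the eigenvalue", {
  ind <- encode_indicators(simulate_accessions(n = 40, seed = 8))
  fit <- fit_pca(ind)
  sc <- as.matrix(fit$scores[-1])
  expect_lt(max(abs(colMeans(sc))), 1e-9)
  expect_equal(unname(apply(sc, 2, var)), unname(fit$eigenvalues),
               tolerance = 1e-9)
  # a hypothetical mean accession projects to the origin
  mean_mat <- matrix(fit$center, nrow = 1,
                     dimnames = list("MEAN", fit$columns))
  mean_row <- dplyr::bind_cols(tibble::tibble(accession = "MEAN"),
                               tibble::as_tibble(mean_mat))
  expect_lt(max(abs(as.matrix(component_scores(fit, mean_row)[-1]))), 1e-9)
})

test_that("results are invariant to accession row order", {
  ind <- encode_indicators(simulate_accessions(n = 30, seed = 12))
  fit <- fit_pca(ind)
  set.seed(1)
  perm <- sample(nrow(ind))
  fit_p <- fit_pca(ind[perm, ])
  expect_equal(fit_p$eigenvalues, fit$eigenvalues, tolerance = 1e-10)
  expect_equal(fit_p$loadings, fit$loadings, tolerance = 1e-8)
  expect_equal(as.matrix(fit_p$scores[-1]),
               as.matrix(fit$scores[perm, -1]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("component selection follows the contribution-rate policy", {
  stub <- structure(list(
    eigenvalues = c(0.797, 0.498, 0.459, 0.420),
    contribution_rate = c(11.108, 6.934, 6.398, 5.847)),
    class = "germ_pca")
  expect_equal(select_components(stub, "min_contribution", threshold = 6),
               1:3)
  expect_equal(select_components(stub, "top_k", k = 4), 1:4)
  expect_error(select_components(stub, "top_k", k = 0), "k must be")
  expect_error(select_components(stub, "top_k", k = 5), "k must be")
  # nothing above threshold: falls back to the leading components
  low <- structure(list(eigenvalues = rep(1, 4),
                        contribution_rate = rep(25, 4) * 0.1),
                   class = "germ_pca")
  expect_equal(select_components(low, "min_contribution", threshold = 6,
                                 fallback_k = 3), 1:3)
  expect_error(select_components(low, "min_contribution", threshold = 6,
                                 fallback_k = NULL), "threshold")
})

test_that("degenerate inputs are rejected", {
  ind <- encode_indicators(simulate_accessions(n = 5, seed = 2))
  expect_error(fit_pca(ind[1, ]), ">= 2 accessions")
  fit <- fit_pca(ind)
  expect_error(component_scores(fit, ind[c(1, 3, 2), ]), NA)
  bad <- ind
  names(bad)[2] <- "renamed"
  expect_error(component_scores(fit, bad), "do not match")
})
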