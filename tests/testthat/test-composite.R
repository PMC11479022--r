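fake_scores <- function(...) {
  vals <- list(...)
  out <- tibble::tibble(accession = sprintf("A%02d", seq_along(vals[[1]])))
  for (j in seq_along(vals)) out[[paste0("PC", j)]] <- vals[[j]]
  out
}

fake_model <- function(contrib) {
  structure(list(eigenvalues = contrib, contribution_rate = contrib),
            class = "germ_pca")
}

test_that("membership rescaling is min-max within each component", {
  u <- membership_rescale(fake_scores(c(1, 2, 3)), 1)
  expect_equal(u$PC1, c(0, 0.5, 1))
  # negating scores mirrors the membership
  u_neg <- membership_rescale(fake_scores(-c(1, 2, 3)), 1)
  expect_equal(u_neg$PC1, 1 - u$PC1)
  expect_warning(
    u_const <- membership_rescale(fake_scores(c(2, 2, 2)), 1),
    "degenerate")
  expect_equal(u_const$PC1, rep(0.5, 3))
  expect_error(membership_rescale(fake_scores(1), 1), ">= 2")
  expect_error(membership_rescale(fake_scores(c(1, 2)), 4), "lacks")
})

test_that("F is the contribution-weighted convex combination of memberships", {
  model <- fake_model(c(11.108, 6.934, 6.398))
  u <- fake_scores(c(1, 0, 0.5), c(1, 0, 0.5), c(1, 0, 0.5))
  f <- f_value(u, model, 1:3)
  expect_equal(f$f_value, c(1, 0, 0.5))
  # membership 1 only on PC1: weight of PC1 over the selected set
  u2 <- fake_scores(c(1, 0), c(0, 0), c(0, 0))
  f2 <- f_value(u2, model, 1:3)
  expect_equal(f2$f_value[1], 11.108 / (11.108 + 6.934 + 6.398),
               tolerance = 1e-12)
  w <- attr(f2, "weights")
  expect_equal(sum(w), 1)
  # normalising over all components shrinks F by the selected share
  model_all <- fake_model(c(11.108, 6.934, 6.398, 5.847))
  f3 <- f_value(fake_scores(c(1, 0), c(1, 0), c(1, 0)), model_all, 1:3,
                normalize_over = "all")
  expect_equal(f3$f_value[1],
               (11.108 + 6.934 + 6.398) / (11.108 + 6.934 + 6.398 + 5.847))
  expect_error(f_value(u, model, integer(0)), "empty")
})

test_that("ranking is descending with ascending-id tie-break", {
  model <- fake_model(100)
  f <- f_value(fake_scores(c(0.9, 0.1, 0.5)), model, 1)
  expect_equal(rank_and_select(f, 2), c("A01", "A03"))
  expect_equal(rank_and_select(f, 3), c("A01", "A03", "A02"))
  expect_error(rank_and_select(f, 0), "k must be")
  expect_error(rank_and_select(f, 4), "k must be")
  # exact ties resolved by id; dense ranks shared
  ftie <- f_value(fake_scores(c(0.5, 0.5, 0.1)), model, 1)
  expect_equal(rank_and_select(ftie, 2), c("A01", "A02"))
  expect_equal(ftie$rank, c(1L, 1L, 2L))
})

test_that("the full composite pipeline is deterministic and bounded", {
  tab <- simulate_accessions(n = 80, seed = 17)
  run <- function() {
    ind <- encode_indicators(tab)
    model <- fit_pca(ind)
    sel <- select_components(model)
    f_value(membership_rescale(model$scores, sel), model, sel)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$f_value, f2$f_value)  # bit-identical reruns
  expect_true(all(f1$f_value >= 0 & f1$f_value <= 1))
})

test_that("F is affine in the indicators: full-design OLS explains it exactly", {
  tab <- simulate_accessions(n = 60, seed = 19)
  ind <- encode_indicators(tab)
  model <- fit_pca(ind)
  sel <- select_components(model)
  f <- f_value(membership_rescale(model$scores, sel), model, sel)
  X <- as.matrix(ind[-1])
  fit <- stats::lm.fit(cbind(1, X), f$f_value)
  r2 <- 1 - sum(fit$residuals^2) / sum((f$f_value - mean(f$f_value))^2)
  expect_gte(r2, 1 - 1e-9)
})

test_that("raising any membership strictly raises F", {
  model <- fake_model(c(10, 5))
  u <- fake_scores(c(0.2, 0.8), c(0.4, 0.1))
  f0 <- f_value(u, model, 1:2)
  for (j in 1:2) {
    u_up <- u
    u_up[[paste0("PC", j)]][1] <- u_up[[paste0("PC", j)]][1] + 0.1
    f1 <- f_value(u_up, model, 1:2)
    expect_gt(f1$f_value[1], f0$f_value[1])
    expect_equal(f1$f_value[2], f0$f_value[2])
  }
})
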