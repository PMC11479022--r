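# Independent oracles used across the suite. Each recomputes a quantity by a
# different route than the implementation under test.

# entropy by direct term-by-term summation over explicit probabilities
shannon_oracle <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (ct in counts) {
    if (ct > 0) {
      p <- ct / total
      acc <- acc - p * log(p)
    }
  }
  acc
}

# PCA via singular value decomposition of the centred data (independent of
# the eigen-of-covariance route in fit_pca)
pca_svd_oracle <- function(m) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(mc)
  list(eigenvalues = sv$d^2 / (nrow(m) - 1),
       scores = sv$u %*% diag(sv$d, nrow = length(sv$d)))
}

# brute-force UPGMA: at every step recompute all between-cluster average
# distances from the original pairwise matrix and merge the closest pair
upgma_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- mean(D[clusters[[i]], clusters[[j]]])
          if (d < best_d) {
            best_d <- d
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# exhaustive best-subset R^2 for a given subset size
best_subset_r2 <- function(X, y, size) {
  best <- -Inf
  for (cols in utils::combn(ncol(X), size, simplify = FALSE)) {
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    best <- max(best, r2)
  }
  best
}

rand_index <- function(a, b) {
  cmb <- utils::combn(length(a), 2)
  same_a <- a[cmb[1, ]] == a[cmb[2, ]]
  same_b <- b[cmb[1, ]] == b[cmb[2, ]]
  mean(same_a == same_b)
}

# compact two-categorical + one-quantitative scheme for unit tests
tiny_scheme <- function() {
  trait_scheme(tibble::tibble(
    trait = c("color", "shape", "size"),
    ipgri_code = c("1.1", "1.2", "1.3"),
    kind = c("categorical", "categorical", "quantitative"),
    classes = list(c("red", "green", "blue"), c("round", "oval"),
                   character()),
    units = c("", "", "cm")))
}

tiny_table <- function() {
  tibble::tibble(
    accession = c("GTM-A", "GTM-B", "GTM-C", "GTM-D"),
    color = c("red", "green", "green", "blue"),
    shape = c("round", "round", "oval", "oval"),
    size = c(1.2, 3.4, 2.2, 5.1))
}

# class counts and printed H' of the 288-accession cardamom collection
# (quantitative traits as their ten sigma-level counts)
cardamom_table1 <- function() {
  list(
    plant_height = list(counts = c(2, 167, 119), h = 0.72),
    stems_per_plant = list(counts = c(45, 106, 83, 54), h = 1.33),
    stem_color = list(counts = c(280, 7, 1), h = 0.14),
    rhizome_color = list(counts = c(32, 168, 86, 1, 1), h = 0.96),
    leaf_shape = list(counts = c(11, 272, 5), h = 0.25),
    leaf_pubescence = list(counts = c(141, 81, 66), h = 1.04),
    panicle_type = list(counts = c(2, 283, 3), h = 0.10),
    panicles_per_stem = list(counts = c(17, 257, 14), h = 0.42),
    panicles_per_plant = list(counts = c(20, 56, 86, 126), h = 1.23),
    panicle_length = list(counts = c(34, 112, 95, 47), h = 1.28),
    clusters_per_panicle = list(counts = c(90, 181, 17), h = 0.82),
    internodal_length = list(counts = c(0, 0, 25, 75, 54, 88, 28, 12, 0, 6),
                             h = 1.68),
    panicle_branching = list(counts = c(12, 276), h = 0.17),
    branching_pattern = list(counts = c(12, 276), h = 0.17),
    capsules_per_cluster = list(counts = c(3, 12, 42, 32, 66, 62, 20, 33, 10, 8),
                                h = 2.02),
    capsule_form = list(counts = c(13, 73, 202), h = 0.74),
    capsule_color = list(counts = c(11, 76, 13, 188), h = 0.89))
}
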