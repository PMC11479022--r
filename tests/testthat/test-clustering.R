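scores_from_matrix <- function(m, ids = sprintf("A%02d", seq_len(nrow(m)))) {
  out <- tibble::tibble(accession = ids)
  for (j in seq_len(ncol(m))) out[[paste0("PC", j)]] <- m[, j]
  out
}

test_that("two accessions merge at their Euclidean distance", {
  sc <- scores_from_matrix(rbind(c(0, 0), c(3, 4)))
  dend <- linkage_average(sc, 1:2)
  expect_equal(dend$hclust$height, 5)
})

test_that("three-point UPGMA averages the between-group distances", {
  # pairwise distances 1 (A-B), 5 (A-C), 5.5 (B-C)
  m <- rbind(c(0, 0), c(1, 0), c(-2.125, sqrt(25 - 2.125^2)))
  dend <- linkage_average(scores_from_matrix(m), 1:2)
  expect_equal(sort(dend$hclust$height), c(1, 5.25), tolerance = 1e-12)
})

test_that("merge heights match a brute-force average-linkage oracle", {
  set.seed(61)
  for (n in c(6, 8, 10)) {
    m <- matrix(rnorm(n * 3), nrow = n)
    sc <- scores_from_matrix(m)
    dend <- linkage_average(sc, 1:3)
    D <- as.matrix(dist(m))
    expect_equal(sort(dend$hclust$height), upgma_oracle(D), tolerance = 1e-10)
  }
})

test_that("cut_k spans singletons to one group with first-appearance labels", {
  set.seed(62)
  m <- matrix(rnorm(12 * 2), nrow = 12)
  dend <- linkage_average(scores_from_matrix(m), 1:2)
  expect_equal(sort(unique(cut_k(dend, 12)$group)), 1:12)
  expect_equal(unique(cut_k(dend, 1)$group), 1L)
  p4 <- cut_k(dend, 4)
  expect_equal(sort(unique(p4$group)), 1:4)
  expect_equal(p4$group[1], 1L)  # first accession defines group 1
  expect_error(cut_k(dend, 0), "k must be")
  expect_error(cut_k(dend, 13), "k must be")
})

test_that("a well-separated toy cut matches the obvious partition", {
  m <- rbind(matrix(rnorm(8, 0, 0.1), ncol = 2),
             matrix(rnorm(8, 10, 0.1), ncol = 2))
  dend <- linkage_average(scores_from_matrix(m), 1:2)
  part <- cut_k(dend, 2)
  expect_equal(part$group, rep(1:2, each = 4))
})

test_that("partitions are invariant to accession order up to relabelling", {
  set.seed(63)
  tab <- simulate_accessions(n = 40, seed = 63)
  ind <- encode_indicators(tab)
  model <- fit_pca(ind)
  part <- cut_k(linkage_average(model$scores, 1:3), 4)
  perm <- sample(nrow(tab))
  model_p <- fit_pca(encode_indicators(tab[perm, ]))
  part_p <- cut_k(linkage_average(model_p$scores, 1:3), 4)
  joined <- dplyr::inner_join(part, part_p, by = "accession")
  # the two labelings must induce the same grouping (a bijection of labels)
  tab2 <- table(joined$group.x, joined$group.y)
  expect_true(all(rowSums(tab2 > 0) == 1) && all(colSums(tab2 > 0) == 1))
})

test_that("group profiles flag dominant classes at the threshold", {
  sc <- tiny_scheme()
  tab <- tibble::tibble(
    accession = sprintf("G%02d", 1:10),
    color = c(rep("red", 9), "green"),
    shape = rep("round", 10),
    size = seq(1, 10))
  part <- tibble::tibble(accession = tab$accession, group = 1L)
  prof <- group_profile(part, tab, sc, dominance = 80)
  red <- prof[prof$trait == "color" & prof$class == "red", ]
  expect_equal(red$percent, 90)
  expect_true(red$dominant)
  round_row <- prof[prof$trait == "shape" & prof$class == "round", ]
  expect_equal(round_row$percent, 100)
  expect_true(round_row$dominant)
  green <- prof[prof$trait == "color" & prof$class == "green", ]
  expect_false(green$dominant)
  # within a group, every trait's class percentages total 100
  sums <- prof |>
    dplyr::group_by(group, trait) |>
    dplyr::summarise(s = sum(percent), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 0.01))
})

test_that("planted dominant classes surface in the recovered group profiles", {
  tab <- simulate_accessions(n = 120, seed = 64, n_groups = 2,
                             concentration = 0.5)
  truth <- planted_truth(tab)
  part <- tibble::tibble(accession = tab$accession, group = truth)
  prof <- group_profile(part, tab[setdiff(names(tab), "latent_group")])
  # concentration this small makes each group near-unanimous on most traits
  n_dominant <- prof |>
    dplyr::filter(dominant) |>
    dplyr::count(group)
  expect_true(all(n_dominant$n >= 5))
})

test_that("the dendrogram exports to Newick and reimports intact", {
  set.seed(65)
  sc <- scores_from_matrix(matrix(rnorm(10), ncol = 2),
                           ids = paste0("ACC", 1:5))
  dend <- linkage_average(sc, 1:2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, paste0("ACC", 1:5))
  expect_error(linkage_average(sc[1, ], 1:2), ">= 2")
})
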