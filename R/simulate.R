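#' Default marginal class frequencies of the cardamom collection
#'
#' Observed class counts of the 15 categorical descriptors over the
#' 288-accession Guatemalan cardamom collection that the default synthetic
#' generator emulates; divided by 288 they give the generator's default
#' class probabilities.
#'
#' @return Named list of named integer count vectors, one per categorical
#'   trait of [cardamom_traits()].
#' @export
cardamom_class_counts <- function() {
  list(
    plant_height = c("<2 m" = 2, "2-3 m" = 167, ">3 m" = 119),
    stems_per_plant = c("<15" = 45, "16-30" = 106, "31-45" = 83, ">45" = 54),
    stem_color = c("Light green" = 280, "Green" = 7, "Yellow" = 1),
    rhizome_color = c("White" = 32, "Light purple" = 168,
                      "Light green" = 86, "Dark green" = 1,
                      "Pale light purple" = 1),
    leaf_shape = c("Lanceolate" = 11, "Oblong" = 272, "Oval" = 5),
    leaf_pubescence = c("Glabra" = 141, "Dense" = 81, "Spaced" = 66),
    panicle_type = c("Creeping" = 2, "Semi-erect" = 283, "Erect" = 3),
    panicles_per_stem = c("1" = 17, "2" = 257, ">3" = 14),
    panicles_per_plant = c("<10" = 20, "11-20" = 56, "21-30" = 86,
                           ">31" = 126),
    panicle_length = c("<50 cm" = 34, "51-75 cm" = 112, "76-100 cm" = 95,
                       ">100 cm" = 47),
    clusters_per_panicle = c("<20" = 90, "20-30" = 181, "30-40" = 17),
    panicle_branching = c("Presence" = 12, "Absence" = 276),
    branching_pattern = c("Proximal" = 12, "Absent" = 276),
    capsule_form = c("Ellipsoid" = 13, "Globose" = 73, "Ovoid" = 202),
    capsule_color = c("Yellow" = 11, "Green" = 76, "Dark green" = 13,
                      "Light green" = 188)
  )
}

#' Default quantitative-trait parameters of the cardamom collection
#'
#' Mean, standard deviation, observed range and recording precision of the
#' two quantitative descriptors: cluster internodal length (cm, to 0.1) and
#' capsules per cluster (integer count).
#'
#' @return Named list with `mean`, `sd`, `min`, `max`, `digits` per trait.
#' @export
cardamom_quant_params <- function() {
  list(
    internodal_length = list(mean = 2.79, sd = 1.55, min = 0.5, max = 18,
                             digits = 1),
    capsules_per_cluster = list(mean = 10.75, sd = 3.74, min = 3, max = 25,
                                digits = 0)
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) return(alpha / sum(alpha))
  g / sum(g)
}

rtruncnorm_reject <- function(n, mean, sd, min, max) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= min & draw <= max])
  }
  out[seq_len(n)]
}

#' Simulate an accession table
#'
#' Generates a synthetic germplasm collection with the statistical structure
#' the analysis pipeline assumes. Categorical traits are drawn independently
#' per accession from the trait's class probabilities — by default the
#' observed marginal frequencies of the 288-accession cardamom collection
#' ([cardamom_class_counts()]). Quantitative traits are drawn from a normal
#' with the collection's mean and SD, truncated by rejection to the observed
#' range and rounded to the recording precision ([cardamom_quant_params()]).
#'
#' With `n_groups > 1` a latent group structure is planted: group sizes are
#' multinomial with equal probabilities, and each group gets its own class
#' probability vectors drawn from a Dirichlet centred on the marginals with
#' parameter `concentration` times the marginal probabilities — smaller
#' `concentration` means stronger between-group divergence (and hence the
#' trait correlations that make PCA and clustering informative). The planted
#' labels are recoverable with [planted_truth()].
#'
#' @param n Number of accessions (default 288).
#' @param seed Integer seed for reproducibility (optional).
#' @param n_groups Number of latent groups (default 1 = no structure).
#' @param concentration Positive Dirichlet concentration multiplier for
#'   multi-group mode (default 30, mild divergence).
#' @param scheme A [trait_scheme()]; defaults to [cardamom_traits()].
#' @param class_probs Named list of per-trait class probability (or count)
#'   vectors; defaults to [cardamom_class_counts()].
#' @param quant_params Named list of per-trait `mean`, `sd`, `min`, `max`,
#'   `digits`; defaults to [cardamom_quant_params()].
#' @return A tibble with `accession` (`SYN-000001`...), one column per
#'   scheme trait, and — in multi-group mode — `latent_group`.
#' @examples
#' tab <- simulate_accessions(n = 100, seed = 42, n_groups = 3,
#'                            concentration = 5)
#' table(planted_truth(tab))
#' @export
simulate_accessions <- function(n = 288, seed = NULL, n_groups = 1,
                                concentration = 30,
                                scheme = cardamom_traits(),
                                class_probs = cardamom_class_counts(),
                                quant_params = cardamom_quant_params()) {
  if (!is.null(seed)) set.seed(seed)
  if (n_groups < 1) abort("n_groups must be >= 1")
  if (n > 0 && n_groups > n) abort("n_groups cannot exceed n")
  if (concentration <= 0) abort("concentration must be positive")
  cat_traits <- scheme_categorical(scheme)
  qt_traits <- scheme_quantitative(scheme)
  for (tr in cat_traits) {
    if (is.null(class_probs[[tr]])) {
      abort(paste0("no class probabilities for trait '", tr, "'"))
    }
    p <- class_probs[[tr]]
    if (any(p < 0) || sum(p) <= 0) {
      abort(paste0("invalid class probabilities for trait '", tr, "'"))
    }
    cls <- scheme_classes(scheme, tr)
    if (length(p) != length(cls)) {
      abort(paste0("class probabilities for '", tr, "' must have ",
                   length(cls), " entries"))
    }
  }
  out <- tibble(accession = sprintf("SYN-%06d", seq_len(n)))
  if (n == 0) {
    for (tr in scheme$trait) out[[tr]] <- character(0)
    return(out)
  }

  if (n_groups > 1) {
    grp <- sample.int(n_groups, n, replace = TRUE)
    group_probs <- lapply(seq_len(n_groups), function(g) {
      lapply(class_probs[cat_traits], function(p) {
        rdirichlet1(concentration * p / sum(p))
      })
    })
  } else {
    grp <- rep(1L, n)
  }

  for (tr in scheme$trait) {
    if (tr %in% cat_traits) {
      cls <- scheme_classes(scheme, tr)
      if (n_groups > 1) {
        v <- character(n)
        for (g in seq_len(n_groups)) {
          idx <- which(grp == g)
          if (length(idx) > 0) {
            v[idx] <- sample(cls, length(idx), replace = TRUE,
                             prob = group_probs[[g]][[tr]])
          }
        }
        out[[tr]] <- v
      } else {
        p <- class_probs[[tr]] / sum(class_probs[[tr]])
        out[[tr]] <- sample(cls, n, replace = TRUE, prob = p)
      }
    } else {
      qp <- quant_params[[tr]]
      if (is.null(qp)) abort(paste0("no quantitative parameters for '", tr, "'"))
      if (qp$min >= qp$max) abort(paste0("min must be < max for '", tr, "'"))
      v <- rtruncnorm_reject(n, qp$mean, qp$sd, qp$min, qp$max)
      out[[tr]] <- round(v, qp$digits)
    }
  }
  if (n_groups > 1) out$latent_group <- as.integer(grp)
  out
}

#' Planted group labels of a multi-group simulation
#'
#' @param df A table from [simulate_accessions()] with `n_groups > 1`.
#' @return Integer vector of latent group labels, one per accession.
#' @export
planted_truth <- function(df) {
  if (!"latent_group" %in% names(df)) {
    abort("no planted groups: table was simulated in single-group mode")
  }
  df[["latent_group"]]
}
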