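#' Stepwise linear regression of a response on trait indicators
#'
#' Builds a compact "selection equation" predicting a response (typically the
#' composite F-value) from trait indicator columns by classical stepwise OLS:
#' at each step the candidate with the smallest partial-F p-value enters if
#' that p-value is below `entry_alpha`; after each entry, included terms
#' whose partial-F p-value (given the others) exceeds `removal_alpha` are
#' removed, largest p first; the cycle repeats until the model is stable.
#' Candidates that are perfectly collinear with the current model (e.g. the
#' last class of a one-hot trait block once its siblings are in) are skipped
#' with a warning. If no candidate passes entry the intercept-only model is
#' returned.
#'
#' @param ind Indicator tibble from [encode_indicators()] (the candidate
#'   design; all classes of all traits are candidates).
#' @param response Numeric vector, one value per accession, in `ind` row
#'   order.
#' @param entry_alpha P-value below which a candidate enters (default 0.05).
#' @param removal_alpha P-value above which an included term is removed
#'   (default 0.10); must be >= `entry_alpha` for the loop to terminate.
#' @return An object of class `germ_stepwise`: `intercept`, `terms` (tibble
#'   with `column`, `trait`, `class`, `coefficient`, in entry order), `r2`,
#'   `r`, `entry_alpha`, `removal_alpha`, `n`.
#' @examples
#' ind <- simulate_accessions(n = 80, seed = 1) |> encode_indicators()
#' y <- 0.3 + 0.2 * ind[["capsule_color|Green"]]
#' fit <- fit_stepwise(ind, y)
#' tidy(fit)
#' @export
fit_stepwise <- function(ind, response, entry_alpha = 0.05,
                         removal_alpha = 0.10) {
  X <- indicator_matrix(ind)
  y <- as.numeric(response)
  n <- nrow(X)
  if (length(y) != n) abort("response length must equal the number of accessions")
  if (any(!is.finite(y))) abort("response must be finite")
  if (entry_alpha > removal_alpha) {
    abort("entry_alpha must be <= removal_alpha")
  }
  tss <- sum((y - mean(y))^2)
  eps <- 1e-12 * max(tss, 1)

  rss_of <- function(cols) {
    if (length(cols) == 0) return(list(rss = tss, rank_ok = TRUE, fit = NULL))
    Xm <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
    qr_x <- qr(Xm)
    list(rss = sum(qr.resid(qr_x, y)^2),
         rank_ok = qr_x$rank == ncol(Xm), qr = qr_x)
  }

  partial_p <- function(rss0, rss1, p1) {
    # one extra parameter; p1 = number of slopes in the larger model
    df2 <- n - p1 - 1
    if (df2 <= 0) return(NA_real_)
    if (rss1 <= eps) return(0)
    fstat <- (rss0 - rss1) / (rss1 / df2)
    stats::pf(max(fstat, 0), 1, df2, lower.tail = FALSE)
  }

  included <- character()
  warned <- character()
  repeat {
    changed <- FALSE
    cur <- rss_of(included)
    # forward entry
    if (n - length(included) - 2 > 0 && cur$rss > eps) {
      cands <- setdiff(colnames(X), included)
      pvals <- rep(NA_real_, length(cands))
      for (ci in seq_along(cands)) {
        trial <- rss_of(c(included, cands[ci]))
        if (!trial$rank_ok) {
          if (!cands[ci] %in% warned) {
            warn(paste0("candidate '", cands[ci],
                        "' is collinear with the model; skipped"))
            warned <- c(warned, cands[ci])
          }
          next
        }
        pvals[ci] <- partial_p(cur$rss, trial$rss, length(included) + 1)
      }
      if (any(!is.na(pvals))) {
        best <- which.min(pvals)
        if (!is.na(pvals[best]) && pvals[best] < entry_alpha) {
          included <- c(included, cands[best])
          changed <- TRUE
        }
      }
    }
    # backward removal
    repeat {
      if (length(included) == 0) break
      full <- rss_of(included)
      pdrop <- vapply(included, function(cl) {
        reduced <- rss_of(setdiff(included, cl))
        partial_p(reduced$rss, full$rss, length(included))
      }, numeric(1))
      worst <- which.max(pdrop)
      if (length(worst) == 1 && !is.na(pdrop[worst]) &&
          pdrop[worst] > removal_alpha) {
        included <- setdiff(included, included[worst])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  if (length(included) == 0) {
    coefs <- numeric(0)
    intercept <- mean(y)
    r2 <- 0
  } else {
    Xm <- cbind(`(Intercept)` = 1, X[, included, drop = FALSE])
    fit <- stats::lm.fit(Xm, y)
    intercept <- fit$coefficients[1]
    coefs <- fit$coefficients[-1]
    rss <- sum(fit$residuals^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
  }
  parts <- strsplit(included, "|", fixed = TRUE)
  terms <- tibble(
    column = included,
    trait = vapply(parts, function(p) p[1], "", USE.NAMES = FALSE),
    class = vapply(parts, function(p) paste(p[-1], collapse = "|"), "",
                   USE.NAMES = FALSE),
    coefficient = unname(coefs))
  structure(list(intercept = unname(intercept), terms = terms,
                 r2 = r2, r = sqrt(max(r2, 0)),
                 entry_alpha = entry_alpha, removal_alpha = removal_alpha,
                 n = n),
            class = "germ_stepwise")
}

#' @export
print.germ_stepwise <- function(x, ...) {
  cat("Stepwise selection equation (", nrow(x$terms), " terms, n = ", x$n,
      ")\n", sep = "")
  cat("  y = ", format(x$intercept, digits = 3), sep = "")
  if (nrow(x$terms) > 0) {
    co <- x$terms$coefficient
    cat(paste0(ifelse(co < 0, " - ", " + "),
               format(abs(co), digits = 3), "*[", x$terms$column, "]"),
        sep = "")
  }
  cat("\n  R =", format(x$r, digits = 4), " R^2 =", format(x$r2, digits = 4),
      "\n")
  invisible(x)
}

#' Predict from a stepwise selection equation
#'
#' @param object A `germ_stepwise` model.
#' @param ind Indicator tibble containing every term column of the model.
#' @param ... Ignored.
#' @return Numeric vector of fitted values.
#' @export
predict.germ_stepwise <- function(object, ind, ...) {
  missing_cols <- setdiff(object$terms$column, names(ind))
  if (length(missing_cols) > 0) {
    abort(paste0("design lacks model column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(object$terms) == 0) return(rep(object$intercept, nrow(ind)))
  m <- as.matrix(ind[object$terms$column])
  object$intercept + as.vector(m %*% object$terms$coefficient)
}

#' Tidy methods for stepwise models
#'
#' `tidy()` returns the intercept and the entered terms with coefficients;
#' `glance()` returns a one-row model summary (`r`, `r2`, `n_terms`, `n`,
#' and the entry/removal thresholds).
#'
#' @param x,... A `germ_stepwise` model; further arguments are ignored.
#' @name germ_stepwise_tidiers
NULL

#' @rdname germ_stepwise_tidiers
#' @method tidy germ_stepwise
#' @export
tidy.germ_stepwise <- function(x, ...) {
  bind_rows(
    tibble(column = "(Intercept)", trait = NA_character_,
           class = NA_character_, coefficient = x$intercept),
    x$terms)
}

#' @rdname germ_stepwise_tidiers
#' @method glance germ_stepwise
#' @export
glance.germ_stepwise <- function(x, ...) {
  tibble(r = x$r, r2 = x$r2, n_terms = nrow(x$terms), n = x$n,
         entry_alpha = x$entry_alpha, removal_alpha = x$removal_alpha)
}
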