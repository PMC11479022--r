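#' Sigma-level binning of a quantitative trait
#'
#' Quantitative traits are stratified into ten levels centred on the trait
#' mean, with successive cut points half a standard deviation apart: level 1
#' collects values below \eqn{\bar{X} - 2\sigma}, level 10 values at or above
#' \eqn{\bar{X} + 2\sigma}, and levels 2-9 are half-open intervals
#' \eqn{[\mathrm{lower}, \mathrm{upper})} of width \eqn{0.5\sigma}. The nine
#' interior cut points are \eqn{\bar{X} + (-2 + 0.5(k-1))\sigma}, k = 1..9.
#' The standard deviation uses the n-1 denominator ([stats::sd()]), matching
#' common statistical software defaults.
#'
#' @param values Numeric vector (at least two distinct finite values).
#' @param mean,sd Optionally override the location and scale instead of
#'   estimating them from `values` (e.g. to reuse published summaries).
#' @return An object of class `germ_binning` with elements `mean`, `sd`,
#'   `boundaries` (nine increasing cut points) and `n_levels` (10).
#' @examples
#' b <- make_binning(mean = 10.75, sd = 3.74)
#' assign_level(c(3, 10.75, 25), b)
#' @export
make_binning <- function(values = NULL, mean = NULL, sd = NULL) {
  if (is.null(mean) || is.null(sd)) {
    v <- values[is.finite(values)]
    if (length(v) < 2) abort("need >= 2 finite values to derive a binning")
    if (is.null(mean)) mean <- base::mean(v)
    if (is.null(sd)) sd <- stats::sd(v)
  }
  if (!is.finite(sd) || sd <= 0) {
    abort("degenerate scale: standard deviation is zero (constant input?)",
          class = "germ_degenerate_scale")
  }
  boundaries <- mean + (-2 + 0.5 * (seq_len(9) - 1)) * sd
  structure(list(mean = mean, sd = sd, boundaries = boundaries,
                 n_levels = 10L),
            class = "germ_binning")
}

#' @param x Numeric vector of trait values.
#' @param b A `germ_binning` object.
#' @return `assign_level()`: integer level(s) in 1..10. The mapping is
#'   monotone non-decreasing in `x` and every finite value falls in exactly
#'   one level.
#' @rdname make_binning
#' @export
assign_level <- function(x, b) {
  stopifnot(inherits(b, "germ_binning"))
  if (any(!is.finite(x))) abort("assign_level needs finite values")
  findInterval(x, b$boundaries) + 1L
}

bin_labels <- function() paste0("L", sprintf("%02d", 1:10))

#' Compute one binning per quantitative trait
#'
#' Helper that derives a [make_binning()] scheme for every quantitative trait
#' in `scheme` from the values observed in `df`.
#'
#' @inheritParams validate_accessions
#' @return Named list of `germ_binning` objects, one per quantitative trait.
#' @export
trait_binnings <- function(df, scheme = cardamom_traits()) {
  qt <- scheme_quantitative(scheme)
  setNames(lapply(qt, function(tr) make_binning(as.numeric(df[[tr]]))), qt)
}
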