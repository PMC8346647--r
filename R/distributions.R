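## Activation-energy distribution families F(E).
##
## A DAEM treats the sample as a continuum of independent first-order
## reactions whose activation energies E follow a probability density F(E).
## Four families are supported, each parameterized by a location e_mean
## (the mean/mode energy, J mol^-1) and a scale sigma (J mol^-1):
##
##   gaussian : F(E) = 1/(sigma sqrt(2 pi)) exp(-(E-e_mean)^2/(2 sigma^2))
##   logistic : F(E) = 1/(4 sigma) sech^2((E-e_mean)/(2 sigma))
##   gumbel   : F(E) = 1/sigma exp(-(z + exp(-z))),  z = (E-e_mean)/sigma
##   cauchy   : F(E) = 1/(pi sigma) [1 + ((E-e_mean)/sigma)^2]^-1
##
## gaussian, logistic and cauchy are symmetric about e_mean; gumbel is
## right-skewed with its mode at e_mean. All four have mode value at e_mean
## of, respectively, 1/(sigma sqrt(2 pi)), 1/(4 sigma), 1/(e sigma) and
## 1/(pi sigma).

DIST_FAMILIES <- c("gaussian", "logistic", "gumbel", "cauchy")

## below this scale (J mol^-1) a distribution is numerically a delta spike:
## spreading 201 quadrature nodes over a sub-joule interval only invites
## catastrophic node clustering, so callers take the single-energy path
.SIGMA_DEGENERATE <- 1

## negative (or tiny) activation energies are unphysical; truncated supports
## are clamped to this floor (J mol^-1)
.E_FLOOR <- 1000

#' Activation-energy distribution specification
#'
#' Creates the description of one pseudo-component's activation-energy
#' density F(E): a family tag plus location and scale.
#'
#' @param family one of `"gaussian"`, `"logistic"`, `"gumbel"`, `"cauchy"`.
#' @param e_mean location (mean activation energy), J mol^-1. Must be
#'   positive. For the asymmetric gumbel family this is the mode.
#' @param sigma scale (standard-deviation-like width), J mol^-1. Must be
#'   non-negative; values below 1 J mol^-1 are treated as a degenerate
#'   (delta) distribution by the quadrature layer.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("gaussian", e_mean = 178648.8, sigma = 1632)
#' @seealso [dist_density()], [dist_support()], [dist_nodes()]
#' @export
dist_spec <- function(family = DIST_FAMILIES, e_mean, sigma) {
  family <- match.arg(family)
  if (!.is_number(e_mean) || e_mean <= 0) .stopf("e_mean must be a positive number (J mol^-1)")
  if (!.is_number(sigma) || sigma < 0) .stopf("sigma must be a non-negative number (J mol^-1)")
  structure(list(family = family, e_mean = e_mean, sigma = sigma),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(e_mean = %.4f kJ mol^-1, sigma = %.4f kJ mol^-1)%s\n",
              x$family, x$e_mean / 1000, x$sigma / 1000,
              if (is_degenerate(x)) " [degenerate: delta]" else ""))
  invisible(x)
}

#' Is a distribution numerically degenerate (delta-like)?
#'
#' @param spec a [dist_spec()].
#' @return `TRUE` when `sigma` is below 1 J mol^-1, in which case the DAEM
#'   reduces to a single first-order reaction at `e_mean`.
#' @export
is_degenerate <- function(spec) spec$sigma < .SIGMA_DEGENERATE

#' Evaluate an activation-energy density
#'
#' Evaluates the family's probability density per unit energy at `e`.
#'
#' @param spec a [dist_spec()] with `sigma > 0` (degenerate specs have no
#'   density; use the delta path via [dist_nodes()]).
#' @param e energies, J mol^-1 (vectorized).
#' @return Densities, mol J^-1; finite and non-negative.
#' @export
dist_density <- function(spec, e) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$sigma <= 0) .stopf("degenerate distribution (sigma = 0) has no density; use the delta path")
  mu <- spec$e_mean; s <- spec$sigma
  switch(spec$family,
    gaussian = stats::dnorm(e, mu, s),
    logistic = stats::dlogis(e, mu, s),
    cauchy   = stats::dcauchy(e, mu, s),
    gumbel   = {
      z <- (e - mu) / s
      ## exp(-(z + exp(-z))): mode at z = 0 with value 1/(e*s)
      .clipped_exp(-(z + .clipped_exp(-z))) / s
    })
}

## quantile function per family (used for truncated supports)
.dist_quantile <- function(spec, p) {
  mu <- spec$e_mean; s <- spec$sigma
  switch(spec$family,
    gaussian = stats::qnorm(p, mu, s),
    logistic = stats::qlogis(p, mu, s),
    cauchy   = stats::qcauchy(p, mu, s),
    gumbel   = mu - s * log(-log(p)))
}

## default truncation coverage; cauchy's heavy tails (undefined variance)
## get a tighter default so supports stay physically sized
.default_coverage <- function(family) if (family == "cauchy") 0.999 else 0.9999

#' Truncated support of an activation-energy density
#'
#' Returns an energy interval containing at least `coverage` of the
#' density's mass, computed from the family's quantile function and clamped
#' below at 1 kJ mol^-1 (negative activation energies are unphysical).
#'
#' @param spec a non-degenerate [dist_spec()].
#' @param coverage probability mass to enclose, in (0, 1). Defaults to
#'   0.9999 (0.999 for the heavy-tailed cauchy family).
#' @return Numeric vector `c(e_lo, e_hi)`, J mol^-1.
#' @export
dist_support <- function(spec, coverage = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  if (is.null(coverage)) coverage <- .default_coverage(spec$family)
  if (!.is_number(coverage) || coverage <= 0 || coverage >= 1)
    .stopf("coverage must lie strictly between 0 and 1")
  tail_p <- (1 - coverage) / 2
  lo <- .dist_quantile(spec, tail_p)
  hi <- .dist_quantile(spec, 1 - tail_p)
  c(max(lo, .E_FLOOR), hi)
}

#' Quadrature nodes and weights for the outer DAEM energy integral
#'
#' Discretizes `integral F(E) ... dE` with equally spaced nodes and
#' trapezoid weights on the truncated support, renormalized to unit total
#' mass (so truncation never loses conversion). For a degenerate spec
#' (sigma below 1 J mol^-1) a single node at `e_mean` with weight 1 is
#' returned, i.e. the delta-distribution limit.
#'
#' @param spec a [dist_spec()].
#' @param n number of nodes (>= 3) for non-degenerate specs; default 201.
#' @param coverage support coverage passed to [dist_support()].
#' @return A list with `e` (nodes, J mol^-1) and `w` (weights summing to 1).
#'   The attribute `raw_mass` records the trapezoid mass before
#'   renormalization, a direct check that the truncation captured the
#'   intended coverage.
#' @details For the cauchy family the quadrature support is additionally
#'   clamped to a +-100 kJ mol^-1 half-width around `e_mean`: the quantile
#'   interval of a heavy-tailed density spans megajoules for kJ-scale
#'   sigma, which equal-spaced nodes cannot resolve, and activation
#'   energies that far from the mean are outside the physically observed
#'   range anyway. Weights are renormalized after any truncation, so the
#'   effective model is a truncated cauchy.
#' @export
dist_nodes <- function(spec, n = 201, coverage = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  if (is_degenerate(spec)) {
    return(structure(list(e = spec$e_mean, w = 1), raw_mass = 1))
  }
  if (!.is_number(n) || n < 3) .stopf("n must be at least 3")
  sup <- dist_support(spec, coverage)
  if (spec$family == "cauchy") {
    sup[1] <- max(sup[1], spec$e_mean - 1e5)
    sup[2] <- min(sup[2], spec$e_mean + 1e5)
  }
  e <- seq(sup[1], sup[2], length.out = n)
  d <- dist_density(spec, e)
  h <- e[2] - e[1]
  w <- d * h
  w[c(1, n)] <- w[c(1, n)] / 2   # trapezoid end corrections
  raw <- sum(w)
  structure(list(e = e, w = w / raw), raw_mass = raw)
}
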