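# Combining per-component p-values into a single gene-level p-value.

#' Fisher's method
#'
#' Combines independent p-values via X = -2 * sum(log p) against a
#' chi-square distribution with 2m degrees of freedom. Zero p-values are
#' clamped at machine epsilon before the log transform.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combine <- function(pvals) {
  if (!length(pvals)) stop("fisher_combine: empty p-value list")
  pvals <- pmax(pvals, .Machine$double.eps)
  x <- -2 * sum(log(pvals))
  pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Harmonic mean p-value (asymptotically exact)
#'
#' Combines p-values with equal weights through the harmonic mean
#' \eqn{\mathring{p} = m / \sum 1/p_i}. The raw harmonic mean is
#' anti-conservative; the adjusted value is the tail probability of
#' \eqn{1/\mathring{p}} under the null, where the mean of m reciprocal
#' uniforms converges to a Landau distribution (stable, alpha = 1,
#' beta = 1) with location log(m) + 1 - Euler's gamma and scale pi/2.
#' The tail is evaluated by numerically integrating the exact
#' non-oscillatory integral representation. A single p-value is returned
#' unchanged.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted harmonic-mean p-value.
#' @export
hmp_combine <- function(pvals) {
  m <- length(pvals)
  if (!m) stop("hmp_combine: empty p-value list")
  if (m == 1L) return(pvals)
  pvals <- pmax(pvals, .Machine$double.eps)
  x <- mean(1 / pvals)  # = 1 / raw harmonic mean p
  landau_upper_tail(x, m)
}

# P(mean of m reciprocal uniforms >= x). Location mu = log(m) + 1 -
# gamma; writing a = x - mu, the upper tail of the standard Landau is
#   (1/pi) Int_0^Inf exp(-t log t - a t) sin(pi t) / t dt,
# which converges for every a (the -t log t term dominates). For large a
# the mass concentrates near t ~ 1/a, so the integral is evaluated in
# the substituted variable u = a t to keep it well-scaled.
landau_upper_tail <- function(x, m) {
  mu <- log(m) + 1 - 0.57721566490153286
  a <- x - mu
  p <- if (a <= 1) {
    f <- function(t) exp(-t * log(t) - a * t) * sin(pi * t) / t
    integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 1000L)$value / pi
  } else {
    g <- function(u) exp(-u - (u / a) * log(u / a)) * sin(pi * u / a) / u
    integrate(g, 0, Inf, rel.tol = 1e-10, subdivisions = 1000L)$value / pi
  }
  min(max(p, 0), 1)
}

#' Geometric mean of two p-values
#'
#' The hybrid statistic sqrt(p_a * p_b) used to merge the Welch-t/Fisher
#' and independence-test/Fisher model branches. Not a calibrated
#' p-value in itself, but empirically tracks the permutation reference
#' better than either branch alone.
#'
#' @param p_a,p_b p-values in (0, 1].
#' @return sqrt(p_a * p_b).
#' @export
geometric_combine <- function(p_a, p_b) {
  sqrt(p_a * p_b)
}

#' Benjamini-Hochberg adjustment tolerating missing values
#'
#' Standard step-up false-discovery-rate adjustment applied to the
#' non-missing entries; `NA`s stay `NA` and the output order matches the
#' input.
#'
#' @param pvals numeric vector, `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}
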