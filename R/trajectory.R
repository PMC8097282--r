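#' Deterministic logistic trajectory of the selected donor allele
#'
#' Frequency of an additively selected donor allele from the admixture
#' pulse to sampling, under the logistic deterministic approximation
#' \deqn{x_g = m e^{s g} / (1 - m + m e^{s g}),}
#' where \code{s} is the per-generation (per allele copy) selection
#' coefficient: a heterozygote carries advantage \code{s}, a donor
#' homozygote \code{2s}, so a heterozygous individual experiences half
#' the homozygote's selective strength.  \code{s > 0} means the donor
#' allele is favored; \code{x_0 = m} exactly.
#'
#' @param dem An [demography()] object.
#' @param s Selection coefficient, \code{|s| < 1}.
#' @param t Number of generations (defaults to \code{dem$t}).
#' @return Numeric vector of length \code{t + 1}; element \code{g + 1}
#'   is the frequency at generation \code{g}.
#' @examples
#' x <- logistic_trajectory(demography(1e4, 0.1, 200), s = 0.05)
#' tail(x, 1)  # ~0.9996
#' @export
logistic_trajectory <- function(dem, s, t = dem$t) {
  dem <- as_demography(dem)
  stopifnot(abs(s) < 1)
  g <- 0:t
  e <- exp(s * g)
  x <- dem$m * e / (1 - dem$m + dem$m * e)
  x[1] <- dem$m
  x
}

#' Conditioned stochastic trajectory of the selected donor allele
#'
#' Mean allele-frequency trajectory over binomial Wright-Fisher forward
#' replicates (2Ne allele copies, additive selection), averaging only
#' replicates in which the allele is not lost by generation \code{t}.
#' Intended for small admixture pulses (m of order 0.01 or less), where
#' conditioning on non-loss pushes the early trajectory above the
#' deterministic logistic curve.
#'
#' @inheritParams logistic_trajectory
#' @param n_reps Number of forward replicates to average (>= 1).
#' @param condition If \code{TRUE} (default), average only replicates
#'   whose allele survives to generation \code{t}.
#' @return Numeric vector of length \code{t + 1} (mean trajectory), with
#'   attribute \code{"n_surviving"}.
#' @export
stochastic_trajectory <- function(dem, s, n_reps = 1000, t = dem$t,
                                  condition = TRUE) {
  dem <- as_demography(dem)
  stopifnot(abs(s) < 1, n_reps >= 1)
  two_ne <- round(2 * dem$Ne)
  x <- matrix(0, t + 1, n_reps)
  p <- rep(dem$m, n_reps)
  x[1, ] <- p
  for (g in seq_len(t)) {
    # deterministic selection update (per-copy additive), then drift
    ps <- p * (1 + s + s * p) / (1 + 2 * s * p)
    p <- rbinom(n_reps, two_ne, ps) / two_ne
    x[g + 1, ] <- p
  }
  keep <- if (condition) x[t + 1, ] > 0 else rep(TRUE, n_reps)
  if (!any(keep))
    stop("selected allele lost in all ", n_reps, " replicates")
  out <- rowMeans(x[, keep, drop = FALSE])
  out[1] <- dem$m
  attr(out, "n_surviving") <- sum(keep)
  out
}

# clip a trajectory away from 0/1 before use in transition-rate recursions
clip_trajectory <- function(x, eps = 1e-9) {
  pmin(pmax(x, eps), 1 - eps)
}
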