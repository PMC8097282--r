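#' Neutral ancestry-transition rates under the one-pulse model
#'
#' Expected ancestry switches per Morgan along a chromosome sampled
#' \code{t} generations after a single admixture pulse, in the absence of
#' selection.  The donor-to-recipient rate follows the one-pulse
#' tract-length result
#' \deqn{L_{10} = 2 N_e (1 - m) (1 - e^{-t / 2 N_e}),}
#' and the recipient-to-donor rate is set by detailed balance so that the
#' stationary donor-ancestry frequency is \code{m}:
#' \eqn{L_{01} = L_{10}\, m / (1 - m)}.
#'
#' @param dem An [demography()] object.
#' @return Named numeric vector \code{c(L10 = , L01 = )}, hazards per
#'   Morgan.
#' @examples
#' neutral_rates(demography(1e5, 0.17, 430))  # L10 ~ 356.5
#' @export
neutral_rates <- function(dem) {
  dem <- as_demography(dem)
  L10 <- 2 * dem$Ne * (1 - dem$m) * (1 - exp(-dem$t / (2 * dem$Ne)))
  c(L10 = L10, L01 = L10 * dem$m / (1 - dem$m))
}

# Haldane map: per-generation recombination probability between two loci
# at genetic distance r Morgans (Poisson crossovers, no interference)
recomb_prob <- function(r) 0.5 * (1 - exp(-2 * r))

# Two-locus hitchhiking recursion.  Track, at recombination distance r from
# the selected site, a = P(marker donor | selected site donor) and
# b = P(marker donor | selected site recipient); per generation the selected
# site frequency moves along the trajectory and recombination mixes each
# conditional with the marginal q = x a + (1 - x) b.  Vectorized over r.
hitchhike_ab <- function(r, traj) {
  cc <- recomb_prob(r)
  a <- rep(1, length(r))
  b <- rep(0, length(r))
  t <- length(traj) - 1L
  x <- clip_trajectory(traj)
  for (g in seq_len(t)) {
    q <- x[g + 1] * a + (1 - x[g + 1]) * b
    a <- (1 - cc) * a + cc * q
    b <- (1 - cc) * b + cc * q
  }
  list(a = a, b = b)
}

# Position-dependent hazards at distances r from the focal site.
#
# Donor-to-recipient: the finite-difference hazard of the recursion's
# survival a(r), folded additively into the neutral one-pulse rate,
# f10 = L10 + h_s - h_0, where h_0 is the same quantity at s = 0 computed
# by identical code.  The deterministic recursion carries no drift, so the
# additive fold restores the 2Ne coalescent saturation; at s = 0 the fold
# is exact, and at large r both raw hazards vanish.  For s > 0 the curve
# is clamped into [0, L10] (it approaches its neutral limit from below).
#
# Recipient-to-donor: local detailed balance with the hitchhiked marginal
# donor frequency q(r) = x_t a + (1 - x_t) b, i.e.
# f01(r) = f10(r) q(r) / (1 - q(r)), so that the chain's local equilibrium
# at distance r is the selection-elevated frequency q(r).  Near a strong
# sweep q -> x_t ~ 1 and f01 is very large (a recipient tract almost
# surely switches to donor within a short distance of the focal site); at
# s = 0 it reduces exactly to L01 = L10 m/(1-m), and at large r it
# approaches L01 from above.
transition_hazards <- function(dem, traj, r, h) {
  dem <- as_demography(dem)
  nr <- neutral_rates(dem)
  L10 <- nr[["L10"]]; L01 <- nr[["L01"]]
  lo <- pmax(r - h, 0)
  hi <- r + h
  span <- hi - lo
  pts <- c(lo, hi)
  n <- length(r)
  sel <- hitchhike_ab(pts, traj)
  neu <- hitchhike_ab(pts, rep(dem$m, length(traj)))
  la_s <- log(sel$a); la_0 <- log(neu$a)
  h10_s <- (la_s[seq_len(n)] - la_s[n + seq_len(n)]) / span
  h10_0 <- (la_0[seq_len(n)] - la_0[n + seq_len(n)]) / span
  f10 <- L10 + h10_s - h10_0
  x_t <- clip_trajectory(traj[length(traj)])
  q <- x_t * sel$a + (1 - x_t) * sel$b
  positive <- x_t >= dem$m
  f10 <- if (positive) pmin(pmax(f10, 0), L10) else pmax(f10, L10)
  qbar <- (q[seq_len(n)] + q[n + seq_len(n)]) / 2
  f01 <- f10 * qbar / pmax(1 - qbar, 1e-12)
  f01 <- if (positive) pmax(f01, L01) else pmin(pmax(f01, 0), L01)
  list(f10 = unname(f10), f01 = unname(f01))
}

#' Transition-rate curve by forward iteration
#'
#' Tabulates the direction-specific ancestry-switch hazards f10(r)
#' (donor to recipient) and f01(r) (recipient to donor), in expected
#' switches per Morgan, as functions of genetic distance r from a focal
#' selected site, by iterating the two-locus hitchhiking recursion
#' forward over the admixture epoch and extracting hazards by centered
#' finite differences, folded to the neutral limits (see
#' [neutral_rates()]).  Under selection f10 is depressed and f01 elevated
#' near the focal site; both approach their neutral limits at large r.
#'
#' @param dem An [demography()] object.
#' @param s Selection coefficient at the focal site.
#' @param r_grid Distances (Morgans, >= 0, sorted) at which to tabulate;
#'   by default a log-spaced grid with 64 points per decade from
#'   r2/1000 to \code{r_max}, where r2 = 2/L10 is the expected neutral
#'   tract length scale.
#' @param r_max Upper end of the default grid.
#' @param traj Optional precomputed allele-frequency trajectory (length
#'   \code{dem$t + 1}); defaults to [logistic_trajectory()].
#' @return An object of class \code{"ai_curve"} (tabulated form).
#' @seealso [four_point_fit()] for the fast parametric approximation.
#' @export
forward_transition_rates <- function(dem, s, r_grid = NULL,
                                     r_max = NULL, traj = NULL) {
  dem <- as_demography(dem)
  nr <- neutral_rates(dem)
  r2 <- 2 / nr[["L10"]]
  if (is.null(r_grid)) {
    if (is.null(r_max)) r_max <- 5 * r2
    lo <- r2 / 1000
    n <- ceiling(64 * log10(r_max / lo))
    r_grid <- c(0, exp(seq(log(lo), log(r_max), length.out = n)))
  }
  if (any(r_grid < 0)) stop("r_grid must be nonnegative")
  r_grid <- sort(unique(r_grid))
  if (is.null(traj)) traj <- logistic_trajectory(dem, s)
  h <- pmax(r_grid * 0.05, r2 * 1e-4)
  fz <- transition_hazards(dem, traj, r_grid, h)
  structure(list(type = "grid", dem = dem, s = s,
                 L10 = nr[["L10"]], L01 = nr[["L01"]],
                 r1 = r2 / 10, r2 = r2,
                 grid = list(r = r_grid, f10 = fz$f10, f01 = fz$f01),
                 fixation = tail(traj, 1) > 1 - 1e-6),
            class = "ai_curve")
}

#' Four-point parametric transition-rate curve
#'
#' Fits the parametric form \deqn{\hat f(r) = L - k e^{-\alpha r^p}} to
#' each direction of the selection-distorted transition-rate curve,
#' anchored at the numerically evaluated hazards at r = 0, r1 and r2
#' plus the neutral limit L.  The anchor distances are r2 = 2/L10 (the
#' expected neutral tract-length scale) and r1 = r2/10.  Writing
#' \eqn{k = L - \hat f(0)} and \eqn{y_i = \log[(L - \hat f(r_i))/k]},
#' the exponents are \eqn{p = \log(y_1/y_2)/\log(r_1/r_2)} and
#' \eqn{\alpha = -y_1 / r_1^p}.  The fitted curve passes through the
#' three anchors exactly and has limit L at large distance.
#'
#' Degenerate anchors (no measurable distortion, k ~ 0) yield the
#' constant neutral curve rather than an error.
#'
#' @inheritParams forward_transition_rates
#' @return An object of class \code{"ai_curve"} (parametric form), with
#'   per-direction parameter lists \code{params10}, \code{params01}.
#' @export
four_point_fit <- function(dem, s, traj = NULL) {
  dem <- as_demography(dem)
  nr <- neutral_rates(dem)
  r2 <- 2 / nr[["L10"]]
  r1 <- r2 / 10
  if (is.null(traj)) traj <- logistic_trajectory(dem, s)
  h <- r1 / 20
  anch <- transition_hazards(dem, traj, c(0, r1, r2), c(h, h, h))
  structure(list(type = "fourpoint", dem = dem, s = s,
                 L10 = nr[["L10"]], L01 = nr[["L01"]],
                 r1 = r1, r2 = r2,
                 params10 = fit_four_point(nr[["L10"]], anch$f10, r1, r2),
                 params01 = fit_four_point(nr[["L01"]], anch$f01, r1, r2),
                 fixation = tail(traj, 1) > 1 - 1e-6),
            class = "ai_curve")
}

# solve (k, alpha, p) from the three anchor values f(0), f(r1), f(r2).
# The family L - k e^{-alpha r^p} requires anchors that approach L
# monotonically with f(r1) strictly between f(0) and f(r2); weak selection
# can leave the middle anchor outside that bracket (the numerically
# extracted curve has a shallow interior dip of order 1% there), in which
# case we fall back to the single exponential through the r = 0 and r2
# anchors (p = 1) rather than failing.
fit_four_point <- function(L, f, r1, r2) {
  k <- L - f[1]
  if (!is.finite(k) || abs(k) <= 1e-10 * max(L, 1))
    return(list(L = L, k = 0, alpha = 0, p = 1))
  eps <- 1e-12
  a1 <- (L - f[2]) / k
  a2 <- min(max((L - f[3]) / k, eps), 1 - eps)
  y2 <- log(a2)
  if (!is.finite(a1) || a1 <= a2 || a1 >= 1) {
    p <- 1
    alpha <- -y2 / r2
  } else {
    y1 <- log(max(a1, eps))
    p <- log(y1 / y2) / log(r1 / r2)
    if (!is.finite(p) || p <= 0) {
      p <- 1
      alpha <- -y2 / r2
    } else {
      alpha <- -y1 / r1^p
    }
  }
  if (!is.finite(alpha) || alpha < 0) alpha <- 0
  list(L = L, k = k, alpha = alpha, p = p)
}

#' Evaluate a transition-rate curve
#'
#' @param curve An \code{"ai_curve"} object.
#' @param r Genetic distances from the focal site (Morgans; absolute
#'   value is used, the model is distance-only).
#' @return List with components \code{f10} and \code{f01}, hazards per
#'   Morgan at each distance.
#' @export
curve_eval <- function(curve, r) {
  stopifnot(inherits(curve, "ai_curve"))
  r <- abs(r)
  if (curve$type == "fourpoint") {
    ev <- function(pp) {
      if (pp$k == 0) rep(pp$L, length(r))
      else pp$L - pp$k * exp(-pp$alpha * r^pp$p)
    }
    list(f10 = pmax(ev(curve$params10), 0), f01 = pmax(ev(curve$params01), 0))
  } else {
    g <- curve$grid
    f10 <- approx(g$r, g$f10, xout = pmin(r, max(g$r)), rule = 2)$y
    f01 <- approx(g$r, g$f01, xout = pmin(r, max(g$r)), rule = 2)$y
    # beyond the tabulated range the curves sit at their neutral limits
    f10[r > max(g$r)] <- curve$L10
    f01[r > max(g$r)] <- curve$L01
    list(f10 = f10, f01 = f01)
  }
}

#' @export
print.ai_curve <- function(x, ...) {
  cat(sprintf("Ancestry transition curve (%s), s = %g: L10 = %.4g, L01 = %.4g, r2 = %.4g M%s\n",
              x$type, x$s, x$L10, x$L01, x$r2,
              if (isTRUE(x$fixation)) " [fixation regime; s underestimated]" else ""))
  invisible(x)
}

# per-interval single-chromosome switch probabilities from the 2-state
# rate pair (f10, f01) over genetic distance d (exact 2-state kernel)
interval_switch_probs <- function(curve, r_mid, d) {
  f <- curve_eval(curve, r_mid)
  tot <- f$f10 + f$f01
  w <- ifelse(tot > 0, -expm1(-tot * d), 0)
  u <- ifelse(tot > 0, f$f10 / tot * w, 0)
  v <- ifelse(tot > 0, f$f01 / tot * w, 0)
  list(u = u, v = v)
}

#' Ancestry-dosage transition matrix
#'
#' Lifts single-chromosome ancestry switch probabilities to the
#' (ploidy + 1)-state dosage chain by assuming independent chromosomes:
#' from dosage i, the next dosage is (i - X) + Y with X ~ Bin(i, u) and
#' Y ~ Bin(ploidy - i, v).
#'
#' @param ploidy Number of chromosomes in the sample.
#' @param u Donor-to-recipient switch probability over the interval.
#' @param v Recipient-to-donor switch probability.
#' @return A (ploidy+1) x (ploidy+1) row-stochastic matrix; rows and
#'   columns are dosages 0..ploidy.
#' @export
dosage_transition_matrix <- function(ploidy, u, v) {
  K <- ploidy + 1
  T <- matrix(0, K, K)
  for (i in 0:ploidy) {
    pX <- dbinom(0:i, i, u)
    pY <- dbinom(0:(ploidy - i), ploidy - i, v)
    for (x in 0:i) {
      j <- (i - x) + 0:(ploidy - i)
      T[i + 1, j + 1] <- T[i + 1, j + 1] + pX[x + 1] * pY
    }
  }
  T
}

#' Per-interval transition matrices for a chain of sites
#'
#' @param curve An \code{"ai_curve"} from [four_point_fit()] or
#'   [forward_transition_rates()].
#' @param gpos Cumulative genetic positions of the sites (Morgans,
#'   nondecreasing).
#' @param focal_gpos Genetic position of the focal selected site.
#' @param ploidy Chromosomes per sample.
#' @return A list of length \code{length(gpos) - 1} of dosage transition
#'   matrices, one per adjacent site pair.
#' @export
site_transition_matrices <- function(curve, gpos, focal_gpos, ploidy) {
  stopifnot(!is.unsorted(gpos))
  d <- diff(gpos)
  r_mid <- abs((gpos[-1] + gpos[-length(gpos)]) / 2 - focal_gpos)
  uv <- interval_switch_probs(curve, r_mid, d)
  lapply(seq_along(d), function(i)
    dosage_transition_matrix(ploidy, uv$u[i], uv$v[i]))
}
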