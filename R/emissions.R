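#' Emission model for ancestry-dosage states
#'
#' Describes how per-site observations are generated given the hidden
#' ancestry dosage.  Selection does not enter the emissions; only the
#' transition rates are affected by it.
#'
#' In pileup mode the observation is a pair of read counts (nA, na):
#' each read samples one of the individual's chromosomes uniformly and
#' reports its allele with per-allele error \code{error}.  Given dosage
#' k (donor chromosomes out of ploidy n), the genotype G (count of A
#' alleles) mixes a Binomial(k, p1) draw from the donor panel frequency
#' with a Binomial(n - k, p0) draw from the recipient panel frequency.
#' In genotype mode the called dosage of allele A is observed directly.
#'
#' Panel allele frequencies are estimated with a +1/+2 pseudocount,
#' \eqn{(c_A + 1)/(c_A + c_a + 2)}, which keeps emissions strictly
#' positive for finite panels; set \code{pseudocount = FALSE} to use raw
#' frequencies (clamped away from 0 and 1).
#'
#' @param mode \code{"pileup"} or \code{"genotype"}.
#' @param error Per-allele read error rate, in [0, 0.5).
#' @param pseudocount Use the +1/+2 panel frequency estimator.
#' @return An object of class \code{"ai_emission"}.
#' @export
emission_model <- function(mode = c("pileup", "genotype"), error = 0.01,
                           pseudocount = TRUE) {
  mode <- match.arg(mode)
  stopifnot(error >= 0, error < 0.5)
  structure(list(mode = mode, error = error, pseudocount = pseudocount),
            class = "ai_emission")
}

panel_freqs <- function(sites, pseudocount = TRUE) {
  if (pseudocount) {
    p0 <- (sites$p0A + 1) / (sites$p0A + sites$p0a + 2)
    p1 <- (sites$p1A + 1) / (sites$p1A + sites$p1a + 2)
  } else {
    eps <- 1e-6
    p0 <- pmin(pmax(sites$p0A / (sites$p0A + sites$p0a), eps), 1 - eps)
    p1 <- pmin(pmax(sites$p1A / (sites$p1A + sites$p1a), eps), 1 - eps)
  }
  list(p0 = p0, p1 = p1)
}

# P(G | dosage k) for G = 0..ploidy, vectorized over sites: convolution of
# Binomial(k, p1) and Binomial(ploidy - k, p0).  Returns a list over states
# k of sites x (ploidy+1) matrices.
genotype_dist_by_state <- function(p0, p1, ploidy) {
  n <- ploidy
  lapply(0:n, function(k) {
    M <- matrix(0, length(p0), n + 1)
    for (j in 0:k) {
      pj <- dbinom(j, k, p1)
      for (i in 0:(n - k))
        M[, j + i + 1] <- M[, j + i + 1] + pj * dbinom(i, n - k, p0)
    }
    M
  })
}

# emission matrices (sites x states) for every sample; the genotype
# mixture is shared across samples of equal ploidy and computed once
compute_emissions <- function(data, em) {
  stopifnot(inherits(data, "ai_counts"), inherits(em, "ai_emission"))
  empty <- (data$sites$p0A + data$sites$p0a == 0) &
           (data$sites$p1A + data$sites$p1a == 0)
  if (any(empty))
    stop("site(s) with zero sampled alleles in both panels reached the ",
         "emission model; they should have been dropped on input")
  pf <- panel_freqs(data$sites, em$pseudocount)
  n_sites <- nrow(data$sites)
  out <- vector("list", nrow(data$samples))
  for (pl in unique(data$samples$ploidy)) {
    Ms <- genotype_dist_by_state(pf$p0, pf$p1, pl)
    phi <- (0:pl) / pl * (1 - em$error) + (1 - (0:pl) / pl) * em$error
    for (si in which(data$samples$ploidy == pl)) {
      nA <- data$obs_A[, si]
      na <- data$obs_a[, si]
      E <- matrix(1, n_sites, pl + 1)
      if (em$mode == "pileup") {
        D <- vapply(0:pl, function(g) dbinom(nA, nA + na, phi[g + 1]),
                    numeric(n_sites))
        for (k in 0:pl) E[, k + 1] <- rowSums(Ms[[k + 1]] * D)
      } else {
        G <- nA  # called dosage of allele A
        ok <- is.finite(G) & G >= 0 & G <= pl
        for (k in 0:pl)
          E[ok, k + 1] <- Ms[[k + 1]][cbind(which(ok), G[ok] + 1)]
      }
      out[[si]] <- E
    }
  }
  out
}

#' Per-site emission probability
#'
#' Probability of one sample's observation at one site given an ancestry
#' dosage state; mostly useful for inspection and testing, the scan
#' computes emissions for all sites at once.
#'
#' @param data An \code{"ai_counts"} object.
#' @param site Site index (row of \code{data$sites}).
#' @param sample Sample index.
#' @param state Ancestry dosage (0..ploidy donor chromosomes).
#' @param em An [emission_model()]; defaults to the data's mode.
#' @return The emission probability.
#' @export
emission_prob <- function(data, site, sample, state,
                          em = emission_model(data$mode)) {
  pl <- data$samples$ploidy[sample]
  stopifnot(state >= 0, state <= pl)
  sub <- subset_counts(data, site)
  compute_emissions(sub, em)[[sample]][1, state + 1]
}
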