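#' Assemble an ancestry-dosage HMM
#'
#' Builds the hidden Markov model for a stretch of sites: per-sample
#' emission matrices, per-interval single-chromosome switch
#' probabilities from a transition curve (selection at a focal site, or
#' the constant neutral rates), and the binomial initial distribution
#' with donor frequency \code{m}.  The state space for a sample of
#' ploidy n is the donor-chromosome dosage \{0, ..., n\}; per-sample
#' chains are independent and the total log-likelihood is the sum over
#' samples.
#'
#' @param data An \code{"ai_counts"} object (single chromosome).
#' @param dem An [demography()] object.
#' @param s Selection coefficient at the focal site; \code{s = 0} gives
#'   the neutral model.
#' @param focal Focal site index (required when \code{s != 0}).
#' @param em An [emission_model()].
#' @param backend \code{"fourpoint"} or \code{"forward"} transition
#'   curve.
#' @param sites Optional indices restricting the model to a window of
#'   sites.
#' @param traj Optional precomputed selected-allele trajectory.
#' @return An object of class \code{"ai_hmm"}.
#' @export
hmm_instance <- function(data, dem, s = 0, focal = NULL,
                         em = emission_model(data$mode),
                         backend = c("fourpoint", "forward"),
                         sites = NULL, traj = NULL) {
  backend <- match.arg(backend)
  dem <- as_demography(dem)
  stopifnot(inherits(data, "ai_counts"))
  if (length(unique(data$sites$chrom)) != 1)
    stop("hmm_instance expects a single chromosome")
  if (s != 0 && is.null(focal)) stop("focal site required when s != 0")
  emis <- compute_emissions(data, em)
  if (is.null(sites)) sites <- seq_len(nrow(data$sites))
  emis <- lapply(emis, function(E) E[sites, , drop = FALSE])
  gpos <- data$sites$gpos[sites]
  focal_g <- if (is.null(focal)) gpos[1] else data$sites$gpos[focal]
  curve <- if (s == 0) neutral_curve(dem)
           else if (backend == "fourpoint") four_point_fit(dem, s, traj = traj)
           else forward_transition_rates(dem, s, traj = traj,
                                         r_max = max(abs(gpos - focal_g)) + 1e-3)
  d <- diff(gpos)
  r_mid <- abs((gpos[-1] + gpos[-length(gpos)]) / 2 - focal_g)
  uv <- interval_switch_probs(curve, r_mid, d)
  structure(list(emissions = emis, u = uv$u, v = uv$v,
                 ploidies = data$samples$ploidy, m = dem$m,
                 gpos = gpos, curve = curve, dem = dem, s = s),
            class = "ai_hmm")
}

# constant-rate curve for the neutral one-pulse model
neutral_curve <- function(dem) {
  nr <- neutral_rates(dem)
  r2 <- 2 / nr[["L10"]]
  structure(list(type = "fourpoint", dem = dem, s = 0,
                 L10 = nr[["L10"]], L01 = nr[["L01"]],
                 r1 = r2 / 10, r2 = r2,
                 params10 = list(L = nr[["L10"]], k = 0, alpha = 0, p = 1),
                 params01 = list(L = nr[["L01"]], k = 0, alpha = 0, p = 1),
                 fixation = FALSE),
            class = "ai_curve")
}

#' Forward-algorithm log-likelihood
#'
#' Exact log P(observations | model) for an assembled HMM, by the scaled
#' forward recursion, summed over the independent per-sample chains.
#'
#' @param h An \code{"ai_hmm"} from [hmm_instance()].
#' @return The log-likelihood (scalar; \code{-Inf} with a warning if
#'   some site has an all-zero emission vector).
#' @export
forward_loglik <- function(h) {
  stopifnot(inherits(h, "ai_hmm"))
  ll <- 0
  for (pl in unique(h$ploidies)) {
    idx <- which(h$ploidies == pl)
    init <- dbinom(0:pl, pl, h$m)
    ll <- ll + cpp_forward_loglik(h$emissions[idx], h$u, h$v, pl, init)
  }
  if (!is.finite(ll))
    warning("all-zero emission vector encountered; log-likelihood is -Inf")
  ll
}

#' Posterior ancestry dosage
#'
#' Forward-backward posterior state probabilities for every sample, and
#' the posterior mean donor dosage per site.  The population donor
#' frequency at a site is the mean over samples of posterior dosage
#' divided by ploidy.
#'
#' @param h An \code{"ai_hmm"} from [hmm_instance()].
#' @return A list: \code{dosage} (site x sample posterior mean dosage),
#'   \code{freq} (per-site posterior donor frequency), and
#'   \code{posterior} (list of site x state matrices per sample).
#' @export
posterior_dosage <- function(h) {
  stopifnot(inherits(h, "ai_hmm"))
  S <- length(h$emissions)
  n <- nrow(h$emissions[[1]])
  dosage <- matrix(0, n, S)
  posts <- vector("list", S)
  for (pl in unique(h$ploidies)) {
    K <- pl + 1
    init <- dbinom(0:pl, pl, h$m)
    Ts <- lapply(seq_len(n - 1), function(i)
      dosage_transition_matrix(pl, h$u[i], h$v[i]))
    for (si in which(h$ploidies == pl)) {
      E <- h$emissions[[si]]
      alpha <- matrix(0, n, K)
      a <- init * E[1, ]
      sc <- numeric(n)
      sc[1] <- sum(a)
      alpha[1, ] <- a / sc[1]
      if (n > 1) for (i in 2:n) {
        a <- (alpha[i - 1, ] %*% Ts[[i - 1]]) * E[i, ]
        sc[i] <- sum(a)
        if (sc[i] <= 0) stop("all-zero emission vector at site ", i)
        alpha[i, ] <- a / sc[i]
      }
      beta <- matrix(0, n, K)
      beta[n, ] <- 1
      if (n > 1) for (i in (n - 1):1)
        beta[i, ] <- (Ts[[i]] %*% (E[i + 1, ] * beta[i + 1, ])) / sc[i + 1]
      post <- alpha * beta
      post <- post / rowSums(post)
      posts[[si]] <- post
      dosage[, si] <- post %*% (0:pl)
    }
  }
  freq <- rowMeans(sweep(dosage, 2, h$ploidies, "/"))
  list(dosage = dosage, freq = freq, posterior = posts)
}
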