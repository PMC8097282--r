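# Shared fixtures, built in code and cached for the session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- builder()
  fixture_cache[[key]]
}

# a tiny hand-written counts object (3 sites, 1 diploid)
toy_counts_text <- function() {
  paste(
    "chr1\t100\t8\t2\t1\t9\t0.0000000000e+00\t2\t1",
    "chr1\t500\t9\t1\t2\t8\t4.0000000000e-05\t0\t3",
    "chr1\t900\t7\t3\t0\t10\t4.0000000000e-05\t1\t1",
    sep = "\n")
}

toy_counts <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(toy_counts_text(), path)
  read_counts_file(path, ploidies = 2)
}

# small simulated data set for fast functional tests
small_sim <- function() {
  cached("small_sim", function() {
    simulate_dataset(demography(2000, 0.2, 60), selected_s = 0.1,
                     n_sites = 400, n_ind = 10, seed = 101)
  })
}

# the validation-study replicate set: one-pulse sweep, m = 0.1, s = 0.05,
# sampled at t = 200 with 25 diploids at Poisson depth 2 and 1% read error.
# Each replicate holds the individually sequenced data, a pooled version of
# the same chromosomes, and the simulation truth.
study_dem <- function() demography(10000, 0.1, 200)
study_s <- 0.05

study_replicates <- function(n_reps = 10, seed_base = 1000) {
  cached("study_reps", function() {
    lapply(seq_len(n_reps), function(i) {
      set.seed(seed_base + i)
      pop <- simulate_admixture(study_dem(),
                                scenario(selected = data.frame(pos = 0.5,
                                                               s = study_s)),
                                n_sample = 25)
      pan <- synthesize_panels(pop, n_sites = 2000)
      rd <- simulate_reads(pan$haps, ploidy = 2)
      rdp <- list(obs_A = matrix(rowSums(rd$obs_A), ncol = 1),
                  obs_a = matrix(rowSums(rd$obs_a), ncol = 1),
                  ploidies = 50L)
      mk <- function(r, pooled) aiscan:::new_counts(
        pan$sites, r$obs_A, r$obs_a,
        data.frame(id = paste0(if (pooled) "pool" else "ind",
                               seq_along(r$ploidies)),
                   ploidy = r$ploidies, stringsAsFactors = FALSE),
        mode = "pileup", pooled = pooled)
      focal_idx <- which.min(abs(pan$sites$pos_bp - 5e6))
      list(data = mk(rd, FALSE), pooled = mk(rdp, TRUE),
           focal_bp = 5e6, trajectory = pop$trajectory,
           end_freq = pop$trajectory[nrow(pop$trajectory), 1],
           sample_freq_focal = mean(pan$anc[, focal_idx]))
    })
  })
}

# s_hat at the top-LR site of a full-chromosome scan
top_site <- function(fit) {
  r <- fit$results[is.finite(fit$results$lr), ]
  r[which.max(r$lr), ]
}

# independent Wright-Fisher deterministic recursion oracle (per-copy
# additive selection): marginal allele fitnesses w_A = 1 + s + s p,
# w_a = 1 + s p, mean fitness 1 + 2 s p
wf_recursion_oracle <- function(m, s, t) {
  p <- numeric(t + 1)
  p[1] <- m
  for (g in seq_len(t))
    p[g + 1] <- p[g] * (1 + s + s * p[g]) / (1 + 2 * s * p[g])
  p
}

# brute-force path-enumeration log-likelihood for one sample
enum_loglik <- function(E, u, v, ploidy, init) {
  n <- nrow(E)
  K <- ploidy + 1
  Ts <- lapply(seq_len(n - 1), function(i)
    dosage_transition_matrix(ploidy, u[i], v[i]))
  paths <- expand.grid(rep(list(seq_len(K)), n))
  tot <- 0
  for (row in seq_len(nrow(paths))) {
    k <- as.integer(paths[row, ])
    p <- init[k[1]] * E[1, k[1]]
    for (i in seq_len(n - 1))
      p <- p * Ts[[i]][k[i], k[i + 1]] * E[i + 1, k[i + 1]]
    tot <- tot + p
  }
  log(tot)
}
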