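make_counts <- function(sites, obs_A, obs_a, ploidy, mode = "pileup",
                        pooled = FALSE) {
  aiscan:::new_counts(sites, obs_A, obs_a,
                      data.frame(id = paste0("s", seq_along(ploidy)),
                                 ploidy = as.integer(ploidy),
                                 stringsAsFactors = FALSE),
                      mode = mode, pooled = pooled)
}

sites_df <- function(n, spacing = 1e-4) {
  data.frame(chrom = "chr1", pos_bp = seq_len(n) * 1000,
             dist_M = c(0, rep(spacing, n - 1)),
             p0A = 80, p0a = 20, p1A = 10, p1a = 90,
             stringsAsFactors = FALSE)
}

test_that("emission probabilities: empty product, hand computation, normalization", {
  em <- emission_model("pileup", error = 0)
  # zero reads: emission 1 for every state
  d0 <- make_counts(sites_df(1), matrix(0), matrix(0), 2)
  for (k in 0:2) expect_equal(emission_prob(d0, 1, 1, k, em), 1)

  # ploidy 1, panels fixed for opposite alleles, one A read:
  # P(state recipient)/P(state donor) = (C + 1)/1 with the pseudocount
  C <- 30
  s1 <- sites_df(1)
  s1$p0A <- C; s1$p0a <- 0; s1$p1A <- 0; s1$p1a <- C
  d1 <- make_counts(s1, matrix(1), matrix(0), 1)
  e0 <- emission_prob(d1, 1, 1, 0, em)
  e1 <- emission_prob(d1, 1, 1, 1, em)
  expect_equal(e0 / e1, C + 1)
  expect_equal(e0, (C + 1) / (C + 2))

  # fixed depth d: probabilities over all read outcomes sum to 1 per state
  em2 <- emission_model("pileup", error = 0.01)
  depth <- 4
  for (k in 0:2) {
    tot <- sum(vapply(0:depth, function(nA) {
      dd <- make_counts(sites_df(1), matrix(nA), matrix(depth - nA), 2)
      emission_prob(dd, 1, 1, k, em2)
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("genotype-mode emissions are the panel-mixture genotype probabilities", {
  s1 <- sites_df(1)
  d <- make_counts(s1, matrix(1), matrix(1), 2, mode = "genotype")
  em <- emission_model("genotype")
  p0 <- (s1$p0A + 1) / (s1$p0A + s1$p0a + 2)
  p1 <- (s1$p1A + 1) / (s1$p1A + s1$p1a + 2)
  # state 1 (one donor, one recipient chromosome), observed dosage 1
  expect_equal(emission_prob(d, 1, 1, 1, em),
               p0 * (1 - p1) + p1 * (1 - p0))
  # dosages sum to 1 over observations for each state
  for (k in 0:2) {
    tot <- sum(vapply(0:2, function(g) {
      dd <- make_counts(s1, matrix(g), matrix(2 - g), 2, mode = "genotype")
      emission_prob(dd, 1, 1, k, em)
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("forward log-likelihood equals brute-force path enumeration", {
  set.seed(7)
  for (trial in 1:4) {
    n <- sample(3:5, 1)
    pl <- sample(1:2, 1)
    ss <- sites_df(n, spacing = 5e-4)
    depth <- matrix(rpois(n, 3), n, 1)
    nA <- matrix(rbinom(n, depth, 0.5), n, 1)
    d <- make_counts(ss, nA, depth - nA, pl)
    dem <- demography(5000, 0.25, 120)
    h <- hmm_instance(d, dem, s = 0.08, focal = 2)
    ll <- forward_loglik(h)
    oracle <- enum_loglik(h$emissions[[1]], h$u, h$v, pl,
                          dbinom(0:pl, pl, dem$m))
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("single-site likelihood is the initial-emission dot product", {
  d <- make_counts(sites_df(1), matrix(2), matrix(1), 2)
  dem <- demography(5000, 0.3, 100)
  h <- hmm_instance(d, dem)
  E <- h$emissions[[1]]
  expect_equal(forward_loglik(h),
               log(sum(dbinom(0:2, 2, 0.3) * E[1, ])))
})

test_that("inserting an uninformative zero-distance site leaves the likelihood unchanged", {
  set.seed(8)
  n <- 6
  ss <- sites_df(n, spacing = 3e-4)
  depth <- matrix(rpois(n, 3), n, 1)
  nA <- matrix(rbinom(n, depth, 0.4), n, 1)
  d <- make_counts(ss, nA, depth - nA, 2)
  dem <- demography(5000, 0.2, 150)
  h <- hmm_instance(d, dem)
  ll <- forward_loglik(h)
  # duplicate site 4 with zero reads at zero distance
  ss2 <- ss[c(1:4, 4:6), ]
  ss2$dist_M[5] <- 0
  ss2$pos_bp <- ss2$pos_bp + seq_len(7)  # keep positions distinct
  nA2 <- matrix(c(nA[1:4], 0, nA[5:6]), ncol = 1)
  dp2 <- matrix(c(depth[1:4], 0, depth[5:6]), ncol = 1)
  d2 <- make_counts(ss2, nA2, dp2 - nA2, 2)
  h2 <- hmm_instance(d2, dem)
  expect_equal(forward_loglik(h2), ll, tolerance = 1e-10)
})

test_that("per-sample chains are independent: total log-likelihood adds over samples", {
  set.seed(9)
  n <- 5
  ss <- sites_df(n)
  depth <- matrix(rpois(2 * n, 3), n, 2)
  nA <- matrix(rbinom(2 * n, depth, 0.5), n, 2)
  d12 <- make_counts(ss, nA, depth - nA, c(2, 2))
  d1 <- make_counts(ss, nA[, 1, drop = FALSE], (depth - nA)[, 1, drop = FALSE], 2)
  d2 <- make_counts(ss, nA[, 2, drop = FALSE], (depth - nA)[, 2, drop = FALSE], 2)
  dem <- demography(5000, 0.2, 150)
  expect_equal(forward_loglik(hmm_instance(d12, dem)),
               forward_loglik(hmm_instance(d1, dem)) +
                 forward_loglik(hmm_instance(d2, dem)))
})

test_that("posteriors are proper and collapse to the prior without data", {
  n <- 8
  ss <- sites_df(n)
  zero <- matrix(0L, n, 1)
  d <- make_counts(ss, zero, zero, 2)
  dem <- demography(5000, 0.2, 150)
  h <- hmm_instance(d, dem)
  post <- posterior_dosage(h)
  expect_equal(rowSums(post$posterior[[1]]), rep(1, n))
  expect_equal(post$dosage[, 1], rep(2 * 0.2, n), tolerance = 1e-10)
  expect_equal(post$freq, rep(0.2, n), tolerance = 1e-10)
})

test_that("posterior donor frequency tracks the simulated sweep", {
  rep1 <- study_replicates()[[1]]
  d <- rep1$data
  focal <- which.min(abs(d$sites$pos_bp - rep1$focal_bp))
  h <- hmm_instance(d, study_dem(), s = study_s, focal = focal)
  post <- posterior_dosage(h)
  expect_lt(abs(post$freq[focal] - rep1$sample_freq_focal), 0.05)
  # far from the sweep the posterior frequency returns toward m
  far <- which.min(abs(d$sites$pos_bp - 5e5))
  expect_lt(post$freq[far], 0.5)
})
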