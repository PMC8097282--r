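test_that("golden-section search recovers the maximizer of a closed-form unimodal function", {
  f <- function(x) -(x - 1.3)^2
  o <- aiscan:::golden_max(f, -2, 4, tol = 1e-5)
  expect_equal(o$x, 1.3, tolerance = 1e-4)
  # boundary maximum: monotone increasing objective ends at the upper bound
  o2 <- aiscan:::golden_max(function(x) x, 0, 2, tol = 1e-5)
  expect_equal(o2$x, 2, tolerance = 1e-3)
})

test_that("likelihood ratio vanishes as s approaches zero", {
  sim <- small_sim()
  focal <- which.min(abs(sim$sites$pos_bp - 5e6))
  lr <- site_likelihood_ratio(sim, focal, s = 1e-6, Ne = 2000, m = 0.2, t = 60)
  expect_lt(abs(lr$lr), 0.05)
})

test_that("gss optimum dominates a post-hoc grid at the same site", {
  sim <- small_sim()
  focal <- which.min(abs(sim$sites$pos_bp - 5e6))
  o <- golden_section_optimize(sim, focal, Ne = 2000, m = 0.2, t = 60)
  expect_gte(o$lr, 0)
  for (s in c(0.005, 0.02, 0.08, 0.14)) {
    lr_s <- site_likelihood_ratio(sim, focal, s, Ne = 2000, m = 0.2, t = 60)$lr
    expect_gte(o$lr + 0.1, lr_s)
  }
})

test_that("scan output is invariant to stride refinement at shared sites", {
  sim <- small_sim()
  f4 <- aiscan(sim, Ne = 2000, m = 0.2, t = 60, stride = 160)
  f2 <- aiscan(sim, Ne = 2000, m = 0.2, t = 60, stride = 80)
  shared <- intersect(f4$results$pos_bp, f2$results$pos_bp)
  expect_gt(length(shared), 1)
  a <- f4$results[match(shared, f4$results$pos_bp), ]
  b <- f2$results[match(shared, f2$results$pos_bp), ]
  expect_equal(a$lr, b$lr)
  expect_equal(a$s_hat, b$s_hat)
  # stride = number of sites evaluates exactly one site
  f1 <- aiscan(sim, Ne = 2000, m = 0.2, t = 60, stride = nrow(sim$sites))
  expect_equal(nrow(f1$results), 1)
})

test_that("windows with too few informative sites are flagged and skipped", {
  sim <- small_sim()
  fit <- aiscan(sim, Ne = 2000, m = 0.2, t = 60, stride = 100,
                min_informative = 1e6)
  expect_true(all(is.na(fit$results$lr)))
  expect_true(all(grepl("too_few_sites", fit$results$flag)))
})

test_that("grid and gss modes agree on the best site and s scale", {
  sim <- small_sim()
  idx <- round(seq(60, 340, length.out = 8))
  gfit <- aiscan(sim, Ne = 2000, m = 0.2, t = 60, mode = "grid",
                 s_grid = c(0.02, 0.05, 0.1, 0.15), sites = idx)
  sfit <- aiscan(sim, Ne = 2000, m = 0.2, t = 60, sites = idx)
  expect_equal(which.max(gfit$results$lr), which.max(sfit$results$lr))
  b <- which.max(sfit$results$lr)
  # gss lr at the optimum is at least the best grid lr at that site
  expect_gte(sfit$results$lr[b] + 1e-6, gfit$results$lr[b])
})

test_that("peak calling applies threshold, separation and leftmost tie-break", {
  res <- data.frame(chrom = "chr1",
                    pos_bp = c(1e6, 2e6, 3e6, 6e6),
                    gpos = c(0.01, 0.02, 0.03, 0.06),
                    s_hat = 0.05, lr = c(20, 25, 18, 30),
                    flag = "", stringsAsFactors = FALSE)
  # all below threshold: empty
  expect_equal(nrow(find_peaks(res, threshold = 50)), 0)
  # 1 cM apart with 2 cM separation: only the higher of each cluster
  pk <- find_peaks(res, threshold = 15, min_sep_cM = 2)
  expect_equal(pk$pos_bp, c(2e6, 6e6))
  # plateau of equal LRs: leftmost wins
  res$lr <- c(20, 20, 20, 20)
  pk2 <- find_peaks(res, threshold = 15, min_sep_cM = 2)
  expect_equal(pk2$pos_bp[1], 1e6)
  expect_equal(pk2$pos_bp, c(1e6, 3e6, 6e6))
})

test_that("null threshold calibration: refusal, bounds, monotonicity", {
  fake_scan <- function(lrs, seed) {
    n <- length(lrs)
    data.frame(chrom = "chr1", pos_bp = seq_len(n) * 1e6,
               gpos = seq_len(n) * 0.03, s_hat = 0.01, lr = lrs,
               flag = "", stringsAsFactors = FALSE)
  }
  expect_error(null_threshold(lapply(1:5, function(i) fake_scan(runif(5), i))),
               "at least 10")
  set.seed(10)
  scans <- lapply(1:20, function(i) fake_scan(runif(8), i))
  thr <- null_threshold(scans, min_sep_cM = 2, target = 1)
  expect_lte(thr$threshold, 1)
  # mean false discoveries at the returned threshold is within target
  fd <- vapply(scans, function(s)
    nrow(find_peaks(s, thr$threshold, min_sep_cM = 2)), numeric(1))
  expect_lte(mean(fd), 1)
  # threshold is nonincreasing in the tolerated false-discovery count
  thr2 <- null_threshold(scans, min_sep_cM = 2, target = 2)
  expect_lte(thr2$threshold, thr$threshold)
})

test_that("scan methods print, summarize, and expose the coefficient", {
  sim <- small_sim()
  fit <- aiscan(sim, Ne = 2000, m = 0.2, t = 60, stride = 80)
  expect_output(print(fit), "Top site")
  expect_named(coef(fit), "s")
  sm <- summary(fit, threshold = 5, min_sep_cM = 2)
  expect_s3_class(sm, "summary.aiscan")
  expect_output(print(sm), "Top sites")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("label-flipped scan localizes a negatively selected introgressed locus", {
  set.seed(55)
  dem <- demography(4000, 0.3, 80)
  sim <- simulate_dataset(dem, selected_s = -0.08, n_sites = 600, n_ind = 15,
                          seed = 55)
  tr <- attr(sim, "truth")
  fl <- flip_labels(sim, dem)
  idx <- seq(20, 580, by = 20)
  fit <- aiscan(fl$data, Ne = fl$dem$Ne, m = fl$dem$m, t = fl$dem$t,
                sites = idx)
  b <- top_site(fit)
  expect_lt(abs(b$pos_bp - tr$loci_bp[1]), 1.5e6)
  expect_gt(b$lr, 5)
})

test_that("fourpoint and forward backends agree on the estimated selection coefficient", {
  rep1 <- study_replicates()[[1]]
  focal <- which.min(abs(rep1$data$sites$pos_bp - rep1$focal_bp))
  o4 <- golden_section_optimize(rep1$data, focal, Ne = 1e4, m = 0.1, t = 200,
                                backend = "fourpoint")
  of <- golden_section_optimize(rep1$data, focal, Ne = 1e4, m = 0.1, t = 200,
                                backend = "forward")
  expect_lt(abs(o4$s_hat - of$s_hat) / o4$s_hat, 0.25)
})
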