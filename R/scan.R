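#' Likelihood-ratio scan for adaptive introgression
#'
#' Fits, at each evaluated site, a model in which an introgressed allele
#' at that site has been under additive positive selection \code{s}
#' since a single admixture pulse, and compares its likelihood to the
#' neutral one-pulse model.  Both likelihoods are computed on the same
#' window of sites around the focal site with the ancestry-dosage HMM;
#' the selection model distorts the ancestry-transition rates through
#' the trajectory of the selected allele and the hitchhiking of linked
#' ancestry.  In \code{"gss"} mode the selection coefficient is
#' optimized per site by golden-section search; in \code{"grid"} mode
#' the likelihood ratio is evaluated for a fixed set of s values.
#'
#' @param data An \code{"ai_counts"} object for a single chromosome (see
#'   [read_counts_file()] or [simulate_dataset()]).
#' @param Ne,m,t One-pulse demography: effective size of the admixed
#'   population, admixture fraction of donor ancestry, generations since
#'   the pulse.  These are inputs (estimated upstream), not estimated
#'   here.
#' @param mode \code{"gss"} (optimize s per site) or \code{"grid"}.
#' @param s_bounds Search bounds for s in gss mode (the search is
#'   log-spaced; defaults to 0.001-0.15).
#' @param s_grid Values of s evaluated in grid mode.
#' @param stride Evaluate every stride-th site.
#' @param sites Optional explicit site indices to evaluate (overrides
#'   \code{stride}).
#' @param window Window half-width as a fraction of the chromosome's
#'   genetic length (default 0.1, i.e. 10% of the chromosome on each
#'   side of the focal site).
#' @param window_morgans Window half-width in Morgans (overrides
#'   \code{window}).
#' @param backend Transition-rate computation: \code{"fourpoint"}
#'   (parametric approximation, default) or \code{"forward"} (tabulated
#'   forward iteration; slower, same contract).
#' @param error Per-allele read error rate for the emission model.
#' @param em An [emission_model()]; overrides \code{error}.
#' @param trajectory Selected-allele trajectory method:
#'   \code{"logistic"} (deterministic, default) or \code{"stochastic"}
#'   (conditioned Wright-Fisher average; for very small m).
#' @param traj_reps Replicates for the stochastic trajectory.
#' @param min_informative Minimum number of informative sites (nonzero
#'   depth) required in a window; sites failing this are flagged and get
#'   \code{NA} results.
#' @param gss_tol Relative tolerance on s for the golden-section search.
#'
#' @return An object of class \code{"aiscan"}: a list with
#'   \code{results} (data frame with one row per evaluated site: chrom,
#'   pos_bp, gpos, s_hat, lr, flag), \code{grid} (grid mode only: long
#'   data frame site x s), and \code{config}.  Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{plot}; see [find_peaks()] for
#'   calibrated peak calling.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(demography(5000, 0.1, 100),
#'                         selected_s = 0.1, n_sites = 400, n_ind = 10,
#'                         seed = 1)
#' fit <- aiscan(sim, Ne = 5000, m = 0.1, t = 100, stride = 40)
#' coef(fit)
#' }
#' @export
aiscan <- function(data, Ne, m, t,
                   mode = c("gss", "grid"),
                   s_bounds = c(0.001, 0.15), s_grid = NULL,
                   stride = 1L, sites = NULL,
                   window = 0.1, window_morgans = NULL,
                   backend = c("fourpoint", "forward"),
                   error = 0.01, em = NULL,
                   trajectory = c("logistic", "stochastic"),
                   traj_reps = 1000,
                   min_informative = 10, gss_tol = 1e-2) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  trajectory <- match.arg(trajectory)
  dem <- demography(Ne, m, t)
  stopifnot(inherits(data, "ai_counts"))
  if (length(unique(data$sites$chrom)) != 1)
    stop("aiscan expects a single chromosome; subset the data first")
  if (mode == "grid" && is.null(s_grid))
    stop("grid mode requires s_grid")
  stopifnot(s_bounds[1] > 0, s_bounds[1] < s_bounds[2], s_bounds[2] < 1)

  if (is.null(em)) em <- emission_model(data$mode, error = error)
  eng <- scan_engine(data, dem, em, window, window_morgans, backend,
                     trajectory, traj_reps, min_informative)

  n <- nrow(data$sites)
  eval_sites <- if (!is.null(sites)) sort(unique(as.integer(sites)))
                else seq(1L, n, by = as.integer(stride))

  res <- data.frame(chrom = data$sites$chrom[eval_sites],
                    pos_bp = data$sites$pos_bp[eval_sites],
                    gpos = data$sites$gpos[eval_sites],
                    s_hat = NA_real_, lr = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  grid_out <- NULL
  if (mode == "grid") {
    grid_out <- expand.grid(site = eval_sites, s = s_grid,
                            KEEP.OUT.ATTRS = FALSE)
    grid_out$chrom <- data$sites$chrom[grid_out$site]
    grid_out$pos_bp <- data$sites$pos_bp[grid_out$site]
    grid_out$gpos <- data$sites$gpos[grid_out$site]
    grid_out$lr <- NA_real_
    grid_out$flag <- ""
    for (k in seq_along(s_grid)) {
      crv <- eng$curve_for(s_grid[k])
      for (i in seq_along(eval_sites)) {
        w <- eng$window_of(eval_sites[i])
        if (!w$ok) {
          grid_out$flag[grid_out$site == eval_sites[i]] <- w$flag
          next
        }
        lr <- eng$window_lr(w, crv)
        grid_out$lr[grid_out$site == eval_sites[i] &
                    grid_out$s == s_grid[k]] <- lr
      }
    }
    for (i in seq_along(eval_sites)) {
      rows <- grid_out[grid_out$site == eval_sites[i], ]
      if (all(is.na(rows$lr))) { res$flag[i] <- rows$flag[1]; next }
      best <- which.max(rows$lr)
      res$s_hat[i] <- rows$s[best]
      res$lr[i] <- rows$lr[best]
      res$flag[i] <- rows$flag[best]
    }
    grid_out <- grid_out[, c("chrom", "pos_bp", "gpos", "site", "s", "lr", "flag")]
  } else {
    for (i in seq_along(eval_sites)) {
      o <- eng$site_gss(eval_sites[i], s_bounds, gss_tol)
      res$s_hat[i] <- o$s_hat
      res$lr[i] <- o$lr
      res$flag[i] <- o$flag
    }
  }

  structure(list(results = res, grid = grid_out,
                 config = list(dem = dem, mode = mode, backend = backend,
                               s_bounds = s_bounds, s_grid = s_grid,
                               window = window,
                               window_M = eng$window_M,
                               stride = as.integer(stride),
                               trajectory = trajectory, em = em,
                               min_informative = min_informative,
                               seed = NULL),
                 samples = data$samples, n_sites = n,
                 call = match.call()),
            class = "aiscan")
}

# Shared machinery for the per-site likelihood-ratio computations: window
# resolution, cached emissions, cached neutral log-likelihoods.
scan_engine <- function(data, dem, em, window, window_morgans, backend,
                        trajectory = "logistic", traj_reps = 1000,
                        min_informative = 10) {
  emissions <- compute_emissions(data, em)
  gpos <- data$sites$gpos
  chrom_len <- max(gpos) - min(gpos)
  window_M <- if (!is.null(window_morgans)) window_morgans
              else window * chrom_len
  depth <- rowSums(data$obs_A, na.rm = TRUE) + rowSums(data$obs_a, na.rm = TRUE)
  informative <- if (data$mode == "pileup") depth > 0
                 else rowSums(!is.na(data$obs_A)) > 0
  groups <- lapply(unique(data$samples$ploidy), function(pl)
    list(pl = pl, idx = which(data$samples$ploidy == pl),
         init = dbinom(0:pl, pl, dem$m)))
  curve0 <- neutral_curve(dem)
  neutral_cache <- new.env(parent = emptyenv())

  traj_for <- function(s) {
    if (trajectory == "stochastic")
      stochastic_trajectory(dem, s, n_reps = traj_reps)
    else logistic_trajectory(dem, s)
  }
  curve_for <- function(s) {
    if (backend == "fourpoint") four_point_fit(dem, s, traj = traj_for(s))
    else forward_transition_rates(dem, s, traj = traj_for(s),
                                  r_max = window_M + 1e-3)
  }

  window_of <- function(j) {
    key <- as.character(j)
    if (!is.null(neutral_cache[[key]])) return(neutral_cache[[key]])
    gj <- gpos[j]
    W <- which(gpos >= gj - window_M & gpos <= gj + window_M)
    flag <- character()
    if (gj - window_M < min(gpos) || gj + window_M > max(gpos))
      flag <- "truncated_window"
    out <- if (sum(informative[W]) < min_informative) {
      list(ok = FALSE, flag = paste(c(flag, "too_few_sites"),
                                    collapse = ","))
    } else {
      Ew <- lapply(emissions, function(E) E[W, , drop = FALSE])
      g <- gpos[W]
      list(ok = TRUE, j = j, W = W, Ew = Ew, g = g, gj = gj,
           ll0 = chain_loglik(Ew, g, gj, curve0, groups),
           flag = paste(flag, collapse = ","))
    }
    neutral_cache[[key]] <- out
    out
  }

  chain_loglik <- function(Ew, g, gj, curve, groups) {
    d <- diff(g)
    r_mid <- abs((g[-1] + g[-length(g)]) / 2 - gj)
    uv <- interval_switch_probs(curve, r_mid, d)
    ll <- 0
    for (grp in groups)
      ll <- ll + cpp_forward_loglik(Ew[grp$idx], uv$u, uv$v, grp$pl, grp$init)
    ll
  }

  window_lr <- function(w, curve) {
    chain_loglik(w$Ew, w$g, w$gj, curve, groups) - w$ll0
  }

  site_lr <- function(j, s) {
    w <- window_of(j)
    if (!w$ok) return(list(lr = NA_real_, flag = w$flag))
    crv <- curve_for(s)
    flag <- w$flag
    if (isTRUE(crv$fixation))
      flag <- paste(c(flag[nzchar(flag)], "fixation"), collapse = ",")
    list(lr = window_lr(w, crv), flag = flag)
  }

  site_gss <- function(j, s_bounds, tol) {
    w <- window_of(j)
    if (!w$ok)
      return(list(s_hat = NA_real_, lr = NA_real_, flag = w$flag))
    fixation <- FALSE
    f <- function(ls) {
      crv <- curve_for(exp(ls))
      if (isTRUE(crv$fixation)) fixation <<- TRUE
      lr <- window_lr(w, crv)
      if (!is.finite(lr)) -Inf else lr
    }
    o <- golden_max(f, log(s_bounds[1]), log(s_bounds[2]), tol = tol)
    flags <- w$flag[nzchar(w$flag)]
    if (o$x >= log(s_bounds[2]) - 2 * tol) flags <- c(flags, "boundary_hi")
    if (o$x <= log(s_bounds[1]) + 2 * tol) flags <- c(flags, "boundary_lo")
    if (fixation) flags <- c(flags, "fixation")
    list(s_hat = exp(o$x), lr = o$f, flag = paste(flags, collapse = ","))
  }

  list(window_of = window_of, window_lr = window_lr, site_lr = site_lr,
       site_gss = site_gss, curve_for = curve_for, window_M = window_M,
       groups = groups, gpos = gpos)
}

# golden-section maximization of f on [a, b]; derivative-free, assumes a
# unimodal objective, tolerance on x
golden_max <- function(f, a, b, tol = 1e-2) {
  gr <- (sqrt(5) - 1) / 2
  c1 <- b - gr * (b - a)
  d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (!is.finite(fc) && !is.finite(fd)) { b <- d1 }
    else if (fc >= fd) { b <- d1 }
    else { a <- c1 }
    c1 <- b - gr * (b - a)
    d1 <- a + gr * (b - a)
    fc <- f(c1); fd <- f(d1)
  }
  xs <- c(c1, d1)
  fs <- c(fc, fd)
  best <- which.max(fs)
  list(x = xs[best], f = fs[best])
}

#' Per-site likelihood ratio at a fixed selection coefficient
#'
#' Log-likelihood of the windowed data under selection \code{s} at the
#' focal site minus that under the neutral model, both on the same
#' window.
#'
#' @inheritParams aiscan
#' @param site Focal site index.
#' @param s Selection coefficient.
#' @param ... Passed to the scan configuration (window, backend,
#'   emission model).
#' @return A list with \code{lr} and \code{flag}.
#' @export
site_likelihood_ratio <- function(data, site, s, Ne, m, t,
                                  window = 0.1, window_morgans = NULL,
                                  backend = "fourpoint", error = 0.01,
                                  em = NULL, min_informative = 10) {
  dem <- demography(Ne, m, t)
  if (is.null(em)) em <- emission_model(data$mode, error = error)
  eng <- scan_engine(data, dem, em, window, window_morgans, backend,
                     min_informative = min_informative)
  eng$site_lr(site, s)
}

#' Golden-section optimization of the selection coefficient at one site
#'
#' @inheritParams site_likelihood_ratio
#' @param s_bounds Search interval for s.
#' @param gss_tol Relative tolerance on s.
#' @return A list with \code{s_hat}, \code{lr} and \code{flag} (which
#'   notes boundary maxima and the fixation regime).
#' @export
golden_section_optimize <- function(data, site, Ne, m, t,
                                    s_bounds = c(0.001, 0.15),
                                    gss_tol = 1e-2,
                                    window = 0.1, window_morgans = NULL,
                                    backend = "fourpoint", error = 0.01,
                                    em = NULL, min_informative = 10) {
  dem <- demography(Ne, m, t)
  if (is.null(em)) em <- emission_model(data$mode, error = error)
  eng <- scan_engine(data, dem, em, window, window_morgans, backend,
                     min_informative = min_informative)
  eng$site_gss(site, s_bounds, gss_tol)
}

#' @export
print.aiscan <- function(x, ...) {
  r <- x$results
  ok <- is.finite(r$lr)
  cat(sprintf("Adaptive-introgression scan (%s, %s backend): %d/%d sites evaluated\n",
              x$config$mode, x$config$backend, sum(ok), nrow(r)))
  print(x$config$dem)
  if (any(ok)) {
    b <- which.max(r$lr)
    cat(sprintf("Top site: %s:%d  LR = %.2f  s_hat = %.4g%s\n",
                r$chrom[b], r$pos_bp[b], r$lr[b], r$s_hat[b],
                if (nzchar(r$flag[b])) paste0("  [", r$flag[b], "]") else ""))
  }
  invisible(x)
}

#' @export
summary.aiscan <- function(object, threshold = NULL, min_sep_cM = 2, ...) {
  r <- object$results
  out <- list(config = object$config,
              n_eval = sum(is.finite(r$lr)),
              n_total = nrow(r),
              top = r[order(-r$lr), ][seq_len(min(5, nrow(r))), ],
              peaks = if (!is.null(threshold))
                find_peaks(object, threshold, min_sep_cM))
  class(out) <- "summary.aiscan"
  out
}

#' @export
print.summary.aiscan <- function(x, ...) {
  cat(sprintf("Scan of %d sites (%d evaluated), mode %s\n",
              x$n_total, x$n_eval, x$config$mode))
  cat("Top sites by likelihood ratio:\n")
  print(x$top, row.names = FALSE)
  if (!is.null(x$peaks)) {
    cat("Peaks:\n")
    print(x$peaks, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.aiscan <- function(object, ...) {
  r <- object$results
  if (!any(is.finite(r$lr))) return(c(s = NA_real_))
  b <- which.max(r$lr)
  c(s = r$s_hat[b])
}

#' @export
plot.aiscan <- function(x, ...) {
  r <- x$results
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(r$pos_bp, r$lr, type = "b", pch = 16, cex = 0.6,
                 xlab = "", ylab = "log likelihood ratio", ...)
  graphics::plot(r$pos_bp, r$s_hat, type = "b", pch = 16, cex = 0.6,
                 xlab = "position (bp)", ylab = "estimated s", ...)
  invisible(x)
}

#' Greedy peak calling on a scan result
#'
#' Selects candidate selected sites by descending likelihood ratio: a
#' site becomes a peak iff its LR is at least \code{threshold} and it
#' lies at least \code{min_sep_cM} centimorgans from every
#' already-accepted (higher) peak.  Ties in LR are broken by leftmost
#' position.
#'
#' @param x An \code{"aiscan"} object (or its \code{results} data
#'   frame with columns gpos, pos_bp, lr, s_hat).
#' @param threshold LR threshold (see [null_threshold()] for
#'   calibration against neutral simulations).
#' @param min_sep_cM Minimum genetic separation between peaks.
#' @param data Optional \code{"ai_counts"} object; when supplied, the
#'   posterior donor frequency at each peak is added (forward-backward
#'   under the fitted selection model).
#' @param Ne,m,t Demography for the posterior computation (defaults to
#'   the scan's).
#' @return Data frame of peaks: chrom, pos_bp, gpos, s_hat, lr (and
#'   freq when \code{data} is given).
#' @export
find_peaks <- function(x, threshold, min_sep_cM = 2, data = NULL,
                       Ne = NULL, m = NULL, t = NULL) {
  r <- if (inherits(x, "aiscan")) x$results else x
  r <- r[is.finite(r$lr), , drop = FALSE]
  r <- r[order(-r$lr, r$gpos), , drop = FALSE]
  sep_M <- min_sep_cM / 100
  acc <- integer()
  for (i in seq_len(nrow(r))) {
    if (r$lr[i] < threshold) break
    if (!length(acc) ||
        all(abs(r$gpos[acc] - r$gpos[i]) >= sep_M * (1 - 1e-9)))
      acc <- c(acc, i)
  }
  pk <- r[acc, , drop = FALSE]
  pk <- pk[order(pk$gpos), , drop = FALSE]
  rownames(pk) <- NULL
  if (!is.null(data) && nrow(pk)) {
    cfg <- if (inherits(x, "aiscan")) x$config else NULL
    dem <- if (!is.null(Ne)) demography(Ne, m, t) else cfg$dem
    pk$freq <- vapply(seq_len(nrow(pk)), function(i) {
      j <- which(data$sites$pos_bp == pk$pos_bp[i] &
                 data$sites$chrom == pk$chrom[i])[1]
      h <- hmm_instance(data, dem, s = max(pk$s_hat[i], 1e-4, na.rm = TRUE),
                        focal = j)
      posterior_dosage(h)$freq[j]
    }, numeric(1))
  }
  pk
}

#' Likelihood-ratio threshold from neutral simulations
#'
#' Given scans of replicate neutral simulations with demography matching
#' the data set of interest, finds the smallest LR threshold at which
#' the expected number of (proximity-filtered) peaks per genome does not
#' exceed \code{target} false discoveries.  Linkage makes analytic
#' per-site cutoffs unreliable; calibration by neutral simulation is the
#' supported route to significance.
#'
#' @param scans A list of at least 10 \code{"aiscan"} objects (or their
#'   results data frames) from neutral-scenario simulations.
#' @param min_sep_cM Peak separation used for filtering (match the
#'   value used for the real scan).
#' @param target Tolerated mean false discoveries per genome.
#' @param genome_factor Ratio of genome genetic length to the simulated
#'   chromosome's (1 when one replicate represents the full genome).
#' @return A list of class \code{"ai_null"}: \code{threshold}, its
#'   bootstrap standard error \code{se}, \code{n_reps}, \code{target}.
#' @export
null_threshold <- function(scans, min_sep_cM = 2, target = 1,
                           genome_factor = 1) {
  if (length(scans) < 10)
    stop("at least 10 neutral replicate scans are needed for a usable ",
         "threshold; got ", length(scans),
         ". Run more neutral simulations.")
  peak_lrs <- lapply(scans, function(s)
    find_peaks(s, threshold = -Inf, min_sep_cM = min_sep_cM)$lr)
  R <- length(scans)
  thr_from <- function(lrs_list) {
    pooled <- sort(unlist(lrs_list), decreasing = TRUE)
    K <- floor(target * length(lrs_list) / genome_factor)
    if (K < 1) return(if (length(pooled)) pooled[1] + 1 else 1)
    if (K >= length(pooled)) return(min(pooled))
    pooled[K]
  }
  thr <- thr_from(peak_lrs)
  boot <- replicate(200, thr_from(peak_lrs[sample.int(R, R, replace = TRUE)]))
  structure(list(threshold = thr, se = sd(boot), n_reps = R,
                 target = target, genome_factor = genome_factor),
            class = "ai_null")
}

#' @export
print.ai_null <- function(x, ...) {
  cat(sprintf("Neutral LR threshold: %.3f (bootstrap se %.3f) for <= %g false discoveries per genome, from %d replicates\n",
              x$threshold, x$se, x$target, x$n_reps))
  invisible(x)
}
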