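#' Selection scenario for the admixture simulator
#'
#' @param selected Data frame of selected sites with columns \code{pos}
#'   (Morgans), \code{s} (per-copy selection coefficient; a heterozygote
#'   experiences half the homozygote's advantage) and optionally
#'   \code{h} (dominance: 0 recessive, 0.5 additive (default), 1
#'   dominant).  \code{NULL} for a neutral scenario.
#' @param start_freq Frequency of the selected allele among donor
#'   chromosomes at the pulse (1 = fixed in the donor; 0.5 = segregating
#'   at 50%).
#' @param dmi Optional two-locus incompatibility: a list with
#'   \code{pos} (length 2, Morgans), \code{s} (interaction coefficient,
#'   < 0 deleterious) and \code{mode}: \code{"dominant"} (any
#'   cross-population allele combination at the two loci is selected
#'   against; dominant sign epistasis) or \code{"one_directional"}
#'   (only the recipient-at-A with donor-at-B combination is).
#' @param pulse_rate,pulse_gens Continuous gene flow after the initial
#'   pulse: per-generation migrant fraction and its duration in
#'   generations (0 = single pulse).
#' @return An object of class \code{"ai_scenario"}.
#' @export
scenario <- function(selected = NULL, start_freq = 1, dmi = NULL,
                     pulse_rate = 0, pulse_gens = 0) {
  if (!is.null(selected)) {
    selected <- as.data.frame(selected)
    if (is.null(selected$h)) selected$h <- 0.5
    stopifnot(all(abs(selected$s) < 1), all(selected$h >= 0 & selected$h <= 1))
  }
  if (!is.null(dmi)) {
    stopifnot(length(dmi$pos) == 2, abs(dmi$s) < 1)
    dmi$mode <- match.arg(dmi$mode, c("dominant", "one_directional"))
  }
  stopifnot(start_freq > 0, start_freq <= 1,
            pulse_rate >= 0, pulse_rate < 1, pulse_gens >= 0)
  structure(list(selected = selected, start_freq = start_freq, dmi = dmi,
                 pulse_rate = pulse_rate, pulse_gens = pulse_gens),
            class = "ai_scenario")
}

#' Forward Wright-Fisher admixture simulation with tract recording
#'
#' Simulates a diploid admixed population forward in time from a single
#' admixture pulse (optionally followed by continuous gene flow), with
#' selection on introgressed alleles, recording exact ancestry tracts on
#' a chromosome of \code{L_M} Morgans.  Meiosis places Poisson(L_M)
#' crossovers uniformly (no interference); parents are sampled with
#' probability proportional to fitness.  Fitness is multiplicative over
#' loci with per-locus factors 1, 1 + 2sh, 1 + 2s for dosages 0, 1, 2
#' (h = 0.5 is additive: the heterozygote carries half the homozygote's
#' advantage), times the incompatibility penalty for DMI scenarios.
#'
#' @param dem An [demography()] object; the census size of the simulated
#'   population is \code{dem$Ne} diploids.
#' @param scn An [scenario()] object.
#' @param L_M Chromosome length in Morgans.
#' @param n_sample Individuals sampled at the end.
#' @param stop_freq Optional early-stop frequency for the first selected
#'   locus (e.g. 0.99); by default the simulation runs the full t
#'   generations and replicates that cross 0.99 are only flagged.
#' @param condition Restart the simulation (up to \code{max_retries}
#'   times) if the first selected allele is lost by generation t; used
#'   for small-pulse scenarios.
#' @param max_retries Retry cap for conditioned runs.
#' @param seed Optional RNG seed (\code{set.seed}).
#' @return An object of class \code{"ai_population"}: sampled
#'   chromosomes as tract lists, the per-generation allele-frequency
#'   trajectory at each tracked locus, the genome-wide donor fraction,
#'   and bookkeeping fields.
#' @export
simulate_admixture <- function(dem, scn = scenario(), L_M = 1,
                               n_sample = 25, stop_freq = NULL,
                               condition = FALSE, max_retries = 100,
                               seed = NULL) {
  dem <- as_demography(dem)
  stopifnot(inherits(scn, "ai_scenario"), L_M > 0, n_sample >= 1)
  if (!is.null(seed)) set.seed(seed)

  sel <- scn$selected
  loci_pos <- if (!is.null(sel)) sel$pos else numeric()
  loci_s <- if (!is.null(sel)) sel$s else numeric()
  loci_h <- if (!is.null(sel)) sel$h else numeric()
  start <- rep(scn$start_freq, length(loci_pos))
  dmi_mode <- 0L; dmi_a <- 0L; dmi_b <- 0L; dmi_s <- 0
  if (!is.null(scn$dmi)) {
    dmi_a <- length(loci_pos)       # 0-based index of first DMI locus
    dmi_b <- dmi_a + 1L
    loci_pos <- c(loci_pos, scn$dmi$pos)
    loci_s <- c(loci_s, 0, 0)
    loci_h <- c(loci_h, 0.5, 0.5)
    start <- c(start, 1, 1)
    dmi_mode <- if (scn$dmi$mode == "dominant") 1L else 2L
    dmi_s <- scn$dmi$s
  }
  if (length(loci_pos)) stopifnot(all(loci_pos >= 0 & loci_pos <= L_M))

  for (try in seq_len(max(1, max_retries))) {
    raw <- cpp_wf_simulate(as.integer(dem$Ne), dem$m, dem$t, L_M,
                           loci_pos, loci_s, loci_h, start,
                           dmi_mode, dmi_a, dmi_b, dmi_s,
                           scn$pulse_rate, as.integer(scn$pulse_gens),
                           if (is.null(stop_freq)) 1.0 else stop_freq,
                           as.integer(n_sample))
    lost <- length(loci_pos) > 0 &&
      raw$trajectory[nrow(raw$trajectory), 1] == 0
    if (!condition || !lost) break
    if (try == max_retries)
      stop("selected allele lost in all ", max_retries,
           " conditioned replicates")
  }

  traj <- raw$trajectory
  colnames(traj) <- if (length(loci_pos)) paste0("locus", seq_along(loci_pos))
  structure(list(chromosomes = raw$chromosomes, trajectory = traj,
                 loci = data.frame(pos = loci_pos, s = loci_s, h = loci_h),
                 dmi = scn$dmi, L_M = L_M, dem = dem, scenario = scn,
                 n_sample = as.integer(n_sample),
                 stopped_at = raw$stopped_at,
                 stopped_early = raw$stopped_early,
                 fixation = length(loci_pos) > 0 &&
                   max(traj[, 1]) >= 0.99,
                 donor_fraction = raw$donor_fraction),
            class = "ai_population")
}

#' @export
print.ai_population <- function(x, ...) {
  cat(sprintf("Simulated admixed population: %d sampled diploids, %g Morgan chromosome, t = %d\n",
              x$n_sample, x$L_M, x$dem$t))
  cat(sprintf("  genome-wide donor fraction %.4f", x$donor_fraction))
  if (nrow(x$loci))
    cat(sprintf("; focal allele frequency %.4f%s",
                x$trajectory[nrow(x$trajectory), 1],
                if (x$fixation) " [>= 0.99: fixation regime]" else ""))
  cat("\n")
  invisible(x)
}

#' Ancestry of sampled chromosomes at given positions
#'
#' @param pop An \code{"ai_population"}.
#' @param positions Positions in Morgans.
#' @return Integer matrix (chromosomes x positions) of ancestries
#'   (0 recipient, 1 donor).
#' @export
tract_ancestry <- function(pop, positions) {
  stopifnot(inherits(pop, "ai_population"))
  out <- matrix(0L, length(pop$chromosomes), length(positions))
  for (i in seq_along(pop$chromosomes)) {
    ch <- pop$chromosomes[[i]]
    n_br <- findInterval(positions, ch$breaks)
    out[i, ] <- bitwXor(ch$anc0, n_br %% 2L)
  }
  out
}

#' Synthesize reference panels and admixed haplotypes
#'
#' Places \code{n_sites} variable sites uniformly on the map, draws an
#' ancestral allele frequency per site from a neutral-SFS-like density
#' (proportional to 1/x), disperses the two ancestral population
#' frequencies around it with a Balding-Nichols model parameterized by a
#' single divergence scalar, samples finite reference panels
#' binomially, and fills each sampled chromosome's alleles according to
#' its local ancestry.  This emulates the marginal ancestry
#' informativeness of panels simulated under a full demographic
#' coalescent without reimplementing one.
#'
#' @param pop An \code{"ai_population"}.
#' @param n_sites Number of variable sites (>= 100).
#' @param divergence Fst-like dispersion of the two population
#'   frequencies around the ancestral frequency, in (0, 1).
#' @param panel_size Haplotypes sampled per reference panel.
#' @param bp_per_morgan Physical scale of the map (bp per Morgan).
#' @param chrom Chromosome label.
#' @return A list: \code{sites} (data frame with positions, genetic
#'   distances and panel counts), \code{haps} (chromosome x site allele
#'   matrix), \code{anc} (chromosome x site ancestry matrix),
#'   \code{freqs} (per-population allele frequencies).
#' @export
synthesize_panels <- function(pop, n_sites = 2000, divergence = 0.2,
                              panel_size = 100, bp_per_morgan = 1e7,
                              chrom = "chr1") {
  stopifnot(inherits(pop, "ai_population"), n_sites >= 100,
            divergence > 0, divergence < 1, panel_size >= 10)
  pos_bp <- sort(unique(1L + as.integer(floor(runif(n_sites) *
                                              (pop$L_M * bp_per_morgan - 1)))))
  gpos <- pos_bp / bp_per_morgan
  ns <- length(pos_bp)

  x <- exp(runif(ns, log(0.05), log(0.95)))      # density ~ 1/x
  shp <- (1 - divergence) / divergence
  p0 <- rbeta(ns, x * shp, (1 - x) * shp)
  p1 <- rbeta(ns, x * shp, (1 - x) * shp)
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
  p1 <- pmin(pmax(p1, 1e-4), 1 - 1e-4)

  p0A <- rbinom(ns, panel_size, p0)
  p1A <- rbinom(ns, panel_size, p1)

  anc <- tract_ancestry(pop, gpos)
  haps <- matrix(0L, nrow(anc), ns)
  for (i in seq_len(nrow(anc))) {
    pr <- ifelse(anc[i, ] == 1L, p1, p0)
    haps[i, ] <- rbinom(ns, 1L, pr)
  }

  sites <- data.frame(chrom = chrom, pos_bp = pos_bp,
                      dist_M = c(0, diff(gpos)),
                      p0A = p0A, p0a = panel_size - p0A,
                      p1A = p1A, p1a = panel_size - p1A,
                      stringsAsFactors = FALSE)
  list(sites = sites, haps = haps, anc = anc,
       freqs = data.frame(p0 = p0, p1 = p1))
}

#' Simulate short-read or genotype observations
#'
#' Per individual and site, draws a Poisson read depth and samples each
#' read's allele from the individual's allele dosage with a per-allele
#' error rate; pooled mode merges all chromosomes into one observation
#' column.  Genotype mode records the true allele dosage directly.
#'
#' @param haps Chromosome x site allele matrix (from
#'   [synthesize_panels()]).
#' @param ploidy Chromosomes per individual (consecutive rows of
#'   \code{haps} are grouped into individuals).
#' @param depth_mean Mean sequencing depth per individual per site.
#' @param error Per-allele read error rate.
#' @param pooled Merge all individuals' reads into one column.
#' @param mode \code{"pileup"} or \code{"genotype"}.
#' @return A list with matrices \code{obs_A}, \code{obs_a} (site x
#'   sample) and the vector of sample \code{ploidies}.
#' @export
simulate_reads <- function(haps, ploidy = 2, depth_mean = 2,
                           error = 0.01, pooled = FALSE,
                           mode = c("pileup", "genotype")) {
  mode <- match.arg(mode)
  n_chr <- nrow(haps)
  ns <- ncol(haps)
  stopifnot(n_chr %% ploidy == 0)
  n_ind <- n_chr / ploidy
  grp <- rep(seq_len(n_ind), each = ploidy)
  G <- t(rowsum(haps, grp))               # site x individual dosage of allele A
  if (mode == "genotype") {
    obs_A <- G
    obs_a <- ploidy - G
  } else {
    depth <- matrix(rpois(ns * n_ind, depth_mean), ns, n_ind)
    phi <- G / ploidy * (1 - error) + (1 - G / ploidy) * error
    obs_A <- matrix(rbinom(ns * n_ind, depth, phi), ns, n_ind)
    obs_a <- depth - obs_A
  }
  if (pooled) {
    obs_A <- matrix(rowSums(obs_A), ncol = 1)
    obs_a <- matrix(rowSums(obs_a), ncol = 1)
    if (mode == "genotype") stop("pooled genotype mode is not defined")
    return(list(obs_A = obs_A, obs_a = obs_a, ploidies = n_chr))
  }
  list(obs_A = obs_A, obs_a = obs_a, ploidies = rep(ploidy, n_ind))
}

#' One-call synthetic data set
#'
#' Runs [simulate_admixture()], [synthesize_panels()] and
#' [simulate_reads()] and assembles an \code{"ai_counts"} object ready
#' for [aiscan()], with the simulation truth attached as attribute
#' \code{"truth"} (trajectory, selected-locus positions in bp, sampled
#' tract ancestries).
#'
#' @inheritParams simulate_admixture
#' @inheritParams synthesize_panels
#' @inheritParams simulate_reads
#' @param selected_s Convenience: selection coefficient of a single
#'   selected site at map position \code{selected_pos} (ignored when a
#'   full \code{scn} is given).
#' @param selected_pos Map position (Morgans) of the convenience
#'   selected site.
#' @param n_ind Number of individuals sampled.
#' @return An \code{"ai_counts"} object with attribute \code{"truth"}.
#' @export
simulate_dataset <- function(dem, selected_s = 0, selected_pos = 0.5,
                             scn = NULL, L_M = 1, n_sites = 2000,
                             n_ind = 25, ploidy = 2, depth_mean = 2,
                             error = 0.01, divergence = 0.2,
                             panel_size = 100, bp_per_morgan = 1e7,
                             pooled = FALSE, mode = c("pileup", "genotype"),
                             condition = FALSE, stop_freq = NULL,
                             seed = NULL, chrom = "chr1") {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scn)) {
    scn <- if (selected_s != 0)
      scenario(selected = data.frame(pos = selected_pos * L_M,
                                     s = selected_s))
    else scenario(selected = data.frame(pos = selected_pos * L_M, s = 0))
  }
  pop <- simulate_admixture(dem, scn, L_M = L_M,
                            n_sample = n_ind * ploidy / 2,
                            condition = condition, stop_freq = stop_freq)
  pan <- synthesize_panels(pop, n_sites = n_sites, divergence = divergence,
                           panel_size = panel_size,
                           bp_per_morgan = bp_per_morgan, chrom = chrom)
  rd <- simulate_reads(pan$haps, ploidy = ploidy, depth_mean = depth_mean,
                       error = error, pooled = pooled, mode = mode)
  samples <- data.frame(id = paste0(if (pooled) "pool" else "ind",
                                    seq_along(rd$ploidies)),
                        ploidy = rd$ploidies, stringsAsFactors = FALSE)
  out <- new_counts(pan$sites, rd$obs_A, rd$obs_a, samples,
                    mode = mode, pooled = pooled)
  truth <- list(trajectory = pop$trajectory,
                loci = pop$loci, dmi = pop$dmi,
                loci_bp = round(pop$loci$pos * bp_per_morgan),
                anc = pan$anc, L_M = L_M, bp_per_morgan = bp_per_morgan,
                fixation = pop$fixation,
                donor_fraction = pop$donor_fraction)
  attr(out, "truth") <- truth
  out
}

#' Swap ancestry labels
#'
#' Exchanges the two reference panels and replaces the admixture
#' fraction m by 1 - m, so that negative selection on donor ancestry can
#' be detected as positive selection on the (relabeled) recipient
#' ancestry.  Applying the flip twice is the identity.
#'
#' @param data An \code{"ai_counts"} object.
#' @param dem An [demography()] object.
#' @return A list with the flipped \code{data} and \code{dem}.
#' @export
flip_labels <- function(data, dem) {
  stopifnot(inherits(data, "ai_counts"))
  dem <- as_demography(dem)
  s <- data$sites
  sites <- s
  sites$p0A <- s$p1A; sites$p0a <- s$p1a
  sites$p1A <- s$p0A; sites$p1a <- s$p0a
  flipped <- new_counts(sites[, setdiff(names(sites), "gpos")],
                        data$obs_A, data$obs_a, data$samples,
                        data$mode, data$pooled)
  attr(flipped, "truth") <- attr(data, "truth")
  list(data = flipped, dem = demography(dem$Ne, 1 - dem$m, dem$t))
}
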