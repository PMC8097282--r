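#' Convert a VCF plus panel assignment to a site-count object
#'
#' Convenience importer for jointly genotyped data: biallelic SNPs are
#' read from a VCF, reference-panel allele counts are tallied from the
#' panel samples' genotypes, and the admixed samples' called dosages
#' become genotype-mode observations.  Allele A is the VCF REF allele.
#' Requires the vcfR package.
#'
#' The VCF carries no genetic map; supply either a constant
#' recombination rate per bp (\code{rate_per_bp}) or a function mapping
#' physical positions to cumulative Morgans (\code{map_fun}).
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param panel0,panel1 Character vectors of sample names forming the
#'   recipient (ancestry 0) and donor (ancestry 1) reference panels.
#' @param samples Character vector of admixed sample names to keep as
#'   observations.
#' @param ploidies Integer vector of their ploidies (recycled if length
#'   1).
#' @param rate_per_bp Constant recombination rate (Morgans per bp).
#' @param map_fun Optional function: positions (bp) -> cumulative
#'   Morgans; overrides \code{rate_per_bp}.
#' @return An \code{"ai_counts"} object in genotype mode.
#' @export
vcf_to_counts <- function(path, panel0, panel1, samples,
                          ploidies = 2L, rate_per_bp = 1e-8,
                          map_fun = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcf_to_counts() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])

  need <- c(panel0, panel1, samples)
  missing <- setdiff(need, colnames(gt))
  if (length(missing))
    stop("samples absent from VCF: ", paste(missing, collapse = ", "))

  # count REF (allele A) and ALT alleles in a genotype string matrix
  count_ref <- function(g) {
    alleles <- gsub("[|/]", "", g)
    nA <- nchar(gsub("[^0]", "", alleles))
    ntot <- nchar(gsub("[^0-9]", "", alleles))
    nA[is.na(g)] <- 0
    ntot[is.na(g)] <- 0
    list(A = nA, tot = ntot)
  }
  tally <- function(panel) {
    c0 <- count_ref(gt[, panel, drop = FALSE])
    list(A = rowSums(matrix(c0$A, nrow = nrow(gt))),
         tot = rowSums(matrix(c0$tot, nrow = nrow(gt))))
  }
  t0 <- tally(panel0)
  t1 <- tally(panel1)

  ploidies <- as.integer(rep(ploidies, length.out = length(samples)))
  obs <- count_ref(gt[, samples, drop = FALSE])
  obs_A <- matrix(obs$A, nrow = nrow(gt))
  obs_tot <- matrix(obs$tot, nrow = nrow(gt))
  # sites with missing or partial calls in a sample are uninformative there
  full <- sweep(obs_tot, 2, ploidies, "==")
  obs_A[!full] <- NA_integer_
  obs_a <- sweep(-obs_A, 2, ploidies, "+")
  colnames(obs_A) <- colnames(obs_a) <- samples

  ord <- order(chrom, pos)
  gpos <- if (!is.null(map_fun)) map_fun(pos[ord]) else pos[ord] * rate_per_bp
  dist_M <- stats::ave(gpos, chrom[ord], FUN = function(g) c(0, diff(g)))

  sites <- data.frame(chrom = chrom[ord], pos_bp = pos[ord],
                      dist_M = dist_M,
                      p0A = t0$A[ord], p0a = t0$tot[ord] - t0$A[ord],
                      p1A = t1$A[ord], p1a = t1$tot[ord] - t1$A[ord],
                      stringsAsFactors = FALSE)
  x <- new_counts(sites, obs_A[ord, , drop = FALSE],
                  obs_a[ord, , drop = FALSE],
                  data.frame(id = samples, ploidy = ploidies,
                             stringsAsFactors = FALSE),
                  mode = "genotype", pooled = FALSE)
  drop_empty_panel_sites(x)
}
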