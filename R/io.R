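#' Read a tab-separated site-count file
#'
#' Parses the package's count-file dialect.  Each row is one site with
#' columns: chromosome, physical position (1-based bp), allele-A and
#' allele-a counts in reference panel 0 (recipient), the same for panel 1
#' (donor), the genetic distance column, and then two observation columns
#' per sample.  In pileup mode the observation columns are read counts
#' (nA, na); in genotype mode they are the called dosage of allele A and
#' its complement (G, ploidy - G).
#'
#' The genetic distance column is interpreted either as Morgans to the
#' previous site (\code{distances = "morgans"}; 0 for the first site of a
#' chromosome) or as a per-bp recombination rate over the preceding
#' interval (\code{distances = "rate"}); both are normalized internally
#' to Morgans.
#'
#' Sites at which either reference panel has zero sampled alleles are
#' dropped (the emission mixture is undefined for a missing panel); the
#' number of dropped sites is reported with a message.
#'
#' @param path Path to the count file.
#' @param ploidies Integer vector of per-sample ploidies (1 = inbred or
#'   haploid, 2 = outbred diploid, n = a pool of n chromosomes), or the
#'   path to a ploidy file with one \code{id<TAB>ploidy} line per sample.
#' @param distances Interpretation of the genetic distance column.
#' @param mode Observation mode of the sample columns.
#' @param pooled Logical; a pooled data set has a single observation
#'   column whose ploidy is the number of pooled chromosomes.
#'
#' @return An object of class \code{"ai_counts"}: a list with elements
#'   \code{sites} (data frame: chrom, pos_bp, dist_M, gpos, p0A, p0a,
#'   p1A, p1a), \code{obs_A} and \code{obs_a} (site x sample integer
#'   matrices), \code{samples} (data frame: id, ploidy), \code{mode} and
#'   \code{pooled}.
#' @seealso [write_counts_file()], [read_ploidy_file()]
#' @export
read_counts_file <- function(path, ploidies,
                             distances = c("morgans", "rate"),
                             mode = c("pileup", "genotype"),
                             pooled = FALSE) {
  distances <- match.arg(distances)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (is.character(ploidies) && length(ploidies) == 1) {
    ps <- read_ploidy_file(ploidies)
    ids <- ps$id
    ploidies <- ps$ploidy
  } else {
    ids <- paste0("sample", seq_along(ploidies))
  }
  ploidies <- as.integer(ploidies)
  if (any(ploidies < 1)) stop("ploidies must be >= 1")
  if (pooled && length(ploidies) != 1)
    stop("pooled mode implies a single observation column")

  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  tab[[1]] <- as.character(tab[[1]])
  S <- length(ploidies)
  if (ncol(tab) != 7 + 2 * S)
    stop(sprintf("count file has %d columns; expected %d for %d sample(s)",
                 ncol(tab), 7 + 2 * S, S))

  chrom <- tab[[1]]
  pos <- tab[[2]]
  cnt <- as.matrix(tab[, 3:6])
  dist <- tab[[7]]
  if (any(!is.finite(pos)) || any(!is.finite(cnt)) || any(!is.finite(dist)))
    stop("non-numeric fields in count file")
  bad <- which(cnt < 0)
  if (length(bad))
    stop("negative panel count at line ", ((bad[1] - 1) %% nrow(cnt)) + 1)
  if (any(dist < 0))
    stop("negative genetic distance at line ", which(dist < 0)[1])

  # positions strictly increasing within each chromosome
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    dp <- diff(pos[i])
    if (any(dp <= 0))
      stop("positions not strictly increasing at line ", i[which(dp <= 0)[1] + 1])
  }

  dist_M <- if (distances == "rate") {
    prev <- c(NA, pos[-length(pos)])
    first <- !duplicated(chrom)
    d <- dist * (pos - prev)
    d[first] <- 0
    d
  } else dist

  obs_A <- as.matrix(tab[, 7 + 2 * seq_len(S) - 1, drop = FALSE])
  obs_a <- as.matrix(tab[, 7 + 2 * seq_len(S), drop = FALSE])
  if (any(obs_A < 0, na.rm = TRUE) || any(obs_a < 0, na.rm = TRUE))
    stop("negative observation counts")
  colnames(obs_A) <- colnames(obs_a) <- ids

  sites <- data.frame(chrom = chrom, pos_bp = pos, dist_M = dist_M,
                      p0A = cnt[, 1], p0a = cnt[, 2],
                      p1A = cnt[, 3], p1a = cnt[, 4],
                      stringsAsFactors = FALSE)
  x <- new_counts(sites, obs_A, obs_a,
                  data.frame(id = ids, ploidy = ploidies,
                             stringsAsFactors = FALSE),
                  mode = mode, pooled = pooled)
  drop_empty_panel_sites(x)
}

new_counts <- function(sites, obs_A, obs_a, samples, mode, pooled) {
  gpos <- stats::ave(sites$dist_M, sites$chrom, FUN = cumsum)
  sites$gpos <- gpos
  structure(list(sites = sites, obs_A = obs_A, obs_a = obs_a,
                 samples = samples, mode = mode, pooled = pooled),
            class = "ai_counts")
}

drop_empty_panel_sites <- function(x) {
  tot0 <- x$sites$p0A + x$sites$p0a
  tot1 <- x$sites$p1A + x$sites$p1a
  keep <- tot0 > 0 & tot1 > 0
  if (!all(keep)) {
    message(sum(!keep), " site(s) dropped: zero sampled alleles in a reference panel")
    x <- subset_counts(x, which(keep))
  }
  x
}

subset_counts <- function(x, idx) {
  sites <- x$sites[idx, , drop = FALSE]
  # recompute distances so the genetic map stays consistent after dropping
  sites$dist_M <- stats::ave(sites$gpos, sites$chrom,
                             FUN = function(g) c(0, diff(g)))
  rownames(sites) <- NULL
  new_counts(sites[, setdiff(names(sites), "gpos")],
             x$obs_A[idx, , drop = FALSE], x$obs_a[idx, , drop = FALSE],
             x$samples, x$mode, x$pooled)
}

#' @export
print.ai_counts <- function(x, ...) {
  cat(sprintf("Site-count data: %d sites on %d chromosome(s), %d sample(s)%s, %s mode\n",
              nrow(x$sites), length(unique(x$sites$chrom)),
              nrow(x$samples), if (x$pooled) " (pooled)" else "", x$mode))
  invisible(x)
}

#' Write a site-count file
#'
#' Inverse of [read_counts_file()]; writing then re-reading (with
#' \code{distances = "morgans"}) reproduces the object, and re-writing a
#' just-read file is byte-identical.
#'
#' @param x An \code{"ai_counts"} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_counts_file <- function(x, path) {
  stopifnot(inherits(x, "ai_counts"))
  s <- x$sites
  obs <- matrix("", nrow(s), 2 * nrow(x$samples))
  obs[, seq(1, ncol(obs), by = 2)] <- sprintf("%d", as.integer(x$obs_A))
  obs[, seq(2, ncol(obs), by = 2)] <- sprintf("%d", as.integer(x$obs_a))
  lines <- paste(s$chrom, sprintf("%d", as.integer(s$pos_bp)),
                 sprintf("%d", as.integer(s$p0A)), sprintf("%d", as.integer(s$p0a)),
                 sprintf("%d", as.integer(s$p1A)), sprintf("%d", as.integer(s$p1a)),
                 sprintf("%.10e", s$dist_M),
                 apply(obs, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a ploidy file
#'
#' One line per sample: \code{id<TAB>ploidy}.
#'
#' @param path File path.
#' @return For the reader, a data frame with columns \code{id} and
#'   \code{ploidy}.
#' @export
read_ploidy_file <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) != 2) stop("ploidy file must have two tab-separated columns")
  pl <- as.integer(tab[[2]])
  if (any(is.na(pl) | pl < 1)) stop("ploidies must be positive integers")
  data.frame(id = as.character(tab[[1]]), ploidy = pl,
             stringsAsFactors = FALSE)
}

#' @param x Data frame with columns \code{id} and \code{ploidy}.
#' @rdname read_ploidy_file
#' @export
write_ploidy_file <- function(x, path) {
  writeLines(paste(x$id, x$ploidy, sep = "\t"), path)
  invisible(path)
}

#' Write scan results to a tab-separated file
#'
#' Emits one header block (lines starting with \code{#}) recording the
#' run parameters, a column header, and one row per evaluated site (and,
#' in grid mode, per grid value of s): chromosome, position, estimated
#' (or fixed) selection coefficient, log-likelihood ratio, and flags.
#'
#' @param fit An \code{"aiscan"} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scan_output <- function(fit, path) {
  stopifnot(inherits(fit, "aiscan"))
  cfg <- fit$config
  hdr <- c(
    sprintf("# aiscan scan: Ne=%g m=%g t=%d mode=%s backend=%s window=%g stride=%d seed=%s",
            cfg$dem$Ne, cfg$dem$m, cfg$dem$t, cfg$mode, cfg$backend,
            cfg$window, cfg$stride,
            if (is.null(cfg$seed)) "NA" else as.character(cfg$seed)),
    "#chrom\tpos\tcM\ts\tlnl_ratio\tflag")
  if (cfg$mode == "grid") {
    g <- fit$grid
    rows <- sprintf("%s\t%d\t%.8g\t%.6g\t%.6f\t%s",
                    g$chrom, as.integer(g$pos_bp), g$gpos * 100, g$s, g$lr,
                    g$flag)
  } else {
    r <- fit$results
    rows <- sprintf("%s\t%d\t%.8g\t%.6g\t%.6f\t%s",
                    r$chrom, as.integer(r$pos_bp), r$gpos * 100, r$s_hat,
                    r$lr, r$flag)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read back a scan output file
#'
#' @param path A file written by [write_scan_output()].
#' @return A data frame with columns chrom, pos_bp, gpos (Morgans), s,
#'   lr, flag.
#' @export
read_scan_output <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), pos_bp = integer(),
                      gpos = numeric(), s = numeric(), lr = numeric(),
                      flag = character(), stringsAsFactors = FALSE))
  tab <- read.table(text = body, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  names(tab) <- c("chrom", "pos_bp", "cM", "s", "lr", "flag")
  tab$gpos <- tab$cM / 100
  tab <- tab[, c("chrom", "pos_bp", "gpos", "s", "lr", "flag")]
  tab$flag[is.na(tab$flag)] <- ""
  tab$chrom <- as.character(tab$chrom)
  tab
}
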