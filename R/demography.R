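#' One-pulse admixture demography
#'
#' Container for the demographic parameters of the one-pulse admixture
#' model: all donor ancestry enters the recipient population in a single
#' generation, \code{t} generations before sampling.
#'
#' @param Ne Effective size of the admixed population (diploid
#'   individuals). Must be positive.
#' @param m Admixture fraction: proportion of the population's ancestry
#'   contributed by the donor population at the pulse, in (0, 1).
#'   Ancestry state 1 denotes the donor (introgressing) population
#'   throughout the package.
#' @param t Generations elapsed between the pulse and sampling (>= 1).
#'
#' @return An object of class \code{"ai_demography"}: a list with
#'   elements \code{Ne}, \code{m}, \code{t}.
#' @examples
#' demography(Ne = 10000, m = 0.1, t = 200)
#' @export
demography <- function(Ne, m, t) {
  stopifnot(is.numeric(Ne), length(Ne) == 1, is.finite(Ne), Ne > 0)
  stopifnot(is.numeric(m), length(m) == 1, m > 0, m < 1)
  stopifnot(is.numeric(t), length(t) == 1, t >= 1)
  structure(list(Ne = unname(Ne), m = unname(m),
                 t = as.integer(round(unname(t)))),
            class = "ai_demography")
}

#' @export
print.ai_demography <- function(x, ...) {
  cat(sprintf("One-pulse admixture model: Ne = %g, m = %g, t = %d generations\n",
              x$Ne, x$m, x$t))
  invisible(x)
}

as_demography <- function(dem) {
  if (inherits(dem, "ai_demography")) return(dem)
  if (is.list(dem) && all(c("Ne", "m", "t") %in% names(dem)))
    return(demography(dem$Ne, dem$m, dem$t))
  stop("expected an 'ai_demography' object (see demography())")
}
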