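#' Convert generations before a reference year to a calendar year
#'
#' year = reference_year - t_gen * generation_time, rounded to the nearest
#' whole year.
#'
#' @param tGen generations before the reference year (>= 0).
#' @param generationTime years per generation.
#' @param referenceYear calendar reference year (e.g. the mean birth year of
#'   the sampled individuals).
#' @return integer calendar year.
#' @examples
#' generationsToYear(22.02, 6, 1992)  # 1860
#' @export
generationsToYear <- function(tGen, generationTime = 6,
                              referenceYear = 1992) {
    stopifnot(all(tGen >= 0), generationTime > 0)
    as.integer(round(referenceYear - tGen * generationTime))
}

#' Implied generation time from a founding date
#'
#' (reference_year - founding_year) / n_generations, the generation time
#' implied when a known founding event is dated n generations before the
#' reference year.
#'
#' @param referenceYear,foundingYear calendar years (founding <= reference).
#' @param nGenerations generations separating the two (> 0).
#' @return years per generation.
#' @examples
#' impliedGenerationTime(1992, 1871, 22)  # 5.5
#' @export
impliedGenerationTime <- function(referenceYear, foundingYear, nGenerations) {
    stopifnot(foundingYear <= referenceYear, nGenerations > 0)
    (referenceYear - foundingYear) / nGenerations
}

#' Expected segment length and ancestor depth of an HBD rate class
#'
#' A homozygous-by-descent class with rate Rc has exponentially distributed
#' segment lengths with mean 1/Rc Morgans and groups ancestors living about
#' Rc/2 generations in the past.
#'
#' @param rc HBD class rate(s), > 0.
#' @return data.frame with \code{rc}, \code{lengthMorgans}, \code{lengthCm},
#'   \code{generations}.
#' @examples
#' hbdClassProperties(c(32, 64))
#' @export
hbdClassProperties <- function(rc) {
    stopifnot(all(rc > 0))
    data.frame(rc = rc, lengthMorgans = 1 / rc, lengthCm = 100 / rc,
               generations = rc / 2)
}

#' Doubling grid of HBD class rates
#'
#' The standard model grid: rates doubling from \code{min} to \code{max}
#' inclusive (defaults 2 to 8192, i.e. 13 classes).
#'
#' @param min,max powers of two.
#' @return numeric vector of rates.
#' @examples
#' length(hbdRateGrid())  # 13
#' @export
hbdRateGrid <- function(min = 2, max = 8192) {
    isPow2 <- function(x) x > 0 && abs(log2(x) - round(log2(x))) < 1e-9
    if (!isPow2(min) || !isPow2(max) || max < min)
        stop("min and max must be powers of two with min <= max")
    2^(log2(min):log2(max))
}
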