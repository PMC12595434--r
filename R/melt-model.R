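#' Three-parameter logistic melting curve
#'
#' Fraction of a protein remaining soluble after heating to
#' \code{temperature}, modelled as a descending logistic with upper
#' asymptote 1 (curves are reference-normalized, so the unheated
#' abundance defines 1) and a lower plateau of thermally resistant
#' signal.
#'
#' @param temperature Numeric vector of temperatures (degrees C).
#' @param tm Melting temperature (degrees C): the point where the
#'   curve crosses \code{(1 + plateau) / 2}; with \code{plateau = 0}
#'   this is the conventional half-denaturation point.
#' @param slope Transition width (degrees C); must be positive.
#'   Smaller values give sharper melting.
#' @param plateau Lower asymptote, a fraction in \verb{[0, 1)}.
#' @return Numeric vector of relative soluble fractions in
#'   \verb{(plateau, 1)}.
#' @examples
#' melt_curve_model(50, tm = 50, slope = 1, plateau = 0)    # 0.5
#' melt_curve_model(c(37, 64), tm = 50, slope = 2, plateau = 0.05)
#' @export
melt_curve_model <- function(temperature, tm, slope, plateau = 0) {
  if (!is.numeric(slope) || length(slope) != 1L || is.na(slope) || slope <= 0) {
    stop("`slope` must be a single positive number", call. = FALSE)
  }
  if (plateau < 0 || plateau >= 1) {
    stop("`plateau` must lie in [0, 1)", call. = FALSE)
  }
  plateau + (1 - plateau) / (1 + exp((temperature - tm) / slope))
}

#' Analytic inverse of the logistic melting curve
#'
#' Temperature at which \code{melt_curve_model} equals \code{y}.
#' Used as an independent oracle for spline-based Tm estimation.
#'
#' @param y Target relative abundance, must satisfy
#'   \code{plateau < y < 1}.
#' @inheritParams melt_curve_model
#' @return Temperature in degrees C.
#' @export
melt_curve_inverse <- function(y, tm, slope, plateau = 0) {
  stopifnot(all(y > plateau), all(y < 1))
  f <- (y - plateau) / (1 - plateau)
  tm + slope * log(1 / f - 1)
}
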