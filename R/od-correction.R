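#' Correct OD600 for the nonlinearity between optical and cell density
#'
#' At higher cell densities the measured OD600 under-reports cell density.
#' The corrected value is obtained from the measured one with the cubic
#'
#' \deqn{OD_{cx} = OD_{me} + 0.499\,OD_{me}^2 + 0.191\,OD_{me}^3}
#'
#' where `me` is the measured and `cx` the corrected optical density.
#'
#' @param od_me Measured OD600, a non-negative numeric vector.
#' @return Corrected OD600, same length as `od_me`.
#' @examples
#' correct_od(1.0) # 1.690
#' @seealso [distort_od()] for the exact functional inverse.
#' @export
correct_od <- function(od_me) {
  check_number(od_me, "od_me", lower = 0)
  od_me + 0.499 * od_me^2 + 0.191 * od_me^3
}

#' Map true OD to the value a plate reader would measure
#'
#' The exact inverse of [correct_od()]: given a corrected (true) optical
#' density, returns the unique non-negative measured value `m` with
#' `m + 0.499 m^2 + 0.191 m^3 = od_true`. Used by the growth-curve
#' simulator so that synthetic plate-reader data carry the same
#' nonlinearity the analysis corrects for. The root is found by Newton
#' iteration on the monotone cubic (derivative >= 1 everywhere), to
#' within 1e-12.
#'
#' @param od_true True (corrected-scale) OD600, non-negative numeric vector.
#' @return Measured-scale OD600, same length.
#' @examples
#' distort_od(1.690) # 1.0
#' correct_od(distort_od(0.7)) # 0.7
#' @export
distort_od <- function(od_true) {
  check_number(od_true, "od_true", lower = 0)
  m <- od_true # starting point; correct_od(m) >= m so Newton descends
  for (i in 1:60) {
    f <- m + 0.499 * m^2 + 0.191 * m^3 - od_true
    if (all(abs(f) <= 1e-12)) break
    fp <- 1 + 0.998 * m + 0.573 * m^2
    m <- pmax(0, m - f / fp)
  }
  m
}
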