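#' Day length from latitude and day of year
#'
#' Forsythe's CBM approximation of day length: the revolution angle
#' \eqn{\theta = 0.2163108 + 2\arctan(0.9671396 \tan(0.00860(J - 186)))}
#' gives the solar declination
#' \eqn{\delta = \arcsin(0.39795 \cos\theta)}, and day length is
#' \deqn{D = 24 - \frac{24}{\pi}\arccos\left[
#'   \frac{\sin(p\pi/180) + \sin(L\pi/180)\sin\delta}
#'        {\cos(L\pi/180)\cos\delta}\right]}
#' with latitude \eqn{L} in degrees and \eqn{p} the daylength coefficient
#' (horizon angle). The default `p = 0.8333` corresponds to apparent
#' sunrise/sunset (solar disc top at the horizon with refraction); `p = 0`
#' is the geometric definition, giving exactly 12 h at the equator.
#'
#' The arccos argument is clamped to `[-1, 1]`; clamping occurs only under
#' polar day/night, and the number of clamped evaluations is attached as
#' attribute `n_clamped` (with a message when nonzero).
#'
#' @param latitude degrees north, vectorized; sensible for |latitude| <= 66
#'   with the default coefficient.
#' @param day_of_year integer day 1-365, vectorized (recycled against
#'   `latitude`).
#' @param coefficient daylength coefficient p, degrees.
#' @return Numeric vector of day lengths in hours.
#' @export
#' @examples
#' daylength(51.4, 172)          # near the June solstice
#' max(daylength(51.4, 1:365))   # annual maximum photoperiod
daylength <- function(latitude, day_of_year, coefficient = 0.8333) {
  if (!all(is.finite(latitude)) || !all(is.finite(day_of_year)) ||
      !is.finite(coefficient)) {
    stop("latitude, day_of_year and coefficient must be finite",
         call. = FALSE)
  }
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  delta <- asin(0.39795 * cos(theta))
  lat <- latitude * pi / 180
  arg <- (sin(coefficient * pi / 180) + sin(lat) * sin(delta)) /
    (cos(lat) * cos(delta))
  n_clamped <- sum(arg < -1 | arg > 1)
  if (n_clamped > 0) {
    message(n_clamped, " day-length evaluation(s) clamped (polar day/night)")
  }
  arg <- pmin(1, pmax(-1, arg))
  out <- 24 - (24 / pi) * acos(arg)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Maximum day length over a growing window
#'
#' The longest photoperiod experienced between sowing and harvest at a
#' collection site (MDL), a proxy for the photoperiod regime a landrace
#' was selected under. Windows wrap past day 365 when harvest precedes
#' sowing in the calendar (southern autumn sowing).
#'
#' @param latitude degrees north (vectorized; recycled with the day
#'   arguments).
#' @param sowing_doy,harvest_doy day-of-year in 1-365.
#' @param coefficient daylength coefficient, degrees; see [daylength()].
#' @return Numeric vector of maximum day lengths, hours.
#' @export
#' @examples
#' mdl(40.1, 121, 274)  # spring sowing at a northern site
mdl <- function(latitude, sowing_doy, harvest_doy, coefficient = 0.8333) {
  stopifnot(all(sowing_doy >= 1 & sowing_doy <= 365),
            all(harvest_doy >= 1 & harvest_doy <= 365))
  n <- max(length(latitude), length(sowing_doy), length(harvest_doy))
  latitude <- rep_len(latitude, n)
  sowing_doy <- rep_len(as.integer(sowing_doy), n)
  harvest_doy <- rep_len(as.integer(harvest_doy), n)
  vapply(seq_len(n), function(i) {
    days <- if (harvest_doy[i] >= sowing_doy[i]) {
      seq.int(sowing_doy[i], harvest_doy[i])
    } else {
      c(seq.int(sowing_doy[i], 365L), seq.int(1L, harvest_doy[i]))
    }
    max(daylength(latitude[i], days, coefficient))
  }, numeric(1))
}

#' Pairwise-complete trait correlation matrix
#'
#' Pearson correlations between trait columns using pairwise-complete
#' observations, with the number of complete pairs per comparison. Pairs
#' with fewer than three complete observations are left `NA` and flagged.
#'
#' @param traits data frame of traits (e.g. flowering time per location,
#'   TAR, AP, MDL).
#' @param columns character vector of columns to correlate; default all
#'   numeric columns.
#' @return A list of class `trait_cor` with elements `r` (correlation
#'   matrix), `n` (pair counts) and `flagged` (pairs with n < 3).
#' @export
trait_correlations <- function(traits, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  x <- as.matrix(traits[columns])
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  ok <- !is.na(x)
  n <- crossprod(ok * 1L)
  r[n < 3] <- NA_real_
  diag(r) <- ifelse(diag(n) >= 1, 1, NA_real_)
  flagged <- which(n < 3 & upper.tri(n), arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = columns[flagged[, 1]], var2 = columns[flagged[, 2]]
  )
  structure(list(r = r, n = n, flagged = flagged), class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 3, ...) {
  cat("<trait_cor> pairwise-complete Pearson correlations\n")
  print(round(x$r, digits))
  if (nrow(x$flagged)) {
    cat("pairs with < 3 complete observations:",
        paste(x$flagged$var1, x$flagged$var2, sep = "~", collapse = ", "),
        "\n")
  }
  invisible(x)
}
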