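#' Thermal hysteresis width between heating and cooling traces
#'
#' Each trace is normalised over the shared temperature span and the
#' mid-transition temperature (where the normalised absorbance crosses half
#' of its total change) is located by linear interpolation; the width is
#' `T_half(heating) - T_half(cooling)`, which is >= 0 for a kinetically
#' limited system and grows with scan rate.
#'
#' @param heating,cooling `th_trace` objects sharing `C_tot` and span (the
#'   cooling argument may also be an equilibrium curve)
#' @return width in degC
#' @export
hysteresis_width <- function(heating, cooling) {
  ch <- attr(heating, "conditions"); cc <- attr(cooling, "conditions")
  if (!is.null(ch$C_tot) && !is.null(cc$C_tot) &&
      abs(ch$C_tot - cc$C_tot) > 1e-9 * ch$C_tot)
    stop("traces have different total strand concentrations")
  lo <- max(min(heating$temperature_C), min(cooling$temperature_C))
  hi <- min(max(heating$temperature_C), max(cooling$temperature_C))
  if (hi - lo < 5)
    stop("temperature spans do not overlap enough to compare")
  t_half(heating, lo, hi) - t_half(cooling, lo, hi)
}

#' Mid-transition temperature of a trace
#'
#' @param trace a `th_trace`
#' @param lo,hi span (degC) over which to normalise; defaults to the trace's
#' @return temperature (degC) at half of the total absorbance change
#' @export
t_half <- function(trace, lo = min(trace$temperature_C),
                   hi = max(trace$temperature_C)) {
  sel <- trace$temperature_C >= lo & trace$temperature_C <= hi
  T_C <- trace$temperature_C[sel]
  A <- trace$absorbance_AU[sel]
  o <- order(T_C)
  T_C <- T_C[o]; A <- A[o]
  Ahalf <- (min(A) + max(A)) / 2
  # first upward crossing of the half level in temperature order
  s <- A - Ahalf
  i <- which(s[-1] * s[-length(s)] <= 0)[1]
  if (is.na(i)) stop("no half-transition crossing found")
  T_C[i] + (T_C[i + 1] - T_C[i]) * (Ahalf - A[i]) / (A[i + 1] - A[i])
}

#' Local maxima of the smoothed melting derivative dA/dT
#'
#' Used to detect biphasic melting: a trap melting at low temperature and a
#' tetramer at high temperature give two separated peaks.
#'
#' @param trace a `th_trace`
#' @param span smoothing half-width in points for the running-mean filter
#' @param min_prominence discard peaks whose height above the larger flanking
#'   minimum is below this fraction of the global dA/dT range
#' @return data frame `temperature_C`, `dAdT` of the detected maxima
#' @export
dAdT_peaks <- function(trace, span = 5L, min_prominence = 0.05) {
  o <- order(trace$temperature_C)
  T_C <- trace$temperature_C[o]; A <- trace$absorbance_AU[o]
  d <- diff(A) / diff(T_C)
  Tm <- (T_C[-1] + T_C[-length(T_C)]) / 2
  # running mean smoothing
  k <- 2L * span + 1L
  dsm <- stats::filter(d, rep(1 / k, k), sides = 2)
  keep <- !is.na(dsm)
  dsm <- as.numeric(dsm[keep]); Tm <- Tm[keep]
  n <- length(dsm)
  ispk <- which(dsm[2:(n - 1)] > dsm[1:(n - 2)] &
                dsm[2:(n - 1)] >= dsm[3:n]) + 1L
  if (!length(ispk))
    return(data.frame(temperature_C = numeric(0), dAdT = numeric(0)))
  rng <- diff(range(dsm))
  prom <- vapply(ispk, function(i) {
    leftmin <- min(dsm[1:i]); rightmin <- min(dsm[i:n])
    dsm[i] - max(leftmin, rightmin)
  }, numeric(1))
  ispk <- ispk[prom >= min_prominence * rng]
  data.frame(temperature_C = Tm[ispk], dAdT = dsm[ispk])
}
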