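#' Temperature programs
#'
#' A program is an ordered list of segments: linear ramps
#' (`ramp_segment(from, to, rate)`, rate in degC/min, sign inferred from the
#' direction) and isothermal holds (`hold_segment(T, duration)`).
#' All temperatures are Celsius at this interface.
#'
#' @param from,to ramp endpoints, degC
#' @param rate absolute scan rate, degC/min (must be > 0)
#' @param T hold temperature, degC
#' @param duration hold length, s
#' @param ... segments built with `ramp_segment()` / `hold_segment()`
#' @return `temperature_program()` returns an object of class
#'   `temperature_program` with precomputed absolute start/end times (s)
#' @examples
#' temperature_program(ramp_segment(85, 5, 0.5), ramp_segment(5, 85, 0.5))
#' @export
temperature_program <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1]]) && is.null(segs[[1]]$kind))
    segs <- segs[[1]]
  stopifnot(length(segs) >= 1L)
  t0 <- 0
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    stopifnot(s$kind %in% c("ramp", "hold"))
    segs[[i]]$t_start <- t0
    t0 <- t0 + s$duration
    segs[[i]]$t_end <- t0
  }
  structure(list(segments = segs, total_time = t0),
            class = "temperature_program")
}

#' @rdname temperature_program
#' @export
ramp_segment <- function(from, to, rate) {
  stopifnot(rate > 0, from != to)
  if (any(c(from, to) < -10) || any(c(from, to) > 110))
    stop("segment temperatures outside the physically sane -10..110 degC")
  dur <- abs(to - from) / rate * 60
  list(kind = "ramp", T_start = from, T_end = to,
       rate_per_s = sign(to - from) * rate / 60, duration = dur)
}

#' @rdname temperature_program
#' @export
hold_segment <- function(T, duration) {
  stopifnot(duration > 0, T >= -10, T <= 110)
  list(kind = "hold", T_start = T, T_end = T, rate_per_s = 0,
       duration = duration)
}

# segment matrix for the compiled integrator: t0, t1, T0 (K), rate (K/s)
.program_matrix <- function(program) {
  t(vapply(program$segments, function(s)
    c(s$t_start, s$t_end, celsius_to_kelvin(s$T_start), s$rate_per_s),
    numeric(4)))
}

# temperature (degC) at absolute program times (vectorised, exact)
program_temperature <- function(program, t) {
  out <- numeric(length(t))
  for (s in program$segments) {
    sel <- t >= s$t_start & t <= s$t_end
    out[sel] <- s$T_start + s$rate_per_s * (t[sel] - s$t_start)
  }
  out
}

# output times for a uniform temperature grid (ramps) or time grid (holds)
.program_out_times <- function(program, grid_C = 0.25) {
  times <- numeric(0)
  for (s in program$segments) {
    if (s$kind == "ramp") {
      n <- max(2L, round(abs(s$T_end - s$T_start) / grid_C) + 1L)
      tt <- seq(s$t_start, s$t_end, length.out = n)
    } else {
      n <- max(2L, ceiling(s$duration / 60) + 1L)
      tt <- seq(s$t_start, s$t_end, length.out = min(n, 500L))
    }
    if (length(times) && abs(tt[1] - times[length(times)]) < 1e-9)
      tt <- tt[-1]
    times <- c(times, tt)
  }
  times
}
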