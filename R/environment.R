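#' Day-indexed environmental forcing series
#'
#' A validated container for daily water temperature (degrees C) and
#' photoperiod (h). Series whose days span at most one year are treated as an
#' annual cycle and extended periodically when queried beyond their last day.
#'
#' @param day strictly increasing vector of days (d).
#' @param temperature water temperature (degrees C), in (0, 45).
#' @param photoperiod day length (h), in `[0, 24]`.
#' @param period length of one cycle in days, or `NULL` for a non-cyclic
#'   series. By default series spanning <= 366 days get `period = 365`.
#' @param monsoon_window integer vector `c(first, last)` day-of-year of the
#'   monsoon nutrient-input window, or `NULL`/empty for no monsoon.
#' @return An object of class `env_series`.
#' @export
env_series <- function(day, temperature, photoperiod,
                       period = if (max(day) <= 366) 365 else NULL,
                       monsoon_window = c(152, 273)) {
  if (length(day) == 0) stop("empty environmental series", call. = FALSE)
  if (length(temperature) != length(day) || length(photoperiod) != length(day)) {
    stop("day, temperature and photoperiod must have equal length", call. = FALSE)
  }
  if (is.unsorted(day, strictly = TRUE)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0 | temperature >= 45)) {
    stop("temperature must lie in (0, 45) degrees C", call. = FALSE)
  }
  if (any(!is.finite(photoperiod)) || any(photoperiod < 0 | photoperiod > 24)) {
    stop("photoperiod must lie in [0, 24] h", call. = FALSE)
  }
  structure(list(day = as.numeric(day), temperature = as.numeric(temperature),
                 photoperiod = as.numeric(photoperiod), period = period,
                 monsoon_window = monsoon_window),
            class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("Environmental series: %d records, days %g..%g%s\n",
              length(x$day), min(x$day), max(x$day),
              if (!is.null(x$period)) sprintf(" (annual cycle, period %g d)",
                                              x$period) else ""))
  cat(sprintf("  temperature %0.1f..%0.1f degC, photoperiod %0.1f..%0.1f h\n",
              min(x$temperature), max(x$temperature),
              min(x$photoperiod), max(x$photoperiod)))
  invisible(x)
}

#' Read a temperature/photoperiod scenario file
#'
#' Parses a whitespace- or tab-delimited text file with columns
#' `day temperature photoperiod`. A header line is optional and `#` starts a
#' comment. Files covering at most one year are cycled annually when queried
#' beyond their last day.
#'
#' @param path path to the scenario file.
#' @param monsoon_window passed to [env_series()].
#' @return An [env_series()].
#' @export
load_scenario <- function(path, monsoon_window = c(152, 273)) {
  lines <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", lines)
  keep <- which(trimws(raw) != "")
  if (length(keep) == 0) stop("scenario file is empty: ", path, call. = FALSE)
  first <- strsplit(trimws(raw[keep[1]]), "[ \t]+")[[1]]
  if (suppressWarnings(any(is.na(as.numeric(first))))) keep <- keep[-1] # header
  if (length(keep) == 0) stop("scenario file has no data rows: ", path,
                              call. = FALSE)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    cells <- strsplit(trimws(raw[ln]), "[ \t]+")[[1]]
    if (length(cells) < 3) {
      stop(sprintf("scenario line %d: expected 3 columns (day temperature photoperiod), got %d",
                   ln, length(cells)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells[1:3]))
    if (any(is.na(vals))) {
      stop(sprintf("scenario line %d: non-numeric cell", ln), call. = FALSE)
    }
    if (vals[3] < 0 || vals[3] > 24) {
      stop(sprintf("scenario line %d: photoperiod %g outside [0, 24] h",
                   ln, vals[3]), call. = FALSE)
    }
    if (vals[2] <= 0 || vals[2] >= 45) {
      stop(sprintf("scenario line %d: temperature %g outside (0, 45) degC",
                   ln, vals[2]), call. = FALSE)
    }
    rows[[i]] <- vals
  }
  m <- do.call(rbind, rows)
  env_series(m[, 1], m[, 2], m[, 3], monsoon_window = monsoon_window)
}

#' Interpolated environmental conditions on a given day
#'
#' Linear interpolation between bracketing records; annual series are
#' extended cyclically (day 366 of a 365-day series maps back to day 1).
#'
#' @param series an [env_series()].
#' @param day simulation day(s), >= 1.
#' @return A list with numeric vectors `temperature` and `photoperiod`.
#' @export
conditions_at <- function(series, day) {
  d <- day
  if (!is.null(series$period)) {
    d <- ((d - series$day[1]) %% series$period) + series$day[1]
  } else {
    d <- clamp(d, min(series$day), max(series$day))
  }
  # for cyclic series, interpolate across the wrap by appending the first
  # record one period later (dropping any records beyond one period)
  xs <- series$day; Ts <- series$temperature; Ps <- series$photoperiod
  if (!is.null(series$period)) {
    inside <- xs < series$day[1] + series$period
    xs <- c(xs[inside], series$day[1] + series$period)
    Ts <- c(Ts[inside], Ts[1])
    Ps <- c(Ps[inside], Ps[1])
  }
  list(temperature = stats::approx(xs, Ts, xout = d, rule = 2)$y,
       photoperiod = stats::approx(xs, Ps, xout = d, rule = 2)$y)
}

#' Generate a monsoon tropical (Kolkata-like) forcing scenario
#'
#' Deterministic annual forcing for the natural habitat of wild zebrafish:
#' sinusoidal water temperature (default 19-31 degrees C peaking in late
#' spring) and the astronomical day length for latitude 22.57 degrees N via
#' the standard solar-declination formula. The monsoon nutrient-input window
#' defaults to days-of-year 152-273 (June-September).
#'
#' @param years number of annual cycles (>= 1); the returned series always
#'   carries `period = 365` so it extends to any horizon.
#' @param mean_temp,amplitude,peak_day annual mean (degrees C), half-range
#'   (degrees C) and day-of-year of the temperature maximum.
#' @param latitude latitude in degrees (default Kolkata, 22.57 N).
#' @param monsoon_window day-of-year window of monsoon inputs.
#' @return An [env_series()] of `365 * years` daily records.
#' @export
generate_monsoon_scenario <- function(years = 1, mean_temp = 25,
                                      amplitude = 6, peak_day = 140,
                                      latitude = 22.57,
                                      monsoon_window = c(152, 273)) {
  if (years < 1) stop("years must be >= 1", call. = FALSE)
  day <- seq_len(365 * years)
  doy <- ((day - 1) %% 365) + 1
  temp <- mean_temp + amplitude * cos(2 * pi * (doy - peak_day) / 365)
  photo <- daylength(doy, latitude)
  env_series(day, temp, photo, period = 365, monsoon_window = monsoon_window)
}

#' Astronomical day length
#'
#' Standard solar-declination day length:
#' `decl = 23.44 * sin(2*pi*(284 + doy)/365)` degrees and
#' `daylength = 24/pi * acos(-tan(lat) * tan(decl))` h (argument clamped for
#' polar day/night).
#'
#' @param doy day of year (1-365), vectorised.
#' @param latitude latitude in degrees.
#' @return Day length in hours.
#' @export
daylength <- function(doy, latitude = 22.57) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  x <- clamp(-tan(latitude * pi / 180) * tan(decl), -1, 1)
  24 / pi * acos(x)
}

#' Is reproduction environmentally permitted?
#'
#' Spawning requires both a long day and warm water:
#' `photoperiod >= P_tau` and `temperature >= T_tau`.
#'
#' @param T_c water temperature (degrees C), vectorised.
#' @param photoperiod day length (h), vectorised.
#' @param P_tau photoperiod threshold (h), default 12.
#' @param T_tau temperature threshold (degrees C), default 22.5.
#' @return Logical vector.
#' @export
reproduction_window <- function(T_c, photoperiod, P_tau = 12, T_tau = 22.5) {
  photoperiod >= P_tau & T_c >= T_tau
}

#' Is the monsoon nutrient-input window active?
#'
#' @param day simulation day(s); reduced to day-of-year modulo 365.
#' @param window integer `c(first, last)` day-of-year, or `NULL`/empty for
#'   never.
#' @return Logical vector.
#' @export
monsoon_active <- function(day, window = c(152, 273)) {
  if (is.null(window) || length(window) < 2) return(rep(FALSE, length(day)))
  doy <- ((day - 1) %% 365) + 1
  doy >= window[1] & doy <= window[2]
}
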