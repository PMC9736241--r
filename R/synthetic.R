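#' Synthetic barn generator configuration
#'
#' The generated table mimics winter barn microclimate records sampled every
#' 10 minutes: diurnal cycles (period 144 steps = 24 h) with persistent AR(1)
#' sensor noise on the exogenous drivers, and a humidity process coupled to
#' four of them. Humidity responds negatively to temperature and light,
#' positively to CO2 (an occupancy/ventilation proxy) and weakly positively
#' to PM2.5, plus an AR(1) disturbance; coarse particulates (PM10, TSP) are
#' noisy multiples of PM2.5, while noise, NH3 and H2S are independent of
#' humidity by construction.
#'
#' @param baseline humidity process intercept (%).
#' @param beta named effects of `air_temp` (%/degC), `co2` (% per mL/m3),
#'   `light` (%/lx) and `pm25` (% per ug/m3) on humidity.
#' @param ar_phi AR(1) coefficient of the humidity disturbance, in (-1, 1).
#' @param noise_sd innovation standard deviation of the humidity disturbance.
#' @param driver_phi AR(1) coefficient of the driver sensor noise.
#' @return a `barn_config` list.
#' @export
barn_config <- function(baseline = 82.5,
                        beta = c(air_temp = -0.8, co2 = 0.004,
                                 light = -0.02, pm25 = 0.05),
                        ar_phi = 0.6, noise_sd = 0.3, driver_phi = 0.9) {
  if (abs(ar_phi) >= 1) stop("barn_config: ar_phi must lie in (-1, 1)")
  if (abs(driver_phi) >= 1) stop("barn_config: driver_phi must lie in (-1, 1)")
  if (noise_sd < 0) stop("barn_config: noise_sd must be >= 0")
  need <- c("air_temp", "co2", "light", "pm25")
  if (!all(need %in% names(beta))) {
    stop("barn_config: beta needs effects for ", paste(need, collapse = ", "))
  }
  structure(list(baseline = baseline, beta = beta, ar_phi = ar_phi,
                 noise_sd = noise_sd, driver_phi = driver_phi),
            class = "barn_config")
}

ar1_series <- function(n, phi, sd) {
  if (sd == 0 || phi == 0 && sd == 0) return(numeric(n))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd), phi, method = "recursive"))
}

#' Generate a synthetic barn sensor table
#'
#' Produces a timestamped multivariate table with the winter sheep-barn
#' schema: air temperature (degC), air humidity (%), CO2 (mL/m3), PM2.5,
#' PM10, TSP (ug/m3), light (lx), noise (dB), NH3 and H2S (mL/m3), at strict
#' 10-minute spacing. Humidity follows
#' `h_t = baseline + beta . drivers_t + e_t` with `e_t` an AR(1)
#' disturbance, clipped to \[0, 100\]. With `noise_sd = 0` and `ar_phi = 0`
#' humidity is an exact deterministic function of the four drivers.
#'
#' @param n_rows number of records, >= 20 (default 2000, two weeks of
#'   10-minute samples).
#' @param seed optional integer seed; the same seed reproduces the table
#'   exactly.
#' @param config a [barn_config()].
#' @param start first timestamp (POSIXct, UTC).
#' @return data.frame with `timestamp` plus the ten sensor columns.
#' @examples
#' tab <- generate_barn_data(200, seed = 1)
#' range(tab$air_humidity)
#' @export
generate_barn_data <- function(n_rows = 2000, seed = NULL,
                               config = barn_config(),
                               start = as.POSIXct("2021-02-08 00:00:00",
                                                 tz = "UTC")) {
  stopifnot(inherits(config, "barn_config"))
  if (n_rows < 20) stop("generate_barn_data: n_rows must be >= 20")
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n_rows)
  day <- 2 * pi * t / 144                       # diurnal phase, period 24 h

  air_temp <- 5.5 + 2.0 * sin(day - pi / 2) + ar1_series(n_rows, config$driver_phi, 0.22)
  co2      <- 1050 + 250 * sin(day + pi / 2) + ar1_series(n_rows, config$driver_phi, 26)
  light    <- pmax(150 + 90 * sin(day - pi / 2) +
                     ar1_series(n_rows, config$driver_phi, 7), 0)
  pm25     <- pmax(15 + 5 * sin(day + pi / 2) +
                     ar1_series(n_rows, config$driver_phi, 1.3), 0.5)
  pm10     <- pmax(2.5 * pm25 + stats::rnorm(n_rows, 0, 8), 0)
  tsp      <- pmax(4.0 * pm25 + stats::rnorm(n_rows, 0, 15), 0)
  noise    <- pmin(pmax(40 + 8 * sin(day - pi / 2) +
                          stats::rnorm(n_rows, 0, 5), 20), 90)
  nh3      <- pmax(0.3 + ar1_series(n_rows, config$driver_phi, 0.1), 0)
  h2s      <- pmax(5 + ar1_series(n_rows, config$driver_phi, 0.3), 0)

  det <- config$baseline +
    config$beta[["air_temp"]] * air_temp + config$beta[["co2"]] * co2 +
    config$beta[["light"]] * light + config$beta[["pm25"]] * pm25
  humidity <- pmin(pmax(det + ar1_series(n_rows, config$ar_phi, config$noise_sd),
                        0), 100)

  data.frame(
    timestamp = start + 600 * (t - 1),
    air_temp = air_temp, air_humidity = humidity, co2 = co2,
    pm25 = pm25, pm10 = pm10, light = light, noise = noise,
    tsp = tsp, nh3 = nh3, h2s = h2s
  )
}

#' Names of the candidate feature columns (the non-target sensors)
#' @return character vector of the nine non-humidity sensor column names.
#' @export
sensor_feature_names <- function() {
  c("air_temp", "co2", "pm25", "pm10", "light", "noise", "tsp", "nh3", "h2s")
}

#' Inject missing values and spikes into a sensor table
#'
#' Corrupts a clean table so the repair stage has work to do: a fraction of
#' randomly chosen sensor cells become `NA`, and a number of humidity cells
#' become out-of-range spikes (e.g. 250%).
#'
#' @param table a sensor table from [generate_barn_data()].
#' @param frac_missing fraction of sensor cells set to `NA`.
#' @param n_spikes number of out-of-range humidity spikes.
#' @param seed optional integer seed.
#' @return the corrupted table.
#' @export
corrupt_barn_data <- function(table, frac_missing = 0.01, n_spikes = 5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- setdiff(names(table), "timestamp")
  n <- nrow(table)
  n_na <- floor(frac_missing * n * length(cols))
  if (n_na > 0) {
    cells <- sample(n * length(cols), n_na)
    for (cell in cells) {
      # never blank the first/last row so interpolation stays bounded
      row <- (cell - 1L) %% n + 1L
      if (row == 1L || row == n) next
      table[row, cols[(cell - 1L) %/% n + 1L]] <- NA_real_
    }
  }
  if (n_spikes > 0) {
    rows <- sample(2:(n - 1L), min(n_spikes, n - 2L))
    table$air_humidity[rows] <- 250
  }
  table
}

#' Write a sensor table as CSV with ISO-8601 timestamps
#' @param table a sensor table.
#' @param path output file path.
#' @export
write_sensor_csv <- function(table, path) {
  out <- table
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a sensor table written by [write_sensor_csv()]
#' @param path CSV file path.
#' @return data.frame with parsed POSIXct timestamps.
#' @export
read_sensor_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(tab)) stop("read_sensor_csv: no timestamp column")
  tab$timestamp <- as.POSIXct(tab$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  tab
}
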