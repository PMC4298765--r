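# Daily meteorological driver: construction, validation and CSV I/O.

DRIVER_COLS <- c("date", "tmin_c", "tmax_c", "precip_mm", "rad_mj_m2",
                 "co2_ppm", "swc_m3_m3")

#' Validate and construct a daily meteorological driver
#'
#' One row per day: date, min/max temperature (deg C), precipitation (mm),
#' global radiation (MJ m-2 d-1), atmospheric CO2 (ppm) and volumetric soil
#' water content (m3 m-3). Days must be consecutive with no gaps.
#'
#' @param df Data frame with the driver columns.
#' @return A validated tibble.
#' @export
meteo_driver <- function(df) {
  miss <- setdiff(DRIVER_COLS, names(df))
  if (length(miss)) stop("driver missing columns: ", paste(miss, collapse = ", "))
  df <- tibble::as_tibble(df[DRIVER_COLS])
  df$date <- as.Date(df$date)
  if (nrow(df) == 0) stop("driver has no days")
  if (nrow(df) > 1 && any(diff(as.numeric(df$date)) != 1)) {
    stop("driver days must be consecutive with no missing days")
  }
  num <- as.matrix(df[-1])
  if (any(!is.finite(num))) stop("driver contains non-finite values")
  if (any(df$swc_m3_m3 <= 0 | df$swc_m3_m3 >= 1)) stop("swc must be in (0, 1)")
  if (any(df$tmin_c > df$tmax_c)) stop("tmin must not exceed tmax")
  df
}

#' Read a driver CSV
#'
#' @param path CSV with columns date, tmin_c, tmax_c, precip_mm, rad_mj_m2,
#'   co2_ppm, swc_m3_m3.
#' @return A validated driver tibble.
#' @export
read_driver_csv <- function(path) {
  meteo_driver(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a driver CSV
#'
#' @param driver Driver tibble.
#' @param path Output path.
#' @export
write_driver_csv <- function(driver, path) {
  utils::write.csv(driver, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory CSV (date, seven pools, all daily fluxes)
#'
#' @param traj A `carbon_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- cbind(data.frame(date = traj$dates),
               as.data.frame(traj$pools), as.data.frame(traj$fluxes))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
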