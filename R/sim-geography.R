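#' Simulate collection-site geography for a structured panel
#'
#' Draws a passport table: one row per accession with group label,
#' latitude band by group (WILD 24-53, NR 40-51.4, HR 34-40, SR 18.2-34
#' degrees N), longitude in 80.5-134 degrees E, nonnegative altitude, an
#' ecotype consistent with the group and latitude, and group-level sowing
#' and harvest days.
#'
#' @param config a [sim_config()].
#' @return A tibble (`sample_id`, `group`, `latitude`, `longitude`,
#'   `altitude`, `ecotype`, `sowing_doy`, `harvest_doy`).
#' @export
simulate_geography <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bands <- list(
    WILD = c(24, 53), NR = c(40, 51.4), HR = c(34, 40), SR = c(18.2, 34)
  )
  groups <- names(config$n_per_group)
  unknown <- setdiff(groups, names(bands))
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  with_op_seed(config$seed, "simulate_geography", {
    rows <- purrr::map(groups, function(g) {
      n <- config$n_per_group[[g]]
      if (n == 0) return(NULL)
      lat <- stats::runif(n, bands[[g]][1], bands[[g]][2])
      sh <- config$sowing_harvest_by_group[[g]]
      if (is.null(sh)) sh <- c(150L, 290L)
      tibble::tibble(
        group = g,
        latitude = lat,
        longitude = stats::runif(n, 80.5, 134.0),
        altitude = pmin(round(stats::rexp(n, 1 / 400)) + 1, 2520),
        ecotype = assign_ecotype(g, lat),
        sowing_doy = sh[1],
        harvest_doy = sh[2]
      )
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::mutate(out,
                         sample_id = sprintf("S%04d", seq_len(nrow(out))),
                         .before = 1)
    out
  })
}

# Ecotype from group and latitude: northern spring types split at 45N,
# Huanghuai spring vs summer, southern spring/summer/autumn by latitude.
assign_ecotype <- function(group, lat) {
  switch(group,
    WILD = rep(NA_character_, length(lat)),
    NR = ifelse(lat >= 45, "NESp", "NSp"),
    HR = ifelse(stats::runif(length(lat)) < 0.06, "HSp", "HSu"),
    SR = c("SSp", "SSu", "SAu")[1 + findInterval(lat, c(24, 30))]
  )
}

#' Simulate bioclimatic variables from geography
#'
#' Adds temperature annual range (TAR, deg C), annual precipitation
#' (AP, mm) and maximum day length over the growing window (MDL, h) to a
#' passport table. TAR increases and AP decreases with latitude (linear
#' trend plus Gaussian noise, slopes from `config$climate_params`); MDL is
#' computed deterministically by [mdl()] from latitude and the sowing and
#' harvest days, with no noise.
#'
#' @param samples passport tibble from [simulate_geography()].
#' @param config a [sim_config()].
#' @return `samples` with columns `TAR`, `AP`, `MDL` appended.
#' @export
simulate_climate <- function(samples, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!"latitude" %in% names(samples) || anyNA(samples$latitude)) {
    stop("samples must carry complete latitudes", call. = FALSE)
  }
  cp <- config$climate_params
  n <- nrow(samples)
  with_op_seed(config$seed, "simulate_climate", {
    dplyr::mutate(
      samples,
      TAR = cp$tar_intercept + cp$tar_slope * .data$latitude +
        stats::rnorm(n, 0, cp$tar_sd),
      AP = pmax(0, cp$ap_intercept + cp$ap_slope * .data$latitude +
                  stats::rnorm(n, 0, cp$ap_sd)),
      MDL = mdl(.data$latitude, .data$sowing_doy, .data$harvest_doy)
    )
  })
}
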