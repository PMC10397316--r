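#' Configure a synthetic world
#'
#' A synthetic world is a planar grid of coarse cells (the analysis grain,
#' analogous to a 0.5 degree global grid with cells close to 50 km at the
#' equator), each subdivided into `fine_per_coarse x fine_per_coarse` fine
#' cells (the climate-data grain, analogous to 30 arc seconds). Rows play the
#' role of latitude: row 1 sits at `lat_range[1]` ("equator" side) and the last
#' row at `lat_range[2]` ("pole" side). All geometry is planar with a fixed
#' km-per-cell scale; there is no map projection.
#'
#' The remaining parameters control the climate generator, see
#' [generate_climate()].
#'
#' @param n_coarse_rows,n_coarse_cols Coarse grid dimensions. Worlds with at
#'   least 144 coarse cells are recommended so that virtual species can clear
#'   the 72-presence-cell minimum used for modelling.
#' @param fine_per_coarse Fine cells per coarse-cell side (so each coarse cell
#'   contains `fine_per_coarse^2` fine cells).
#' @param n_years Number of years of climate; 35 emulates a 1979-2013 span.
#' @param cell_size_km Side length of a coarse cell in km.
#' @param seed Integer seed; the world is deterministic given the config.
#' @param lat_range Nominal latitudes (degrees) assigned to the first and last
#'   coarse row; used for latitudinal-band summaries.
#' @param temp_equator Mean annual temperature (degrees C) at `lat_range[1]`
#'   and sea level.
#' @param temp_lat_gradient Cooling in degrees C per degree of nominal latitude.
#' @param lapse_rate Cooling in degrees C per km of elevation.
#' @param anomaly_sd_range Interannual temperature anomaly standard deviation
#'   (degrees C) at the equatorial and polar rows; interpolated linearly in
#'   between, so interannual temperature variability increases polewards.
#' @param anomaly_sd_col_amp Amplitude of a smooth sinusoidal column modulation
#'   of the anomaly SD (0 disables). This decorrelates interannual variability
#'   from the purely latitudinal mean-temperature gradient.
#' @param anomaly_sd_relief Extra interannual variability over rough terrain:
#'   multiplicative factor `1 + anomaly_sd_relief * sd(elevation within
#'   cell)/1000`. Couples the spatial- and temporal-variability fields the way
#'   mountain climates couple them.
#' @param relief_m Elevation spread (m) of fine cells inside the mountain
#'   block; 0 gives perfectly flat terrain everywhere.
#' @param base_elev_m Baseline elevation (m).
#' @param mountain_rows,mountain_cols Length-2 fractions of the coarse grid
#'   delimiting the contiguous mountain block.
#' @param prec_wet,prec_dry Long-term annual precipitation (mm) at the
#'   equatorial and polar rows (log-interpolated).
#' @param prec_lon_amp Amplitude (log scale) of a smooth longitudinal wet-dry
#'   gradient.
#' @param prec_spatial_sdlog SD (log scale) of static fine-scale precipitation
#'   heterogeneity within coarse cells.
#' @param prec_cv_range Range of the interannual log-scale SD of annual
#'   precipitation; varied smoothly across columns so different "regions" have
#'   different interannual precipitation variability.
#'
#' @return An object of class `world_config` (a validated list).
#' @seealso [generate_climate()], [generate_community()]
#' @export
world_config <- function(n_coarse_rows = 20, n_coarse_cols = 20,
                         fine_per_coarse = 8, n_years = 35,
                         cell_size_km = 50, seed = 1L,
                         lat_range = c(0, 70),
                         temp_equator = 28, temp_lat_gradient = 0.55,
                         lapse_rate = 6.5,
                         anomaly_sd_range = c(0.3, 1.2),
                         anomaly_sd_col_amp = 0.5,
                         anomaly_sd_relief = 0.5,
                         relief_m = 1200, base_elev_m = 100,
                         mountain_rows = c(0.3, 0.6),
                         mountain_cols = c(0.15, 0.4),
                         prec_wet = 2200, prec_dry = 400,
                         prec_lon_amp = 0.4,
                         prec_spatial_sdlog = 0.12,
                         prec_cv_range = c(0.08, 0.35)) {
  cfg <- list(
    n_coarse_rows = as.integer(n_coarse_rows),
    n_coarse_cols = as.integer(n_coarse_cols),
    fine_per_coarse = as.integer(fine_per_coarse),
    n_years = as.integer(n_years),
    cell_size_km = cell_size_km, seed = as.integer(seed),
    lat_range = lat_range,
    temp_equator = temp_equator, temp_lat_gradient = temp_lat_gradient,
    lapse_rate = lapse_rate,
    anomaly_sd_range = anomaly_sd_range,
    anomaly_sd_col_amp = anomaly_sd_col_amp,
    anomaly_sd_relief = anomaly_sd_relief,
    relief_m = relief_m, base_elev_m = base_elev_m,
    mountain_rows = mountain_rows, mountain_cols = mountain_cols,
    prec_wet = prec_wet, prec_dry = prec_dry,
    prec_lon_amp = prec_lon_amp,
    prec_spatial_sdlog = prec_spatial_sdlog,
    prec_cv_range = prec_cv_range
  )
  counts <- c("n_coarse_rows", "n_coarse_cols", "fine_per_coarse", "n_years")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("'", f, "' must be a single count >= 1", call. = FALSE)
  }
  if (cfg$cell_size_km <= 0) stop("'cell_size_km' must be > 0", call. = FALSE)
  if (any(cfg$anomaly_sd_range < 0) || diff(cfg$anomaly_sd_range) < 0)
    stop("'anomaly_sd_range' must be non-negative and non-decreasing", call. = FALSE)
  if (cfg$relief_m < 0) stop("'relief_m' must be >= 0", call. = FALSE)
  if (any(cfg$prec_cv_range < 0)) stop("'prec_cv_range' must be >= 0", call. = FALSE)
  class(cfg) <- "world_config"
  cfg
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config> ", x$n_coarse_rows, "x", x$n_coarse_cols,
      " coarse cells (", x$fine_per_coarse, "^2 fine cells each), ",
      x$n_years, " years, ", x$cell_size_km, " km cells, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# ---- grid geometry helpers ----------------------------------------------

n_cells <- function(config) config$n_coarse_rows * config$n_coarse_cols

#' Coarse-cell ids and coordinates
#'
#' Coarse cells are numbered row-major: `id = (row - 1) * n_coarse_cols + col`.
#'
#' @param config A [world_config()].
#' @return `cell_grid()` returns a data.frame with one row per coarse cell:
#'   `cell_id`, `row`, `col`, nominal latitude `lat` (degrees, row centre) and
#'   planar centre coordinates `x_km`, `y_km`.
#' @export
cell_grid <- function(config) {
  R <- config$n_coarse_rows; C <- config$n_coarse_cols
  row <- rep(seq_len(R), each = C)
  col <- rep(seq_len(C), times = R)
  data.frame(
    cell_id = seq_len(R * C), row = row, col = col,
    lat = cell_latitude(row, config),
    x_km = (col - 0.5) * config$cell_size_km,
    y_km = (row - 0.5) * config$cell_size_km
  )
}

#' @rdname cell_grid
#' @param row Coarse row index (vectorized).
#' @export
cell_latitude <- function(row, config) {
  R <- config$n_coarse_rows
  config$lat_range[1] + (row - 0.5) / R * diff(config$lat_range)
}

# coarse cell id of every fine cell, as an FR x FC integer matrix
fine_to_coarse_ids <- function(config) {
  f <- config$fine_per_coarse
  R <- config$n_coarse_rows; C <- config$n_coarse_cols
  cr <- ((seq_len(R * f) - 1L) %/% f) + 1L
  cc <- ((seq_len(C * f) - 1L) %/% f) + 1L
  outer(cr, cc, function(r, c) (r - 1L) * C + c)
}

# ---- climate cube ---------------------------------------------------------

#' Construct a fine-grain climate cube
#'
#' Low-level constructor, mostly useful for hand-built cubes in tests and for
#' real-data mode where the arrays come from external rasters. For synthetic
#' worlds use [generate_climate()].
#'
#' @param temperature,precipitation Numeric arrays `[year, fine_row, fine_col]`;
#'   precipitation must be strictly positive (annual sums).
#' @param elevation Numeric matrix `[fine_row, fine_col]` (m).
#' @param config The [world_config()] describing the grid geometry.
#' @param anomaly_sd,prec_sdlog Optional `[row, col]` matrices with the true
#'   injected interannual variability per coarse cell (recorded by the
#'   generator; used by variance-recovery checks).
#' @return An object of class `climate_cube`.
#' @export
climate_cube <- function(temperature, precipitation, elevation, config,
                         anomaly_sd = NULL, prec_sdlog = NULL) {
  stopifnot(inherits(config, "world_config"))
  FR <- config$n_coarse_rows * config$fine_per_coarse
  FC <- config$n_coarse_cols * config$fine_per_coarse
  dt <- dim(temperature)
  if (length(dt) != 3L || !all(dt == c(config$n_years, FR, FC)))
    stop("temperature must be a [n_years, ", FR, ", ", FC, "] array", call. = FALSE)
  if (!identical(dim(precipitation), dt))
    stop("temperature and precipitation must share dimensions", call. = FALSE)
  if (!identical(dim(elevation), dt[2:3]))
    stop("elevation must be a [", FR, ", ", FC, "] matrix", call. = FALSE)
  if (any(precipitation <= 0))
    stop("precipitation must be strictly positive everywhere", call. = FALSE)
  structure(
    list(temperature = temperature, precipitation = precipitation,
         elevation = elevation, config = config,
         anomaly_sd = anomaly_sd, prec_sdlog = prec_sdlog),
    class = "climate_cube"
  )
}

#' @export
print.climate_cube <- function(x, ...) {
  d <- dim(x$temperature)
  cat("<climate_cube> ", d[1], " years x ", d[2], " x ", d[3], " fine cells (",
      x$config$n_coarse_rows, " x ", x$config$n_coarse_cols, " coarse)\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic multi-year climate cube
#'
#' Builds annual temperature and precipitation fields at the fine grain,
#' emulating the large-scale structure of global climatologies:
#' \itemize{
#'   \item mean temperature decreases with nominal latitude (rows) and with
#'     elevation (lapse rate);
#'   \item a contiguous mountain block has high within-coarse-cell relief, so
#'     sub-grid spatial variability concentrates there;
#'   \item interannual temperature anomalies are drawn independently per year
#'     and coarse cell, with a standard deviation that increases monotonically
#'     from the equatorial to the polar row, modulated smoothly across columns
#'     and amplified over rough terrain;
#'   \item precipitation is log-normal (hence strictly positive) with a wet
#'     equator / dry pole gradient, a smooth longitudinal wet-dry gradient,
#'     static fine-scale heterogeneity, and an interannual coefficient of
#'     variation that varies by region (columns).
#' }
#' Anomalies are constant within a coarse cell, so the interannual variability
#' a downstream aggregation recovers at the coarse grain equals the injected
#' per-cell SD up to sampling error. The injected values are recorded in the
#' returned cube (`anomaly_sd`, `prec_sdlog`).
#'
#' The generator is fully deterministic given `config` (including its seed).
#'
#' @param config A [world_config()].
#' @return A [climate_cube()].
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "world_config"))
  R <- config$n_coarse_rows; C <- config$n_coarse_cols
  f <- config$fine_per_coarse; Y <- config$n_years
  FR <- R * f; FC <- C * f
  fr_of <- ((seq_len(FR) - 1L) %/% f) + 1L  # coarse row of each fine row
  fc_of <- ((seq_len(FC) - 1L) %/% f) + 1L  # coarse col of each fine col
  set.seed(config$seed)

  # elevation: flat baseline plus one rough mountain block
  mrows <- pmax(1L, ceiling(config$mountain_rows * R))
  mcols <- pmax(1L, ceiling(config$mountain_cols * C))
  mountain <- matrix(FALSE, R, C)
  mountain[mrows[1]:mrows[2], mcols[1]:mcols[2]] <- TRUE
  mountain_fine <- mountain[((seq_len(FR) - 1L) %/% f) + 1L,
                            ((seq_len(FC) - 1L) %/% f) + 1L, drop = FALSE]
  u <- matrix(stats::runif(FR * FC), FR, FC)
  # terrain roughness: maximal in the mountain block, elsewhere a gentle
  # rolling amplitude varying smoothly across columns (plains vs hill country)
  rcol <- 0.5 + 0.5 * sin(2 * pi * (seq_len(C) - 0.5) / C + pi)
  rough_fine <- matrix((0.03 + 0.12 * rcol)[fc_of], FR, FC, byrow = TRUE)
  rough_fine[mountain_fine] <- 1
  elev <- matrix(config$base_elev_m, FR, FC)
  elev[mountain_fine] <- config$base_elev_m + 0.8 * config$relief_m
  elev <- elev + config$relief_m * rough_fine * (u - 0.5)

  # within-coarse-cell elevation SD (drives the relief amplification)
  ids <- fine_to_coarse_ids(config)
  nfc <- f * f
  if (nfc > 1) {
    es <- rowsum(as.vector(elev), as.vector(ids))
    es2 <- rowsum(as.vector(elev)^2, as.vector(ids))
    relief_sd <- sqrt(pmax(0, (es2 - es^2 / nfc) / (nfc - 1)))
  } else relief_sd <- rep(0, R * C)
  relief_sd <- matrix(relief_sd, R, C, byrow = TRUE)

  # interannual temperature anomaly SD per coarse cell
  row_sd <- if (R > 1) {
    config$anomaly_sd_range[1] +
      (seq_len(R) - 1) / (R - 1) * diff(config$anomaly_sd_range)
  } else rep(mean(config$anomaly_sd_range), 1)
  col_mod <- 1 + config$anomaly_sd_col_amp *
    sin(2 * pi * (seq_len(C) - 0.5) / C)
  anomaly_sd <- outer(row_sd, col_mod) *
    (1 + config$anomaly_sd_relief * relief_sd / 1000)

  # temperature: latitudinal base - lapse-rate cooling + coarse-cell anomaly
  lat_fine <- config$lat_range[1] +
    (seq_len(FR) - 0.5) / FR * diff(config$lat_range)
  base_t <- matrix(config$temp_equator - config$temp_lat_gradient * lat_fine,
                   FR, FC) - config$lapse_rate * elev / 1000
  anom <- array(stats::rnorm(Y * R * C, sd = rep(anomaly_sd, each = Y)),
                dim = c(Y, R, C))
  temperature <- array(0, dim = c(Y, FR, FC))
  for (y in seq_len(Y))
    temperature[y, , ] <- base_t + anom[y, fr_of, fc_of, drop = FALSE][1, , ]

  # precipitation: log-normal with smooth gradients and regional interannual CV
  lat_norm <- (lat_fine - config$lat_range[1]) /
    max(diff(config$lat_range), .Machine$double.eps)
  meanlog_lat <- log(config$prec_wet) +
    lat_norm * (log(config$prec_dry) - log(config$prec_wet))
  lon_norm <- (seq_len(FC) - 0.5) / FC
  # fine-scale precipitation heterogeneity scales with terrain roughness
  # (orographic effect), so sub-grid spatial variability of precipitation
  # shares the smooth regional structure of the terrain
  sp_sd <- config$prec_spatial_sdlog *
    (0.5 + matrix(rcol[fc_of], FR, FC, byrow = TRUE))
  sp_sd[mountain_fine] <- 1.5 * config$prec_spatial_sdlog
  meanlog <- outer(meanlog_lat, config$prec_lon_amp * cos(2 * pi * lon_norm),
                   `+`) +
    matrix(stats::rnorm(FR * FC), FR, FC) * sp_sd
  cv_col <- config$prec_cv_range[1] + diff(config$prec_cv_range) *
    (1 + sin(2 * pi * (seq_len(C) - 0.5) / C + pi / 2)) / 2
  prec_sdlog <- matrix(cv_col, R, C, byrow = TRUE)
  panom <- array(stats::rnorm(Y * R * C, sd = rep(prec_sdlog, each = Y)),
                 dim = c(Y, R, C))
  precipitation <- array(0, dim = c(Y, FR, FC))
  for (y in seq_len(Y))
    precipitation[y, , ] <- exp(meanlog + panom[y, fr_of, fc_of, drop = FALSE][1, , ])

  climate_cube(temperature, precipitation, elev, config,
               anomaly_sd = anomaly_sd, prec_sdlog = prec_sdlog)
}
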