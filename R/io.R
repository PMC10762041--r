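#' @useDynLib soilphos, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Build and validate a run configuration
#'
#' @param nx,ny,n_countries,n_crops synthetic-world settings.
#' @param years simulation years.
#' @param mineralization_preset `"v1.1"` or `"v1.0"`.
#' @param p_c_inf steady-state solution P concentration, mgP/L.
#' @param n_days days per year.
#' @param ensemble_n,ensemble_seed ensemble settings.
#' @param frozen_drivers drivers held at mean values in ensembles.
#' @param seed world seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(nx = 10, ny = 10, n_countries = 4, n_crops = 3,
                       years = 1950:2018,
                       mineralization_preset = "v1.1", p_c_inf = 0.1,
                       n_days = 365, ensemble_n = 100, ensemble_seed = 1,
                       frozen_drivers = character(), seed = 1) {
  cfg <- list(nx = nx, ny = ny, n_countries = n_countries, n_crops = n_crops,
              years = years, mineralization_preset = mineralization_preset,
              p_c_inf = p_c_inf, n_days = n_days, ensemble_n = ensemble_n,
              ensemble_seed = ensemble_seed, frozen_drivers = frozen_drivers,
              seed = seed)
  stopifnot(p_c_inf >= 0, n_days >= 1, ensemble_n >= 1,
            mineralization_preset %in% c("v1.0", "v1.1"))
  world_config(nx, ny, n_countries, years, n_crops)  # validates grid/years
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as a key = value text file
#'
#' A copy with all defaults resolved is archived next to run outputs for
#' provenance.
#'
#' @param cfg a `run_config`.
#' @param path file path.
#' @return `read_config` returns a `run_config`.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (length(v) == 0) return("")
    if (is.numeric(v) && length(v) > 1 && all(diff(v) == 1)) {
      return(paste0(v[1], ":", v[length(v)]))
    }
    paste(v, collapse = ",")
  }
  lines <- vapply(names(cfg), function(k) paste0(k, " = ", fmt(cfg[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(sub("\\s*=\\s*", "\x01", lines), "\x01", fixed = TRUE)
  vals <- list()
  for (p in kv) {
    key <- trimws(p[1]); raw <- if (length(p) > 1) trimws(p[2]) else ""
    v <- if (raw == "") character() else if (grepl("^-?[0-9.]+:-?[0-9.]+$", raw)) {
      r <- as.numeric(strsplit(raw, ":")[[1]]); r[1]:r[2]
    } else {
      parts <- strsplit(raw, ",")[[1]]
      num <- suppressWarnings(as.numeric(parts))
      if (anyNA(num)) parts else num
    }
    vals[[key]] <- v
  }
  do.call(run_config, vals)
}

fmt_full <- function(x) sprintf("%.17g", x)

write_values_csv <- function(df, value_cols, path) {
  for (v in value_cols) df[[v]] <- fmt_full(df[[v]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write simulation (and optional ensemble CV) outputs
#'
#' One CSV with the annual pools per land cover (kgP ha-1), one with the
#' annual diagnostics/fluxes (kgP ha-1 yr-1), one with the cell land area,
#' and, when a CV array is supplied, one CSV with the coefficient of
#' variation on the same layout as the pools of the final year. Values are
#' serialized at full precision, so a write/read round trip is bit-exact.
#' A `units.json` file records the units of every file.
#'
#' @param sim a `simulation` from [run_simulation()].
#' @param dir output directory (created if needed).
#' @param cv optional CV array from [coefficient_of_variation()].
#' @param config optional `run_config` archived alongside.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(sim, dir, cv = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ny <- length(sim$years)
  n <- dim(sim$pools)[1]
  grid_df <- expand.grid(cell = seq_len(n), land_cover = c("crop", "grass"),
                         pool = pool_names(), year = sim$years,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid_df$value <- as.vector(sim$pools)
  paths <- file.path(dir, c("pools_mean.csv", "diagnostics_mean.csv",
                            "land_area.csv", "units.json"))
  write_values_csv(grid_df, "value", paths[1])
  di <- rbind(cbind(land_cover = "crop", sim$diagnostics$crop),
              cbind(land_cover = "grass", sim$diagnostics$grass))
  write_values_csv(di, setdiff(names(di), c("land_cover", "year", "cell")),
                   paths[2])
  write_values_csv(data.frame(cell = sim$grid$cell,
                              land_area_ha = sim$grid$land_area_ha),
                   "land_area_ha", paths[3])
  units <- list(pools_mean = "kgP ha-1", diagnostics_mean = "kgP ha-1 yr-1",
                land_area = "ha")
  written <- paths
  if (!is.null(cv)) {
    cv_df <- expand.grid(cell = seq_len(n), land_cover = c("crop", "grass"),
                         pool = pool_names(), KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    cv_df$value <- as.vector(cv)
    p <- file.path(dir, "pools_cv.csv")
    write_values_csv(cv_df, "value", p)
    units$pools_cv <- "1"
    written <- c(written, p)
  }
  jsonlite::write_json(units, paths[4], auto_unbox = TRUE)
  if (!is.null(config)) write_config(config, file.path(dir, "config.txt"))
  invisible(written)
}

#' Read simulation outputs written by [write_outputs()]
#'
#' @param dir directory written by [write_outputs()].
#' @return list with `pools` array (cells x land-cover x pool x years),
#'   `diagnostics`, `land_area`, `units` and optionally `cv`.
#' @export
read_outputs <- function(dir) {
  pools_df <- utils::read.csv(file.path(dir, "pools_mean.csv"))
  years <- sort(unique(pools_df$year))
  n <- max(pools_df$cell)
  pools <- array(as.numeric(pools_df$value), c(n, 2, 7, length(years)),
                 dimnames = list(NULL, c("crop", "grass"), pool_names(),
                                 years))
  out <- list(pools = pools,
              diagnostics = utils::read.csv(file.path(dir, "diagnostics_mean.csv")),
              land_area = utils::read.csv(file.path(dir, "land_area.csv")),
              units = jsonlite::read_json(file.path(dir, "units.json"),
                                          simplifyVector = TRUE))
  cvp <- file.path(dir, "pools_cv.csv")
  if (file.exists(cvp)) {
    cv_df <- utils::read.csv(cvp)
    out$cv <- array(as.numeric(cv_df$value), c(n, 2, 7),
                    dimnames = list(NULL, c("crop", "grass"), pool_names()))
  }
  out
}
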