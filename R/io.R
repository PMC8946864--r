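# Unit-aware length parsing: numeric values are metres; strings may carry an
# explicit unit suffix ("13 mm", "1.3cm", "0.013 m").
.parse_length <- function(x, key) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("config key '%s': length must be a single positive number", key))
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("config key '%s': length must be a number (metres) or a string with unit", key))
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(mm|cm|m)\\s*$", x))[[1L]]
  if (length(m) != 3L)
    stop(sprintf("config key '%s': cannot parse length '%s' (use e.g. '13 mm', '1.3 cm', '0.013 m')",
                 key, x))
  v <- as.numeric(m[2L])
  if (!is.finite(v) || v <= 0)
    stop(sprintf("config key '%s': length must be positive", key))
  v * switch(m[3L], mm = 1e-3, cm = 1e-2, m = 1)
}

#' Parse a run configuration file
#'
#' Reads a YAML (or JSON, by file extension) configuration describing a run:
#' \preformatted{
#' implant:
#'   preset: implant_A          # or explicit length/diffusivity
#'   # length: 13 mm            # mm/cm/m suffixes accepted
#'   # diffusivity: 2e-6        # m^2/s
#' load:
#'   t_hot: 60                  # degC, default 60
#'   t_body: 37                 # degC, default 37
#'   exposure_time: 2           # s, required
#' series:
#'   n_terms: 200
#'   resonance_tol: 1e-8
#' grid:
#'   times: [0, 5, 10]          # s
#'   positions: [0, 0.0065]     # m; or named_points: [B1, B2, B3]
#' }
#' Exactly one of `preset` and the explicit `length`/`diffusivity` pair must
#' be present.  Unknown keys, missing mandatory fields and malformed units
#' are each rejected with a diagnostic naming the offending key.
#'
#' @param path path to the configuration file.
#' @return An object of class `"run_config"`: list with `model`, `load`,
#'   `cfg`, and (if a grid was given) `grid`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known_top <- c("implant", "load", "series", "grid")
  extra <- setdiff(names(raw), known_top)
  if (length(extra))
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))

  imp <- raw$implant
  if (is.null(imp)) stop("config key 'implant' is mandatory")
  extra <- setdiff(names(imp), c("preset", "length", "diffusivity", "label"))
  if (length(extra))
    stop(sprintf("unknown key(s) under 'implant': %s", paste(extra, collapse = ", ")))
  has_preset <- !is.null(imp$preset)
  has_explicit <- !is.null(imp$length) || !is.null(imp$diffusivity)
  if (has_preset && has_explicit)
    stop("'implant' must contain either 'preset' or explicit 'length'/'diffusivity', not both")
  if (has_preset) {
    model <- preset_model(imp$preset)
  } else {
    if (is.null(imp$length) || is.null(imp$diffusivity))
      stop("'implant' needs both 'length' and 'diffusivity' when no 'preset' is given")
    model <- implant_model(.parse_length(imp$length, "implant.length"),
                           imp$diffusivity,
                           label = if (is.null(imp$label)) "" else imp$label)
  }

  ld <- raw$load
  extra <- setdiff(names(ld), c("t_hot", "t_body", "exposure_time"))
  if (length(extra))
    stop(sprintf("unknown key(s) under 'load': %s", paste(extra, collapse = ", ")))
  if (is.null(ld$exposure_time))
    stop("config key 'load.exposure_time' is mandatory (seconds)")
  load <- thermal_load(
    t_hot = if (is.null(ld$t_hot)) 60 else ld$t_hot,
    t_body = if (is.null(ld$t_body)) 37 else ld$t_body,
    exposure_time = ld$exposure_time)

  sr <- raw$series
  extra <- setdiff(names(sr), c("n_terms", "resonance_tol"))
  if (length(extra))
    stop(sprintf("unknown key(s) under 'series': %s", paste(extra, collapse = ", ")))
  cfg <- series_config(
    n_terms = if (is.null(sr$n_terms)) 200L else sr$n_terms,
    resonance_tol = if (is.null(sr$resonance_tol)) 1e-8 else sr$resonance_tol)

  grid <- NULL
  if (!is.null(raw$grid)) {
    g <- raw$grid
    extra <- setdiff(names(g), c("times", "positions", "named_points"))
    if (length(extra))
      stop(sprintf("unknown key(s) under 'grid': %s", paste(extra, collapse = ", ")))
    if (is.null(g$times)) stop("config key 'grid.times' is mandatory when 'grid' is given")
    if (!is.null(g$positions) && !is.null(g$named_points))
      stop("'grid' must contain either 'positions' or 'named_points', not both")
    pos <- if (!is.null(g$named_points))
      sort(vapply(g$named_points, location_y, numeric(1L), model = model))
    else if (!is.null(g$positions)) as.numeric(unlist(g$positions))
    else stop("'grid' needs 'positions' or 'named_points'")
    grid <- evaluation_grid(as.numeric(unlist(g$times)), pos)
  }

  structure(list(model = model, load = load, cfg = cfg, grid = grid),
            class = "run_config")
}

.fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Write a temperature field to CSV or JSON
#'
#' CSV output is long-format with header `t_s, y_m, temperature_C, method`
#' in time-outer row order, values serialised at 17 significant digits so a
#' read-back reproduces the field exactly.  JSON output carries the grid,
#' the value matrix and a full provenance block (model, load, series or
#' finite-difference configuration).
#'
#' @param field a `"temperature_field"`.
#' @param path output file path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_field()]
#' @export
write_field <- function(field, path, format = c("csv", "json")) {
  stopifnot(inherits(field, "temperature_field"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(
      t_s = .fmt17(rep(field$times, each = length(field$positions))),
      y_m = .fmt17(rep(field$positions, times = length(field$times))),
      temperature_C = .fmt17(as.vector(t(field$values))),
      method = field$method)
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("failed to write field to '%s': %s", path, conditionMessage(ok)))
  } else {
    obj <- list(
      times = field$times, positions = field$positions,
      values = field$values, method = field$method,
      provenance = list(
        model = field$model[c("length", "diffusivity", "label")],
        load = field$load[c("t_hot", "t_body", "exposure_time")],
        config = unclass(field$config)))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a temperature field written by [write_field()]
#'
#' @param path a CSV file produced by [write_field()].
#' @param model,load,config optional provenance to attach; a field read from
#'   CSV alone carries `NULL` provenance.
#' @return A `"temperature_field"`.
#' @export
read_field <- function(path, model = NULL, load = NULL, config = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "y_m", "temperature_C", "method")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' is not a field CSV (expected columns %s)",
                 path, paste(need, collapse = ", ")))
  times <- unique(df$t_s)
  positions <- unique(df$y_m)
  V <- matrix(df$temperature_C, nrow = length(times),
              ncol = length(positions), byrow = TRUE)
  structure(
    list(times = times, positions = positions, values = V,
         method = df$method[1L], model = model, load = load, config = config),
    class = "temperature_field")
}

#' Generate deterministic golden fixtures
#'
#' Writes, into `output_dir`, one CSV per standard figure dataset
#' (`fig2.csv` ... `fig7.csv`, 17-significant-digit values) and
#' `presets.json` holding every preset's length, diffusivity and intrinsic
#' time.  The artifact is fully deterministic: repeated runs produce
#' byte-identical files.
#'
#' @param output_dir directory to write into (created if absent).
#' @param cfg a [series_config()].
#' @return Character vector of files written, invisibly.
#' @export
generate_golden_fixtures <- function(output_dir, cfg = series_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (id in 2:7) {
    df <- figure_dataset(id, cfg)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], .fmt17)
    f <- file.path(output_dir, sprintf("fig%d.csv", id))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  presets <- lapply(names(.preset_table), function(nm) {
    m <- preset_model(nm)
    list(name = nm, length_m = m$length, diffusivity_m2_s = m$diffusivity,
         intrinsic_time_s = intrinsic_time(m))
  })
  f <- file.path(output_dir, "presets.json")
  jsonlite::write_json(presets, f, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  written <- c(written, f)
  invisible(written)
}
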