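#' Pipeline parameters
#'
#' Returns the full list of tunable parameters of the staging pipeline with
#' their defaults. All downstream functions that take a `params` argument
#' accept the output of this function; individual entries can be overridden
#' by name.
#'
#' The defaults encode the staging workflow's standard values
#' (initial threshold at 20% of Otsu's threshold; 30 middle-axis sample
#' points; 10% band foreground fraction for the oocyte boundary; 12 sectors
#' for the follicle distribution; centripetal band width 0.8 standard
#' deviations along the major axis) and documented implementation choices
#' elsewhere (average-filter window, Chan-Vese energy weights and
#' initialization, shrink factors, decision thresholds).
#'
#' @param ... named overrides of individual defaults.
#'
#' @return A named list of parameters:
#' \describe{
#'   \item{otsu_scale}{fraction of Otsu's threshold used for the initial
#'     binarization (default 0.2).}
#'   \item{filter_window}{odd window size (px) of the average filter used to
#'     bridge nearby foreground regions (default 15).}
#'   \item{cv_mu}{Chan-Vese boundary-length weight (default 0.15; small
#'     follicle nuclei span only a few pixels, and a heavier length penalty
#'     can swallow them).}
#'   \item{cv_lambda1,cv_lambda2}{inside/outside fidelity weights (default 1).}
#'   \item{cv_max_iter}{iteration cap of the level-set evolution (default 400).}
#'   \item{cv_init_radius,cv_init_spacing}{radius and spacing (px) of the
#'     grid of initialization circles (defaults 3.5 and 10; the spacing
#'     must be tight enough that every nucleus overlaps the initial
#'     interface, since a level set cannot nucleate new components).}
#'   \item{shrink_orient}{radial shrink factor used when orienting the
#'     posterior-anterior axis (default 0.85).}
#'   \item{shrink_follicle}{radial shrink factor used when separating
#'     follicle cells (default 0.80).}
#'   \item{n_axis_points}{number of middle-axis sample points (default 30).}
#'   \item{oocyte_frac_threshold}{band foreground fraction defining the
#'     oocyte boundary (default 0.10).}
#'   \item{n_sectors}{number of angular sectors for the follicle-cell
#'     distribution (default 12).}
#'   \item{polytene_median_fragments}{median watershed fragments per nucleus
#'     at or above which a chamber is called blob-positive (default 3).}
#'   \item{centripetal_bandwidth_sds}{detection-band width as a multiple of
#'     the SD along the major axis (default 0.8).}
#'   \item{centripetal_rim_frac}{rim-proximity threshold for centripetal
#'     cells, as a fraction of the SD along the minor axis (default 0.15).}
#'   \item{centripetal_min_cells}{centripetal-cell count at or above which a
#'     chamber is called stage 10B (default 2).}
#'   \item{pixel_size}{fallback physical pixel size in micrometres, used when
#'     an image file carries no calibration (default `NA`).}
#' }
#' @export
#' @examples
#' p <- chamber_params(otsu_scale = 0.25)
#' p$otsu_scale
chamber_params <- function(...) {
  defaults <- list(
    otsu_scale = 0.2,
    filter_window = 15L,
    cv_mu = 0.15,
    cv_lambda1 = 1,
    cv_lambda2 = 1,
    cv_max_iter = 400L,
    cv_init_radius = 3.5,
    cv_init_spacing = 10,
    shrink_orient = 0.85,
    shrink_follicle = 0.80,
    n_axis_points = 30L,
    oocyte_frac_threshold = 0.10,
    n_sectors = 12L,
    polytene_median_fragments = 3,
    centripetal_bandwidth_sds = 0.8,
    centripetal_rim_frac = 0.15,
    centripetal_min_cells = 2L,
    pixel_size = NA_real_
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults <- modifyList(defaults, overrides)
  }
  defaults
}

#' Read pipeline parameters from a flat configuration file
#'
#' Parses a flat TOML-style `key = value` file (comments starting with `#`
#' and blank lines ignored; values may be numbers, `true`/`false`, or quoted
#' strings) and merges it onto [chamber_params()] defaults.
#'
#' @param path path to the configuration file.
#' @return A parameter list as from [chamber_params()].
#' @export
read_chamber_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]
    val <- trimws(m[3])
    if (grepl('^".*"$', val) || grepl("^'.*'$", val)) {
      val <- substr(val, 2, nchar(val) - 1)
    } else if (tolower(val) %in% c("true", "false")) {
      val <- as.logical(val)
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    kv[[key]] <- val
  }
  do.call(chamber_params, kv)
}
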