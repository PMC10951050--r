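#' Read or write a preprocessing configuration (YAML)
#'
#' The configuration collects every tiling/QC/stain threshold exposed by the
#' preprocessing stage so runs are reproducible from one file:
#' \code{tile_edge}, \code{min_tumor_fraction}, the \code{\link{qc_tile}}
#' thresholds (\code{bg_sat}, \code{bg_val}, \code{max_bg_fraction},
#' \code{min_laplacian_var}) and the \code{\link{estimate_stains}}
#' parameters (\code{od_threshold}, \code{angle_percentile},
#' \code{conc_percentile}).  Missing keys fall back to the documented
#' defaults.
#'
#' @param path YAML file path.
#' @param config Named list of overrides (write).
#' @return The configuration as a named list.
#' @export
read_prep_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_prep_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

#' @rdname read_prep_config
#' @export
write_prep_config <- function(config, path) {
  yaml::write_yaml(utils::modifyList(default_prep_config(), config), path)
  invisible(path)
}

#' @rdname read_prep_config
#' @export
default_prep_config <- function() {
  list(tile_edge = 512, min_tumor_fraction = 0.5,
       bg_sat = 0.08, bg_val = 220, max_bg_fraction = 0.5,
       min_laplacian_var = 15,
       od_threshold = 0.15, angle_percentile = 1, conc_percentile = 99)
}
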