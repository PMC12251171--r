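#' Write sweep outputs
#'
#' Writes a completed sweep in portable plain-text form: the sweep table as
#' CSV with a stable column order, density maps as tab-separated matrices,
#' per-configuration photon/detection counts, and run metadata (config,
#' seeds, package version) as JSON.  Reruns with the same configuration
#' produce byte-identical files.
#'
#' @param table a \code{ppg_sweep} data frame
#' @param out_dir output directory (created if missing)
#' @param maps optional named list of \code{\link{run_density_map}}
#'   objects
#' @param metadata optional named list merged into the metadata JSON
#' @return The output directory, invisibly.
#' @export
write_outputs <- function(table, out_dir, maps = NULL, metadata = list()) {
  stopifnot(is.data.frame(table))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cols <- c("wavelength", "distance", "theta_s", "theta_d", "S_bar",
            "S_se", "S_bar_prime", "dpf", "dpf_se", "mean_max_depth",
            "depth_se", "n_detected", "n_photons")
  cols <- cols[cols %in% names(table)]
  utils::write.csv(as.data.frame(table)[, cols],
                   file.path(out_dir, "sweep.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(table)[, c("wavelength", "distance",
                                            "theta_s", "theta_d",
                                            "n_detected", "n_photons")],
                   file.path(out_dir, "counts.csv"), row.names = FALSE)
  if (!is.null(maps)) {
    for (nm in names(maps)) {
      m <- maps[[nm]]
      stopifnot(inherits(m, "ppg_density"))
      utils::write.table(m$map,
                         file.path(out_dir, paste0("density_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  ctl <- attr(table, "control")
  cfg <- attr(table, "config")
  meta <- c(list(
    package = "ppgmc",
    version = as.character(utils::packageVersion("ppgmc")),
    control = if (!is.null(ctl)) unclass(ctl),
    grid = if (!is.null(cfg)) list(wavelengths = cfg$wavelengths,
                                   distances = cfg$distances,
                                   theta_s = cfg$theta_s,
                                   theta_d = cfg$theta_d)),
    metadata)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a run configuration file
#'
#' Parses a YAML run file describing scene, sweep grid and control
#' parameters (the format used by the command-line interface) into a
#' \code{\link{sweep_config}}.
#'
#' @param path YAML file path
#' @return A \code{\link{sweep_config}}.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read run configuration files")
  y <- yaml::read_yaml(path)
  ctl_args <- y$control
  ctl <- if (is.null(ctl_args)) run_control()
         else do.call(run_control, ctl_args)
  sweep_config(
    wavelengths = if (is.null(y$wavelengths)) c(520, 637, 940)
                  else unlist(y$wavelengths),
    distances = if (is.null(y$distances)) c(2, 3, 4, 5)
                else unlist(y$distances),
    theta_s = if (is.null(y$theta_s)) c(0, 15, 25, 35, 45, 55)
              else unlist(y$theta_s),
    theta_d = if (is.null(y$theta_d)) c(0, 25, 35, 45, 55)
              else unlist(y$theta_d),
    control = ctl,
    scene_args = if (is.null(y$scene)) list() else y$scene)
}
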