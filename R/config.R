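# Pipeline configuration: one object grouping the conversion, correction,
# gamma and plane-extraction settings, round-trippable through YAML.

#' Pipeline configuration
#'
#' @param conversion a [conversion_config()].
#' @param corrections a [correction_config()].
#' @param gamma list with `criteria` (list of [gamma_criteria()]; the first
#'   is the primary, verdict-driving set) and `threshold_pct` (per-beam
#'   passing threshold, percent).
#' @param plane list with `spacing_mm` (analysis-plane lattice spacing) and
#'   `margin_mm` (margin around the CIAO bounding box).
#' @param point_tolerance_pct tolerance of the per-beam point-dose
#'   cross-check, percent.
#' @return an object of class `imu_config`.
#' @export
imu_config <- function(conversion = conversion_config(),
                       corrections = correction_config(),
                       gamma = list(criteria = list(gamma_criteria(3, 3),
                                                    gamma_criteria(3, 2)),
                                    threshold_pct = 95),
                       plane = list(spacing_mm = 1, margin_mm = 20),
                       point_tolerance_pct = 5) {
  stopifnot(inherits(conversion, "conversion_config"),
            inherits(corrections, "correction_config"),
            length(gamma$criteria) >= 1,
            all(vapply(gamma$criteria, inherits, TRUE, "gamma_criteria")),
            gamma$threshold_pct > 0, gamma$threshold_pct <= 100,
            plane$spacing_mm > 0, plane$margin_mm >= 0,
            point_tolerance_pct > 0)
  structure(list(conversion = conversion, corrections = corrections,
                 gamma = gamma, plane = plane,
                 point_tolerance_pct = point_tolerance_pct),
            class = "imu_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Sections `conversion`, `corrections`, `gamma`, `plane` and
#' `point_tolerance_pct` override the package defaults; omitted keys keep
#' their default values.
#'
#' @param path YAML file.
#' @return an [imu_config()].
#' @export
read_imu_config <- function(path) {
  y <- yaml::read_yaml(path)
  conv <- do.call(conversion_config, y$conversion %||% list())
  corr <- do.call(correction_config, y$corrections %||% list())
  gm <- imu_config()$gamma
  if (!is.null(y$gamma)) {
    if (!is.null(y$gamma$criteria))
      gm$criteria <- lapply(y$gamma$criteria, function(cr)
        do.call(gamma_criteria, cr))
    if (!is.null(y$gamma$threshold_pct))
      gm$threshold_pct <- y$gamma$threshold_pct
  }
  pl <- imu_config()$plane
  if (!is.null(y$plane)) pl[names(y$plane)] <- y$plane
  imu_config(conversion = conv, corrections = corr, gamma = gm, plane = pl,
             point_tolerance_pct = y$point_tolerance_pct %||% 5)
}

#' Write a pipeline configuration to a YAML file
#'
#' @param config an [imu_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_imu_config <- function(config, path) {
  stopifnot(inherits(config, "imu_config"))
  y <- list(
    conversion = unclass(config$conversion),
    corrections = unclass(config$corrections),
    gamma = list(criteria = lapply(config$gamma$criteria, unclass),
                 threshold_pct = config$gamma$threshold_pct),
    plane = config$plane,
    point_tolerance_pct = config$point_tolerance_pct)
  y$conversion$energy_relabel <- as.list(config$conversion$energy_relabel)
  yaml::write_yaml(y, path)
  invisible(path)
}
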