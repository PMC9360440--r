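#' Run configuration
#'
#' YAML configuration shared by the command-line tools: beam blocks, pupil
#' grid, imaging and restoration parameters. Unknown keys are rejected so a
#' typo cannot silently fall back to a default, and every run can re-emit the
#' fully resolved configuration for reproducibility.
#'
#' @name run-config
NULL

config_schema <- function() {
  list(
    beams = list(type = NA, na = NA, na_max = NA, na_min = NA,
                 fill_factor = NA, side_beamlet_kx = NA,
                 amplitude_scale = NA),
    grid = list(n = NA, k_max = NA),
    n_medium = NA,
    imaging = list(density = NA, sbr = NA, brightness = NA, seeds = NA,
                   volume_um = NA, voxel_um = NA, psf_counts = NA),
    restoration = list(rl_convergence_fraction = NA, wiener_nsr = NA,
                       dark_current = NA, max_iter = NA),
    output = list(dir = NA),
    log_level = NA
  )
}

check_keys <- function(x, schema, path = "") {
  bad <- setdiff(names(x), names(schema))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "))
  for (nm in names(x)) {
    sub <- schema[[nm]]
    if (is.list(sub) && is.list(x[[nm]])) {
      if (nm == "beams") {
        for (i in seq_along(x$beams))
          check_keys(x$beams[[i]], sub, sprintf("beams[%d].", i))
      } else {
        check_keys(x[[nm]], sub, paste0(nm, "."))
      }
    }
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' @param path YAML file.
#' @return Named list with defaults filled in (`grid`, `n_medium`,
#'   `restoration`); errors on unknown keys.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 resolves a bare `n` key as boolean FALSE; map it back so the
  # grid sample count can be written unquoted
  if (!is.null(cfg$grid)) {
    names(cfg$grid)[names(cfg$grid) %in% c("FALSE", "no")] <- "n"
  }
  check_keys(cfg, config_schema())
  if (is.null(cfg$grid)) cfg$grid <- list()
  if (is.null(cfg$grid$n)) cfg$grid$n <- 1025L
  if (is.null(cfg$grid$k_max)) cfg$grid$k_max <- 1
  if (is.null(cfg$n_medium)) cfg$n_medium <- 1.33
  if (is.null(cfg$restoration)) cfg$restoration <- list()
  r <- cfg$restoration
  if (is.null(r$rl_convergence_fraction)) r$rl_convergence_fraction <- 0.25
  if (is.null(r$wiener_nsr)) r$wiener_nsr <- 0.005
  if (is.null(r$dark_current)) r$dark_current <- 0
  if (is.null(r$max_iter)) r$max_iter <- 500L
  cfg$restoration <- r
  cfg
}

#' Write a resolved configuration copy
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Beam spec from a configuration beam block
#'
#' @param block named list with at least `type`.
#' @export
beam_from_config <- function(block) {
  args <- block
  args$beam_type <- args$type
  args$type <- NULL
  do.call(beam_spec, args[!vapply(args, is.null, logical(1L))])
}
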