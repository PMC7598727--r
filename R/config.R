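#' Analysis configuration
#'
#' Bundles every tunable constant of the analysis pipeline with its
#' default: the linkage cutoff (nm), the reference-spacing fit constants
#' and cutoff scaling factors of the ribbon assignment, the histogram
#' bin width, the beta dihedral region, the cluster-curve smoothing
#' window, the critical size and its radius of gyration for the shifted
#' scaling fit, the RNG seed, and the declared XYZ length unit.
#' The configuration round-trips unchanged through YAML serialization.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `ft_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    cutoff = 0.5,
    a_fit = 9.6192,
    b_fit = -0.0009,
    s_par = 0.88,
    s_perp = 0.47,
    bin_width = 0.02,
    beta_phi = c(-180, -45),
    beta_psi = list(c(45, 180), c(-180, -120)),
    smooth_window = 5,
    m_star = 25,
    rg_star = 1.332,
    seed = 1,
    xyz_unit = "nm",
    axis_selection = "side_chain"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  for (key in c("cutoff", "a_fit", "s_par", "s_perp", "bin_width", "rg_star")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("configuration error: '", key, "' must be a positive number", call. = FALSE)
    }
  }
  structure(cfg, class = c("ft_config", "list"))
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$beta_psi)) raw$beta_psi <- lapply(raw$beta_psi, as.numeric)
  do.call(analysis_config, raw)
}

#' @rdname analysis_config
#' @param config An `ft_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_beta_region <- function(config) {
  list(phi = config$beta_phi, psi = config$beta_psi)
}

# One-line "# key=value" header block echoed into CSV outputs.
config_header <- function(config) {
  flat <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.list(v)) v <- paste(vapply(v, paste, "", collapse = ":"), collapse = ";")
    paste0("# ", k, "=", paste(v, collapse = ":"))
  }, "")
  unname(flat)
}
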