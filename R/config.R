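#' Default pipeline configuration
#'
#' All tunables in one list. Sizes are in bp, scale factors are
#' multiplicative track-unit ratios, `alpha`/`beta` live in log2 space.
#'
#' \describe{
#'   \item{bin_size}{Genome bin width for classification and output (50).}
#'   \item{flank}{Half-width of the profile window at reference sites (1000);
#'     the aggregate profile spans center +/- flank at `profile_bin`
#'     resolution.}
#'   \item{profile_bin}{Bin width inside profile windows (50).}
#'   \item{signal_frac}{Fraction of the profile window treated as the central
#'     signal region (0.2, i.e. center +/- 200 bp at defaults).}
#'   \item{flank_inner, flank_outer}{Background flanks: bins at
#'     \[flank_inner, flank_outer) bp from the site center on both sides
#'     (2000-4000).}
#'   \item{pseudocount}{Global pseudocount shared by all log2 operations (1).}
#'   \item{chi2_quantile}{Mahalanobis outlier cutoff quantile, chi-squared
#'     2 df (0.99).}
#'   \item{two_pass}{Re-estimate Mahalanobis statistics after removal
#'     (FALSE).}
#'   \item{subtract_background}{Background-subtract central means when
#'     estimating sfsig (TRUE).}
#'   \item{mode}{"two-tier", "background-only" or "single-factor".}
#'   \item{sfbg, sfsig, alpha, beta, noise}{Optional user overrides of the
#'     five parameters (NULL = estimate).}
#'   \item{stat}{Differential statistic: "fc", "poisson" or "both".}
#'   \item{fc_cutoff}{Fold-change threshold, boundary inclusive (2).}
#'   \item{q}{BH-adjusted significance level for the Poisson test (0.05).}
#'   \item{adjust}{Apply Benjamini-Hochberg adjustment (TRUE).}
#' }
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(bin_size = 50L, flank = 1000L, profile_bin = 50L, signal_frac = 0.2,
       flank_inner = 2000L, flank_outer = 4000L, pseudocount = 1,
       chi2_quantile = 0.99, two_pass = FALSE, subtract_background = TRUE,
       mode = "two-tier", sfbg = NULL, sfsig = NULL, alpha = NULL,
       beta = NULL, noise = NULL,
       stat = "both", fc_cutoff = 2, q = 0.05, adjust = TRUE)
}

# keys that may legitimately be NULL (parameter overrides)
.override_keys <- c("sfbg", "sfsig", "alpha", "beta", "noise")

#' Resolve a run configuration from defaults, a config file and flags
#'
#' Precedence is flag > config file > default. Unknown keys are an error
#' (with a nearest-name suggestion); values are coerced to the default's
#' type, erroring on mismatch. Parameter-override keys accept numbers or
#' NULL.
#'
#' @param config_file Optional path to a `key: value` text file (one pair
#'   per line, `#` comments allowed).
#' @param flags Named list of command-line overrides.
#' @param defaults The base configuration.
#' @return The resolved configuration list, with a `source` attribute naming
#'   where each key came from.
#' @export
resolve_config <- function(config_file = NULL, flags = list(),
                           defaults = default_config()) {
  cfg <- defaults
  src <- stats::setNames(rep("default", length(cfg)), names(cfg))
  apply_layer <- function(layer, origin) {
    for (key in names(layer)) {
      if (!key %in% names(defaults)) {
        sugg <- names(defaults)[which.min(utils::adist(key, names(defaults)))]
        stop("unknown configuration key '", key, "' (did you mean '",
             sugg, "'?)")
      }
      cfg[[key]] <<- coerce_config_value(key, layer[[key]], defaults[[key]])
      src[key] <<- origin
    }
  }
  if (!is.null(config_file)) apply_layer(read_config_file(config_file), "config-file")
  flags <- flags[!vapply(flags, is.null, logical(1))]
  apply_layer(flags, "flag")
  structure(cfg, source = src)
}

coerce_config_value <- function(key, value, default) {
  if (key %in% .override_keys) {
    if (is.null(value) || (is.character(value) && value %in% c("NULL", "none"))) {
      return(NULL)
    }
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("key '", key, "' expects a number, got '", value, "'")
    return(v)
  }
  if (is.character(default)) return(as.character(value))
  if (is.logical(default)) {
    v <- as.logical(value)
    if (is.na(v)) stop("key '", key, "' expects TRUE/FALSE, got '", value, "'")
    return(v)
  }
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v)) stop("key '", key, "' expects a number, got '", value, "'")
  if (is.integer(default)) v <- as.integer(v)
  v
}

# Minimal `key: value` reader (YAML-like flat mapping; no nesting).
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", lines[i], "'")
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write the resolved configuration next to a run's outputs
#'
#' @param config A resolved configuration from [resolve_config()].
#' @param path Output path (conventionally `run_config.resolved`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  src <- attr(config, "source")
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s: %s  # %s", k,
            if (is.null(v)) "NULL" else as.character(v),
            if (!is.null(src)) src[[k]] else "default")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
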