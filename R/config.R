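# Flat key=value analysis configuration.

config_defaults <- function() {
  list(
    sd_cutoff = 0, maf_min = 0.01, window_bp = 1e6,
    fdr_level = 0.05, n_permutations = 100, n_null_sets = 1000,
    gwas_p_threshold = 1e-4, proxy_r2 = 0.8, prune_r2 = 0.7,
    prune_window_bp = 5e5, maf_bin_width = 0.05, opportunity_bin_width = 50,
    chrom_subset = "", seed = 1,
    n_samples = 339, effect_per_allele = 5, residual_sd = 15,
    target_power = 0.8, scenario = "planted_meqtl", out_dir = "."
  )
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key=value`; `#` starts a comment. Unknown keys are
#' kept verbatim (paths etc.); known numeric keys are coerced.
#'
#' @param path Config file path.
#' @return Named list merged over the package defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) mk_stop("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) mk_stop("malformed config line: '%s'", lines[bad][1L])
  vals <- lapply(kv, function(x) trimws(paste(x[-1L], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  cfg <- config_defaults()
  num_keys <- names(Filter(is.numeric, cfg))
  for (k in names(vals)) {
    cfg[[k]] <- if (k %in% num_keys) as.numeric(vals[[k]]) else vals[[k]]
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (k in c("fdr_level", "gwas_p_threshold", "proxy_r2", "prune_r2"))
    stopifnot_scalar_prob(cfg[[k]], k)
  for (k in c("window_bp", "prune_window_bp"))
    if (cfg[[k]] <= 0) mk_stop("'%s' must be > 0", k)
  if (cfg$seed != round(cfg$seed)) mk_stop("seed must be an integer")
  invisible(cfg)
}

config_chroms <- function(cfg) {
  if (!nzchar(cfg$chrom_subset)) NULL else
    trimws(strsplit(cfg$chrom_subset, ",")[[1L]])
}
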