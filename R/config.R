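#' Default threshold configuration
#'
#' Returns the full named list of tunable thresholds used by the index
#' computations, the zone segmentation and the criterion battery. The
#' ATS/ERS-printed values (back-extrapolated volume 0.15 L / 5% of FVC,
#' end-of-test volume 0.025 L over 1 s, forced expiratory time 6 s for
#' adults, repeatability 0.15 L) are defaults here; every threshold for the
#' novel shape criteria is a calibration artifact of this package, chosen so
#' that clean synthetic maneuvers pass and decisively defective ones fail
#' (see the package vignette), and all are overridable via [read_config()]
#' or by editing the returned list.
#'
#' @param ... Named overrides, e.g. `default_config(fet_min = 3)`.
#' @return Named list of class `spiro_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # ingest / preprocessing
    resample_rate    = 100,    # Hz
    smoothing_window = 0.05,   # s, local-quadratic smoothing for derivatives

    # zone segmentation
    onset_fraction = 0.02,     # onset = first flow >= this fraction of PEF
    z2_fraction    = 0.80,     # peak zone = flow >= this fraction of PEF
    z4_window      = 1.0,      # s, end-of-test zone length

    # traditional ATS/ERS thresholds
    bev_abs        = 0.15,     # L
    bev_frac       = 0.05,     # fraction of FVC
    eotv_threshold = 0.025,    # L
    eotv_window    = 1.0,      # s
    fet_min        = 6.0,      # s (adult rule)
    repeatability_delta = 0.15, # L

    # Z2: peak timing and shape
    peft_max = 0.20,           # s, C3 peak too late
    peft_min = 0.02,           # s, C4 peak too early
    flat_peak_ratio     = 0.90, # fraction of PEF defining the "flat" band
    flat_peak_width_max = 0.30, # s, C5a/C5b
    bimodal_prominence  = 0.10, # fraction of PEF, C5c
    c6_threshold        = 1.00, # 1/s: PEF/FVC ratio floor, C6 (slow peak)

    # Z1: ascent regularity
    c1_signflip_max = 4,       # sign changes of d2F/dV2 on the ascent
    c1_amp_floor    = 0.05,    # normalized curvature amplitude floor
    c2a_trend_window = 0.07,   # s, trend-removal window for the C2a residual
    c2a_resid_max   = 0.011,   # high-frequency flow residual sd over Z1, / PEF
    c2b_excursion_max = 80,    # normalized |d2F/dV2| excursion cap

    # Z3: descent regularity
    c7_flow_floor     = 0.10,  # fraction of PEF below which dF/dV is not used
    c7_slope_max      = 12,    # (L/s)/L, C7a
    c7_slope_var_max  = 30,    # ((L/s)/L)^2, C7b
    c7_segment_width  = 0.5,   # L, C7c sliding volume window
    c7_segment_var_max = 40,   # ((L/s)/L)^2, C7c
    c7_signflip_max   = 1.0,   # chord-weighted sign-change score, C7d

    # Z4: end-of-test refinements and oscillation
    c10_window2        = 0.5,  # s, alternative EOTV window (C10b)
    c10_threshold2     = 0.04, # L, alternative EOTV threshold (C10c)
    c10_eotv_tex_slope = 0.5,  # 1/s, slope of the Tex-indexed EOTV threshold
    c11_osc_amplitude  = 0.06, # L/s, minimum flow swing between extrema
    c11_signflip_max   = 4,    # dF/dt sign changes in Z4

    # Z5: single-peak checks
    c12_prominence = 0.10,     # fraction of PEF
    c12_fev1_band  = 0.50      # L, volume band around the FEV1 point
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop_input("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  validate_config(cfg)
  structure(cfg, class = "spiro_config")
}

validate_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop_input("all config entries must be numeric scalars")
  if (any(unlist(cfg) <= 0)) stop_input("all thresholds must be > 0")
  fracs <- c("onset_fraction", "z2_fraction", "bev_frac", "flat_peak_ratio",
             "bimodal_prominence", "c7_flow_floor", "c12_prominence")
  for (k in fracs) {
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1) {
      stop_input(k, " must lie strictly in (0, 1)")
    }
  }
  invisible(cfg)
}

#' @export
print.spiro_config <- function(x, ...) {
  cat("<spiro_config>", length(x), "thresholds\n")
  for (k in names(x)) cat(sprintf("  %-20s %g\n", k, x[[k]]))
  invisible(x)
}

#' A short digest identifying a configuration
#'
#' Used to stamp quality reports with the configuration that produced them.
#'
#' @param cfg A config from [default_config()] or [read_config()].
#' @return Character scalar digest.
#' @export
config_fingerprint <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) sprintf("%.10g", v), ""),
             sep = "=", collapse = ";")
  # polynomial rolling hash modulo a Mersenne prime, over the canonical
  # key=value string; stable across platforms
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read / write a threshold configuration
#'
#' Flat `key = value` text, one entry per line, `#` comments allowed.
#' Unknown keys are rejected; missing keys take their defaults. Policy lines
#' (`policy.rejecting`, `policy.warning`) are comma-separated criterion ids
#' and are returned in the `policy` attribute.
#'
#' @param path File path.
#' @return `read_config()`: a `spiro_config`; if the file carries policy
#'   lines, a [grade_policy()] is attached as attribute `"policy"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop_input("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  pol <- grepl("^policy\\.", keys)
  over <- as.list(as.numeric(vals[!pol]))
  names(over) <- keys[!pol]
  if (anyNA(over)) stop_input("non-numeric config value for: ",
                              paste(keys[!pol][is.na(over)], collapse = ", "))
  cfg <- do.call(default_config, over)
  if (any(pol)) {
    getset <- function(key) {
      i <- match(key, keys)
      if (is.na(i)) character(0) else trimws(strsplit(vals[i], ",")[[1]])
    }
    attr(cfg, "policy") <- grade_policy(rejecting = getset("policy.rejecting"),
                                        warning = getset("policy.warning"))
  }
  cfg
}

#' @rdname read_config
#' @param cfg Configuration to write.
#' @param policy Optional [grade_policy()] to embed in the same file.
#' @export
write_config <- function(cfg, path, policy = NULL) {
  lines <- sprintf("%s = %.17g", names(cfg), unlist(cfg))
  if (!is.null(policy)) {
    lines <- c(lines,
               paste("policy.rejecting =", paste(policy$rejecting, collapse = ",")),
               paste("policy.warning =", paste(policy$warning, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
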