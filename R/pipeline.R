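# ---- configuration ----------------------------------------------------------

#' End-to-end analysis configuration
#'
#' Describes a full run of the analysis sequence: (optional) simulation,
#' hourly/daily averaging, gap filling, transformation to rates of change,
#' segmentation, per-segment Morlet transforms aggregated into global
#' spectra with red-noise significance, and wavelet coherence with phase
#' histograms for the requested pairs.
#'
#' @param simulate `NULL`, or a list with fields `duration` (days) and
#'   optionally `start_time`, `gaps` (named list of gap-length vectors per
#'   variable) and any [ecosystem_params()] argument; the dataset is then
#'   generated rather than read.
#' @param inputs `NULL`, or a named list of CSV paths (names are variable
#'   labels; `water_level` and, for daily chlorophyll, `par` are special).
#' @param dj,level wavelet scale resolution and significance level.
#' @param min_segment_hourly,min_segment_daily minimum gap-free run lengths,
#'   in samples (strictly-greater-than-100-hours and 60-days conventions).
#' @param coherence_pairs list of pair requests, each a list with fields
#'   `x`, `y` (variable labels among the computed hourly/daily products:
#'   the biological variables, `water_level`, `tc`, `tidal_range`),
#'   `cadence` (`"hourly"` or `"daily"`), `band` (period interval, minutes),
#'   and optionally `transform` (logical, rate-of-change both series;
#'   default `TRUE` for concentrations at hourly cadence, `FALSE`
#'   otherwise).
#' @param surrogates Monte-Carlo surrogate pairs for coherence significance.
#' @param seed master seed: forwarded to the simulator and every stochastic
#'   stage, and recorded in all outputs.
#' @param out_dir output directory.
#' @return A list of class `tw_config`.
#' @export
pipeline_config <- function(simulate = list(duration = 180),
                            inputs = NULL, dj = 1 / 24, level = 0.95,
                            min_segment_hourly = 101,
                            min_segment_daily = 61,
                            coherence_pairs = list(), surrogates = 100,
                            seed = 1L, out_dir = tempfile("tidewave_run")) {
  if (is.null(simulate) && is.null(inputs))
    stop("config needs either `simulate` or `inputs`")
  if (!is.null(inputs)) {
    missing <- !vapply(inputs, file.exists, TRUE)
    if (any(missing))
      stop("input file(s) not found: ",
           paste(unlist(inputs[missing]), collapse = ", "))
  }
  structure(as.list(environment()), class = "tw_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file's top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `tw_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

# tiny stable FNV-1a hash so outputs can be traced to their configuration
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL    # where results land is not part of their identity
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                        # xor touches the low byte only
    h <- ((h - lo + bitwXor(as.integer(lo), as.integer(b))) * 16777619) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# ---- pipeline ---------------------------------------------------------------

analyze_variable <- function(series, min_segment, dj, level, transform) {
  work <- fill_small_gaps(series)
  if (transform) work <- log_smooth_diff(work)
  segs <- find_segments(work, min_segment)
  if (!length(segs)) return(NULL)
  longest <- max(vapply(segs, function(s) s$length, 0L))
  params <- wavelet_params(dj = dj)
  scales <- cwt_scales(longest, work$step, params)
  spectra <- lapply(segs, function(s)
    morlet_cwt(extract_segment(work, s), params, scales = scales))
  gws <- global_spectrum(spectra, level = level)
  list(series = work, segments = segs, spectra = spectra, gws = gws)
}

band_peaks <- function(gws, bands) {
  out <- list(overall = as.numeric(peak_period(gws)))
  for (nm in names(bands)) {
    pk <- tryCatch(peak_period(gws, bands[[nm]]), error = function(e) NULL)
    if (!is.null(pk))
      out[[nm]] <- list(period_min = as.numeric(pk),
                        boundary = isTRUE(attr(pk, "boundary")))
  }
  out
}

resolve_pair_series <- function(label, products, cadence) {
  key <- paste(label, cadence, sep = ".")
  s <- products[[key]]
  if (is.null(s)) stop("coherence pair refers to unknown product: ", key)
  s
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> average -> gap-fill -> transform ->
#' segment -> wavelet/global spectra -> coherence/phase histograms, writes
#' every intermediate series as CSV plus a machine-readable `summary.json`
#' (peak periods per variable and cadence in standard tidal bands, phase
#' statistics per coherence pair) and a plain-text log. Every output records
#' the seed and a hash of the configuration. A fixed seed makes the summary
#' byte-reproducible.
#'
#' @param config a [pipeline_config()] (or a path readable by
#'   [read_config()]).
#' @return Invisibly, a list with the summary, the computed products and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "tw_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                             append = TRUE)
  cat("", file = log_path)
  hash <- config_hash(config)
  logln("tidewave %s | seed %d | config %s",
        as.character(utils::packageVersion("tidewave")), config$seed, hash)

  # -- acquire data -----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    eco_args <- sim[setdiff(names(sim), c("duration", "start_time", "gaps"))]
    eco_args$seed <- eco_args$seed %||% config$seed
    tide <- generate_water_level(tide_config(
      duration = sim$duration %||% 180,
      start_time = sim$start_time %||% "2007-01-01"))
    ds <- generate_ecosystem(tide, do.call(ecosystem_params, eco_args))
    raw <- ds[setdiff(names(ds), "truth")]
    if (!is.null(sim$gaps)) {
      for (nm in names(sim$gaps))
        raw[[nm]] <- inject_gaps(raw[[nm]], sim$gaps[[nm]],
                                 seed = config$seed)
    }
    dir.create(file.path(out, "data"), showWarnings = FALSE)
    for (nm in names(raw))
      write_timeseries(raw[[nm]], file.path(out, "data", paste0(nm, ".csv")))
    jsonlite::write_json(ds$truth, file.path(out, "data", "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    logln("simulated %d series (%g d)", length(raw), sim$duration %||% 180)
  } else {
    raw <- lapply(config$inputs, read_timeseries)
    for (nm in names(raw)) raw[[nm]]$variable <- nm
    logln("read %d input series", length(raw))
  }

  bio_vars <- intersect(c("chlorophyll", "spm", "salinity", "temperature"),
                        names(raw))
  hourly_bands <- list(quarter_diurnal = c(300, 450),
                       semidiurnal = c(600, 900), diel = c(1200, 1800))
  daily_bands <- list(spring_neap = c(10, 20) * 1440)

  products <- list()
  peaks <- list(hourly = list(), daily = list())

  # -- hourly branch ----------------------------------------------------
  for (nm in bio_vars) {
    h <- hourly_average(raw[[nm]])
    products[[paste0(nm, ".hourly")]] <- h
    res <- analyze_variable(h, config$min_segment_hourly, config$dj,
                            config$level, transform = TRUE)
    if (!is.null(res)) {
      products[[paste0("rate_", nm, ".hourly")]] <- res$series
      peaks$hourly[[nm]] <- band_peaks(res$gws, hourly_bands)
    }
  }
  if ("water_level" %in% names(raw)) {
    wh <- hourly_average(raw$water_level)
    products[["water_level.hourly"]] <- wh
    res <- analyze_variable(wh, config$min_segment_hourly, config$dj,
                            config$level, transform = FALSE)
    if (!is.null(res))
      peaks$hourly$water_level <- band_peaks(res$gws, hourly_bands)
    # difference the hourly averages (not average the 10-min differences):
    # both TC and the rate-of-change series then share the same effective
    # timestamp, so cross-phase estimates are unbiased
    tc <- tidal_current_speed(wh)
    products[["tc.hourly"]] <- tc
    res <- analyze_variable(tc, config$min_segment_hourly, config$dj,
                            config$level, transform = FALSE)
    if (!is.null(res)) peaks$hourly$tc <- band_peaks(res$gws, hourly_bands)
    tr <- tidal_range(raw$water_level)
    products[["tidal_range.daily"]] <- tr
    res <- analyze_variable(tr, config$min_segment_daily, config$dj,
                            config$level, transform = FALSE)
    if (!is.null(res))
      peaks$daily$tidal_range <- band_peaks(res$gws, daily_bands)
  }

  # -- daily branch -----------------------------------------------------
  for (nm in bio_vars) {
    d <- if (nm == "chlorophyll") {
      if (is.null(raw$par)) next
      daily_average(raw[[nm]], par = raw$par)
    } else daily_average(raw[[nm]])
    products[[paste0(nm, ".daily")]] <- d
    res <- analyze_variable(d, config$min_segment_daily, config$dj,
                            config$level, transform = TRUE)
    if (!is.null(res)) {
      products[[paste0("rate_", nm, ".daily")]] <- res$series
      peaks$daily[[nm]] <- band_peaks(res$gws, daily_bands)
    }
  }

  for (nm in names(products))
    write_timeseries(products[[nm]],
                     file.path(out, paste0(sub("\\.", "_", nm), ".csv")))
  logln("computed %d intermediate products", length(products))

  # -- coherence pairs --------------------------------------------------
  coh_stats <- list()
  min_seg <- c(hourly = config$min_segment_hourly,
               daily = config$min_segment_daily)
  for (i in seq_along(config$coherence_pairs)) {
    pr <- config$coherence_pairs[[i]]
    cadence <- pr$cadence %||% "hourly"
    sx <- resolve_pair_series(pr$x, products, cadence)
    sy <- resolve_pair_series(pr$y, products, cadence)
    # align on the shared grid, then analyse the longest jointly gap-free run
    both <- sx
    both$values <- ifelse(is.na(sx$values) | is.na(sy$values), NA_real_, 1)
    segs <- find_segments(both, min_seg[[cadence]])
    if (!length(segs)) {
      logln("pair %s~%s: no joint segment long enough, skipped", pr$x, pr$y)
      next
    }
    seg <- segs[[which.max(vapply(segs, function(s) s$length, 0L))]]
    coh <- wavelet_coherence(extract_segment(sx, seg),
                             extract_segment(sy, seg),
                             wavelet_params(dj = config$dj))
    coh <- mc_coherence_significance(extract_segment(sx, seg),
                                     extract_segment(sy, seg), coh,
                                     n_surrogates = config$surrogates,
                                     seed = config$seed + i,
                                     level = config$level)
    ph <- suppressWarnings(phase_distribution(coh, pr$band))
    key <- paste(pr$x, pr$y, cadence, sep = "~")
    coh_stats[[key]] <- list(
      band_min = pr$band, n_significant = ph$n,
      circ_mean_deg = ph$circ_mean, circ_sd_deg = ph$circ_sd,
      lag_min = if (is.na(ph$circ_mean)) NA_real_
                else phase_to_lag(ph$circ_mean, mean(pr$band)),
      frac_significant_in_band = {
        inband <- coh$periods >= pr$band[1L] & coh$periods <= pr$band[2L]
        outside <- outer(coh$periods, coh$coi, `<=`)[inband, , drop = FALSE]
        mean(coh$signif_mask[inband, , drop = FALSE][outside])
      })
    logln("pair %s: %d significant phase angles, circular mean %.1f deg",
          key, ph$n, ph$circ_mean)
  }

  summary <- list(package = "tidewave",
                  version = as.character(utils::packageVersion("tidewave")),
                  seed = config$seed, config_hash = hash,
                  peak_periods = peaks, coherence = coh_stats)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  logln("done")
  invisible(list(summary = summary, products = products, out_dir = out))
}
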