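#' Analysis run configuration
#'
#' Bundles everything [run_full_analysis()] needs: the input mode, the
#' simulator configuration (synthetic mode) or input paths (file mode),
#' the bloom threshold, driver-binning choices, and the output
#' directory.
#'
#' @param mode `"synthetic"` (simulate the dataset) or `"files"` (read a
#'   NetCDF bundle).
#' @param sim a [sim_config()] (synthetic mode).
#' @param bundle_path NetCDF bundle path (file mode).
#' @param out_dir output directory (created if missing).
#' @param bloom_threshold spring-climatology threshold, mg Chl m-3.
#' @param n_bins,min_count binning choices passed to [bin_relation()].
#' @param composite_lags lag offsets in steps for the event composite.
#' @param verbose print stage-level progress.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("synthetic", "files"),
                            sim = sim_config(),
                            bundle_path = NULL,
                            out_dir = "results",
                            bloom_threshold = 0.65,
                            n_bins = 9,
                            min_count = 10,
                            composite_lags = -3:3,
                            verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(bundle_path)) stop("file mode requires 'bundle_path'")
    if (!file.exists(bundle_path))
      stop("stage 'read': input file not found: ", bundle_path)
  }
  if (bloom_threshold < 0) stop("bloom_threshold must be non-negative")
  structure(list(mode = mode, sim = sim, bundle_path = bundle_path,
                 out_dir = out_dir, bloom_threshold = bloom_threshold,
                 n_bins = n_bins, min_count = min_count,
                 composite_lags = composite_lags, verbose = verbose),
            class = "analysis_config")
}

# First free versioned variant of a path: "x.csv", then "x_v2.csv", ...
fresh_path <- function(path) {
  if (!file.exists(path)) return(path)
  ext <- tools::file_ext(path)
  stem <- sub(paste0("\\.", ext, "$"), "", path)
  v <- 2
  repeat {
    cand <- sprintf("%s_v%d.%s", stem, v, ext)
    if (!file.exists(cand)) return(cand)
    v <- v + 1
  }
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message("stage '", name, "' ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

write_fields_nc <- function(fields, path) {
  f1 <- fields[[1]]
  ax <- f1$axis
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", f1$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", f1$lat)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(ax$center), unlim = TRUE)
  vars <- lapply(fields, function(f)
    ncdf4::ncvar_def(f$name, f$units, list(dim_lon, dim_lat, dim_time),
                     1e30, longname = f$name, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(fields))
    ncdf4::ncvar_put(nc, vars[[k]], aperm(fields[[k]]$values, c(3, 2, 1)))
  invisible(path)
}

#' Run the full analysis chain
#'
#' Simulates (or reads) the co-registered SChl/NHF/WS dataset, then
#' decomposes SChl, computes growth rates and driver derivatives,
#' detects shutdown events and builds the lag composite, bins growth
#' against d(NHF)/dt per phase, and maps seasonal climatologies, ISV
#' intensity, sign agreement and the bloom region. Every artifact is
#' written under `config$out_dir` (never overwriting: existing names get
#' a versioned suffix) and listed with an MD5 checksum in a JSON
#' manifest. Identical configuration and seed give identical checksums.
#'
#' @param config an [analysis_config()].
#' @return The manifest, invisibly: a list with `files` (name, path,
#'   md5), `counts`, and the manifest path.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  vb <- config$verbose
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) fresh_path(file.path(config$out_dir, name))
  files <- list()
  add <- function(files, label, path) { files[[label]] <- path; files }

  bundle <- if (config$mode == "synthetic") {
    run_stage("simulate", vb, simulate_dataset(config$sim))
  } else {
    run_stage("read", vb, read_bundle(config$bundle_path))
  }
  axis <- bundle$schl$axis
  n_lat <- length(bundle$schl$lat); n_lon <- length(bundle$schl$lon)

  if (config$mode == "synthetic") {
    p <- out("bundle.nc")
    run_stage("write_bundle", vb, write_bundle(bundle, p))
    files <- add(files, "bundle", p)
  }
  p <- out("pixel_series.csv")
  run_stage("write_pixel", vb, write_pixel_csv(bundle, p, 1L, 1L))
  files <- add(files, "pixel_series", p)

  p_year <- length(unique(axis$step))
  run_stage("decompose", vb, {
    d <- x11_decompose_field(bundle$schl, p_year)
    p <- out("decomposition.nc")
    write_fields_nc(list(d$trend, d$seasonal, d$irregular), p)
    files <- add(files, "decomposition", p)
  })

  derived <- run_stage("metrics", vb, {
    nstep <- axis$n_steps
    growth <- array(NA_real_, c(nstep - 1, n_lat, n_lon))
    for (i in seq_len(n_lat)) for (j in seq_len(n_lon))
      growth[, i, j] <- net_growth_rate(bundle$schl$values[, i, j],
                                        axis$step_days)
    dnhf <- array(NA_real_, dim(growth))
    dws <- array(NA_real_, dim(growth))
    for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
      dnhf[, i, j] <- forward_derivative(bundle$nhf$values[, i, j],
                                         axis$step_days)
      dws[, i, j] <- forward_derivative(bundle$ws$values[, i, j],
                                        axis$step_days)
    }
    df <- data.frame(date = axis$center[-nstep],
                     growth = growth[, 1, 1],
                     dnhf = dnhf[, 1, 1], dws = dws[, 1, 1],
                     phase = classify_intervals(bundle$nhf$values[, 1, 1]))
    p <- out("derived_series.csv")
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <- add(files, "derived_series", p)
    list(growth = growth, dnhf = dnhf, dws = dws)
  })

  comp <- run_stage("events", vb, {
    lags <- config$composite_lags
    vals <- rep(list(numeric(0)), length(lags))
    n_cross <- 0L
    for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
      ev <- find_zero_crossings(bundle$nhf$values[, i, j], axis)
      n_cross <- n_cross + sum(ev$direction == "neg_pos" & ev$persistent)
      v <- composite_values(derived$growth[, i, j], ev, lags)
      for (k in seq_along(lags)) vals[[k]] <- c(vals[[k]], v[[k]])
    }
    comp_tab <- summarize_composite(vals, lags * axis$step_days)
    p <- out("composite.csv")
    utils::write.csv(comp_tab, p, row.names = FALSE, quote = FALSE)
    files <- add(files, "composite", p)

    win_idx <- unlist(lapply(unique(axis$year), analysis_window_indices,
                             axis = axis))
    in_window <- (seq_len(axis$n_steps) %in% win_idx)[-axis$n_steps]
    g <- as.vector(derived$growth)
    d <- as.vector(derived$dnhf)
    lab <- as.vector(apply(bundle$nhf$values, c(2, 3), classify_intervals))
    keep <- rep(in_window, n_lat * n_lon)
    phase_sets <- list(
      transition = c("TRANSITION_SHUTDOWN", "TRANSITION_RESUME"),
      winter = "WINTER_UNSTABLE",
      spring = "SPRING_STABLE")
    for (nm in names(phase_sets)) {
      tab <- bin_relation(g, d, labels = lab, phases = phase_sets[[nm]],
                          keep = keep, min_count = config$min_count)
      p <- out(paste0("binned_", nm, ".csv"))
      utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
      files <- add(files, paste0("binned_", nm), p)
    }
    list(table = comp_tab, n_crossings = n_cross)
  })

  run_stage("maps", vb, {
    clim_w <- seasonal_climatology(bundle$schl, "winter")
    clim_s <- seasonal_climatology(bundle$schl, "spring")
    mask <- bloom_mask(clim_s, config$bloom_threshold)
    maps <- list(
      clim_w, clim_s,
      isv_std_map(bundle, "winter",
                  p = length(unique(axis$step))),
      isv_std_map(bundle, "spring",
                  p = length(unique(axis$step))),
      sign_agreement_map(derived$growth, derived$dnhf, axis, "winter",
                         "nhf", bundle$schl$lat, bundle$schl$lon),
      sign_agreement_map(derived$growth, derived$dnhf, axis, "spring",
                         "nhf", bundle$schl$lat, bundle$schl$lon),
      sign_agreement_map(derived$growth, derived$dws, axis, "winter",
                         "ws", bundle$schl$lat, bundle$schl$lon))
    p <- out("maps.nc")
    write_fields_nc(maps, p)
    files <- add(files, "maps", p)
    p <- out("bloom_mask.txt")
    write_mask_ascii(mask, bundle$schl$lat, bundle$schl$lon, p)
    files <- add(files, "bloom_mask", p)
  })

  manifest <- run_stage("manifest", vb, {
    paths <- unlist(files)
    sums <- unname(tools::md5sum(paths))
    m <- list(
      mode = config$mode,
      seed = if (config$mode == "synthetic") config$sim$seed else NULL,
      counts = list(pixels = n_lat * n_lon,
                    steps = axis$n_steps,
                    intervals = (axis$n_steps - 1) * n_lat * n_lon,
                    persistent_crossings = comp$n_crossings),
      files = data.frame(name = names(files), path = unname(paths),
                         md5 = sums))
    p <- out("manifest.json")
    jsonlite::write_json(m, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    m$manifest_path <- p
    m
  })
  if (vb) message("done: ", length(files), " artifact(s) in ",
                  config$out_dir)
  invisible(manifest)
}
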