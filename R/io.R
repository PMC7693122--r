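#' Column schemas for instrument CSV exports
#'
#' Named lists mapping canonical column names to accepted header aliases,
#' so that vendor export dialects are handled by alias maps rather than
#' per-vendor parsers.
#'
#' @return A named list of alias character vectors.
#' @name schemas
NULL

#' @rdname schemas
#' @export
schema_frequency_sweep <- function() list(
  f = c("f_Hz", "f", "freq", "frequency", "frequency_Hz"),
  G_storage = c("Gprime_Pa", "G_storage", "Gp", "G1", "storage_modulus"),
  G_loss = c("Gdoubleprime_Pa", "G_loss", "Gpp", "G2", "loss_modulus"))

#' @rdname schemas
#' @export
schema_msd <- function() list(
  lag = c("lag_s", "lag", "time_s", "t"),
  msd = c("msd_m2", "msd", "MSD"))

#' @rdname schemas
#' @export
schema_profile <- function() list(
  x_mm = c("x_mm", "x", "position_mm", "depth_mm"),
  c = c("c_g_per_m3", "c", "concentration", "conc"))

#' @rdname schemas
#' @export
schema_fcs <- function() list(
  tau = c("tau_s", "tau", "lag_s"),
  G = c("G", "g", "acf", "autocorrelation"))

#' @rdname schemas
#' @export
schema_tcspc <- function() list(
  t_ns = c("t_ns", "time_ns", "t"),
  counts = c("counts", "photons", "n"))

#' @rdname schemas
#' @export
schema_transmittance <- function() list(
  wavelength = c("wavelength_nm", "wavelength", "lambda_nm", "lambda"),
  transmittance = c("transmittance", "T", "trans"))

#' Read a typed, schema-validated CSV table
#'
#' Reads a CSV whose header is matched (case-insensitively) against the
#' schema's alias lists; columns are renamed to their canonical names and
#' checked to be numeric. Leading `#` lines are treated as metadata
#' comments of the form `# key: value` and returned in the `metadata`
#' attribute.
#'
#' @param path CSV file path.
#' @param schema One of the `schema_*()` alias maps.
#' @return A data frame with canonical column names and a `metadata`
#'   attribute.
#' @export
read_table <- function(path, schema) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    kv <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(kv) == 3) {
      val <- suppressWarnings(as.numeric(kv[3]))
      metadata[[trimws(kv[2])]] <- if (is.na(val)) trimws(kv[3]) else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  out <- list()
  for (canon in names(schema)) {
    hit <- which(tolower(names(df)) %in% tolower(schema[[canon]]))
    if (length(hit) == 0)
      stop("missing column `", canon, "` (accepted: ",
           paste(schema[[canon]], collapse = ", "), ") in ", path,
           call. = FALSE)
    col <- df[[hit[1]]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num) && !anyNA(col)) {
      bad <- which(is.na(num))[1]
      stop("non-numeric value in column `", names(df)[hit[1]],
           "`, data row ", bad, " of ", path, call. = FALSE)
    }
    out[[canon]] <- num
  }
  structure(as.data.frame(out), metadata = metadata)
}

#' Write a table as CSV at full double precision
#'
#' @param records Data frame to write.
#' @param path Output path.
#' @param metadata Optional named list written as leading `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, format(metadata[[k]], digits = 15)),
               con)
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(x) format(x, digits = 15))
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Modality-specific CSV readers
#'
#' Thin wrappers over [read_table()] that construct the corresponding
#' typed object, picking physical parameters (temperature, tracer radius,
#' beam waist, diffusion time, ...) from `# key: value` metadata lines
#' when present.
#'
#' @param path CSV file path.
#' @return The corresponding typed object.
#' @name readers
NULL

#' @rdname readers
#' @export
read_frequency_sweep <- function(path) {
  df <- read_table(path, schema_frequency_sweep())
  md <- attr(df, "metadata")
  frequency_sweep(df$f, df$G_storage, df$G_loss,
                  sample_id = if (!is.null(md$sample_id)) md$sample_id
                    else NA_character_,
                  temperature = if (!is.null(md$temperature)) md$temperature
                    else 298.15)
}

#' @rdname readers
#' @export
read_msd_trace <- function(path) {
  df <- read_table(path, schema_msd())
  md <- attr(df, "metadata")
  msd_trace(df$lag, df$msd,
            tracer_radius = if (!is.null(md$tracer_radius)) md$tracer_radius
              else 50e-9,
            temperature = if (!is.null(md$temperature)) md$temperature
              else 298.15)
}

#' @rdname readers
#' @export
read_concentration_profile <- function(path) {
  df <- read_table(path, schema_profile())
  md <- attr(df, "metadata")
  if (is.null(md$t_h)) stop("profile file must carry `# t_h:` metadata",
                            call. = FALSE)
  concentration_profile(df$x_mm, df$c, t_h = md$t_h,
                        composition = if (!is.null(md$composition))
                          md$composition else NA_character_)
}

#' @rdname readers
#' @export
read_fcs_curve <- function(path) {
  df <- read_table(path, schema_fcs())
  md <- attr(df, "metadata")
  fcs_curve(df$tau, df$G,
            w0 = if (!is.null(md$w0)) md$w0 else 0.3e-6,
            kappa = if (!is.null(md$kappa)) md$kappa else 5)
}

#' @rdname readers
#' @export
read_tcspc <- function(path) {
  df <- read_table(path, schema_tcspc())
  decay_histogram(df$t_ns, df$counts)
}

#' @rdname readers
#' @export
read_transmittance <- function(path, path_cm = 1) {
  df <- read_table(path, schema_transmittance())
  turbidity_spectrum(df$wavelength, df$transmittance, path_cm = path_cm)
}

#' Read or write a grayscale micrograph (TIFF or PNG)
#'
#' @param path Image path; format chosen by extension.
#' @param pixel_size Pixel size in nm/px to attach.
#' @return A [pore_image()].
#' @export
read_pore_image <- function(path, pixel_size = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]   # first channel of RGB
  pore_image(img, pixel_size = pixel_size, source = path)
}

#' @rdname read_pore_image
#' @param image A [pore_image()] to write.
#' @export
write_pore_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  m <- unclass(image)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path),
    png = png::writePNG(m, path),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Run a configured analysis stage
#'
#' Executes one modality of the pipeline from a validated configuration
#' (a YAML file path or an equivalent named list), writes its outputs and
#' returns a report recording the seed, a hash of the configuration and
#' the package version, so identical configurations give byte-identical
#' numeric outputs.
#'
#' Supported modalities: `"rheology"` (sweep CSV -> Maxwell fit + network
#' estimate), `"microrheology"` (MSD CSV -> GSER spectrum CSV),
#' `"diffusion"` (profile CSVs -> diffusion-fit table), `"fcs"`,
#' `"lifetime"`, `"turbidity"`, `"pores"` (micrograph -> pore and skeleton
#' CSVs) and `"synthetic_diffusion_demo"` (generate profiles from supplied
#' parameter rows and recover them end-to-end into a summary table).
#'
#' @param config YAML file path or named list. Common fields: `modality`,
#'   `input` (path or vector of paths), `out_dir`, `seed`, plus
#'   modality-specific parameters (`n_elements`, `temperature`, `csol`,
#'   `tail_start`, `path_cm`, `pixel_size`, `min_area_px`,
#'   `use_watershed`, `rows` for the demo).
#' @return A list of class `pipeline_report` with `modality`, `outputs`
#'   (paths), `results`, `seed`, `config_hash`, `package_version`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$modality))
  for (p in c("temperature", "csol", "path_cm", "pixel_size"))
    if (!is.null(config[[p]]) && config[[p]] <= 0)
      stop("configuration parameter `", p, "` must be positive",
           call. = FALSE)
  for (f in config$input)
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outputs <- character(0); results <- NULL
  temp <- if (is.null(config$temperature)) 298.15 else config$temperature

  if (config$modality == "rheology") {
    sw <- read_frequency_sweep(config$input)
    n <- if (!is.null(config$n_elements)) config$n_elements
      else select_n(sw, n_max = min(4, (nrow(sw) - 1) %/% 2))
    fit <- fit_maxwell(sw, n)
    net <- network_estimate(fit, temperature = temp)
    results <- list(fit = fit, network = net)
    out <- file.path(out_dir, "maxwell_fit.json")
    jsonlite::write_json(list(
      n = fit$n, Gi = fit$Gi, lambdai = fit$lambdai, G_total = fit$G_total,
      rho_x_mol_m3 = net$rho_x, xi_m = net$xi), out,
      auto_unbox = TRUE, digits = NA)
    outputs <- out
  } else if (config$modality == "microrheology") {
    tr <- read_msd_trace(config$input)
    sp <- gser_moduli(tr)
    results <- list(spectrum = sp)
    out <- file.path(out_dir, "gser_spectrum.csv")
    write_table(as.data.frame(sp), out)
    outputs <- out
  } else if (config$modality == "diffusion") {
    csol <- if (is.null(config$csol)) 10 else config$csol
    fits <- lapply(config$input, function(p)
      fit_profile(read_concentration_profile(p), csol = csol))
    results <- list(fits = fits,
                    summary = if (length(fits) >= 2) aggregate_fits(fits))
    out <- file.path(out_dir, "diffusion_fits.csv")
    write_table(data.frame(
      input = unlist(config$input),
      t_h = vapply(fits, `[[`, numeric(1), "t_h"),
      Deff_um2_s = vapply(fits, `[[`, numeric(1), "Deff"),
      c0_g_m3 = vapply(fits, `[[`, numeric(1), "c0"),
      epsilon = vapply(fits, `[[`, numeric(1), "epsilon")), out)
    outputs <- out
  } else if (config$modality == "fcs") {
    fit <- fit_fcs(read_fcs_curve(config$input))
    results <- list(fit = fit)
    out <- file.path(out_dir, "fcs_fit.json")
    jsonlite::write_json(list(N = fit$N, tauD_s = fit$tauD,
                              Ds_um2_s = fit$Ds), out,
                         auto_unbox = TRUE, digits = NA)
    outputs <- out
  } else if (config$modality == "lifetime") {
    tail_start <- if (is.null(config$tail_start)) 1 else config$tail_start
    fit <- fit_lifetime(read_tcspc(config$input), tail_start = tail_start)
    results <- list(fit = fit)
    out <- file.path(out_dir, "lifetime_fit.json")
    jsonlite::write_json(list(tau_fl_ns = fit$tau_fl,
                              background = fit$background), out,
                         auto_unbox = TRUE, digits = NA)
    outputs <- out
  } else if (config$modality == "turbidity") {
    path_cm <- if (is.null(config$path_cm)) 1 else config$path_cm
    ts <- read_transmittance(config$input, path_cm = path_cm)
    fit <- wavelength_exponent(ts)
    results <- list(fit = fit)
    if (!is.null(config$mapping)) {
      map <- utils::read.csv(config$mapping)
      results$correlation_length_um <- correlation_length(fit, map)
    }
    out <- file.path(out_dir, "turbidity_fit.json")
    jsonlite::write_json(c(list(exponent = fit$exponent,
                                r_squared = fit$r_squared),
                           results["correlation_length_um"]), out,
                         auto_unbox = TRUE, digits = NA)
    outputs <- out
  } else if (config$modality == "pores") {
    img <- read_pore_image(config$input,
                           pixel_size = if (is.null(config$pixel_size))
                             NA_real_ else config$pixel_size)
    pre <- preprocess(img)
    bin <- threshold_maxentropy(pre)
    pores <- analyze_pores(bin,
      use_watershed = isTRUE(config$use_watershed),
      min_area_px = if (is.null(config$min_area_px)) 4
        else config$min_area_px)
    skel <- analyze_skeleton(bin)
    results <- list(pores = pores, skeleton = skel)
    out1 <- file.path(out_dir, "pores.csv")
    out2 <- file.path(out_dir, "skeleton.csv")
    write_table(pores$table, out1)
    write_table(skel$branches, out2)
    outputs <- c(out1, out2)
  } else if (config$modality == "synthetic_diffusion_demo") {
    rows <- config$rows
    if (is.null(rows))
      rows <- list(list(composition = "0%", Deff = 389, epsilon = 5.3),
                   list(composition = "0.010%", Deff = 27, epsilon = 64.8))
    csol <- if (is.null(config$csol)) 10 else config$csol
    fits <- list()
    for (row in rows) {
      prs <- gen_concentration_profiles(row$Deff, row$epsilon * csol,
                                        spec = generator_spec(seed))
      for (pr in prs) {
        attr(pr, "composition") <- row$composition
        ft <- fit_profile(pr, csol = csol)
        ft$composition <- row$composition
        fits[[length(fits) + 1]] <- ft
      }
    }
    results <- list(summary = aggregate_fits(fits))
    out <- file.path(out_dir, "diffusion_summary.csv")
    write_table(results$summary, out)
    outputs <- out
  } else {
    stop("unknown modality: ", config$modality, call. = FALSE)
  }

  structure(list(modality = config$modality, outputs = outputs,
                 results = results, seed = seed,
                 config_hash = config_hash(config),
                 package_version =
                   as.character(utils::packageVersion("gelmetrics"))),
            class = "pipeline_report")
}

# order-independent hash of the configuration list
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(s)) %% 997)) %% .Machine$integer.max)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report [", x$modality, "] gelmetrics ",
      x$package_version, "\n", sep = "")
  cat("  seed:", x$seed, " config:", x$config_hash, "\n")
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}
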