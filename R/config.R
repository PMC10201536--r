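#' Load a packaged preset or a user configuration
#'
#' Presets "AT" and "GC" ship with the package as YAML files; a user config
#' is any YAML/JSON file with the same block structure (`preset`,
#' `surface`, `duplex`, `scan`, `mep`, `steering`, `seed`). Validation is
#' strict: unknown keys anywhere in the file are errors, so a typo cannot
#' silently miscalibrate a run.
#'
#' @param preset "AT" or "GC", or a path to a YAML/JSON config file.
#' @return Object of class `run_config`: validated list with parameter
#'   objects in the module blocks.
#' @examples
#' cfg <- load_config("AT")
#' cfg$surface$step1_exponent
#' @export
load_config <- function(preset = "AT") {
  path <- if (file.exists(preset)) {
    preset
  } else if (preset %in% c("AT", "GC")) {
    system.file("extdata", paste0("preset_", preset, ".yaml"),
                package = "tautopath", mustWork = TRUE)
  } else {
    stop("load_config(): '", preset, "' is neither a file nor a packaged preset")
  }
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(raw, source = path)
}

block_to_params <- function(block, constructor, known, where) {
  unknown <- setdiff(names(block), known)
  if (length(unknown)) {
    stop("config block '", where, "' has unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(constructor, block)
}

validate_run_config <- function(raw, source = "<config>") {
  top_known <- c("preset", "surface", "duplex", "scan", "mep", "steering",
                 "seed", "output_dir", "log_level")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown)) {
    stop("config ", source, " has unknown top-level key(s): ",
         paste(unknown, collapse = ", "))
  }
  preset <- raw$preset %||% "AT"
  surface <- block_to_params(
    raw$surface %||% list(), surface_params,
    c("preset", "step1_reverse_base", "step1_reverse_prefactor",
      "step1_exponent", "step2_slope", "step2_onset",
      "spt_asymmetry_intercept", "spt_asymmetry_slope",
      "dpt_asymmetry_intercept", "dpt_asymmetry_slope",
      "sequential_penalty", "stability_epsilon"), "surface")
  if (is.null(raw$surface$preset)) {
    surface <- do.call(surface_params,
                       c(list(preset = preset),
                         raw$surface %||% list()))
  }
  duplex <- block_to_params(
    raw$duplex %||% list(), duplex_params,
    names(formals(duplex_params)), "duplex")
  scan <- block_to_params(
    raw$scan %||% list(), scan_config,
    names(formals(scan_config)), "scan")
  mep <- block_to_params(
    raw$mep %||% list(), mlneb_config,
    names(formals(mlneb_config)), "mep")
  steering <- block_to_params(
    raw$steering %||% list(), steering_protocol,
    names(formals(steering_protocol)), "steering")
  structure(list(preset = preset, surface = surface, duplex = duplex,
                 scan = scan, mep = mep, steering = steering,
                 seed = as.integer(raw$seed %||% 1L),
                 output_dir = raw$output_dir %||% ".",
                 log_level = raw$log_level %||% "info"),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> preset", x$preset, "| seed", x$seed, "\n")
  invisible(x)
}

#' Serialize a run configuration to YAML
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config A `run_config`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  strip <- function(p, drop = character(0)) {
    p <- unclass(p)
    p[setdiff(names(p), drop)]
  }
  out <- list(
    preset = config$preset,
    surface = strip(config$surface)[
      setdiff(names(unclass(config$surface)), "preset_label")],
    duplex = strip(config$duplex),
    scan = strip(config$scan),
    mep = strip(config$mep),
    steering = strip(config$steering, drop = "force_ev_a"),
    seed = config$seed,
    output_dir = config$output_dir,
    log_level = config$log_level
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a pipeline command and write its artifacts
#'
#' The command-level interface mirroring the shell entry point: each
#' command materializes one module's outputs under `out_dir` together with
#' a manifest (config hash, seed, package version) that makes the artifact
#' reproducible.
#'
#' Commands: `"scan"` (separation scans, canonical + tautomeric CSV),
#' `"mep"` (minimum-energy paths and barrier table CSV over the
#' transition-state grid), `"barriers"` (barrier table + classification +
#' onset JSON), `"unzip"` (steered ensemble summary CSV), `"report"`
#' (landscape report JSON: onset, exponent, lifetime, temperature bound),
#' `"fixtures"` (synthetic structure fixtures as extended-XYZ).
#'
#' @param command One of scan, mep, barriers, unzip, report, fixtures.
#' @param config A `run_config` from [load_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the written `files` and the computed
#'   result object.
#' @export
run_pipeline <- function(command = c("scan", "mep", "barriers", "unzip",
                                     "report", "fixtures"),
                         config = load_config("AT"),
                         out_dir = config$output_dir) {
  command <- match.arg(command)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    f <- file.path(out_dir, name); files <<- c(files, f); f
  }

  result <- switch(
    command,
    scan = {
      scans <- dplyr::bind_rows(
        run_separation_scan(config$scan, config$duplex, config$surface,
                            form = "canonical"),
        run_separation_scan(config$scan, config$duplex, config$surface,
                            form = "tautomeric"))
      utils::write.csv(scans, emit("scan.csv"), row.names = FALSE)
      scans
    },
    mep = ,
    barriers = {
      bt <- barrier_table(config$surface, config = config$mep)
      utils::write.csv(bt, emit("barriers.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(onset = detect_onset(bt),
             classification = bt$classification),
        emit("onset.json"), auto_unbox = TRUE, digits = NA)
      bt
    },
    unzip = {
      sys <- build_duplex(config$duplex)
      ens <- run_steered(sys, config$steering)
      hist <- angle_histogram(ens)
      utils::write.csv(hist$counts, emit("angle_histogram.csv"),
                       row.names = FALSE)
      summ <- ens$frames |>
        dplyr::group_by(replica) |>
        dplyr::summarise(max_separation = max(.data$separation),
                         mean_theta = mean(.data$theta))
      utils::write.csv(summ, emit("unzip_summary.csv"), row.names = FALSE)
      ens
    },
    report = {
      rep <- landscape_report(config$surface, config = config$mep)
      jsonlite::write_json(
        list(preset = config$preset,
             onset = rep$onset,
             exponent = rep$power_law$exponent,
             prefactor = rep$power_law$prefactor,
             r_squared = rep$power_law$r_squared,
             min_lifetime_ps = rep$min_lifetime,
             barrier_temperature_K = rep$barrier_temperature),
        emit("report.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(rep$barriers, emit("report_barriers.csv"),
                       row.names = FALSE)
      rep
    },
    fixtures = {
      frames <- lapply(c(0, 0.222, 0.444), function(d) {
        synth_fixture_structures(d = d,
                                 eq_length = config$duplex$hbond_eq_length,
                                 lever_arm = config$duplex$lever_arm)
      })
      write_structures(frames, emit("fixtures.xyz"))
      files <- c(files, file.path(out_dir, "fixtures.xyz.json"))
      frames
    })

  manifest <- list(
    command = command,
    preset = config$preset,
    seed = config$seed,
    config_hash = digest::digest(unclass(config)),
    package_version = as.character(utils::packageVersion("tautopath")),
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(files = c(files, file.path(out_dir, "manifest.json")),
                 result = result))
}
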