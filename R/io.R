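#' @title File I/O and fixtures
#' @description
#' All on-disk formats are plain delimited text with '#'-prefixed metadata
#' headers, matching what force-spectroscopy instruments export: rupture
#' forces as a single numeric column (pN), force-distance curves as two
#' columns (distance um, force pN), run configurations as YAML.
#' @name cli_io
NULL

header_lines <- function(meta) {
  vapply(names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]])),
         character(1))
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Write / read rupture-force datasets
#'
#' One force per row in pN; '#'-prefixed header records n, velocity, seed
#' and protocol so a simulation can be re-run from the file alone.
#'
#' @param dataset A [rupture_dataset()].
#' @param path File path.
#' @return `read_rupture_forces` returns a `rupture_dataset` with metadata
#'   restored from the header when present; `write_rupture_forces` returns
#'   `path` invisibly.
#' @export
write_rupture_forces <- function(dataset, path) {
  stopifnot(inherits(dataset, "rupture_dataset"))
  meta <- list(format = "nldfs rupture forces", units = "pN",
               n = dataset$n, protocol = dataset$protocol_label,
               velocity_um_s = dataset$velocity, seed = dataset$seed)
  if (!is.null(dataset$params)) {
    meta$xb_nm <- dataset$params$xb
    meta$koff_th_s <- dataset$params$koff_th
    meta$kBT_pN_nm <- dataset$params$kBT
  }
  writeLines(c(header_lines(meta),
               formatC(dataset$forces, format = "g", digits = 15)), path)
  invisible(path)
}

#' @rdname write_rupture_forces
#' @export
read_rupture_forces <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta <- parse_header(lines)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0) stop(sprintf("no numeric rows in %s", path))
  vals <- suppressWarnings(as.numeric(lines[body]))
  if (anyNA(vals)) {
    bad <- body[which(is.na(vals))[1]]
    stop(sprintf("non-numeric value on line %d of %s: '%s'",
                 bad, path, lines[bad]))
  }
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  params <- if (!is.null(meta$xb_nm)) {
    bond_parameters(as.numeric(meta$xb_nm), as.numeric(meta$koff_th_s),
                    as.numeric(meta$kBT_pN_nm))
  } else NULL
  rupture_dataset(vals,
                  velocity = num_or_na(meta$velocity_um_s),
                  protocol_label = if (is.null(meta$protocol)) NA_character_
                                   else meta$protocol,
                  params = params,
                  seed = if (is.null(meta$seed)) NA_integer_
                         else as.integer(as.numeric(meta$seed)))
}

#' Read a tabulated force-distance curve
#'
#' Two whitespace- or comma-delimited numeric columns: distance in um,
#' force in pN. Lines starting with '#' are comments.
#'
#' @param path File path.
#' @return A data frame with columns `distance` (um) and `force` (pN).
#' @export
read_force_distance <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0) stop(sprintf("no data rows in %s", path))
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  if (any(lengths(parts) < 2))
    stop("each data row must have two columns: distance (um), force (pN)")
  d <- as.numeric(vapply(parts, `[`, character(1), 1))
  f <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(d) || anyNA(f)) stop("non-numeric entries in force-distance file")
  data.frame(distance = d, force = f)
}

#' Run configuration
#'
#' A nested key/value (YAML) file describing bond parameters, the loading
#' protocol, and the simulation/spectrum/fit/study settings. Round-trips
#' losslessly through [read_run_config()] / [write_run_config()].
#'
#' @param path File path.
#' @param config A named list.
#' @return `read_run_config`: a named list; `write_run_config`: `path`,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default run configuration
#'
#' The worked worm-like chain example: xb = 0.70 nm, koff_th = 1e-4 /s,
#' kBT = 4.11 pN nm, lp = 3 nm, Lc = 10 um, pulling velocities 10 to 1e4
#' nm/s (0.01 to 10 um/s), spectrum kernel 3 pN.
#'
#' @return A named list suitable for [write_run_config()].
#' @export
default_run_config <- function() {
  list(
    bond = list(xb = 0.70, koff_th = 1e-4, kbt = 4.11),
    protocol = list(type = "wlc", lp = 3.0, lc = 10.0, v = 0.01),
    velocities = c(0.01, 0.1, 1, 10),
    simulate = list(n = 50, seed = 1),
    spectrum = list(sigma = 3.0, n_grid = 2048),
    fit = list(max_iterations = 500, reltol = 1e-10),
    study = list(sample_sizes = c(50, 300), iterations = 500, sigma = 3.0,
                 seed = 1))
}

#' Build objects from a configuration list
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param velocity Optional velocity (um/s) overriding `config$protocol$v`.
#' @return `protocol_from_config`: a `loading_protocol`;
#'   `bond_from_config`: a [bond_parameters()]; `family_from_config`: a
#'   `protocol_family`.
#' @export
protocol_from_config <- function(config, velocity = NULL) {
  pc <- config$protocol
  if (is.null(pc$type)) stop("config$protocol$type missing")
  v <- if (!is.null(velocity)) velocity else pc$v
  switch(pc$type,
    linear = {
      if (!is.null(pc$rate)) linear_protocol(pc$rate)
      else linear_protocol(pc$a1 * v)
    },
    power = ,
    power_law = {
      a <- if (!is.null(pc$coefficient)) pc$coefficient
           else if (!is.null(pc$a2)) pc$a2 else pc$a1
      n <- if (!is.null(pc$exponent)) pc$exponent
           else if (!is.null(pc$a2)) 2 else 1
      power_law_protocol(a, n, v)
    },
    wlc = wlc_protocol(pc$lp, pc$lc, v,
                       kBT = if (is.null(config$bond$kbt)) 4.11
                             else config$bond$kbt),
    tabulated = {
      fd <- read_force_distance(pc$file)
      tabulated_protocol(fd$distance, fd$force, v,
                         smooth_window = pc$smooth_window)
    },
    stop(sprintf("unknown protocol type '%s'", pc$type)))
}

#' @rdname protocol_from_config
#' @export
bond_from_config <- function(config) {
  bc <- config$bond
  bond_parameters(bc$xb, bc$koff_th,
                  kBT = if (is.null(bc$kbt)) 4.11 else bc$kbt)
}

#' @rdname protocol_from_config
#' @export
family_from_config <- function(config) {
  pc <- config$protocol
  kbt <- if (is.null(config$bond$kbt)) 4.11 else config$bond$kbt
  switch(pc$type,
    linear = linear_family(pc$a1),
    power = ,
    power_law = power_law_family(
      if (!is.null(pc$coefficient)) pc$coefficient else pc$a2,
      if (!is.null(pc$exponent)) pc$exponent else 2),
    wlc = wlc_family(pc$lp, pc$lc, kBT = kbt),
    stop(sprintf("no velocity-indexed family for protocol type '%s'",
                 pc$type)))
}

#' Generate a complete synthetic fixture set
#'
#' Writes, under `dir`: a tabulated worm-like chain force-distance curve
#' (`wlc_curve.txt`), rupture-force datasets for each configured velocity
#' at N in {50, 300} (`ruptures_vXXX_nYYY.txt`), and the analytic
#' velocity/peak-force table (`peak_table.txt`). Deterministic under the
#' config's master seed: regenerating with the same seed reproduces the
#' numeric content byte for byte.
#'
#' @param config A configuration list; defaults to [default_run_config()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
generate_fixtures <- function(config = default_run_config(), dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop(sprintf("cannot create directory %s", dir))
  params <- bond_from_config(config)
  fam <- family_from_config(config)
  vels <- unlist(config$velocities)
  master <- config$simulate$seed
  paths <- character(0)

  # tabulated WLC force-distance curve on 200 nodes
  pc <- config$protocol
  if (identical(pc$type, "wlc")) {
    L <- seq(0, pc$lc * 0.995, length.out = 200)
    Fi <- wlc_force(pc$lp, pc$lc, L,
                    kBT = if (is.null(config$bond$kbt)) 4.11
                          else config$bond$kbt)
    p <- file.path(dir, "wlc_curve.txt")
    writeLines(c(header_lines(list(
      format = "nldfs force-distance curve",
      columns = "distance_um force_pN",
      lp_nm = pc$lp, lc_um = pc$lc)),
      sprintf("%.10g %.10g", L, Fi)), p)
    paths <- c(paths, p)
  }

  set.seed(master)
  seeds <- matrix(sample.int(.Machine$integer.max, length(vels) * 2),
                  nrow = length(vels))
  for (j in seq_along(vels)) {
    prot <- fam(vels[j])
    sm <- rupture_sampler(params, prot)
    for (ni in 1:2) {
      N <- c(50, 300)[ni]
      d <- sample_rupture_forces(params, prot, N, seed = seeds[j, ni],
                                 sampler = sm)
      p <- file.path(dir, sprintf("ruptures_v%g_n%d.txt", vels[j], N))
      write_rupture_forces(d, p)
      paths <- c(paths, p)
    }
  }

  Fstar <- predict_peak_forces(params, fam, vels)
  p <- file.path(dir, "peak_table.txt")
  writeLines(c(header_lines(list(
    format = "nldfs analytic velocity/peak-force table",
    columns = "velocity_um_s peak_force_pN",
    xb_nm = params$xb, koff_th_s = params$koff_th,
    kBT_pN_nm = params$kBT)),
    sprintf("%.10g %.6f", vels, Fstar)), p)
  paths <- c(paths, p)
  invisible(paths)
}
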