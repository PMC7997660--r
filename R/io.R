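#' Default run configuration
#'
#' All tunable analysis defaults in one nested list: worm-like chain
#' parameters, construct geometry, burst thresholds (5 bp excursion, 25 bp
#' processivity), smoothing and velocity windows (51 / 50 points), melt
#' criteria (2 bp / 5 sample pairing, 4 bp bare-hairpin amplitude, 0.2 s
#' max lifetime), the mean low-processivity burst duration `tau_low` (7 s),
#' simulator parameters, and fitting options.
#'
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    wlc = list(
      ds = list(persistence_nm = 50, contour_nm = 0.34, stretch_pN = 1000),
      ss = list(persistence_nm = 1.0, contour_nm = 0.59, stretch_pN = 1000),
      kT_pNnm = 4.11),
    construct = list(handle_bp = 3050, loading_site_nt = 10, stem_bp = 89,
                     loop_nt = 4),
    bursts = list(min_excursion_bp = 5, threshold_bp = 25,
                  smooth_window_points = 51, velocity_window_points = 50,
                  velocity_bin_bp = 2, tau_low_s = 7),
    melt = list(min_step_bp = 2, window_points = 5, bare_min_amplitude_bp = 4,
                max_lifetime_s = 0.2),
    steps = list(quality_threshold = 1.2),
    simulator = list(forward_rate = 5, backstep_prob = 0.19,
                     backslide_prob = 0.05, k_on = 1.2e8, amplitude_bp = 5,
                     lifetime_s = 0.020, noise_sd = 0.3,
                     sampling_rate_hz = 89,
                     bursts_per_molecule_mean = 5,
                     bursts_per_molecule_sd = 1),
    fit = list(n_boot = 200, free_koff_prime = FALSE),
    seed = 1L), class = "run_config")
}

.validate_config <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]))
      .validate_config(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      .merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; keys not present in
#' [default_config()] are rejected.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  .validate_config(user, cfg)
  structure(.merge_config(unclass(cfg), user), class = "run_config")
}

#' Short stable hash of a configuration
#'
#' Polynomial rolling hash (djb2-style, mod 2^31 to stay in R's integer
#' range) of the YAML serialization, carried in output-table headers so
#' results can be traced back to the configuration that produced them.
#'
#' @param config A `run_config` list.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read a trace in the tab-separated trace format
#'
#' Plain TSV with `# key = value` comment headers (`force_pN`, `rpa2_nM`,
#' `sampling_rate_hz`, `seed`, `units`, `molecule_id`) followed by two
#' columns `time_s` and `position`. `read_trace()` restores the metadata;
#' a file in nm units is converted to bp on load using the ssDNA
#' worm-like chain at the header force (two released nucleotides per
#' unwound base pair), which requires `force_pN` in the header.
#'
#' @param trace An `unwind_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "unwind_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(force_pN = attr(trace, "force_pN"),
            rpa2_nM = attr(trace, "rpa2_nM"),
            sampling_rate_hz = attr(trace, "sampling_rate_hz"),
            seed = attr(trace, "seed"),
            units = attr(trace, "units"),
            molecule_id = attr(trace, "molecule_id"))
  for (nm in names(meta))
    writeLines(sprintf("# %s = %s", nm, meta[[nm]]), con)
  writeLines("time_s\tposition", con)
  utils::write.table(data.frame(trace), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' @rdname write_trace
#' @param convert_to_bp Convert nm-unit files to bp on load (default TRUE).
#' @return `read_trace()` returns an `unwind_trace`.
#' @export
read_trace <- function(path, convert_to_bp = TRUE) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  meta <- list()
  for (i in hdr_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([^=[:space:]]+)\\s*=\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) != 3)
      stop("malformed header at line ", i, ": '", lines[i], "'")
    meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!all(c("time_s", "position") %in% names(dat)))
    stop("trace file must have columns time_s and position")
  num <- function(x) if (is.null(x) || x == "NA") NA_real_ else as.numeric(x)
  units <- if (is.null(meta$units)) "bp" else meta$units
  force <- num(meta$force_pN)
  position <- dat$position
  if (units == "nm" && convert_to_bp) {
    if (is.na(force))
      stop("nm-unit trace requires force_pN in the header for conversion")
    position <- bp_unwound(position, force)
    units <- "bp"
  }
  unwind_trace(dat$time_s, position, force_pN = force,
               rpa2_nM = num(meta$rpa2_nM),
               sampling_rate_hz = num(meta$sampling_rate_hz),
               units = units,
               molecule_id = if (is.null(meta$molecule_id)) "trace1"
                 else meta$molecule_id,
               seed = if (is.null(meta$seed) || meta$seed == "NA")
                 NA_integer_ else as.integer(meta$seed))
}

#' Write / read a result table with a commented header
#'
#' TSV with `# key = value` comments (including the config hash) above the
#' column header; used for step, event, burst, summary, and fit tables.
#'
#' @param x Data frame.
#' @param path File path.
#' @param meta Named character vector of header metadata.
#' @export
write_result_table <- function(x, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s = %s", nm, meta[[nm]]), con)
  utils::write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_result_table
#' @return `read_result_table()` returns the data frame with header
#'   metadata in attribute `meta`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  meta <- character()
  for (i in hdr_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([^=[:space:]]+)\\s*=\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) == 3) meta[m[2]] <- trimws(m[3])
  }
  dat <- utils::read.table(
    text = lines[setdiff(seq_along(lines), hdr_idx)],
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  attr(dat, "meta") <- meta
  dat
}

#' Write a first-passage dataset as TSV
#'
#' @param fp A `first_passage` data frame.
#' @param path File path.
#' @param meta Extra header metadata.
#' @export
write_first_passage <- function(fp, path, meta = character()) {
  write_result_table(as.data.frame(fp), path, meta)
}

#' @rdname write_first_passage
#' @export
read_first_passage <- function(path) {
  dat <- read_result_table(path)
  class(dat) <- c("first_passage", class(dat))
  dat
}
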