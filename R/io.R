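#' Write a binned spectrum to delimited text
#'
#' Format: `# key=value` metadata lines (`phase`, `duration_s`,
#' `sample_flow_lpm`, `run_id`) followed by a CSV table with header
#' `bin_lower_um,bin_upper_um,count`. Counts round-trip bit-exact.
#'
#' @param spec A `binned_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "binned_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# phase=", spec$phase),
    paste0("# duration_s=", format(spec$duration, digits = 17)),
    paste0("# sample_flow_lpm=", format(spec$sample_flow, digits = 17)),
    paste0("# run_id=", spec$run_id),
    "bin_lower_um,bin_upper_um,count"
  ), con)
  writeLines(sprintf("%.17g,%.17g,%.17g",
                     spec$grid$lower, spec$grid$upper, spec$counts), con)
  invisible(path)
}

# Parse "# key=value" metadata lines at the top of a file.
parse_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read a binned spectrum from delimited text
#'
#' Counterpart of [write_spectrum()]. The size grid is reconstructed from the
#' bin edges; bins must be contiguous and counts non-negative, otherwise a
#' parse error naming the offending line is raised.
#'
#' @param path File path.
#' @return A `binned_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- parse_meta(lines)
  for (k in c("phase", "duration_s", "sample_flow_lpm", "run_id")) {
    if (is.null(meta[[k]])) {
      stop("parse error in ", path, ": missing metadata key '", k, "'",
           call. = FALSE)
    }
  }
  body_at <- which(!grepl("^#", lines))[1L]
  if (is.na(body_at) || lines[body_at] != "bin_lower_um,bin_upper_um,count") {
    stop("parse error in ", path, " line ", body_at %||% NA,
         ": expected header 'bin_lower_um,bin_upper_um,count'", call. = FALSE)
  }
  tab <- utils::read.csv(text = lines[seq(body_at, length(lines))])
  if (!is.numeric(tab$count) || anyNA(tab$count)) {
    bad <- body_at + which(is.na(suppressWarnings(as.numeric(tab$count))))[1L]
    stop("parse error in ", path, " line ", bad, ": non-numeric count",
         call. = FALSE)
  }
  if (any(tab$count < 0)) {
    bad <- body_at + which(tab$count < 0)[1L]
    stop("parse error in ", path, " line ", bad, ": negative count",
         call. = FALSE)
  }
  k <- nrow(tab)
  if (k > 1L) {
    gap <- abs(tab$bin_lower_um[-1L] - tab$bin_upper_um[-k]) >
      1e-9 * tab$bin_upper_um[-k]
    if (any(gap)) {
      bad <- body_at + which(gap)[1L] + 1L
      stop("parse error in ", path, " line ", bad, ": non-contiguous bins",
           call. = FALSE)
    }
  }
  ratios <- tab$bin_upper_um[-k] / tab$bin_lower_um[-k]   # last bin may be clipped
  ipd <- as.integer(round(1 / log10(stats::median(ratios))))
  widths <- tab$bin_upper_um - tab$bin_lower_um
  grid <- structure(
    list(lower = tab$bin_lower_um, upper = tab$bin_upper_um,
         centers = tab$bin_lower_um + widths / 2, widths = widths,
         intervals_per_decade = ipd),
    class = "size_grid"
  )
  binned_spectrum(grid, tab$count, phase = meta$phase,
                  duration = as.numeric(meta$duration_s),
                  sample_flow = as.numeric(meta$sample_flow_lpm),
                  run_id = meta$run_id)
}

#' Write a flow trace to delimited text
#'
#' Format: `# device=` and `# phase_bounds=i,j` metadata lines followed by a
#' CSV table `time_s,flow_lpm[,pressure_kpa]`.
#'
#' @param trace A `flow_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flow_trace <- function(trace, path) {
  stopifnot(inherits(trace, "flow_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# device=", trace$device), con)
  if (!is.null(trace$phase_marks)) {
    writeLines(paste0("# phase_bounds=", trace$phase_marks[1L], ",",
                      trace$phase_marks[2L]), con)
  }
  if (is.null(trace$pressure_drop)) {
    writeLines("time_s,flow_lpm", con)
    writeLines(sprintf("%.17g,%.17g", trace$time, trace$flow), con)
  } else {
    writeLines("time_s,flow_lpm,pressure_kpa", con)
    writeLines(sprintf("%.17g,%.17g,%.17g", trace$time, trace$flow,
                       trace$pressure_drop), con)
  }
  invisible(path)
}

#' Read a flow trace from delimited text
#'
#' @param path File path.
#' @return A `flow_trace`.
#' @export
read_flow_trace <- function(path) {
  lines <- readLines(path)
  meta <- parse_meta(lines)
  body_at <- which(!grepl("^#", lines))[1L]
  tab <- utils::read.csv(text = lines[seq(body_at, length(lines))])
  if (!all(c("time_s", "flow_lpm") %in% names(tab))) {
    stop("parse error in ", path, ": expected columns time_s, flow_lpm",
         call. = FALSE)
  }
  marks <- NULL
  if (!is.null(meta$phase_bounds)) {
    marks <- as.integer(strsplit(meta$phase_bounds, ",")[[1L]])
  }
  flow_trace(tab$time_s, tab$flow_lpm,
             pressure_drop = tab$pressure_kpa,
             device = meta$device %||% "device", phase_marks = marks)
}

#' Read a study manifest
#'
#' Loads `manifest.csv` from a generated study tree and checks that every
#' referenced file exists and that (device, run, mode, phase, kind) rows are
#' unique.
#'
#' @param dir Study directory containing `manifest.csv`.
#' @return The manifest data frame with an absolute `path` column.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) {
    stop("no manifest.csv found in ", dir, call. = FALSE)
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device", "run_id", "mode", "phase", "kind", "path")
  if (!all(need %in% names(m))) {
    stop("parse error in ", path, ": manifest must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, m[c("device", "run_id", "mode", "phase", "kind")])
  if (anyDuplicated(key)) {
    stop("manifest has duplicate (device, run, mode, phase, kind) rows",
         call. = FALSE)
  }
  m$path <- file.path(dir, m$path)
  missing <- !file.exists(m$path)
  if (any(missing)) {
    stop("manifest references missing file(s): ",
         paste(utils::head(m$path[missing], 3L), collapse = ", "),
         call. = FALSE)
  }
  m
}
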