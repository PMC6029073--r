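#' Construct a single flow-cytometry sample
#'
#' A flow sample is one replicate's vector of per-cell fluorescence
#' intensities together with its metadata: strain, replicate id, experiment
#' day and induction condition. Samples are stored as rows of a tibble
#' with the intensity vector in a list column, so collections of samples
#' compose with the usual dplyr verbs.
#'
#' @param strain Strain identifier (e.g. `"WT"`, `"opy2_d233_245"`).
#' @param replicate Replicate identifier, unique within (strain, day,
#'   condition).
#' @param day Experiment-day identifier; wild-type pooling is done within
#'   a day.
#' @param condition `"uninduced"` or `"induced"` (0.4 M NaCl, 60 min).
#' @param intensities Numeric vector of per-cell fluorescence values
#'   (arbitrary units); must be finite with at least `min_events` values.
#' @param min_events Minimum number of events accepted (default 100).
#' @return A one-row tibble with columns `strain`, `replicate`, `day`,
#'   `condition`, `n_events`, `intensities` (list column).
#' @export
flow_sample <- function(strain, replicate, day, condition, intensities,
                        min_events = 100L) {
  condition <- match.arg(condition, c("uninduced", "induced"))
  intensities <- as.numeric(intensities)
  if (length(intensities) == 0) {
    stop("flow_sample(): no events in sample ", strain, "/", replicate)
  }
  if (length(intensities) < min_events) {
    stop("flow_sample(): sample ", strain, "/", replicate, " has ",
         length(intensities), " events; floor is ", min_events)
  }
  if (!all(is.finite(intensities))) {
    stop("flow_sample(): non-finite intensities in ", strain, "/", replicate)
  }
  tibble::tibble(
    strain = as.character(strain),
    replicate = as.character(replicate),
    day = as.character(day),
    condition = condition,
    n_events = length(intensities),
    intensities = list(intensities)
  )
}

# internal: sanity-check a tibble of flow samples
validate_flow_samples <- function(x, min_events = 100L) {
  need <- c("strain", "replicate", "day", "condition", "n_events",
            "intensities")
  if (!all(need %in% names(x))) {
    stop("expected a flow-sample tibble with columns ",
         paste(need, collapse = ", "))
  }
  key <- paste(x$strain, x$replicate, x$day, x$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (strain, replicate, day, condition) keys: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  }
  ok <- purrr::map2_lgl(x$intensities, x$n_events, function(v, n) {
    length(v) == n && n >= min_events && all(is.finite(v))
  })
  if (!all(ok)) {
    stop("invalid flow sample(s): ",
         paste(x$strain[!ok], x$replicate[!ok], sep = "/", collapse = "; "))
  }
  invisible(x)
}

#' Read a sample sheet and its per-replicate data files
#'
#' The sample sheet is a TSV with columns `strain`, `replicate`, `day`,
#' `condition` and `path`; each `path` points (relative to `data_root`) to
#' a one-column numeric CSV/TSV of per-cell intensities, with an optional
#' single header line. Values are loaded unmodified and event order is
#' preserved.
#'
#' @param sheet_path Path to the sample-sheet TSV.
#' @param data_root Directory against which relative `path` entries are
#'   resolved (default: the sheet's directory).
#' @param min_events Minimum events per sample (default 100).
#' @return A flow-sample tibble (one row per sheet row).
#' @export
read_sample_table <- function(sheet_path, data_root = dirname(sheet_path),
                              min_events = 100L) {
  if (!file.exists(sheet_path)) {
    stop("read_sample_table(): sheet not found: ", sheet_path)
  }
  sheet <- utils::read.delim(sheet_path, sep = "\t",
                             colClasses = "character", check.names = FALSE)
  need <- c("strain", "replicate", "day", "condition", "path")
  if (!all(need %in% names(sheet))) {
    stop("read_sample_table(): sheet must have columns ",
         paste(need, collapse = ", "))
  }
  rows <- purrr::pmap(sheet[need], function(strain, replicate, day,
                                            condition, path) {
    f <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(data_root, path)
    where <- paste0("row (", strain, ", ", replicate, ", ", day, ", ",
                    condition, ")")
    if (!file.exists(f)) {
      stop("read_sample_table(): missing data file ", f, " for ", where)
    }
    x <- read_intensity_file(f, where)
    flow_sample(strain, replicate, day, condition, x,
                min_events = min_events)
  })
  out <- dplyr::bind_rows(rows)
  validate_flow_samples(out, min_events = min_events)
  out
}

# one-column numeric file, optional header line; decimal point only
read_intensity_file <- function(path, where = path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop("read_sample_table(): no events in ", path, " for ", where)
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1]) && length(lines) > 1) {
    # tolerate a single header line
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (length(vals) == 0) {
    stop("read_sample_table(): no events in ", path, " for ", where)
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("read_sample_table(): non-numeric value '", lines[bad], "' at data line ",
         bad, " of ", path, " for ", where)
  }
  vals
}

#' Write flow samples as per-replicate files plus a sample sheet
#'
#' Inverse of [read_sample_table()]: each sample's intensities are written
#' to a one-column file with full double precision (17 significant
#' digits, so values survive a write/read round trip bit for bit), and a
#' sample sheet TSV indexes them.
#'
#' @param samples Flow-sample tibble.
#' @param dir Output directory (created if needed).
#' @param sheet_name File name of the sheet inside `dir`.
#' @return The sheet path, invisibly.
#' @export
write_flow_samples <- function(samples, dir, sheet_name = "samples.tsv") {
  validate_flow_samples(samples)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s_%s_%s_%s.csv", samples$strain, samples$replicate,
                   samples$day, samples$condition)
  purrr::walk2(samples$intensities, paths, function(v, p) {
    writeLines(c("intensity", sprintf("%.17g", v)), file.path(dir, p))
  })
  sheet <- data.frame(strain = samples$strain, replicate = samples$replicate,
                      day = samples$day, condition = samples$condition,
                      path = paths)
  sheet_path <- file.path(dir, sheet_name)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sheet_path)
}

#' Write analysis records to a TSV file
#'
#' Writes any record tibble (divergence records, test results, fit
#' summaries) as tab-separated text with a stable column order and full
#' double precision, so that [read_records()] recovers the numeric values
#' exactly.
#'
#' @param records A data frame of records; list columns are not supported.
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_records <- function(records, out_path) {
  records <- as.data.frame(records)
  if (any(vapply(records, is.list, logical(1)))) {
    stop("write_records(): list columns cannot be serialised; flatten first")
  }
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  ok <- tryCatch({
    utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_records(): cannot write ", out_path, ": ",
                        conditionMessage(ok))
  invisible(out_path)
}

#' Read back a record TSV written by [write_records()]
#'
#' @param path Path to the TSV.
#' @return A tibble with numeric columns restored.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("read_records(): no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  num <- vapply(df, function(v) {
    is.numeric(v) || (is.character(v) && length(v) > 0 &&
                        !anyNA(suppressWarnings(as.numeric(v))))
  }, logical(1))
  df[num] <- lapply(df[num], function(v) as.numeric(v))
  tibble::as_tibble(df)
}
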