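# Delimiter sniffing for instrument exports: comma, semicolon or tab, with
# tolerance for the German decimal comma that SI Analytics logs use when
# exported with a semicolon delimiter.
.sniff_sep <- function(lines) {
  counts <- vapply(c(";", "\t", ","), function(s)
    stats::median(lengths(strsplit(lines, s, fixed = TRUE))), numeric(1))
  seps <- names(counts)[counts >= 3]
  if (length(seps) == 0) stop_slurrycbc("format",
    "could not detect a delimiter (need columns for volume, pH, temperature)")
  seps[1]
}

.match_col <- function(nms, patterns, what) {
  hit <- which(Reduce(`|`, lapply(patterns, function(p) grepl(p, nms, ignore.case = TRUE))))
  if (length(hit) == 0)
    stop_slurrycbc("format", "no column recognised for %s (columns: %s)",
                   what, paste(nms, collapse = ", "))
  hit[1]
}

#' Read a titration log
#'
#' Reads a delimited instrument log (comma, semicolon or tab separated;
#' decimal commas tolerated) with columns for cumulative titrant volume
#' (mL), pH and temperature (degC), attaches the sample metadata, and
#' returns a validated [titration_record()]. Rows are sorted by volume;
#' duplicate volumes keep the last pH reading.
#'
#' @param file_path path to the log file; lines starting with `#` are
#'   ignored.
#' @param metadata named list passed on to [titration_record()]
#'   (`sample_id`, `slurry_type`, `storage`, `week`, `replicate`,
#'   `direction`, `titrant`, `titrant_molarity`, `sample_mass`,
#'   `diluent_mass`).
#' @return a `titration_record`.
#' @export
read_titration <- function(file_path, metadata = list()) {
  lines <- readLines(file_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop_slurrycbc("format", "file %s has no data rows", file_path)
  sep <- .sniff_sep(lines)
  dec <- if (sep == ";" && any(grepl("[0-9],[0-9]", lines[-1]))) "," else "."
  df <- utils::read.table(text = lines, sep = sep, dec = dec, header = TRUE,
                          stringsAsFactors = FALSE)
  iv <- .match_col(names(df), c("^vol", "ml"), "cumulative volume (mL)")
  ip <- .match_col(names(df), c("^ph$", "^ph[._ ]"), "pH")
  it <- .match_col(names(df), c("^temp", "celsius"), "temperature (degC)")
  steps <- data.frame(volume_mL = as.numeric(df[[iv]]),
                      pH = as.numeric(df[[ip]]),
                      temperature = as.numeric(df[[it]]))
  if (anyNA(steps)) stop_slurrycbc("data", "non-numeric values in %s", file_path)
  # cumulative dose can never decrease in acquisition order; a decrease
  # signals a corrupt or truncated export, not a reorderable log
  if (any(diff(steps$volume_mL) < 0))
    stop_slurrycbc("data", "cumulative volume decreases within %s", file_path)
  do.call(titration_record, c(list(steps = steps), metadata))
}

#' Read a batch of titration logs from a manifest
#'
#' The manifest (YAML or JSON) maps log files to their metadata: a list of
#' entries each with a `file` field plus any [titration_record()] metadata
#' fields. Relative paths resolve against the manifest's directory.
#'
#' @param manifest_path path to the YAML/JSON manifest.
#' @return list of `titration_record` objects.
#' @export
read_batch <- function(manifest_path) {
  entries <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  lapply(entries, function(e) {
    f <- e$file
    if (is.null(f)) stop_slurrycbc("format", "manifest entry without a 'file' field")
    if (!file.exists(f)) f <- file.path(base, f)
    read_titration(f, e[setdiff(names(e), "file")])
  })
}

#' Write result tables as tidy delimited files
#'
#' Writes each table of a named list (peak tables, segment tables, CBC
#' curves, QC tables) as a CSV under `out_dir`, with units (taken from the
#' table's `units` attribute) recorded as `#` comment lines that
#' [read_result_table()] skips on the way back in.
#'
#' @param results a data.frame or a named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  if (is.data.frame(results)) results <- list(results = results)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop_slurrycbc("parameter", "results list must be named")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_slurrycbc("io", "cannot create output directory %s", out_dir)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    path <- file.path(out_dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    units <- attr(results[[nm]], "units")
    if (!is.null(units)) writeLines(paste("#", units), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a table written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame, `#` comment lines skipped.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
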