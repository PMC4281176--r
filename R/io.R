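detect_sep <- function(header_line) {
  for (s in c("\t", ",", ";")) {
    if (grepl(s, header_line, fixed = TRUE)) return(s)
  }
  " "
}

#' Read a maneuver from a delimited text file
#'
#' The file must have a header naming at least `time` and one of `flow` /
#' `volume`; the delimiter (tab, comma, semicolon or whitespace) is
#' auto-detected. Units default to s, L/s and L; set `units` entries to
#' `"ms"` / `"mL/s"` / `"mL"` for millisecond or milliliter data, which are
#' converted on ingest (with a message). Validation and any resampling
#' follow [maneuver()]. When both flow and volume columns are present, both
#' are kept and their mutual consistency is checked to 0.01 L.
#'
#' @param path File path.
#' @param units Named list with entries `time`, `flow`, `volume`.
#' @param resample_rate Target rate (Hz) for non-uniform input.
#' @return A [maneuver()].
#' @export
read_maneuver <- function(path,
                          units = list(time = "s", flow = "L/s", volume = "L"),
                          resample_rate = 100) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- detect_sep(header)
  df <- read.table(path, header = TRUE, sep = sep, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!"time" %in% names(df)) stop_input("missing 'time' column in ", path)
  if (!any(c("flow", "volume") %in% names(df))) {
    stop_input("need a 'flow' or 'volume' column in ", path)
  }
  if (any(diff(df$time) <= 0)) {
    stop_input("time column is not strictly increasing in ", path)
  }
  time <- df$time
  if (identical(units$time, "ms")) {
    time <- time / 1000
    message("converted time from ms to s")
  }
  flow <- df[["flow"]]
  if (!is.null(flow) && identical(units$flow, "mL/s")) {
    flow <- flow / 1000
    message("converted flow from mL/s to L/s")
  }
  volume <- df[["volume"]]
  if (!is.null(volume) && identical(units$volume, "mL")) {
    volume <- volume / 1000
    message("converted volume from mL to L")
  }
  mnv <- maneuver(time = time, flow = flow, volume = volume,
                  meta = list(source = path),
                  resample_rate = resample_rate)
  if (!is.null(flow) && !is.null(volume)) {
    v_chk <- integrate_flow(mnv$flow, mnv$time)
    dev <- max(abs(v_chk - (mnv$volume - mnv$volume[1])))
    if (dev > 0.01) {
      warning("flow and volume columns disagree by up to ",
              signif(dev, 3), " L after integration")
    }
  }
  mnv
}

#' Write a maneuver to a delimited text file
#'
#' Tab-separated columns `time`, `flow`, `volume` in s, L/s, L at full
#' double precision, so a write-read round trip is exact to 1e-9.
#'
#' @param mnv A [maneuver()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maneuver <- function(mnv, path) {
  df <- data.frame(time = sprintf("%.12g", mnv$time),
                   flow = sprintf("%.12g", mnv$flow),
                   volume = sprintf("%.12g", mnv$volume))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a session manifest
#'
#' A session file is a delimited table with a `file` column of maneuver
#' file paths (relative paths resolve against the manifest's directory) and
#' optional `id` and `label` columns (labels in \{0, 1, 2\}).
#'
#' @param path Manifest file path.
#' @return List with `maneuvers` (list of [maneuver()]), `ids`, `labels`
#'   (or `NULL`).
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  header <- readLines(path, n = 1L)
  df <- read.table(path, header = TRUE, sep = detect_sep(header),
                   strip.white = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"file" %in% names(df)) stop_input("session manifest needs a 'file' column")
  if (nrow(df) < 1L) stop_input("session manifest is empty")
  if ("label" %in% names(df) && !all(df$label %in% c(0, 1, 2))) {
    stop_input("session labels must be 0, 1 or 2")
  }
  base <- dirname(path)
  files <- ifelse(grepl("^/", df$file), df$file, file.path(base, df$file))
  list(maneuvers = lapply(files, read_maneuver),
       ids = if ("id" %in% names(df)) df$id else basename(files),
       labels = if ("label" %in% names(df)) as.integer(df$label) else NULL)
}

#' Write a labeled synthetic dataset to disk
#'
#' One tab-separated curve file per maneuver plus a `manifest.csv` with
#' columns id, file, label, defect, severity, seed.
#'
#' @param dataset A [generate_labeled_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$file <- paste0(man$id, ".tsv")
  for (i in seq_along(dataset$maneuvers)) {
    write_maneuver(dataset$maneuvers[[i]], file.path(dir, man$file[i]))
  }
  mpath <- file.path(dir, "manifest.csv")
  write.table(man[, c("id", "file", "label", "defect", "severity", "seed")],
              mpath, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

report_to_list <- function(report) {
  list(grade = report$grade,
       config_fingerprint = report$config_fingerprint,
       indices = report$indices[c("FVC", "FEV1", "PEF", "PEFT", "T_zero",
                                  "BEV", "EOTV", "Tex", "FET100")],
       criteria = lapply(report$criterion_results, function(r) {
         list(id = r$criterion_id, outcome = r$outcome,
              metrics = r$metrics, thresholds = r$thresholds,
              reason = r$reason)
       }))
}

#' Serialize a quality report
#'
#' @param report A [assess_maneuver()] result.
#' @param path Output path; `NULL` writes to standard output.
#' @param format `"text"` (human-readable table) or `"json"`.
#' @return `path` (or the text, invisibly, when `path` is `NULL`).
#' @export
write_report <- function(report, path = NULL, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                            digits = NA, null = "null", pretty = TRUE)
  } else {
    tab <- report_table(report)
    lines <- c(sprintf("grade: %d", report$grade),
               sprintf("config: %s", report$config_fingerprint),
               sprintf("%-6s %-14s %-22s %s", "id", "outcome", "metric", "value"),
               sprintf("%-6s %-14s %-22s %s", tab$criterion, tab$outcome,
                       ifelse(is.na(tab$metric), "-", tab$metric),
                       ifelse(is.na(tab$value), "-",
                              formatC(tab$value, digits = 5, format = "g"))))
    txt <- paste(lines, collapse = "\n")
  }
  if (is.null(path)) {
    cat(txt, "\n", sep = "")
    invisible(txt)
  } else {
    writeLines(as.character(txt), path)
    invisible(path)
  }
}
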