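# Trial store I/O. Two on-disk forms:
#  * "csv": a long delimited-text table (comma delimiter, '.' decimal,
#    '#'-prefixed metadata comments "key=value" for fs/subject/dimension)
#    with columns trial_id, channel, rating, value — one row per sample, in
#    sample order. Fully text, locale-fixed.
#  * "rds": an R serialization of a trial_set, for runtime round-trips of
#    large subjects.

.montage_all <- function() montage_channels()

#' Read a labeled trial set from disk
#'
#' Ratings are mapped to class labels by the >= 5 rule (rating >= 5 is
#' positive). Channels whose label is not in the 32-channel montage are
#' skipped with a warning.
#'
#' @param path File path.
#' @param format `"csv"` (long delimited text) or `"rds"`.
#' @return A [trial_set()].
#' @export
read_trials <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "rds") {
    ts <- readRDS(path)
    if (!inherits(ts, "trial_set")) stop("file does not contain a trial_set")
    return(ts)
  }
  meta <- list(fs = NULL, subject = "unknown", dimension = "arousal")
  for (ln in grep("^#", readLines(path, n = 50L), value = TRUE)) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      if (key %in% names(meta)) meta[[key]] <- val
    }
  }
  if (is.null(meta$fs)) stop("schema error: missing 'fs' metadata comment")
  fs <- as.numeric(meta$fs)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("trial_id", "channel", "rating", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  }
  montage <- .montage_all()
  unknown <- setdiff(unique(df$channel), montage)
  if (length(unknown) > 0) {
    warning("skipping unknown channel label(s): ",
            paste(unknown, collapse = ", "))
    df <- df[df$channel %in% montage, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid channel data in file")
  trials <- lapply(unique(df$trial_id), function(id) {
    sub <- df[df$trial_id == id, , drop = FALSE]
    data <- lapply(split(sub$value, sub$channel), as.numeric)
    list(trial_id = id, rating = sub$rating[1], data = data)
  })
  trial_set(meta$subject, trials, fs = fs, dimension = meta$dimension)
}

#' Write a trial set to disk
#'
#' @param trials A [trial_set()].
#' @param path Destination file.
#' @param format `"csv"` or `"rds"`; see [read_trials()].
#' @export
write_trials <- function(trials, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(trials, path)
    return(invisible(path))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", format(trials$fs)),
               sprintf("# subject=%s", trials$subject),
               sprintf("# dimension=%s", trials$dimension)), con)
  writeLines("trial_id,channel,rating,value", con)
  for (tr in trials$trials) {
    rating <- if (!is.null(tr$rating)) tr$rating
              else if (tr$label == "positive") 7 else 3
    for (ch in names(tr$data)) {
      writeLines(sprintf("%s,%s,%s,%s", tr$trial_id, ch, format(rating),
                         formatC(tr$data[[ch]], digits = 6, format = "g")),
                 con)
    }
  }
  invisible(path)
}

#' Write an evaluation report
#'
#' Writes the per-pair confusion table as delimited text (6-significant-digit
#' fixed formatting, deterministic byte stream) and a JSON summary (mean/sd
#' accuracy, pair and tie counts, config echo) next to it.
#'
#' @param report An `evaluation_report` with at least one pair.
#' @param path CSV destination; the JSON summary goes to
#'   `<path without extension>_summary.json`.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "evaluation_report")) {
    stop("report must be an evaluation_report")
  }
  if (is.null(report$pairs) || nrow(report$pairs) < 1L) {
    stop("report must contain at least one template pair")
  }
  df <- report$pairs
  df$accuracy <- formatC(df$accuracy, digits = 6, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(path), "_summary.json")
  summary <- list(
    mean_accuracy = report$mean_accuracy,
    sd_accuracy = report$sd_accuracy,
    n_pairs = report$n_pairs,
    tie_count = report$tie_count,
    config = report$config
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = path, json = json_path))
}

#' Read back an evaluation report written by [write_report()]
#'
#' @param path The CSV path given to [write_report()].
#' @return An `evaluation_report`; confusion counts round-trip exactly.
#' @export
read_report <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(path), "_summary.json")
  summary <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  df$accuracy <- as.numeric(df$accuracy)
  structure(
    list(pairs = df, mean_accuracy = summary$mean_accuracy,
         sd_accuracy = summary$sd_accuracy, n_pairs = summary$n_pairs,
         tie_count = summary$tie_count, config = as.list(summary$config)),
    class = "evaluation_report"
  )
}

#' Write a BREM as delimited text
#'
#' 5 rows x 6 columns (or 6C for region matrices) with header row and a
#' leading rhythm-name column.
#'
#' @param brem A `brem` or `region_brem`.
#' @param path Destination file.
#' @export
write_brem <- function(brem, path) {
  m <- .brem_values(brem)
  df <- data.frame(rhythm = rownames(m),
                   apply(m, 2, function(x) formatC(x, digits = 6, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BREM written by [write_brem()]
#' @param path File path.
#' @return A numeric matrix with rhythm row names.
#' @export
read_brem_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
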