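#' Write a recording to the columnar text format
#'
#' Header comment lines carry metadata (`# sampling_rate=...`,
#' `# frequencies=...`, `# seed=...`), followed by a CSV with columns
#' `time,I_f1,Q_f1,I_f2,Q_f2,...`.
#'
#' @param recording An `mf_recording`.
#' @param path Output file path.
#' @param digits Significant digits written per value.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, digits = 10) {
  stopifnot(inherits(recording, "mf_recording"))
  n <- nrow(recording$signal)
  k <- ncol(recording$signal)
  tt <- (seq_len(n) - 1L) / recording$sampling_rate
  cols <- vector("list", 1 + 2 * k)
  cols[[1]] <- tt
  nms <- "time"
  for (j in seq_len(k)) {
    cols[[2 * j]] <- Re(recording$signal[, j])
    cols[[2 * j + 1]] <- Im(recording$signal[, j])
    nms <- c(nms, paste0("I_f", j), paste0("Q_f", j))
  }
  df <- stats::setNames(as.data.frame(cols), nms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate=%.10g", recording$sampling_rate),
               sprintf("# frequencies=%s",
                       paste(format(as.numeric(recording$frequencies),
                                    scientific = FALSE, trim = TRUE),
                             collapse = ",")),
               sprintf("# seed=%d", as.integer(recording$meta$seed %||% NA))),
             con)
  utils::write.table(format(df, digits = digits, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording from the columnar text format
#' @param path File written by [write_recording()].
#' @return An `mf_recording`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path, n = 50)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta_lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  sr <- as.numeric(get_meta("sampling_rate"))
  fr <- get_meta("frequencies")
  if (is.null(sr) || is.na(sr) || is.null(fr)) {
    stop(sprintf("malformed recording header in '%s': %s", path,
                 "missing sampling_rate/frequencies metadata"),
         call. = FALSE)
  }
  freqs <- frequency_set(as.numeric(strsplit(fr, ",")[[1]]))
  seed <- suppressWarnings(as.integer(get_meta("seed")))

  df <- utils::read.csv(path, comment.char = "#")
  k <- length(freqs)
  need <- c(paste0("I_f", seq_len(k)), paste0("Q_f", seq_len(k)))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("recording '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  signal <- matrix(complex(real = 0), nrow(df), k)
  for (j in seq_len(k)) {
    signal[, j] <- complex(real = df[[paste0("I_f", j)]],
                           imaginary = df[[paste0("Q_f", j)]])
  }
  colnames(signal) <- frequency_labels(freqs)
  structure(list(sampling_rate = sr,
                 duration = nrow(df) / sr,
                 frequencies = freqs,
                 signal = signal,
                 meta = list(seed = seed, generator = "file",
                             source = path)),
            class = "mf_recording")
}

#' Write / read a ground-truth or detected-event table as CSV
#' @param events Data frame (`cell_events` or `detected_events`).
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_events_csv <- function(events, path) {
  df <- as.data.frame(events)
  freqs <- attr(events, "frequencies")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(freqs)) {
    writeLines(sprintf("# frequencies=%s",
                       paste(format(freqs, scientific = FALSE, trim = TRUE),
                             collapse = ",")), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  lines <- readLines(path, n = 5)
  meta <- grep("^#\\s*frequencies=", lines, value = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  if (length(meta) > 0) {
    attr(df, "frequencies") <-
      as.numeric(strsplit(sub("^#\\s*frequencies=", "", meta[1]), ",")[[1]])
  }
  if ("flag" %in% names(df)) {
    class(df) <- c("detected_events", "data.frame")
  } else if ("center_time" %in% names(df)) {
    class(df) <- c("cell_events", "data.frame")
  }
  df
}

#' Serialize / restore min-max normalization statistics as key-value text
#' @param stats A [fit_normalizer()] object.
#' @param path Text file path.
#' @return `path` invisibly (write); a `minmax_norm` (read).
#' @export
write_normalizer <- function(stats, path) {
  stopifnot(inherits(stats, "minmax_norm"))
  lines <- c(sprintf("feature=%s", paste(stats$feature_names, collapse = ",")),
             sprintf("min=%s", paste(format(stats$min, digits = 17),
                                     collapse = ",")),
             sprintf("max=%s", paste(format(stats$max, digits = 17),
                                     collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    sub(paste0("^", key, "="), "",
        grep(paste0("^", key, "="), lines, value = TRUE)[1])
  }
  nms <- strsplit(val("feature"), ",")[[1]]
  mins <- as.numeric(strsplit(val("min"), ",")[[1]])
  maxs <- as.numeric(strsplit(val("max"), ",")[[1]])
  structure(list(min = stats::setNames(mins, nms),
                 max = stats::setNames(maxs, nms),
                 degenerate = maxs == mins,
                 feature_names = nms),
            class = "minmax_norm")
}

#' Persist / restore a trained viability model
#'
#' The model (including its embedded normalizer and metadata) is stored as
#' a serialized R object.
#'
#' @param model A `viability_svm`.
#' @param path File path (conventionally `.rds`).
#' @return `path` invisibly (write); a `viability_svm` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "viability_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "viability_svm")) {
    stop(sprintf("'%s' is not a saved viability model", path), call. = FALSE)
  }
  model
}
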