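#' Activity classes of the thigh-monitor epoch table
#'
#' The eight behaviour classes reported per 60-s epoch by the thigh
#' monitor's classifier export, in the package's canonical column order.
#'
#' @return Character vector of class names.
#' @export
behaviour_classes <- function() {
  c("sedentary", "upright", "stepping", "cycling", "primary_lying",
    "secondary_lying", "seated_transport", "non_wear")
}

# Tie-break priority for dominant-class labelling: rarer / more specific
# classes win ties (ties are measure-zero in field data; tests need
# determinism).
class_priority <- function() {
  c("stepping", "cycling", "upright", "seated_transport", "sedentary",
    "secondary_lying", "primary_lying", "non_wear")
}

default_behaviour_map <- local({
  m <- c("epoch_start", behaviour_classes(), "steps")
  stats::setNames(m, m)
})

#' Construct a behaviour epoch table
#'
#' Validates and classes a per-minute thigh behaviour table: one row per
#' 60-s epoch with the seconds spent in each activity class and the step
#' count. Epoch starts must sit on the 60-s grid and be strictly
#' increasing; gaps in the grid are legitimate (missing epochs) and are
#' never filled.
#'
#' @param df Data frame with column `epoch_start` plus the eight class
#'   columns (seconds) and `steps`.
#' @param sum_tolerance_s Allowed deviation of per-row class seconds from
#'   60 (exports round per-class seconds); default 0.5 s.
#' @return A `behaviour_epochs` data frame.
#' @export
behaviour_epochs <- function(df, sum_tolerance_s = 0.5) {
  cls <- behaviour_classes()
  need <- c("epoch_start", cls, "steps")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  df$epoch_start <- clock_time(df$epoch_start)
  tt <- as.numeric(df$epoch_start)
  if (any(tt %% 60 != 0)) {
    stop("integrity error: epoch_start not on the 60-s grid at row ",
         which(tt %% 60 != 0)[1L], call. = FALSE)
  }
  if (nrow(df) > 1L && any(diff(tt) <= 0)) {
    stop("integrity error: epoch_start not strictly increasing at row ",
         which(diff(tt) <= 0)[1L] + 1L, call. = FALSE)
  }
  sums <- rowSums(df[, cls])
  bad <- which(abs(sums - 60) > sum_tolerance_s)
  if (length(bad)) {
    stop("integrity error: class seconds sum to ", sums[bad[1L]],
         " (not 60 +/- ", sum_tolerance_s, ") at row ", bad[1L],
         call. = FALSE)
  }
  if (any(df$steps < 0)) {
    stop("integrity error: negative step count at row ",
         which(df$steps < 0)[1L], call. = FALSE)
  }
  bad_steps <- which(df$steps > 0 & df$stepping <= 0)
  if (length(bad_steps)) {
    stop("integrity error: steps > 0 with zero stepping seconds at row ",
         bad_steps[1L], call. = FALSE)
  }
  class(df) <- c("behaviour_epochs", "data.frame")
  df
}

#' Read a behaviour epoch table
#'
#' Reads the per-minute CSV export of the thigh monitor's behaviour
#' classification (seconds per activity class and steps per 60-s epoch),
#' mapping source columns through the dialect and validating every row.
#' Gaps in the 60-s grid are preserved as missing epochs, never zero-filled.
#'
#' @param path Path to the CSV.
#' @param dialect A [dialect()] whose `column_map` maps the canonical fields
#'   (`epoch_start`, the eight classes, `steps`) to source columns; `NULL`
#'   map means source columns already use canonical names.
#' @param sum_tolerance_s Passed to [behaviour_epochs()].
#' @return A `behaviour_epochs` data frame.
#' @export
read_behaviour_epochs <- function(path, dialect = limbwear::dialect(),
                                  sum_tolerance_s = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- resolve_map(dialect, c("epoch_start", behaviour_classes(), "steps"),
                     default_behaviour_map)
  df <- read.csv(path, check.names = FALSE)
  miss <- setdiff(unname(map), names(df))
  if (length(miss)) {
    stop("missing mandatory column '", miss[1L], "' in ", path, call. = FALSE)
  }
  out <- df[, unname(map)]
  names(out) <- names(map)
  if (!is.null(dialect$time_format)) {
    out$epoch_start <- clock_time(out$epoch_start,
                                  format = dialect$time_format)
  }
  behaviour_epochs(out, sum_tolerance_s = sum_tolerance_s)
}

#' Write a behaviour epoch table
#'
#' @param table A `behaviour_epochs` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_behaviour_epochs <- function(table, path) {
  out <- as.data.frame(table)
  out$epoch_start <- iso_stamp(out$epoch_start)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic result export with run manifest
#'
#' Writes every table in `tables` as a CSV with fixed column order,
#' ISO-8601 timestamps and `.` decimal separator, plus a `manifest.json`
#' recording the configuration hash, the seed, and MD5 checksums of the
#' inputs and of every emitted file. Identical inputs and configuration
#' produce byte-identical output files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param config Optional configuration object; hashed into the manifest.
#' @param inputs Optional character vector of input file paths to checksum.
#' @param seed Optional integer seed recorded in the manifest.
#' @return Invisibly, the paths written (manifest last).
#' @export
export_results <- function(tables, out_dir, config = NULL, inputs = NULL,
                           seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    for (j in seq_along(df)) {
      if (inherits(df[[j]], "POSIXct")) df[[j]] <- iso_stamp(df[[j]])
      if (inherits(df[[j]], "Date")) df[[j]] <- format(df[[j]], "%Y-%m-%d")
      if (is.list(df[[j]])) df[[j]] <- NULL
    }
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE, quote = FALSE, eol = "\n")
    paths <- c(paths, p)
  }
  manifest <- list(
    config_hash = hash_object(config),
    seed = if (is.null(seed)) NA else as.integer(seed),
    inputs = if (length(inputs)) {
      data.frame(path = basename(inputs),
                 md5 = unname(tools::md5sum(inputs)))
    } else list(),
    outputs = data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}

# MD5 of the canonical JSON serialisation of an R object (config hashing).
hash_object <- function(x) {
  if (is.null(x)) return(NA_character_)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
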