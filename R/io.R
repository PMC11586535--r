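# File formats: PCM16 mono WAV recordings and the versioned cohort CSV.

.WAV_BITS <- 16L

#' Write a recording as PCM 16-bit mono WAV
#'
#' @param recording A `pcg_recording` with samples in \[-1, 1\].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_wav <- function(recording, path) {
  x <- recording$samples
  if (max(abs(x)) > 1 + 1e-9) stop("samples exceed [-1, 1]")
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  fs <- as.integer(recording$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + nbytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(.WAV_BITS, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM 16-bit mono WAV file
#'
#' Amplitudes are normalized to \[-1, 1\] (division by 2^15); compressed or
#' multi-channel files are rejected.
#'
#' @param path WAV file path.
#' @param patient_id,site Optional identifiers stored on the recording.
#' @return A `pcg_recording`.
#' @export
read_wav <- function(path, patient_id = NA_character_,
                     site = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAV file: ", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("compressed WAV not supported (format ",
                             fmt[1], ")")
      if (fmt[2] != 1L) stop("only mono WAV supported (", fmt[2],
                             " channels)")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM supported (", bits, " bits)")
      if (sz > 16) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      if (is.null(fs)) stop("data chunk before fmt chunk in ", path)
      pcm <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                     endian = "little")
      return(structure(list(patient_id = patient_id, site = site,
                            samples = pmax(pcm / 32767, -1),
                            sample_rate = fs),
                       class = "pcg_recording"))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}

# ---- cohort CSV ----------------------------------------------------------

.COHORT_SCHEMA_VERSION <- "caninemurmur_cohort_v1"

.COHORT_REQUIRED <- c("patient_id", "disease", "levine_left_apex",
                      "levine_left_base", "levine_right_side")

.COHORT_OPTIONAL <- c("site_of_recruitment", "mmvd_stage", "age",
                      "body_weight", "bcs", "sex", "heart_rate",
                      "arrhythmia_flag", "point_of_maximal_intensity",
                      "la_ao", "lvidd", "pimobendan_flag",
                      "loop_diuretic_flag")

#' Write / read the cohort table
#'
#' One row per dog.  The header is preceded by a schema-version comment
#' line.  Required columns: patient identifier, disease, and the three
#' per-site Levine grades; all other documented columns are optional and
#' missing values are kept as `NA` (missingness is first-class).  Unknown
#' columns are preserved on read but ignored by the pipeline.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `read_cohort` returns the typed cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(.COHORT_REQUIRED, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .COHORT_SCHEMA_VERSION), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(.COHORT_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("levine_left_apex", "levine_left_base",
                "levine_right_side")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad) > 0) {
      stop("unparseable cell in column ", col, ", row ", bad[1])
    }
    if (any(stats::na.omit(v) < 0 | stats::na.omit(v) > 6)) {
      stop("Levine grades in ", col, " must be 0-6")
    }
    df[[col]] <- v
  }
  for (col in intersect(c("age", "body_weight", "la_ao", "lvidd"),
                        names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad) > 0) {
      stop("unparseable cell in column ", col, ", row ", bad[1])
    }
    df[[col]] <- v
  }
  for (col in intersect(c("bcs", "heart_rate"), names(df))) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  for (col in intersect(c("arrhythmia_flag", "pimobendan_flag",
                          "loop_diuretic_flag"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}
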