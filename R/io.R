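#' Write / read a PVR trace file
#'
#' Trace files are plain CSV with `#`-prefixed header metadata lines
#' (`# sampling_interval_ms=...`, `# cuff_pressure_mmhg=...`,
#' `# limb_id=...`) followed by `t_ms,pressure_mmhg` rows at full precision.
#' Ground-truth beat annotations, when present, travel in a JSON sidecar
#' (`<path>.truth.json`).
#'
#' @param trace A `pvr_trace`.
#' @param path Output CSV path.
#' @param sidecar Write the ground-truth sidecar when available (default
#'   TRUE).
#' @return `write_trace()`: `path`, invisibly. `read_trace()`: a
#'   `pvr_trace`.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  meta <- c(
    sprintf("# sampling_interval_ms=%.17g", attr(trace, "sampling_interval")),
    sprintf("# cuff_pressure_mmhg=%.17g", attr(trace, "cuff_pressure")),
    sprintf("# limb_id=%s", attr(trace, "limb_id"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("t_ms,pressure_mmhg", con)
  writeLines(sprintf("%.17g,%.17g", trace$t_ms, trace$pressure_mmhg), con)
  gt <- attr(trace, "ground_truth")
  if (sidecar && !is.null(gt)) {
    jsonlite::write_json(gt, paste0(path, ".truth.json"), digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_trace
#' @param path Path of a trace CSV written by [write_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("t_ms", "pressure_mmhg"))) {
    abort("trace file must have header 't_ms,pressure_mmhg'")
  }
  fields <- strsplit(body[-1], ",", fixed = TRUE)
  bad_shape <- which(lengths(fields) != 2)
  if (length(bad_shape) > 0) {
    abort(sprintf("malformed trace rows at data line(s): %s",
                  paste(bad_shape, collapse = ", ")))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 2, byrow = TRUE)
  )
  bad_num <- which(!stats::complete.cases(vals))
  if (length(bad_num) > 0) {
    abort(sprintf("malformed trace rows at data line(s): %s",
                  paste(bad_num, collapse = ", ")))
  }
  df <- tibble(t_ms = vals[, 1], pressure_mmhg = vals[, 2])
  gt <- NULL
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    gt <- as_tibble(jsonlite::fromJSON(sidecar))
  }
  new_pvr_trace(
    as_tibble(df),
    sampling_interval = as.numeric(meta$sampling_interval_ms %||% 1),
    cuff_pressure = as.numeric(meta$cuff_pressure_mmhg %||% 50),
    limb_id = meta$limb_id %||% NA_character_,
    ground_truth = gt
  )
}

COHORT_REQUIRED <- c("limb_id", "glass", "imd", "pulsatile", "ust_ms",
                     "usr", "msa_mmhg")

#' Write / read a limb-level cohort table
#'
#' Plain CSV with a mandatory header row; numeric fields round-trip at full
#' precision. On read, schema violations (missing columns, negative MSA,
#' USR outside (0,1), unknown GLASS/IMD levels) are rejected with the
#' offending rows.
#'
#' @param records Cohort tibble.
#' @param path CSV path.
#' @return `write_cohort()`: `path` invisibly; `read_cohort()`: tibble.
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing_cols <- setdiff(COHORT_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(
    (!is.na(df$msa_mmhg) & df$msa_mmhg < 0) |
      (!is.na(df$usr) & (df$usr <= 0 | df$usr >= 1)) |
      !(as.character(df$glass) %in% GLASS_LEVELS) |
      !(as.character(df$imd) %in% IMD_LEVELS)
  )
  if (length(bad) > 0) {
    abort(sprintf("invalid cohort rows (data line %s): msa >= 0, 0 < usr < 1, known GLASS/IMD required",
                  paste(bad, collapse = ", ")))
  }
  df$glass <- factor(as.character(df$glass), levels = GLASS_LEVELS,
                     ordered = TRUE)
  df$imd <- factor(as.character(df$imd), levels = IMD_LEVELS)
  as_tibble(df)
}

#' Write an evaluation report
#'
#' Serialize a named list of evaluation results (tibbles and scalars) as
#' JSON, with a provenance block (config hash, seeds, package version).
#'
#' @param report Named list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, digits = NA, na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
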