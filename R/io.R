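# File I/O: CSV schemas for track tables, count snapshots and count
# distributions; JSON/YAML parameter files. Comma-separated, UTF-8,
# '.' decimal, header row required; all times in minutes after P40.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.check_numeric <- function(df, cols, path, allow_na = character(0)) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("", "NA", NA)))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s', row %d",
                   path, cl, bad[1L]), call. = FALSE)
    }
    na_rows <- which(is.na(v))
    if (length(na_rows) && !cl %in% allow_na) {
      stop(sprintf("%s: missing value in column '%s', row %d",
                   path, cl, na_rows[1L]), call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

#' Read and write filopodium track tables
#'
#' Track-table CSV schema: columns `object_id`, `class`, `t_birth_min`,
#' `t_death_min` (empty/NA = censored); an optional `terminal` column
#' is preserved. Death before birth is a schema error reported with its
#' row number.
#'
#' @param path CSV file path.
#' @return data.frame (read) or `path`, invisibly (write).
#' @export
read_track_table <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("object_id", "class", "t_birth_min", "t_death_min"),
                path)
  df <- .check_numeric(df, c("t_birth_min", "t_death_min"), path,
                       allow_na = "t_death_min")
  bad <- which(!is.na(df$t_death_min) & df$t_death_min < df$t_birth_min)
  if (length(bad)) {
    stop(sprintf("%s: death before birth in row %d", path, bad[1L]),
         call. = FALSE)
  }
  df
}

#' @param tracks track data.frame.
#' @rdname read_track_table
#' @export
write_track_table <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write count-snapshot tables
#'
#' Snapshot CSV schema: column `t_min` plus one non-negative integer
#' count column per category (e.g. `sF`, `lF`, `sB`, `synB`).
#'
#' @param path CSV file path.
#' @return data.frame (read) or `path`, invisibly (write).
#' @export
read_snapshots <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, "t_min", path)
  count_cols <- setdiff(names(df), c("t_min", "terminal"))
  df <- .check_numeric(df, c("t_min", "terminal"[
    "terminal" %in% names(df)], count_cols), path)
  for (cl in count_cols) {
    bad <- which(df[[cl]] < 0 | df[[cl]] != round(df[[cl]]))
    if (length(bad)) {
      stop(sprintf("%s: column '%s' must be non-negative integers (row %d)",
                   path, cl, bad[1L]), call. = FALSE)
    }
  }
  df
}

#' @param snapshots snapshot data.frame.
#' @rdname read_snapshots
#' @export
write_snapshots <- function(snapshots, path) {
  utils::write.csv(snapshots, path, row.names = FALSE)
  invisible(path)
}

#' Read and write count distributions
#'
#' Distribution CSV schema: columns `count` (non-negative integers,
#' contiguous from 0) and `frequency` (non-negative; normalized on
#' read).
#'
#' @param path CSV file path.
#' @return named probability vector (read) or `path`, invisibly
#'   (write).
#' @export
read_distribution <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("count", "frequency"), path)
  df <- .check_numeric(df, c("count", "frequency"), path)
  if (any(df$frequency < 0)) {
    stop(path, ": negative frequency", call. = FALSE)
  }
  o <- order(df$count)
  if (!identical(as.integer(df$count[o]), seq(0L, nrow(df) - 1L))) {
    stop(path, ": 'count' must be the contiguous integers 0..N",
         call. = FALSE)
  }
  p <- df$frequency[o] / sum(df$frequency)
  stats::setNames(p, df$count[o])
}

#' @param p probability or frequency vector on support `0..N`.
#' @rdname read_distribution
#' @export
write_distribution <- function(p, path) {
  utils::write.csv(
    data.frame(count = seq_along(p) - 1L, frequency = as.numeric(p)),
    path, row.names = FALSE)
  invisible(path)
}

#' Read and write developmental parameter files
#'
#' Parameters are stored as a JSON (or YAML) mapping keyed by genotype
#' label; coefficient order in `poly_coeffs` is `p0` (constant) through
#' `p5`. A file missing `c4` is filled with the published default
#' 1/120 min^-1, with a notice. Unknown keys are rejected.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return named list of [dev_params()] (read) or `path`, invisibly
#'   (write).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- c("c1_sF", "c1_lF", "c2_sF", "c2_lF", "c3", "c4", "c5", "c6",
             "B50", "t_half", "poly_coeffs", "f1_mode", "drive_table",
             "lambda_P60")
  out <- list()
  for (label in names(raw)) {
    entry <- raw[[label]]
    unknown <- setdiff(names(entry), known)
    if (length(unknown)) {
      stop(sprintf("%s: unknown key(s) in '%s': %s", path, label,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (is.null(entry$c4)) {
      message("'", label, "': c4 missing; using published default 1/120")
      entry$c4 <- 1 / 120
    }
    drive <- entry$drive_table; lam <- entry$lambda_P60
    entry$drive_table <- NULL; entry$lambda_P60 <- NULL
    p <- do.call(dev_params, c(list(genotype_label = label), entry))
    if (!is.null(drive)) attr(p, "drive_table") <- as.data.frame(drive)
    if (!is.null(lam)) attr(p, "lambda_P60") <- unlist(lam)
    out[[label]] <- p
  }
  out
}

#' @param params named list of `dev_params` (or a single one).
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  if (inherits(params, "dev_params")) {
    params <- stats::setNames(list(params), params$genotype_label)
  }
  ser <- lapply(params, function(p) {
    e <- unclass(p)
    e$genotype_label <- NULL
    if (!is.null(attr(p, "drive_table"))) {
      e$drive_table <- attr(p, "drive_table")
    }
    if (!is.null(attr(p, "lambda_P60"))) {
      e$lambda_P60 <- as.list(attr(p, "lambda_P60"))
    }
    e
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(ser, path, precision = 15L)
  } else {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  }
  invisible(path)
}

#' Write a JSON provenance record for a run
#'
#' @param config named list of run configuration (subcommand,
#'   arguments, seed).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path) {
  rec <- c(config,
           list(package = "filosyn",
                package_version =
                  as.character(utils::packageVersion("filosyn")),
                timestamp = format(Sys.time(), tz = "UTC",
                                   "%Y-%m-%dT%H:%M:%SZ")))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
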