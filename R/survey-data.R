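#' Read a segment table
#'
#' Reads the per-segment effort table of a line- or point-transect survey from
#' delimited text. Segments are the sampling units of the spatial model: each
#' row carries an identifier, the effort (line length) expended, planar
#' coordinates and any environmental covariates, plus optionally a time label
#' and a count of detections.
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param schema Optional named character vector mapping canonical column names
#'   (`segment_id`, `effort_length`, `x`, `y`, and optionally `time_label`,
#'   `count`) to the column names used in the file, e.g.
#'   `c(segment_id = "Sample.Label", effort_length = "Effort")`. Columns not
#'   mentioned are kept under their file names and treated as covariates.
#' @param delim Field delimiter, default `","`.
#'
#' @return A validated tibble with canonical columns first; any further
#'   columns are per-segment covariates.
#' @export
read_segments <- function(path, schema = NULL, delim = ",") {
  df <- read_table_checked(path, delim)
  df <- apply_schema(df, schema,
                     required = c("segment_id", "effort_length", "x", "y"),
                     context = "segment table")
  validate_segments(df)
}

#' Read an observation table
#'
#' Reads per-detection records: the segment on which each detection was made,
#' the perpendicular distance from the trackline, the group size, and any
#' covariates of the detection process (e.g. Beaufort sea state).
#'
#' @inheritParams read_segments
#' @param schema Named character vector mapping `segment_id`, `distance` and
#'   optionally `size` to file column names.
#' @param segments Optional segment table; if supplied, observations are
#'   checked to reference only known segments.
#' @return A validated tibble; `size` defaults to 1 when absent.
#' @export
read_observations <- function(path, schema = NULL, delim = ",", segments = NULL) {
  df <- read_table_checked(path, delim)
  df <- apply_schema(df, schema, required = c("segment_id", "distance"),
                     context = "observation table")
  validate_observations(df, segments = segments)
}

#' Read a set of time-indexed prediction grids
#'
#' Prediction grids describe where and when abundance is predicted: one grid
#' per time period, each cell with an area and the covariate values the model
#' formula needs. Grids can be stored as one long file with a `period` column
#' or as one file per period.
#'
#' @param paths Character vector of file paths. A single path is read as a
#'   long table (requiring a `period` column unless `periods` is given); with
#'   several paths each file is one period.
#' @param schema Named character vector mapping `cell_id`, `cell_area` and
#'   optionally `period` to file column names.
#' @param periods Optional period labels, one per file (or, for a single file
#'   without a period column, length-1 label for the whole file).
#' @param delim Field delimiter.
#' @return A validated long tibble with columns `period`, `cell_id`,
#'   `cell_area` and covariates. Cells with missing covariate values are
#'   dropped with a warning (they cannot be predicted), mirroring surveys
#'   where environmental fields are occasionally unavailable.
#' @export
read_prediction_grids <- function(paths, schema = NULL, periods = NULL, delim = ",") {
  read_one <- function(path, period_label) {
    df <- read_table_checked(path, delim)
    df <- apply_schema(df, schema, required = c("cell_id", "cell_area"),
                       context = "prediction grid")
    if (!is.null(period_label)) df$period <- period_label
    if (!"period" %in% names(df)) {
      rlang::abort(
        sprintf("prediction grid '%s' has no 'period' column and no period label was supplied", path),
        class = "dsmflow_schema_error")
    }
    df
  }
  if (length(paths) == 1L) {
    out <- read_one(paths, if (!is.null(periods)) periods[[1]] else NULL)
  } else {
    if (!is.null(periods) && length(periods) != length(paths)) {
      rlang::abort("length(periods) must equal length(paths)",
                   class = "dsmflow_schema_error")
    }
    labs <- periods %||% paths
    out <- purrr::map2(paths, labs, read_one) |> purrr::list_rbind()
  }
  validate_grids(out)
}

#' Validate a segment table
#'
#' Checks the invariants every segment table must satisfy: unique ids,
#' strictly positive effort, integer non-negative counts (when present),
#' finite coordinates.
#'
#' @param segments A data frame of segments.
#' @return The segments as a tibble, invisibly unchanged apart from class.
#' @export
validate_segments <- function(segments) {
  segments <- tibble::as_tibble(segments)
  need <- c("segment_id", "effort_length", "x", "y")
  miss <- setdiff(need, names(segments))
  if (length(miss) > 0) {
    rlang::abort(paste0("segment table is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "dsmflow_schema_error")
  }
  dup <- segments$segment_id[duplicated(segments$segment_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicated segment_id: ",
                        paste(unique(dup), collapse = ", ")),
                 class = "dsmflow_invariant_error")
  }
  if (!is.numeric(segments$effort_length)) {
    bad <- which(is.na(suppressWarnings(as.numeric(segments$effort_length))))
    rlang::abort(paste0("non-numeric effort_length (first bad row: ",
                        if (length(bad)) bad[1] else "?", ")"),
                 class = "dsmflow_parse_error")
  }
  if (any(!is.finite(segments$effort_length)) || any(segments$effort_length <= 0)) {
    rlang::abort("effort_length must be finite and > 0 for every segment",
                 class = "dsmflow_invariant_error")
  }
  if ("count" %in% names(segments)) {
    cnt <- segments$count
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
      rlang::abort("count must be a non-negative integer for every segment",
                   class = "dsmflow_invariant_error")
    }
  }
  segments
}

#' Validate an observation table
#'
#' @param obs A data frame of observations.
#' @param segments Optional segment table for referential checks.
#' @return The observations as a tibble; `size` filled with 1 when absent.
#' @export
validate_observations <- function(obs, segments = NULL) {
  obs <- tibble::as_tibble(obs)
  miss <- setdiff(c("segment_id", "distance"), names(obs))
  if (length(miss) > 0) {
    rlang::abort(paste0("observation table is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "dsmflow_schema_error")
  }
  if (!"size" %in% names(obs)) obs$size <- 1
  if (any(!is.finite(obs$distance)) || any(obs$distance < 0)) {
    rlang::abort("distance must be finite and >= 0",
                 class = "dsmflow_invariant_error")
  }
  if (any(!is.finite(obs$size)) || any(obs$size < 1)) {
    rlang::abort("size must be >= 1", class = "dsmflow_invariant_error")
  }
  if (!is.null(segments)) {
    orphan <- setdiff(unique(obs$segment_id), segments$segment_id)
    if (length(orphan) > 0) {
      rlang::abort(paste0("observations reference unknown segment_id: ",
                          paste(orphan, collapse = ", ")),
                   class = "dsmflow_linkage_error")
    }
  }
  obs
}

#' Validate a prediction-grid table
#'
#' @param grids Long tibble with `period`, `cell_id`, `cell_area` and
#'   covariate columns.
#' @return The grids as a tibble with rows carrying missing covariates
#'   removed (with a warning naming the periods affected).
#' @export
validate_grids <- function(grids) {
  grids <- tibble::as_tibble(grids)
  miss <- setdiff(c("period", "cell_id", "cell_area"), names(grids))
  if (length(miss) > 0) {
    rlang::abort(paste0("prediction grid is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "dsmflow_schema_error")
  }
  if (any(!is.finite(grids$cell_area)) || any(grids$cell_area <= 0)) {
    rlang::abort("cell_area must be finite and > 0",
                 class = "dsmflow_invariant_error")
  }
  has_na <- !stats::complete.cases(grids)
  if (any(has_na)) {
    bad_periods <- unique(grids$period[has_na])
    rlang::warn(sprintf(
      "dropping %d grid cell(s) with missing covariates (periods: %s)",
      sum(has_na), paste(utils::head(bad_periods, 5), collapse = ", ")))
    grids <- grids[!has_na, , drop = FALSE]
  }
  grids
}

#' Per-segment searched area
#'
#' Adds the area surveyed by each segment: for line transects the strip
#' `2 * truncation * effort_length`; for point transects the circle
#' `pi * truncation^2`. Truncation and effort share one distance unit
#' (conventionally km), so areas are in that unit squared; no unit conversion
#' is attempted.
#'
#' @param segments Segment table.
#' @param truncation Truncation distance w (> 0), same units as effort.
#' @param sampler `"line"` (default) or `"point"`.
#' @return The segment tibble with an `area` column appended.
#' @export
#' @examples
#' seg <- tibble::tibble(segment_id = "a", effort_length = 10, x = 0, y = 0)
#' segment_area(seg, truncation = 5.5)$area  # 110
segment_area <- function(segments, truncation, sampler = c("line", "point")) {
  sampler <- match.arg(sampler)
  if (!is.numeric(truncation) || length(truncation) != 1L || truncation <= 0) {
    rlang::abort("truncation must be a single positive distance",
                 class = "dsmflow_domain_error")
  }
  segments <- validate_segments(segments)
  segments$area <- switch(sampler,
    line  = 2 * truncation * segments$effort_length,
    point = rep(pi * truncation^2, nrow(segments)))
  segments
}

#' Attach per-segment counts from the observation table
#'
#' Counts the in-truncation detections on each segment, either as number of
#' groups or as total individuals (sum of group sizes). Segments with no
#' detections get count 0; observations beyond the truncation distance are
#' excluded.
#'
#' @param segments Segment table.
#' @param obs Observation table; every `segment_id` must exist in `segments`.
#' @param response `"groups"` (default) or `"individuals"`.
#' @param truncation Truncation distance w; observations with
#'   `distance > truncation` are dropped before counting.
#' @return The segment tibble with a `count` column (replacing any present).
#' @export
attach_counts <- function(segments, obs, response = c("groups", "individuals"),
                          truncation = Inf) {
  response <- match.arg(response)
  segments <- validate_segments(segments)
  obs <- validate_observations(obs, segments = segments)
  obs <- obs[obs$distance <= truncation, , drop = FALSE]
  agg <- obs |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(count = if (response == "groups") dplyr::n()
                     else sum(.data$size), .groups = "drop")
  segments$count <- NULL
  out <- dplyr::left_join(segments, agg, by = "segment_id")
  out$count <- ifelse(is.na(out$count), 0, out$count)
  out
}

#' Correction factors for the detection offset
#'
#' A correction factor is an externally-estimated multiplicative probability
#' applied to the survey offset or the final estimates: trackline detection
#' probability g(0), or availability. `coincident = FALSE` marks an estimate
#' from independent data, whose uncertainty enters by the delta method
#' (squared CVs add); coincident corrections must instead be absorbed into
#' the spatial model.
#'
#' @param name Label, e.g. `"g0"` or `"availability"`.
#' @param estimate Probability in (0, 1].
#' @param cv Coefficient of variation, >= 0.
#' @param coincident Logical; was the estimate made from the same survey?
#' @return A one-row tibble; bind rows to build a correction set.
#' @export
#' @examples
#' correction_factor("g0", 0.921, 0.023)
correction_factor <- function(name, estimate, cv, coincident = FALSE) {
  if (!is.numeric(estimate) || estimate <= 0 || estimate > 1) {
    rlang::abort("correction estimate must lie in (0, 1]",
                 class = "dsmflow_domain_error")
  }
  if (!is.numeric(cv) || cv < 0) {
    rlang::abort("correction cv must be >= 0", class = "dsmflow_domain_error")
  }
  tibble::tibble(name = as.character(name), estimate = estimate,
                 cv = cv, coincident = isTRUE(coincident))
}

#' Write survey tables to delimited text
#'
#' Thin wrappers over [readr::write_csv()] so synthetic surveys round-trip
#' through exactly the files the readers consume.
#'
#' @param x Table to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_segments <- function(x, path) {
  readr::write_csv(validate_segments(x), path)
  invisible(x)
}

#' @rdname write_segments
#' @export
write_observations <- function(x, path) {
  readr::write_csv(validate_observations(x), path)
  invisible(x)
}

#' @rdname write_segments
#' @export
write_prediction_grids <- function(x, path) {
  readr::write_csv(validate_grids(x), path)
  invisible(x)
}

# -- internal helpers ---------------------------------------------------------

read_table_checked <- function(path, delim) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path),
                 class = "dsmflow_io_error")
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

apply_schema <- function(df, schema, required, context) {
  if (!is.null(schema)) {
    schema <- unlist(schema)
    missing_src <- setdiff(unname(schema), names(df))
    if (length(missing_src) > 0) {
      rlang::abort(sprintf("%s: schema refers to absent column(s): %s",
                           context, paste(missing_src, collapse = ", ")),
                   class = "dsmflow_schema_error")
    }
    names(df)[match(schema, names(df))] <- names(schema)
  }
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("%s: missing required column(s): %s",
                         context, paste(miss, collapse = ", ")),
                 class = "dsmflow_schema_error")
  }
  df
}
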