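# Plate data model: filename metadata parsing, plate-map loading, metadata
# joins, and object-table persistence (CSV and single-file SQLite with the
# same schema).

#' Parse plate/well/hour metadata from a frame filename
#'
#' Filenames encode acquisition metadata through a user-configurable template
#' with named fields `{plate}`, `{well}` and `{hour}` (default
#' `"{plate}_{well}_{hour}h.tif"`, matching the synthetic generator's output).
#'
#' @param path frame path; only the basename is matched against the template.
#' @param pattern filename template containing `{plate}`, `{well}`, `{hour}`.
#' @return list with `plate_id`, `well_id`, `hour` (integer) and `path`.
#' @examples
#' parse_frame_metadata("P1_B2_07h.tif", "{plate}_{well}_{hour}h.tif")
#' @export
parse_frame_metadata <- function(path, pattern = "{plate}_{well}_{hour}h.tif") {
  fields <- c("plate", "well", "hour")
  for (f in fields) {
    if (!grepl(paste0("{", f, "}"), pattern, fixed = TRUE)) {
      stopf("pattern must contain the named field {%s}: %s", f, pattern)
    }
  }
  # tokenize into placeholders and literal stretches; escape the literals
  # character-by-character and turn placeholders into named capture groups
  ph <- gregexpr("\\{(plate|well|hour)\\}", pattern)[[1L]]
  groups <- c(plate = "(?<plate>[A-Za-z0-9.-]+)", well = "(?<well>[A-Za-z]+[0-9]+)",
              hour = "(?<hour>[0-9]+)")
  esc_lit <- function(s) {
    if (nchar(s) == 0L) return("")
    paste(vapply(strsplit(s, "")[[1L]], function(ch) {
      if (grepl("[A-Za-z0-9_]", ch)) ch else paste0("\\", ch)
    }, ""), collapse = "")
  }
  rx <- "^"
  pos <- 1L
  for (i in seq_along(ph)) {
    rx <- paste0(rx, esc_lit(substr(pattern, pos, ph[i] - 1L)))
    name <- substr(pattern, ph[i] + 1L, ph[i] + attr(ph, "match.length")[i] - 2L)
    rx <- paste0(rx, groups[[name]])
    pos <- ph[i] + attr(ph, "match.length")[i]
  }
  rx <- paste0(rx, esc_lit(substr(pattern, pos, nchar(pattern))), "$")
  base <- basename(path)
  m <- regexpr(rx, base, perl = TRUE)
  if (m == -1L) {
    stopf("filename '%s' does not match template '%s'", base, pattern)
  }
  st <- attr(m, "capture.start")[1L, ]
  le <- attr(m, "capture.length")[1L, ]
  get1 <- function(f) substr(base, st[[f]], st[[f]] + le[[f]] - 1L)
  list(plate_id = get1("plate"), well_id = get1("well"),
       hour = as.integer(get1("hour")), path = path)
}

#' Read a plate map CSV
#'
#' The plate map assigns each well its cell line and experimental condition
#' (e.g. fibronectin concentration). Required columns: `plate`, `well`,
#' `cell_line`, `condition`; optional: `condition_value`, `replicate_group`.
#'
#' @param file CSV path with a header row.
#' @return data.frame with columns `plate_id`, `well_id`, `cell_line`,
#'   `condition`, `condition_value`, `replicate_group`.
#' @export
read_plate_map <- function(file) {
  pm <- read.csv(file, stringsAsFactors = FALSE)
  req <- c("plate", "well", "cell_line", "condition")
  miss <- setdiff(req, names(pm))
  if (length(miss) > 0L) {
    stopf("plate map %s is missing required column(s): %s", file,
          paste(miss, collapse = ", "))
  }
  if (is.null(pm$condition_value)) {
    pm$condition_value <- suppressWarnings(as.numeric(pm$condition))
  }
  if (is.null(pm$replicate_group)) pm$replicate_group <- NA_character_
  key <- paste(pm$plate, pm$well, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(paste0(pm$plate, "/", pm$well)[duplicated(key)])
    stopf("duplicate (plate, well) in plate map: %s", paste(dup, collapse = ", "))
  }
  data.frame(plate_id = as.character(pm$plate), well_id = as.character(pm$well),
             cell_line = as.character(pm$cell_line),
             condition = as.character(pm$condition),
             condition_value = as.numeric(pm$condition_value),
             replicate_group = as.character(pm$replicate_group),
             stringsAsFactors = FALSE)
}

#' Annotate an object table with plate-map metadata
#'
#' Appends `cell_line`, `condition`, `condition_value` and `replicate_group`
#' columns by joining on `(plate_id, well_id)`. Feature values are never
#' modified. Under `strict = TRUE` (default) any object in a well absent from
#' the plate map is an error, so data cannot be dropped silently.
#'
#' @param objects ObjectTable data.frame with `plate_id` and `well_id`.
#' @param plate_map output of [read_plate_map()].
#' @param strict error on unmapped wells (default `TRUE`); otherwise unmapped
#'   rows get `NA` metadata.
#' @return the annotated ObjectTable (same row count when strict).
#' @export
annotate_objects <- function(objects, plate_map, strict = TRUE) {
  meta_cols <- c("cell_line", "condition", "condition_value", "replicate_group")
  objects <- objects[, setdiff(names(objects), meta_cols), drop = FALSE]
  if (nrow(objects) == 0L) {
    for (mc in meta_cols) objects[[mc]] <- character(0)
    objects$condition_value <- numeric(0)
    return(objects)
  }
  key_o <- paste(objects$plate_id, objects$well_id, sep = "\r")
  key_m <- paste(plate_map$plate_id, plate_map$well_id, sep = "\r")
  hit <- match(key_o, key_m)
  if (strict && anyNA(hit)) {
    bad <- unique(paste0(objects$plate_id, "/", objects$well_id)[is.na(hit)])
    stopf("wells absent from plate map: %s", paste(bad, collapse = ", "))
  }
  for (mc in meta_cols) objects[[mc]] <- plate_map[[mc]][hit]
  objects
}

object_key_cols <- c("plate_id", "well_id", "hour", "object_id")

#' Write an object table to CSV or a single-file SQLite database
#'
#' Both backends use an identical schema and round-trip numeric values
#' exactly (CSV floats are written with 17 significant digits). The backend
#' is selected by extension: `.csv` for CSV, anything else (conventionally
#' `.sqlite` / `.db`) for SQLite.
#'
#' @param objects ObjectTable data.frame.
#' @param dest destination path.
#' @param table SQLite table name (default `"per_object"`), mirroring a
#'   configurable experiment table prefix.
#' @return `dest`, invisibly.
#' @export
write_object_table <- function(objects, dest, table = "per_object") {
  if (tolower(tools::file_ext(dest)) == "csv") {
    df <- objects
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    }
    write.table(df, dest, sep = ",", row.names = FALSE, qmethod = "double",
                fileEncoding = "UTF-8")
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), dest)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    DBI::dbWriteTable(con, table, objects, overwrite = TRUE)
  }
  invisible(dest)
}

#' Read an object table written by [write_object_table()]
#'
#' @param src CSV or SQLite path.
#' @param table SQLite table name (default `"per_object"`).
#' @return ObjectTable data.frame.
#' @export
read_object_table <- function(src, table = "per_object") {
  if (!file.exists(src)) stopf("object table not found: %s", src)
  if (tolower(tools::file_ext(src)) == "csv") {
    df <- read.csv(src, stringsAsFactors = FALSE)
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), src)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    df <- DBI::dbReadTable(con, table)
  }
  # metadata columns are text by schema, even when their values look numeric
  for (mc in intersect(c("plate_id", "well_id", "cell_line", "condition",
                         "replicate_group"), names(df))) {
    df[[mc]] <- as.character(df[[mc]])
  }
  validate_object_table(df, src)
  df
}

validate_object_table <- function(df, src) {
  miss <- setdiff(object_key_cols, names(df))
  if (length(miss) > 0L) {
    stopf("object table %s is missing key column(s): %s", src,
          paste(miss, collapse = ", "))
  }
  feat <- setdiff(names(df), c(object_key_cols, "centroid_row", "centroid_col",
                               "cell_line", "condition", "condition_value",
                               "replicate_group"))
  for (f in feat) {
    if (!is.numeric(df[[f]]) && !all(is.na(df[[f]]))) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[f]]))) & !is.na(df[[f]]))
      stopf("non-numeric value in feature column '%s' of %s (data row %d)",
            f, src, if (length(bad)) bad[1L] else NA_integer_)
    }
  }
  invisible(df)
}
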