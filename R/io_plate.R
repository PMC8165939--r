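#' Construct a frame series
#'
#' A `frame_series` holds one well's ordered grayscale time-lapse: a list of
#' integer matrices in native intensity units (0..255 for 8-bit, 0..65535 for
#' 16-bit), plus acquisition metadata. Each well is treated as an independent
#' time course.
#'
#' @param frames list of >= 2 integer matrices, all the same dimensions.
#' @param well_id well identifier, e.g. `"B02"`.
#' @param condition condition label for the well, or `NA` if unknown.
#' @param interval hours between consecutive frames (> 0).
#' @param pixel_size micrometres per pixel, or `NA` if unknown.
#' @param t0_index 1-based timepoint index of the first frame.
#' @param bit_depth 8 or 16; intensity thresholds downstream are expressed in
#'   these native units.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, well_id, condition = NA_character_,
                         interval = 1, pixel_size = NA_real_, t0_index = 1L,
                         bit_depth = 8L) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("a frame series needs at least 2 frames")
  d <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok))
    stop("all frames must be matrices of identical dimensions")
  if (!is.numeric(interval) || interval <= 0)
    stop("interval must be > 0 hours")
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16")
  structure(
    list(frames = lapply(frames, function(f) {
           storage.mode(f) <- "integer"; f
         }),
         well_id = as.character(well_id),
         condition = as.character(condition),
         interval = as.numeric(interval),
         pixel_size = as.numeric(pixel_size),
         t0_index = as.integer(t0_index),
         bit_depth = as.integer(bit_depth)),
    class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("frame_series: well %s (%s), %d frames of %dx%d, %g h interval\n",
              x$well_id, x$condition, length(x$frames), d[1L], d[2L],
              x$interval))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

#' Read or write a plate layout
#'
#' A plate layout maps wells to condition labels, e.g. wells in columns 1-3
#' to the self-renewing `E8` medium and columns 10-12 to the differentiating
#' `KSR_BMP4` medium. Stored as CSV with columns `well,condition`.
#'
#' @param path CSV file path.
#' @return `read_layout`: data.frame with columns `well`, `condition`.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well", "condition") %in% names(df)))
    stop("layout file must have columns 'well' and 'condition'")
  validate_layout(df[c("well", "condition")])
}

#' @rdname read_layout
#' @param layout data.frame with columns `well`, `condition`.
#' @export
write_layout <- function(layout, path) {
  layout <- validate_layout(layout)
  utils::write.csv(layout, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout),
            all(c("well", "condition") %in% names(layout)))
  if (anyDuplicated(layout$well))
    stop("duplicate well ids in layout: ",
         paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "))
  layout$well <- as.character(layout$well)
  layout$condition <- as.character(layout$condition)
  layout
}

#' Tile a 2x2 grid of fields into one well image
#'
#' Multi-field acquisitions (4 fields per well at low magnification) are
#' abutted into a single raster in row-major field order, with no overlap
#' registration or blending.
#'
#' @param fields list of exactly 4 matrices, all the same dimensions.
#' @return A matrix of dimensions `(2 h, 2 w)`.
#' @export
tile_fields <- function(fields) {
  if (!is.list(fields) || length(fields) != 4L)
    stop("tile_fields expects exactly 4 fields, got ", length(fields))
  d <- dim(fields[[1L]])
  if (!all(vapply(fields, function(f) identical(dim(f), d), logical(1))))
    stop("all fields must have identical dimensions")
  rbind(cbind(fields[[1L]], fields[[2L]]),
        cbind(fields[[3L]], fields[[4L]]))
}

## filename template -> regex; placeholders {well}, {field}, {timepoint},
## optionally with printf-ish widths like {timepoint:03d}
template_regex <- function(pattern) {
  keys <- character(0)
  rx <- gsub("([.^$+()\\[\\]\\\\])", "\\\\\\1", pattern)
  repl <- function(rx, key) {
    m <- regmatches(rx, regexpr(sprintf("\\{%s(:0?([0-9]+)d)?\\}", key), rx))
    if (!length(m)) return(list(rx = rx, hit = FALSE))
    w <- sub(sprintf("\\{%s(:0?([0-9]+)d)?\\}", key), "\\2", m)
    grp <- if (key == "well") "([A-Za-z0-9]+)"
           else if (nzchar(w)) sprintf("([0-9]{%s})", w)
           else "([0-9]+)"
    list(rx = sub(sprintf("\\{%s(:0?[0-9]+d)?\\}", key), grp, rx, fixed = FALSE),
         hit = TRUE)
  }
  for (key in c("well", "field", "timepoint")) {
    # record order of first appearance
    pos <- regexpr(sprintf("\\{%s(:0?[0-9]+d)?\\}", key), rx)
    if (pos > 0) keys <- c(keys, key)
  }
  keys <- keys[order(vapply(keys, function(k)
    regexpr(sprintf("\\{%s(:0?[0-9]+d)?\\}", k), rx), integer(1)))]
  for (key in keys) rx <- repl(rx, key)$rx
  list(regex = paste0("^", rx, "$"), keys = keys)
}

format_template <- function(pattern, well, field, timepoint) {
  out <- pattern
  subst <- function(out, key, val) {
    m <- regmatches(out, regexpr(sprintf("\\{%s(:0?[0-9]+d)?\\}", key), out))
    if (!length(m)) return(out)
    fmt <- sub(sprintf("\\{%s(:(0?[0-9]+d))?\\}", key), "\\2", m)
    txt <- if (nzchar(fmt)) sprintf(paste0("%", fmt), as.integer(val))
           else as.character(val)
    sub(sprintf("\\{%s(:0?[0-9]+d)?\\}", key), txt, out)
  }
  out <- subst(out, "well", well)
  out <- subst(out, "field", field)
  subst(out, "timepoint", timepoint)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    bits <- if (max(raw) <= 1 && attr(raw, "bits.per.sample") %||% 8 > 8) 16L else 8L
    img <- round(raw * (2^bits - 1))
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse replicated gray channels
  storage.mode(img) <- "integer"
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_gray_image <- function(img, path, bit_depth = 8L) {
  mx <- 2^bit_depth - 1
  ext <- tolower(tools::file_ext(path))
  norm <- pmin(pmax(img, 0L), mx) / mx
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = as.integer(bit_depth))
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Load per-well time-lapse series from a directory of images
#'
#' Filenames encode well, field and timepoint through a template such as
#' `"{well}_f{field:02d}_t{timepoint:03d}.tif"`. Timepoints must form a
#' contiguous 1-based range per well; wells with 4 fields per timepoint are
#' tiled 2x2 via [tile_fields()] before insertion.
#'
#' @param directory directory containing the images.
#' @param pattern filename template with `{well}`, `{timepoint}` and
#'   optionally `{field}` placeholders (zero-padded widths as `{timepoint:03d}`).
#' @param layout plate layout data.frame (see [read_layout()]), or `NULL` to
#'   leave conditions unknown.
#' @param interval hours between timepoints.
#' @param pixel_size micrometres per pixel, or `NA`.
#' @return Named list of [frame_series()], one per well.
#' @export
load_series <- function(directory, pattern = "{well}_f{field:02d}_t{timepoint:03d}.tif",
                        layout = NULL, interval = 1, pixel_size = NA_real_) {
  tr <- template_regex(pattern)
  files <- list.files(directory)
  hit <- grepl(tr$regex, files)
  files <- files[hit]
  if (!length(files)) stop("no files in ", directory, " match pattern ", pattern)
  gr <- regmatches(files, regexec(tr$regex, files))
  meta <- as.data.frame(do.call(rbind, lapply(gr, `[`, -1L)),
                        stringsAsFactors = FALSE)
  names(meta) <- tr$keys
  meta$file <- files
  if (!"field" %in% names(meta)) meta$field <- "1"
  meta$timepoint <- as.integer(meta$timepoint)
  meta$field <- as.integer(meta$field)

  out <- list()
  for (w in sort(unique(meta$well))) {
    mw <- meta[meta$well == w, ]
    tps <- sort(unique(mw$timepoint))
    full <- seq(min(tps), max(tps))
    missing_tp <- setdiff(full, tps)
    if (length(missing_tp))
      stop(sprintf("well %s is missing timepoint(s) %s", w,
                   paste(missing_tp, collapse = ", ")))
    frames <- lapply(full, function(tp) {
      mt <- mw[mw$timepoint == tp, ]
      mt <- mt[order(mt$field), ]
      imgs <- lapply(file.path(directory, mt$file), read_gray_image)
      if (length(imgs) == 1L) imgs[[1L]]
      else if (length(imgs) == 4L) tile_fields(imgs)
      else stop(sprintf("well %s timepoint %d has %d fields; expected 1 or 4",
                        w, tp, length(imgs)))
    })
    dims <- unique(lapply(frames, dim))
    if (length(dims) > 1L)
      stop("well ", w, ": mixed image shapes across timepoints")
    cond <- NA_character_
    if (!is.null(layout)) {
      i <- match(w, layout$well)
      if (!is.na(i)) cond <- layout$condition[i]
    }
    bit_depth <- if (max(vapply(frames, max, numeric(1))) > 255) 16L else 8L
    out[[w]] <- frame_series(frames, well_id = w, condition = cond,
                             interval = interval, pixel_size = pixel_size,
                             t0_index = min(tps), bit_depth = bit_depth)
  }
  out
}

#' Write a frame series to disk as one image per timepoint
#'
#' Counterpart of [load_series()] for a single-field series; used by the
#' phantom simulator and for round-trip testing.
#'
#' @param series a [frame_series()].
#' @param directory output directory (created if missing).
#' @param pattern filename template (see [load_series()]).
#' @return Invisibly, the written file paths.
#' @export
write_series <- function(series, directory,
                         pattern = "{well}_f{field:02d}_t{timepoint:03d}.tif") {
  stopifnot(inherits(series, "frame_series"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(series$frames))
  for (i in seq_along(series$frames)) {
    tp <- series$t0_index + i - 1L
    fn <- format_template(pattern, series$well_id, 1L, tp)
    paths[i] <- file.path(directory, fn)
    write_gray_image(series$frames[[i]], paths[i], series$bit_depth)
  }
  invisible(paths)
}

#' Feature table columns, in canonical order
#' @keywords internal
feature_table_columns <- function() {
  c("well", "timepoint", "condition", "area_px2", "area_um2", "perimeter",
    "form_factor", "eccentricity", "solidity", "extent", "major_axis_len",
    "minor_axis_len", "width_to_length_ratio", "centroid_row", "centroid_col",
    "empty", "low_confidence")
}

#' Write / read a per-(well, timepoint) feature table
#'
#' CSV with one row per (well, timepoint); numeric values round-trip to
#' better than 1e-9.
#'
#' @param table feature table data.frame (see [assemble_table()]).
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table must be a non-empty data.frame")
  unknown <- setdiff(names(table), feature_table_columns())
  if (length(unknown))
    stop("unknown feature table columns: ", paste(unknown, collapse = ", "))
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table`: the feature table data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), feature_table_columns())
  if (length(unknown))
    stop("unknown feature table columns: ", paste(unknown, collapse = ", "))
  df$well <- as.character(df$well)
  df$timepoint <- as.integer(df$timepoint)
  for (cn in c("empty", "low_confidence"))
    if (cn %in% names(df)) df[[cn]] <- as.logical(df[[cn]])
  num <- setdiff(feature_table_columns(),
                 c("well", "timepoint", "condition", "empty",
                   "low_confidence"))
  for (cn in intersect(num, names(df)))
    df[[cn]] <- as.numeric(df[[cn]])  # an all-NA column reads as logical
  df
}

#' Write classifier predictions to CSV
#'
#' @param predictions data.frame from [evaluate_classifier()].
#' @param path CSV path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
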