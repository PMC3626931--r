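## I/O: PNG/TIFF images, 16-bit label maps, layer/network JSON and the CSV
## results export. All writers are deterministic byte-for-byte: fixed column
## order, fixed float formatting, "\n" line endings.

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Read an RGB image
#'
#' PNG or TIFF; returns an 8-bit-scale H x W x 3 array (values 0..255).
#' Grayscale inputs are replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path file path.
#' @return numeric H x W x 3 array.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    ol_stop("io", sprintf("cannot read image: no such file '%s'", path))
  ext <- file_ext(path)
  x <- tryCatch(switch(ext,
                       png = png::readPNG(path),
                       tif = , tiff = tiff::readTIFF(path),
                       ol_stop("io", sprintf(
                         "unsupported image format '%s' for '%s'", ext, path))),
                error = function(e) ol_stop("io", sprintf(
                  "failed to read '%s': %s", path, conditionMessage(e))))
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  nch <- dim(x)[3L]
  x <- switch(as.character(nch),
              "1" = x[, , c(1L, 1L, 1L), drop = FALSE],
              "2" = x[, , c(1L, 1L, 1L), drop = FALSE],  # gray + alpha
              "3" = x,
              "4" = x[, , 1:3, drop = FALSE],
              ol_stop("io", sprintf("unsupported channel count %d in '%s'",
                                    nch, path)))
  round(x * 255)
}

#' Write an RGB image (8-bit PNG or TIFF)
#'
#' @param image numeric H x W x 3 array, values 0..255.
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @export
write_image <- function(image, path) {
  x <- pmin(pmax(image, 0), 255) / 255
  switch(file_ext(path),
         png = png::writePNG(x, path),
         tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
         ol_stop("io", sprintf("unsupported image format for '%s'", path)))
  invisible(path)
}

#' Write and read label maps
#'
#' Label maps are stored as single-channel images, id 0 = background:
#' 16-bit TIFF (`.tif`/`.tiff`, ids up to 65535, the recommended format) or
#' 8-bit PNG (ids up to 255). Round trips are lossless.
#'
#' @param map integer matrix of object ids.
#' @param path output path.
#' @export
write_label_map <- function(map, path) {
  map <- as_label_map(map)
  mx <- if (length(map)) max(map) else 0L
  ext <- file_ext(path)
  if (ext == "png") {
    if (mx > 255L)
      ol_stop("overflow", sprintf(
        "label map id %d exceeds the PNG limit of 255; write a .tif instead",
        mx))
    png::writePNG(map / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (mx > 65535L)
      ol_stop("overflow", sprintf(
        "label map id %d exceeds the 16-bit limit of 65535", mx))
    tiff::writeTIFF(map / 65535, path, bits.per.sample = 16L)
  } else {
    ol_stop("io", sprintf("unsupported label map format for '%s'", path))
  }
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path))
    ol_stop("io", sprintf("cannot read label map: no such file '%s'", path))
  ext <- file_ext(path)
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    grid <- matrix(round(as.numeric(x) * (2^depth - 1)), nrow(x), ncol(x))
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    grid <- x
  } else {
    ol_stop("io", sprintf("unsupported label map format for '%s'", path))
  }
  storage.mode(grid) <- "integer"
  as_label_map(grid)
}

# Float formatting with read-back fidelity: integers print bare, everything
# else with 17 significant digits (round-trip exact for doubles).
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) ""
    else if (v == floor(v) && abs(v) < 2^53) sprintf("%.0f", v)
    else sprintf("%.17g", v)
  }, character(1))
}

csv_quote <- function(s) {
  needs <- grepl('[",\n\r]', s)
  s[needs] <- paste0('"', gsub('"', '""', s[needs]), '"')
  s
}

#' Export a layer's objects to CSV
#'
#' Writes `id,class,<feature columns>` with feature columns in lexicographic
#' (byte) order, one row per object sorted by id, RFC 4180 quoting, `"\n"`
#' line endings and full-precision numbers. Unclassified objects export
#' class `""`. If objects carry heterogeneous feature sets, missing cells
#' are empty and a warning is issued.
#'
#' @param layer an `ObjectLayer`.
#' @param path output CSV path.
#' @return invisibly, the results `data.frame` (one row per object).
#' @export
export_csv <- function(layer, path) {
  feats <- lapply(layer$objects, `[[`, "features")
  all_names <- unique(unlist(lapply(feats, names)))
  all_names <- if (is.null(all_names)) character(0)
               else sort(all_names, method = "radix")
  if (length(feats) &&
      !all(vapply(feats, function(f) all(all_names %in% names(f)),
                  logical(1))))
    warning("objects carry heterogeneous feature sets; missing cells are empty",
            call. = FALSE)
  ids <- layer_ids(layer)
  ord <- order(ids)
  header <- paste(c("id", "class", csv_quote(all_names)), collapse = ",")
  rows <- vapply(ord, function(i) {
    o <- layer$objects[[i]]
    cls <- if (is.na(o$class_name)) "" else o$class_name
    vals <- vapply(all_names, function(nm) {
      if (!nm %in% names(o$features)) "" else fmt_num(o$features[[nm]])
    }, character(1))
    paste(c(sprintf("%d", o$id), csv_quote(cls), vals), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  df <- data.frame(id = ids[ord],
                   class = vapply(layer$objects[ord], function(o)
                     if (is.na(o$class_name)) "" else o$class_name,
                     character(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  for (nm in all_names)
    df[[nm]] <- vapply(layer$objects[ord], function(o) {
      if (!nm %in% names(o$features)) NA_real_ else o$features[[nm]]
    }, numeric(1))
  invisible(df)
}

#' Serialize a layer's object records to JSON
#'
#' Writes `{"provenance", "objects": [{"id", "class", "features": {...}}]}`;
#' pixel geometry lives in the label-map file written alongside (see
#' [write_label_map()]).
#'
#' @param layer an `ObjectLayer`.
#' @param path output JSON path.
#' @export
write_layer_json <- function(layer, path) {
  objs <- lapply(layer$objects, function(o) {
    rec <- list(id = o$id)
    if (!is.na(o$class_name)) rec$class <- o$class_name
    rec$features <- as.list(o$features)
    rec
  })
  names(objs) <- NULL
  jsonlite::write_json(list(provenance = layer$provenance, objects = objs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize an object network to a JSON adjacency list
#'
#' @param network an `ObjectNetwork`.
#' @param path output JSON path.
#' @export
write_network_json <- function(network, path) {
  adj <- lapply(network$neighbourhoods, function(nbh) {
    lapply(nbh$neighbours, function(r)
      list(voronoi_border = r$voronoi_border,
           touching_border = r$touching_border,
           touching = r$touching))
  })
  jsonlite::write_json(list(max_distance = network$max_distance,
                            neighbourhoods = adj),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
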