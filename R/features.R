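## Per-object features. All feature writers are pure: they return a copy of
## the layer with entries added to each object's named feature vector and
## never alter geometry.

set_feature <- function(layer, id, name, value) {
  layer$objects[[as.character(id)]]$features[[name]] <- as.numeric(value)
  layer
}

## ---- morphometry -----------------------------------------------------------

#' Morphometric features
#'
#' Sets `area` (pixel count), `contour_length` (crack-edge count of the outer
#' boundary), `form_factor` = contour_length^2 / area (16 for any square,
#' larger for elongated shapes) and the centroid (`centroid_row`,
#' `centroid_col`, mean pixel coordinates, 1-based).
#'
#' @param layer an `ObjectLayer` with contours populated.
#' @return the layer with features set.
#' @export
morphometry <- function(layer) {
  nr <- nrow(layer$label_map)
  for (o in layer$objects) {
    idx <- which(layer$label_map == o$id)
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    f <- o$features
    f[["area"]] <- as.numeric(o$pixel_count)
    f[["contour_length"]] <- as.numeric(o$contour$length)
    f[["form_factor"]] <- o$contour$length^2 / o$pixel_count
    f[["centroid_row"]] <- mean(rr)
    f[["centroid_col"]] <- mean(cc)
    layer$objects[[as.character(o$id)]]$features <- f
  }
  layer
}

## ---- channel intensity -----------------------------------------------------

check_image_shape <- function(layer, image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L ||
      !identical(d[1:2], dim(layer$label_map)))
    ol_stop("inconsistent_input",
            "image must be H x W x 3 and match the label map shape")
}

#' Mean RGB channel intensities per object
#'
#' Sets `mean_R`, `mean_G`, `mean_B`: the arithmetic mean of each channel
#' over the object's pixels.
#'
#' @param layer an `ObjectLayer`.
#' @param image numeric H x W x 3 array matching the label map shape.
#' @return the layer with features set.
#' @export
channel_intensity <- function(layer, image) {
  check_image_shape(layer, image)
  chans <- c("R", "G", "B")
  for (o in layer$objects) {
    idx <- which(layer$label_map == o$id)
    for (k in 1:3) {
      layer <- set_feature(layer, o$id, paste0("mean_", chans[k]),
                           mean(image[, , k][idx]))
    }
  }
  layer
}

## ---- stain deconvolution ---------------------------------------------------

#' Stain matrix constructor
#'
#' Rows are unit-norm stain vectors in RGB optical-density space.
#'
#' @param vectors 3 x 3 numeric matrix (stain x RGB); rows are renormalized.
#' @param names stain names, length 3.
#' @return a `StainMatrix` (matrix with stain row names).
#' @export
stain_matrix <- function(vectors, names) {
  m <- as.matrix(vectors)
  stopifnot(identical(dim(m), c(3L, 3L)), length(names) == 3L)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) ol_stop("invalid_stain_matrix", "zero stain vector")
  m <- m / norms
  if (abs(det(m)) < 1e-8)
    ol_stop("invalid_stain_matrix", "stain matrix is singular")
  rownames(m) <- names
  colnames(m) <- c("R", "G", "B")
  structure(m, class = c("StainMatrix", "matrix"))
}

#' Standard H-DAB stain matrix
#'
#' The widely used hematoxylin/DAB optical-density vectors of the
#' color-deconvolution literature (Ruifrok & Johnston), with the residual
#' stain as the normalized cross product.
#'
#' @return a `StainMatrix` with stains `hematoxylin`, `DAB`, `residual`.
#' @export
hdab_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  stain_matrix(rbind(h, d, r), c("hematoxylin", "DAB", "residual"))
}

#' Load a stain matrix from JSON
#'
#' Expects `{"names": [3 strings], "vectors": [[3 x 3 numbers]]}` (rows =
#' stains, columns = R,G,B optical densities).
#'
#' @param path JSON file path.
#' @return a `StainMatrix`.
#' @export
read_stain_matrix <- function(path) {
  doc <- jsonlite::fromJSON(path)
  stain_matrix(matrix(as.numeric(t(doc$vectors)), 3L, 3L, byrow = TRUE),
               doc$names)
}

# Optical density of 8-bit-scale intensities: OD = -log10((I + 1)/255).
# The +1 guards log(0) at I = 0; its exact inverse is I = 255 * 10^-OD - 1,
# which compose_stains() uses so that mix-then-unmix round-trips.
od_transform <- function(intensity) -log10((intensity + 1) / 255)

#' Unmix an RGB image into per-stain concentration grids
#'
#' Per pixel, the RGB optical densities `OD = -log10((I + 1)/255)` are
#' solved against the stain matrix; negative concentrations are clipped to 0
#' (physical non-negativity). Concentrations are in OD units.
#'
#' @param image numeric H x W x 3 array, values in \[0, 255\].
#' @param stains a `StainMatrix` (default [hdab_matrix()]).
#' @return named list of per-stain concentration matrices.
#' @export
deconvolve <- function(image, stains = hdab_matrix()) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    ol_stop("inconsistent_input", "image must be an H x W x 3 array")
  minv <- solve(unclass(stains))
  od <- od_transform(matrix(as.numeric(image), d[1L] * d[2L], 3L))
  conc <- od %*% minv
  conc[conc < 0] <- 0
  out <- lapply(1:3, function(k) matrix(conc[, k], d[1L], d[2L]))
  names(out) <- rownames(stains)
  out
}

#' Render per-stain concentrations back to RGB intensities
#'
#' The exact forward model of [deconvolve()]: `I = 255 * 10^-(c . M) - 1`,
#' clipped to \[0, 255\]. Used by the synthetic generators and round-trip
#' tests; within the non-saturating range, `deconvolve(compose_stains(c))`
#' recovers `c` exactly.
#'
#' @param conc named list of concentration matrices (one per stain row).
#' @param stains a `StainMatrix`.
#' @return numeric H x W x 3 array of (unquantized) intensities.
#' @export
compose_stains <- function(conc, stains = hdab_matrix()) {
  stopifnot(length(conc) == 3L)
  d <- dim(conc[[1L]])
  cmat <- cbind(as.numeric(conc[[1L]]), as.numeric(conc[[2L]]),
                as.numeric(conc[[3L]]))
  od <- cmat %*% unclass(stains)
  intens <- pmin(pmax(255 * 10^(-od) - 1, 0), 255)
  array(intens, dim = c(d, 3L))
}

#' Mean stain concentrations per object
#'
#' Unmixes the image with [deconvolve()] and sets `mean_<stain>` (e.g.
#' `mean_hematoxylin`, `mean_DAB`) as the per-object mean concentration.
#'
#' @inheritParams channel_intensity
#' @param stains a `StainMatrix`.
#' @return the layer with features set.
#' @export
stain_intensity <- function(layer, image, stains = hdab_matrix()) {
  check_image_shape(layer, image)
  conc <- deconvolve(image, stains)
  for (o in layer$objects) {
    idx <- which(layer$label_map == o$id)
    for (s in names(conc)) {
      layer <- set_feature(layer, o$id, paste0("mean_", s),
                           mean(conc[[s]][idx]))
    }
  }
  layer
}

## ---- class-relational features ---------------------------------------------

#' Class-relational features from the neighbourhood network
#'
#' For every object and every class name in `classes`, sets
#' `border_to_<class>` (number of the object's contour pixels 8-adjacent to
#' any pixel of an object of that class — the BorderTo contact-length proxy),
#' `num_neighbouring_<class>` (Voronoi neighbours of that class) and
#' `num_touching_<class>` (touching neighbours of that class).
#'
#' @param layer a classified `ObjectLayer`.
#' @param network an `ObjectNetwork` built from `layer`.
#' @param classes character vector of class names to relate against.
#' @return the layer with features set.
#' @export
relational_features <- function(layer, network, classes) {
  ids <- layer_ids(layer)
  if (!all(as.character(ids) %in% names(network$neighbourhoods)))
    ol_stop("inconsistent_input", "network does not cover the layer's objects")
  class_of <- stats::setNames(layer_classes(layer), as.character(ids))
  for (o in layer$objects) {
    nbl <- neighbour_labels(layer$label_map, o$contour$points)
    nbh_ids <- network_neighbours(network, o$id)
    tch_ids <- network_neighbours(network, o$id, touching_only = TRUE)
    for (cl in classes) {
      members <- ids[!is.na(class_of) & class_of == cl & ids != o$id]
      border <- if (length(members))
        sum(rowSums(matrix(nbl %in% members, nrow(nbl))) > 0L) else 0L
      layer <- set_feature(layer, o$id, paste0("border_to_", cl), border)
      layer <- set_feature(layer, o$id, paste0("num_neighbouring_", cl),
                           sum(class_of[as.character(nbh_ids)] == cl,
                               na.rm = TRUE))
      layer <- set_feature(layer, o$id, paste0("num_touching_", cl),
                           sum(class_of[as.character(tch_ids)] == cl,
                               na.rm = TRUE))
    }
  }
  layer
}
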