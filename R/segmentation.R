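## Segmentation: raw image -> ObjectLayer.
## Otsu + connected components + area filter + priority channel merge. This
## stack is a deliberately simple, documented segmenter: it does not split
## touching objects within one channel (see the methods vignette).

#' Otsu threshold of an intensity channel
#'
#' Builds a 256-bin histogram (values binned by `floor`, clipped to 0..255)
#' and returns the threshold maximizing the between-class variance, i.e. the
#' candidate `t` for which the split `value <= t` vs `value > t` has maximal
#' weighted squared mean separation. Ties resolve to the lowest `t`;
#' deterministic.
#'
#' @param channel numeric matrix with values in \[0, 255\].
#' @return threshold (scalar); pixels strictly above it are foreground under
#'   [threshold_segment()] with `polarity = "above"`.
#' @export
otsu_threshold <- function(channel) {
  if (length(channel) == 0L)
    ol_stop("degenerate_histogram", "empty channel has no histogram")
  v <- pmin(pmax(floor(as.numeric(channel)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    ol_stop("degenerate_histogram",
            "constant channel: between-class variance undefined")
  n <- sum(h)
  levels <- 0:255
  w0 <- cumsum(h) / n                       # weight of class {<= t}
  m0 <- cumsum(h * levels) / n              # unnormalized first moment
  mt <- m0[256L]
  # between-class variance at candidate t = levels[i]
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mt * w0 - m0)^2 / denom, -Inf)
  sigma_b[256L] <- -Inf                     # t = 255 leaves one class empty
  levels[which.max(sigma_b)]
}

#' Threshold a channel into a binary mask
#'
#' @param channel numeric matrix.
#' @param threshold scalar.
#' @param polarity `"above"` (mask where `channel > threshold`) or `"below"`
#'   (`channel < threshold`).
#' @return logical matrix.
#' @export
threshold_segment <- function(channel, threshold, polarity = c("above", "below")) {
  polarity <- match.arg(polarity)
  if (polarity == "above") channel > threshold else channel < threshold
}

#' Label connected foreground components as an object layer
#'
#' 8-connected components, ids 1..K in raster-scan order of first occurrence.
#'
#' @param mask logical matrix.
#' @return an `ObjectLayer` (passes [validate_layer()]).
#' @export
connected_components <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  lab <- cpp_label_components(mask, 8L)
  build_layer(lab, provenance = "connected_components")
}

#' Remove objects below an area cutoff
#'
#' Objects with `pixel_count < min_area` are deleted from both the label map
#' and the object list; surviving objects keep their ids, classes and
#' features.
#'
#' @param layer an `ObjectLayer`.
#' @param min_area minimum pixel count (>= 1) to survive.
#' @return filtered `ObjectLayer`.
#' @export
remove_small <- function(layer, min_area) {
  stopifnot(min_area >= 1)
  keep <- vapply(layer$objects, function(o) o$pixel_count >= min_area,
                 logical(1))
  drop_ids <- layer_ids(layer)[!keep]
  grid <- layer$label_map
  if (length(drop_ids)) grid[grid %in% drop_ids] <- 0L
  new_layer(grid, layer$objects[keep], provenance = "remove_small")
}

#' Channel specification for multi-channel merging
#'
#' @param channel_index 1, 2 or 3 (R/G/B).
#' @param class_name class assigned to this channel's objects.
#' @param priority integer; lower wins pixel conflicts.
#' @export
channel_spec <- function(channel_index, class_name, priority) {
  stopifnot(channel_index %in% 1:3)
  list(channel_index = as.integer(channel_index),
       class_name = as.character(class_name),
       priority = as.integer(priority))
}

#' Segment and merge several image channels into one classified layer
#'
#' Each requested channel is Otsu-thresholded (foreground above threshold),
#' componentized and filtered by `per_channel_min_area`. Pixels claimed by
#' several channels are assigned to the highest-priority channel (lowest
#' `priority` number), so the result does not depend on the order of `specs`.
#' Components are relabelled after conflict resolution, in priority order
#' then raster order, and carry their channel's class name.
#'
#' @param image numeric H x W x 3 array, values in \[0, 255\].
#' @param specs list of [channel_spec()] entries with unique priorities.
#' @param per_channel_min_area area filter applied within each channel.
#' @return classified `ObjectLayer`.
#' @export
merge_channel_layers <- function(image, specs, per_channel_min_area = 1L) {
  if (length(specs) < 1L)
    ol_stop("bad_argument", "merge_channel_layers needs at least one channel spec")
  pr <- vapply(specs, `[[`, integer(1), "priority")
  if (anyDuplicated(pr))
    ol_stop("bad_argument", "channel priorities must be unique")
  nr <- dim(image)[1L]; nc <- dim(image)[2L]
  if (nr == 0L || nc == 0L)
    return(new_layer(matrix(integer(), nr, nc), list(), "merge_channels"))
  specs <- specs[order(pr)]
  masks <- vector("list", length(specs))
  claimed <- matrix(FALSE, nr, nc)
  for (i in seq_along(specs)) {
    ch <- image[, , specs[[i]]$channel_index]
    t <- otsu_threshold(ch)
    m <- threshold_segment(ch, t, "above")
    lab <- cpp_label_components(m, 8L)
    if (max(lab) > 0L && per_channel_min_area > 1L) {
      areas <- tabulate(lab[lab > 0L], nbins = max(lab))
      small <- which(areas < per_channel_min_area)
      if (length(small)) m[lab %in% small] <- FALSE
    }
    m <- m & !claimed            # higher-priority channels already own these
    claimed <- claimed | m
    masks[[i]] <- m
  }
  grid <- matrix(0L, nr, nc)
  class_of <- character(0)
  offset <- 0L
  for (i in seq_along(specs)) {
    lab <- cpp_label_components(masks[[i]], 8L)
    k <- max(lab)
    if (k > 0L) {
      grid[lab > 0L] <- lab[lab > 0L] + offset
      class_of <- c(class_of,
                    stats::setNames(rep(specs[[i]]$class_name, k),
                                    as.character(offset + seq_len(k))))
      offset <- offset + k
    }
  }
  layer <- build_layer(grid, provenance = "merge_channels")
  for (id in names(layer$objects))
    layer$objects[[id]]$class_name <- class_of[[id]]
  layer
}
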