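## Topology: discrete Voronoi tessellation of the label map and the
## object neighbourhood network derived from it.
##
## Two distinct relations are exposed: "neighbouring" (the objects' Voronoi
## influence zones share a border; 4-adjacency of cells, counted in crack
## edges) and "touching" (the objects themselves have 8-adjacent pixels,
## with the shared border measured in contour pixels).

#' Discrete Voronoi tessellation of an object layer
#'
#' Assigns every pixel (including background) the id of the object containing
#' the Euclidean-nearest object pixel (pixel centres, exact squared
#' distances); ties are broken towards the lowest object id. With
#' `max_distance` set, pixels farther than that from every object keep id 0.
#'
#' @param layer an `ObjectLayer` with at least one object.
#' @param max_distance optional reach limit in pixels (default unlimited).
#' @return a `VoronoiMap`: list with `grid` (integer id per pixel),
#'   `distance` (distance to the nearest object pixel) and `max_distance`.
#' @export
voronoi_tessellate <- function(layer, max_distance = NULL) {
  if (length(layer$objects) == 0L)
    ol_stop("empty_layer", "cannot tessellate a layer with no objects")
  md <- if (is.null(max_distance)) Inf else as.numeric(max_distance)
  res <- cpp_voronoi(layer$label_map, layer_ids(layer), md)
  structure(list(grid = res$assign, distance = res$distance,
                 max_distance = max_distance),
            class = "VoronoiMap")
}

# Count unordered adjacent-pixel pairs with different positive labels.
# offsets: list of c(dr, dc) shifts. Returns data.frame(a, b, n) with a < b.
adjacent_pairs <- function(grid, offsets) {
  nr <- nrow(grid); nc <- ncol(grid)
  acc_a <- integer(0); acc_b <- integer(0)
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    if (nr - abs(dr) < 1L || nc - abs(dc) < 1L) next
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- grid[r1, c1, drop = FALSE]
    b <- grid[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a != b & a > 0L & b > 0L
    acc_a <- c(acc_a, pmin(a[sel], b[sel]))
    acc_b <- c(acc_b, pmax(a[sel], b[sel]))
  }
  if (length(acc_a) == 0L)
    return(data.frame(a = integer(0), b = integer(0), n = integer(0)))
  key <- paste(acc_a, acc_b)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(a = as.integer(vapply(parts, `[[`, character(1), 1L)),
             b = as.integer(vapply(parts, `[[`, character(1), 2L)),
             n = as.integer(tab))
}

# Labels of the 8-neighbourhood of each point; off-grid positions read 0.
neighbour_labels <- function(grid, pts) {
  nr <- nrow(grid); nc <- ncol(grid)
  n <- nrow(pts)
  out <- matrix(0L, n, 8L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    k <- k + 1L
    rr <- pts[, 1L] + dr; cc <- pts[, 2L] + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (any(ok)) out[ok, k] <- grid[cbind(rr[ok], cc[ok])]
  }
  out
}

#' Build the object neighbourhood network
#'
#' Two objects are *neighbouring* iff their Voronoi cells have 4-adjacent
#' pixels; `voronoi_border` counts those cross-cell pixel-edge pairs (crack
#' edges) and is symmetric. Two objects are *touching* iff they have
#' 8-adjacent pixels in the label map; `touching_border` counts, per
#' direction, the object's own contour pixels that are 8-adjacent to the
#' other object.
#'
#' @param layer an `ObjectLayer`.
#' @param voronoi a `VoronoiMap` computed from `layer`.
#' @return an `ObjectNetwork`: list with `neighbourhoods` (per object id, a
#'   list of per-neighbour records `voronoi_border`/`touching_border`/
#'   `touching`) and `max_distance`.
#' @export
build_network <- function(layer, voronoi) {
  if (!identical(dim(layer$label_map), dim(voronoi$grid)))
    ol_stop("inconsistent_input",
            "voronoi map shape does not match the layer's label map")
  ids <- layer_ids(layer)
  if (!all(unique(as.integer(voronoi$grid)) %in% c(0L, ids)))
    ol_stop("inconsistent_input",
            "voronoi map assigns ids absent from the layer")
  four <- list(c(0L, 1L), c(1L, 0L))
  eight <- c(four, list(c(1L, 1L), c(1L, -1L)))
  vb <- adjacent_pairs(voronoi$grid, four)
  tp <- adjacent_pairs(layer$label_map, eight)
  touch_key <- paste(tp$a, tp$b)
  nb <- stats::setNames(
    lapply(ids, function(id) list(object_id = id, neighbours = list())),
    as.character(ids))
  for (i in seq_len(nrow(vb))) {
    a <- vb$a[i]; b <- vb$b[i]; n <- vb$n[i]
    touching <- paste(a, b) %in% touch_key
    rec_ab <- list(voronoi_border = n, touching_border = 0L,
                   touching = touching)
    nb[[as.character(a)]]$neighbours[[as.character(b)]] <- rec_ab
    nb[[as.character(b)]]$neighbours[[as.character(a)]] <- rec_ab
  }
  # touching pairs are always Voronoi neighbours (their cells contain their
  # own adjacent pixels); fill in directed touching-border pixel counts
  for (i in seq_len(nrow(tp))) {
    a <- tp$a[i]; b <- tp$b[i]
    for (pair in list(c(a, b), c(b, a))) {
      o <- get_object(layer, pair[1L])
      nbl <- neighbour_labels(layer$label_map, o$contour$points)
      cnt <- sum(rowSums(nbl == pair[2L]) > 0L)
      key1 <- as.character(pair[1L]); key2 <- as.character(pair[2L])
      rec <- nb[[key1]]$neighbours[[key2]]
      if (is.null(rec))   # touching but cells meet only diagonally: still record
        rec <- list(voronoi_border = 0L, touching_border = 0L, touching = TRUE)
      rec$touching <- TRUE
      rec$touching_border <- cnt
      nb[[key1]]$neighbours[[key2]] <- rec
    }
  }
  structure(list(neighbourhoods = nb, max_distance = voronoi$max_distance),
            class = "ObjectNetwork")
}

# Neighbour ids of one object, optionally restricted to touching neighbours.
network_neighbours <- function(network, id, touching_only = FALSE) {
  nbh <- network$neighbourhoods[[as.character(id)]]
  if (is.null(nbh)) return(integer(0))
  nbs <- nbh$neighbours
  if (touching_only)
    nbs <- Filter(function(r) isTRUE(r$touching), nbs)
  as.integer(names(nbs))
}
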