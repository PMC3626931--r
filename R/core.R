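#' @title Object layers: label maps plus object records
#'
#' @description An `ObjectLayer` is the unit passed between processing steps:
#' an integer label map (0 = background, each positive value an object id)
#' together with one record per object holding its contour, pixel count,
#' optional class name and a named feature vector.
#'
#' @name ObjectLayer
#' @keywords internal
NULL

## ---- label-map helpers -----------------------------------------------------

as_label_map <- function(grid) {
  if (!is.matrix(grid)) ol_stop("invalid_label_map", "label map must be a matrix")
  if (length(grid) && (anyNA(grid) || any(grid < 0)))
    ol_stop("invalid_label_map", "label map values must be non-negative integers")
  if (is.double(grid)) {
    if (length(grid) && any(grid != floor(grid)))
      ol_stop("invalid_label_map", "label map values must be integers")
    storage.mode(grid) <- "integer"
  }
  grid
}

# ids present in a label map, ascending
map_ids <- function(grid) {
  u <- sort(unique(as.integer(grid)))
  u[u > 0L]
}

## ---- hole filling and contour tracing --------------------------------------

# Fill interior holes of a binary mask: background components (4-connected)
# that do not touch the matrix border are holes.
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr == 0L || nc == 0L) return(mask)
  bg <- cpp_label_components(!mask, 4L)
  border_ids <- unique(c(bg[1L, ], bg[nr, ], bg[, 1L], bg[, nc]))
  border_ids <- border_ids[border_ids > 0L]
  mask | !(bg %in% c(0L, border_ids))
}

# Trace the outer crack-edge boundary of a filled, 8-connected mask.
#
# The boundary is walked along pixel edges (cracks) between object and
# non-object pixels, clockwise in screen coordinates, resolving diagonal
# configurations by a left turn so that 8-connected diagonals stay on one
# contour. Returns the ordered closed chain of boundary pixels (consecutive
# points 8-adjacent) and the crack-edge count (the contour length).
trace_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2L:(nr + 1L), 2L:(nc + 1L)] <- mask
  rs1 <- 1L:(nr + 1L); rs2 <- 2L:(nr + 2L)
  cs1 <- 1L:(nc + 1L); cs2 <- 2L:(nc + 2L)
  # directed crack edges by their start corner (corner (y,x) -> index y+1,x+1)
  edge <- list(
    E = pad[rs2, cs2, drop = FALSE] & !pad[rs1, cs2, drop = FALSE],
    S = pad[rs2, cs1, drop = FALSE] & !pad[rs2, cs2, drop = FALSE],
    W = pad[rs1, cs1, drop = FALSE] & !pad[rs2, cs1, drop = FALSE],
    N = pad[rs1, cs2, drop = FALSE] & !pad[rs1, cs1, drop = FALSE]
  )
  n_edges <- sum(edge$E) + sum(edge$S) + sum(edge$W) + sum(edge$N)
  if (n_edges == 0L)
    return(list(points = matrix(integer(), 0L, 2L), length = 0L))
  # start at the raster-first object pixel's top-left corner heading East
  first <- which(t(mask))[1L]                   # raster order (row-major)
  r0 <- (first - 1L) %/% nc + 1L
  c0 <- first - (r0 - 1L) * nc
  dirs <- c("E", "S", "W", "N")                 # clockwise cycle
  d_end  <- list(E = c(0L, 1L), S = c(1L, 0L), W = c(0L, -1L), N = c(-1L, 0L))
  d_pix  <- list(E = c(1L, 1L), S = c(1L, 0L), W = c(0L, 0L), N = c(0L, 1L))
  pts_r <- integer(n_edges); pts_c <- integer(n_edges); np <- 0L
  y <- r0 - 1L; x <- c0 - 1L; d <- "E"
  steps <- 0L
  repeat {
    steps <- steps + 1L
    p <- d_pix[[d]]
    pr <- y + p[1L]; pc <- x + p[2L]
    if (np == 0L || pts_r[np] != pr || pts_c[np] != pc) {
      np <- np + 1L; pts_r[np] <- pr; pts_c[np] <- pc
    }
    e <- d_end[[d]]
    y <- y + e[1L]; x <- x + e[2L]
    if (y == r0 - 1L && x == c0 - 1L) {
      # back at start corner; the start edge was E, so stop before re-walking
      break
    }
    # outgoing edge: prefer left turn, then straight, then right turn
    di <- match(d, dirs)
    cand <- dirs[c((di - 2L) %% 4L + 1L, di, di %% 4L + 1L)]
    nd <- NA_character_
    for (cd in cand) {
      if (edge[[cd]][y + 1L, x + 1L]) { nd <- cd; break }
    }
    if (is.na(nd))
      ol_stop("internal", "contour tracing lost the boundary (malformed mask)")
    d <- nd
    if (steps > n_edges)
      ol_stop("internal", "contour tracing failed to close")
  }
  pts <- cbind(row = pts_r[seq_len(np)], col = pts_c[seq_len(np)])
  # drop a duplicated wrap-around point
  if (np > 1L && pts[1L, 1L] == pts[np, 1L] && pts[1L, 2L] == pts[np, 2L])
    pts <- pts[-np, , drop = FALSE]
  list(points = pts, length = steps)
}

# Contour of the object with the given id: outer contour of the hole-filled
# mask, computed on the object's bounding box for speed. Pixel area is the
# raw (unfilled) pixel count.
object_contour <- function(grid, id) {
  idx <- which(grid == id)
  nr <- nrow(grid)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  r1 <- min(rr); r2 <- max(rr); c1 <- min(cc); c2 <- max(cc)
  sub <- grid[r1:r2, c1:c2, drop = FALSE] == id
  tr <- trace_contour(fill_holes(sub))
  pts <- tr$points
  pts[, 1L] <- pts[, 1L] + r1 - 1L
  pts[, 2L] <- pts[, 2L] + c1 - 1L
  list(points = pts, length = tr$length, area = length(idx))
}

## ---- layer construction ----------------------------------------------------

new_object <- function(id, contour, pixel_count,
                       class_name = NA_character_,
                       features = stats::setNames(numeric(0), character(0))) {
  list(id = as.integer(id), contour = contour,
       pixel_count = as.integer(pixel_count),
       class_name = class_name, features = features)
}

new_layer <- function(label_map, objects, provenance = "manual") {
  structure(list(label_map = label_map,
                 objects = objects,
                 provenance = provenance),
            class = "ObjectLayer")
}

#' Build an object layer from a label map
#'
#' Creates one object record per distinct positive id in the map, with
#' contour (outer crack-edge boundary of the hole-filled mask) and pixel
#' count populated, class unset and features empty. If a single id labels
#' several disconnected components (8-connectivity), each component is
#' re-labelled with a fresh id; fresh ids continue past the current maximum
#' and are assigned in raster-scan order of first occurrence.
#'
#' @param label_map integer matrix; 0 = background, positive values = ids.
#' @param provenance tag recorded on the layer (producing step name).
#' @return an `ObjectLayer`.
#' @examples
#' m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 7L
#' layer <- build_layer(m)
#' layer$objects[[1]]$pixel_count   # 9
#' layer$objects[[1]]$contour$length  # 12 crack edges
#' @export
build_layer <- function(label_map, provenance = "build_layer") {
  grid <- as_label_map(label_map)
  ids <- map_ids(grid)
  if (length(ids) == 0L) return(new_layer(grid, list(), provenance))
  # split ids whose pixel set is disconnected under 8-connectivity
  next_id <- max(ids) + 1L
  split_pieces <- list()   # list of (first_raster_index, pixel_index_vector)
  nr <- nrow(grid); nc <- ncol(grid)
  for (id in ids) {
    comp <- cpp_label_components(grid == id, 8L)
    k <- max(comp)
    if (k > 1L) {
      for (j in seq_len(k)) {
        idx <- which(comp == j)
        rr <- (idx - 1L) %% nr; cc <- (idx - 1L) %/% nr
        raster <- rr * nc + cc
        split_pieces[[length(split_pieces) + 1L]] <-
          list(first = min(raster), idx = idx)
      }
      grid[grid == id] <- 0L
    }
  }
  if (length(split_pieces)) {
    ord <- order(vapply(split_pieces, `[[`, numeric(1), "first"))
    for (piece in split_pieces[ord]) {
      grid[piece$idx] <- next_id
      next_id <- next_id + 1L
    }
    ids <- map_ids(grid)
  }
  objects <- lapply(ids, function(id) {
    ct <- object_contour(grid, id)
    new_object(id, ct, ct$area)
  })
  names(objects) <- as.character(ids)
  new_layer(grid, objects, provenance)
}

#' Validate an object layer
#'
#' Checks the layer invariants and reports violations instead of raising:
#' unique object ids, bijection between object records and positive map
#' values, and agreement of each record's `pixel_count` with the map.
#'
#' @param layer an `ObjectLayer`.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_layer <- function(layer) {
  out <- character(0)
  ids <- vapply(layer$objects, `[[`, integer(1), "id")
  if (anyDuplicated(ids))
    out <- c(out, sprintf("duplicate id: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  present <- map_ids(layer$label_map)
  for (id in setdiff(ids, present))
    out <- c(out, sprintf("object %d has no pixels in the label map", id))
  for (id in setdiff(present, ids))
    out <- c(out, sprintf("map id %d has no object record", id))
  tab <- tabulate(layer$label_map[layer$label_map > 0L],
                  nbins = max(c(0L, present, ids)))
  for (o in layer$objects) {
    if (o$id %in% present && o$id %in% ids && tab[o$id] != o$pixel_count)
      out <- c(out, sprintf(
        "object %d pixel_count %d != %d pixels in the label map",
        o$id, o$pixel_count, tab[o$id]))
  }
  out
}

#' Binary mask of one object
#'
#' @param layer an `ObjectLayer`.
#' @param id object id present in the layer.
#' @return logical matrix, `TRUE` exactly where `label_map == id`.
#' @export
object_mask <- function(layer, id) {
  if (!as.character(id) %in% names(layer$objects))
    ol_stop("missing_object", sprintf("no object with id %s in layer", id))
  layer$label_map == id
}

# Look up an object record; shared error for unknown ids.
get_object <- function(layer, id) {
  o <- layer$objects[[as.character(id)]]
  if (is.null(o))
    ol_stop("missing_object", sprintf("no object with id %s in layer", id))
  o
}

layer_ids <- function(layer) {
  vapply(layer$objects, `[[`, integer(1), "id", USE.NAMES = FALSE)
}

layer_classes <- function(layer) {
  vapply(layer$objects, `[[`, character(1), "class_name", USE.NAMES = FALSE)
}

#' @export
print.ObjectLayer <- function(x, ...) {
  cls <- layer_classes(x)
  cat(sprintf("ObjectLayer [%s]: %d x %d map, %d objects (%d classified)\n",
              x$provenance, nrow(x$label_map), ncol(x$label_map),
              length(x$objects), sum(!is.na(cls))))
  invisible(x)
}
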