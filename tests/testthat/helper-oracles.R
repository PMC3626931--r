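# Independent brute-force oracles and random-fixture builders. Everything
# here is deliberately naive (per-pixel loops, exhaustive searches) and
# shares no code with the implementation paths it checks.

# Flood-fill connected-components labelling, raster order, plain R queues.
oracle_flood_fill <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4L) list(c(-1,0), c(1,0), c(0,-1), c(0,1))
          else list(c(-1,0), c(1,0), c(0,-1), c(0,1),
                    c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  nid <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nid <- nid + 1L
    queue <- list(c(r, c)); lab[r, c] <- nid
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        rr <- p[1L] + o[1L]; cc <- p[2L] + o[2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nid
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Per-pixel nearest-object search: exact Euclidean distance to every object
# pixel, lowest id wins exact squared-distance ties.
oracle_voronoi <- function(label_map, max_distance = NULL) {
  nr <- nrow(label_map); nc <- ncol(label_map)
  ids <- sort(unique(label_map[label_map > 0L]))
  px_r <- matrix(rep(seq_len(nr), nc), nr, nc)
  px_c <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best <- matrix(Inf, nr, nc)
  who <- matrix(0L, nr, nc)
  for (id in ids) {
    idx <- which(label_map == id)
    sr <- (idx - 1L) %% nr + 1L
    sc <- (idx - 1L) %/% nr + 1L
    d <- matrix(Inf, nr, nc)
    for (k in seq_along(sr)) {
      dk <- (px_r - sr[k])^2 + (px_c - sc[k])^2
      d <- pmin(d, dk)
    }
    upd <- d < best        # strict: earlier (lower) ids keep exact ties
    best[upd] <- d[upd]
    who[upd] <- id
  }
  if (!is.null(max_distance)) who[best > max_distance^2] <- 0L
  list(assign = who, dist = sqrt(best))
}

# Exhaustive Otsu: for every candidate t, split the (floored) values and
# compute the between-class variance directly from the two subsets.
oracle_otsu <- function(values) {
  v <- pmin(pmax(floor(as.numeric(values)), 0), 255)
  n <- length(v)
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n; w1 <- length(hi) / n
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Crack-edge perimeter by direct pixel-edge counting on a (filled) mask.
oracle_crack_length <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  sum(core & !pad[1:nr, 2:(nc + 1L)]) +
    sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) +
    sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

# Digital disk mask: pixel centres within radius r of the centre.
disk_mask <- function(r) {
  n <- 2L * r + 3L
  ctr <- r + 2L
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix(FALSE, n, n)
  m[as.matrix(g[(g$row - ctr)^2 + (g$col - ctr)^2 <= r^2, ])] <- TRUE
  m
}

# Random layer: stamp k random rectangles/blobs (later stamps overwrite),
# then normalize through build_layer (splits overwritten remnants).
random_layer <- function(seed, nr = 32L, nc = 32L, k = 6L) {
  set.seed(seed)
  m <- matrix(0L, nr, nc)
  for (id in seq_len(k)) {
    h <- sample(2:7, 1L); w <- sample(2:7, 1L)
    r <- sample(seq_len(nr - h), 1L); c <- sample(seq_len(nc - w), 1L)
    m[r:(r + h - 1L), c:(c + w - 1L)] <- id
  }
  build_layer(m)
}

# Random classified layer for relational-feature checks.
random_classified_layer <- function(seed, nr = 32L, nc = 32L, k = 6L,
                                    classes = c("a", "b", "c")) {
  layer <- random_layer(seed, nr, nc, k)
  set.seed(seed + 10000L)
  for (id in names(layer$objects))
    layer$objects[[id]]$class_name <- sample(classes, 1L)
  layer
}

layer_ids_of <- function(layer) {
  vapply(layer$objects, `[[`, integer(1), "id", USE.NAMES = FALSE)
}

# Matrix of a small labelled scene used across files: two 3x3 squares in
# contact plus an isolated square.
contact_scene <- function() {
  m <- matrix(0L, 9, 14)
  m[2:4, 2:4] <- 1L    # square A
  m[2:4, 5:7] <- 2L    # square B, full 3-pixel vertical contact with A
  m[7:9, 11:13] <- 3L  # isolated square
  m
}
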