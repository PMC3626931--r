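test_that("voronoi tessellation handles single seeds, splits and ties", {
  # single object claims everything
  m <- matrix(0L, 7, 9); m[3, 4] <- 4L
  v <- voronoi_tessellate(build_layer(m))
  expect_true(all(v$grid == 4L))
  expect_equal(v$distance[3, 4], 0)

  # 1x10 line with seeds at both ends splits at the midpoint
  m2 <- matrix(0L, 1, 10); m2[1, 1] <- 1L; m2[1, 10] <- 2L
  v2 <- voronoi_tessellate(build_layer(m2))
  expect_equal(as.integer(v2$grid), rep(c(1L, 2L), each = 5))

  # exact equidistant tie goes to the lower id: seeds at cols 1 and 11,
  # column 6 is 5 away from both
  m3 <- matrix(0L, 1, 11); m3[1, 1] <- 1L; m3[1, 11] <- 2L
  v3 <- voronoi_tessellate(build_layer(m3))
  expect_equal(v3$grid[1, 6], 1L)

  expect_error(voronoi_tessellate(build_layer(matrix(0L, 4, 4))),
               class = "objlayer_empty_layer")
})

test_that("voronoi tessellation equals the brute-force oracle", {
  for (seed in 1:20) {
    layer <- random_layer(seed, 24, 24, seed %% 6 + 1L)
    if (length(layer$objects) == 0L) next
    v <- voronoi_tessellate(layer)
    o <- oracle_voronoi(layer$label_map)
    expect_identical(v$grid, o$assign)
    expect_equal(v$distance, o$dist, tolerance = 1e-12)
  }
})

test_that("max_distance truncates cells and never adds neighbour pairs", {
  layer <- random_layer(5, 40, 40, 5)
  v_all <- voronoi_tessellate(layer)
  expect_equal(sum(tabulate(v_all$grid[v_all$grid > 0L])), length(v_all$grid))
  prev_pairs <- NULL
  for (md in c(Inf, 8, 4, 2)) {
    v <- voronoi_tessellate(layer, if (is.finite(md)) md else NULL)
    o <- oracle_voronoi(layer$label_map, if (is.finite(md)) md else NULL)
    expect_identical(v$grid, o$assign)
    net <- build_network(layer, v)
    pairs <- unlist(lapply(net$neighbourhoods, function(nbh) {
      nms <- names(nbh$neighbours)
      if (length(nms)) paste(nbh$object_id, nms) else character(0)
    }))
    if (!is.null(prev_pairs)) expect_true(all(pairs %in% prev_pairs))
    prev_pairs <- pairs
  }
})

test_that("network distinguishes neighbouring from touching", {
  # two 3x3 squares separated by a one-pixel gap: cells meet, no touching
  m <- matrix(0L, 7, 12); m[2:4, 2:4] <- 1L; m[2:4, 6:8] <- 2L
  l <- build_layer(m)
  net <- build_network(l, voronoi_tessellate(l))
  rec <- net$neighbourhoods[["1"]]$neighbours[["2"]]
  expect_gte(rec$voronoi_border, 1L)
  expect_false(rec$touching)
  expect_equal(rec$touching_border, 0L)

  # direct 3-pixel contact: touching with touching_border 3 on both sides
  m2 <- contact_scene()
  l2 <- build_layer(m2)
  net2 <- build_network(l2, voronoi_tessellate(l2))
  r12 <- net2$neighbourhoods[["1"]]$neighbours[["2"]]
  r21 <- net2$neighbourhoods[["2"]]$neighbours[["1"]]
  expect_true(r12$touching && r21$touching)
  expect_equal(r12$touching_border, 3L)
  expect_equal(r21$touching_border, 3L)
  # the isolated square has no touching neighbours
  nb3 <- net2$neighbourhoods[["3"]]$neighbours
  expect_false(any(vapply(nb3, `[[`, logical(1), "touching")))

  expect_error(build_network(l2, voronoi_tessellate(l)),
               class = "objlayer_inconsistent_input")
})

test_that("network symmetry, touching implies neighbouring, cells partition", {
  for (seed in 1:12) {
    layer <- random_layer(seed + 100, 32, 32, 7)
    if (length(layer$objects) < 2L) next
    v <- voronoi_tessellate(layer)
    net <- build_network(layer, v)
    # cells partition the image
    expect_equal(sum(v$grid > 0L), length(v$grid))
    # symmetry with equal shared voronoi borders; recount the border from
    # the map for every pair
    for (nbh in net$neighbourhoods) {
      a <- nbh$object_id
      for (b_chr in names(nbh$neighbours)) {
        b <- as.integer(b_chr)
        rec <- nbh$neighbours[[b_chr]]
        back <- net$neighbourhoods[[b_chr]]$neighbours[[as.character(a)]]
        expect_false(is.null(back))
        expect_equal(rec$voronoi_border, back$voronoi_border)
        # pairwise recount: 4-adjacent pixel pairs with cells {a, b}
        g <- v$grid
        cnt <- sum(g[, -ncol(g)] == a & g[, -1] == b) +
               sum(g[, -ncol(g)] == b & g[, -1] == a) +
               sum(g[-nrow(g), ] == a & g[-1, ] == b) +
               sum(g[-nrow(g), ] == b & g[-1, ] == a)
        expect_equal(rec$voronoi_border, cnt)
        # touching pairs are recorded as neighbours
        if (rec$touching) expect_true(back$touching)
      }
    }
    # every 8-adjacent object pair appears with touching = TRUE
    lm <- layer$label_map
    for (dr in 0:1) for (dc in -1:1) {
      if (dr == 0L && dc <= 0L) next
      nr <- nrow(lm); nc <- ncol(lm)
      r1 <- 1:(nr - dr); c1 <- max(1, 1 - dc):min(nc, nc - dc)
      a <- lm[r1, c1, drop = FALSE]; b <- lm[r1 + dr, c1 + dc, drop = FALSE]
      sel <- a > 0L & b > 0L & a != b
      if (any(sel)) {
        pairs <- unique(cbind(a[sel], b[sel]))
        for (i in seq_len(nrow(pairs))) {
          rec <- net$neighbourhoods[[as.character(pairs[i, 1])]]$
            neighbours[[as.character(pairs[i, 2])]]
          expect_true(isTRUE(rec$touching))
        }
      }
    }
  }
})
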