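square_layer <- function(n) {
  m <- matrix(0L, n + 4L, n + 4L)
  m[3:(n + 2L), 3:(n + 2L)] <- 1L
  morphometry(build_layer(m))
}

test_that("form factor matches closed forms for squares and rectangles", {
  # every n x n square: (4n)^2 / n^2 = 16 exactly
  for (n in 1:20) {
    f <- square_layer(n)$objects[[1]]$features
    expect_identical(f[["form_factor"]], 16)
    expect_identical(f[["area"]], as.numeric(n^2))
    expect_identical(f[["contour_length"]], as.numeric(4 * n))
  }
  # 1 x 4 rectangle: contour 10, area 4, form factor 25
  m <- matrix(0L, 5, 8); m[3, 2:5] <- 1L
  f <- morphometry(build_layer(m))$objects[[1]]$features
  expect_identical(f[["contour_length"]], 10)
  expect_identical(f[["form_factor"]], 25)
  # all rectangles w, h <= 12: (2(w+h))^2 / (w h)
  for (w in 1:12) for (h in 1:12) {
    m <- matrix(0L, h + 2L, w + 2L)
    m[2:(h + 1L), 2:(w + 1L)] <- 1L
    f <- morphometry(build_layer(m))$objects[[1]]$features
    expect_equal(f[["form_factor"]], (2 * (w + h))^2 / (w * h))
  }
})

test_that("digital disks converge monotonically to the rasterized constant", {
  # crack-edge perimeter of a digital disk: the form factor approaches
  # 64/pi from above as the radius grows
  ff <- vapply(c(20L, 40L, 80L), function(r) {
    mask <- disk_mask(r)
    l <- morphometry(connected_components(mask))
    f <- l$objects[[1]]$features
    # oracle values from direct counting on the same rasterization
    expect_equal(f[["contour_length"]], oracle_crack_length(mask))
    expect_equal(f[["area"]], sum(mask))
    f[["form_factor"]]
  }, numeric(1))
  expect_true(all(diff(ff) < 0))
  expect_true(all(ff > 64 / pi))
  expect_lt(ff[3] - 64 / pi, 0.35)
})

test_that("centroids and channel means equal direct averaging", {
  m <- matrix(0L, 9, 9); m[2:4, 2:4] <- 1L; m[7, 7] <- 2L
  img <- array(0, c(9, 9, 3))
  img[, , 1] <- 10; img[, , 2] <- 20; img[, , 3] <- 30
  l <- channel_intensity(morphometry(build_layer(m)), img)
  f1 <- l$objects[["1"]]$features
  expect_equal(f1[["centroid_row"]], 3)
  expect_equal(f1[["centroid_col"]], 3)
  expect_equal(f1[["mean_R"]], 10)
  expect_equal(f1[["mean_B"]], 30)
  # single-pixel object takes that pixel's values
  img[7, 7, ] <- c(1, 2, 3)
  l <- channel_intensity(l, img)
  expect_equal(l$objects[["2"]]$features[["mean_G"]], 2)

  # random image: equals an explicit loop-and-average oracle
  set.seed(42)
  layer <- random_layer(13, 20, 20, 4)
  rimg <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  l <- channel_intensity(layer, rimg)
  for (o in l$objects) {
    idx <- which(layer$label_map == o$id)
    acc <- c(0, 0, 0)
    for (i in idx) {
      r <- (i - 1) %% 20 + 1; c <- (i - 1) %/% 20 + 1
      acc <- acc + rimg[r, c, ]
    }
    expect_equal(unname(o$features[c("mean_R", "mean_G", "mean_B")]),
                 acc / length(idx), tolerance = 1e-12)
  }
  expect_error(channel_intensity(layer, array(0, c(5, 5, 3))),
               class = "objlayer_inconsistent_input")
})

test_that("stain deconvolution inverts the forward model", {
  st <- hdab_matrix()
  # white pixel: zero optical density, all concentrations clip to 0
  white <- array(255, c(1, 1, 3))
  expect_equal(unname(unlist(deconvolve(white, st))), c(0, 0, 0))

  # pure hematoxylin field at k = 0.5 round-trips
  k <- 0.5
  conc <- list(matrix(k, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4))
  back <- deconvolve(compose_stains(conc, st), st)
  expect_equal(max(abs(back$hematoxylin - k)), 0, tolerance = 1e-6)
  expect_lt(max(back$DAB), 1e-6)

  # mix-then-unmix on 1000 random concentration triples in [0,1]^3
  set.seed(99)
  cm <- matrix(runif(3000, 0, 1), 1000, 3)
  img <- compose_stains(list(matrix(cm[, 1], 1000, 1),
                             matrix(cm[, 2], 1000, 1),
                             matrix(cm[, 3], 1000, 1)), st)
  # keep only non-saturating pixels (no channel clipped at 0 intensity)
  ok <- apply(img, 1, function(px) all(px > 0 & px < 255))
  expect_gt(sum(ok), 500)
  back <- deconvolve(img, st)
  rec <- cbind(as.numeric(back$hematoxylin), as.numeric(back$DAB),
               as.numeric(back$residual))
  expect_lt(max(abs(rec[ok, ] - cm[ok, ])), 1e-6)

  # singular matrix rejected
  expect_error(stain_matrix(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
                            c("a", "b", "c")),
               class = "objlayer_invalid_stain_matrix")
})

test_that("per-object stain means respect the forward model and ordering", {
  st <- hdab_matrix()
  m <- matrix(0L, 10, 20); m[3:6, 3:6] <- 1L; m[3:6, 13:16] <- 2L
  conc_h <- matrix(0, 10, 20)
  conc_h[m == 1L] <- 0.2
  conc_h[m == 2L] <- 0.8
  img <- compose_stains(list(conc_h, matrix(0, 10, 20), matrix(0, 10, 20)), st)
  l <- stain_intensity(build_layer(m), img, st)
  f1 <- l$objects[["1"]]$features; f2 <- l$objects[["2"]]$features
  expect_equal(f1[["mean_hematoxylin"]], 0.2, tolerance = 1e-6)
  expect_equal(f2[["mean_hematoxylin"]], 0.8, tolerance = 1e-6)
  expect_lt(f1[["mean_DAB"]], 1e-6)
  expect_lt(f1[["mean_hematoxylin"]], f2[["mean_hematoxylin"]])
  # objects over white background have zero stain means
  white <- array(255, c(10, 20, 3))
  lw <- stain_intensity(build_layer(m), white, st)
  expect_equal(lw$objects[["1"]]$features[["mean_hematoxylin"]], 0)
  expect_equal(lw$objects[["1"]]$features[["mean_DAB"]], 0)
})

test_that("relational features count contact pixels and class neighbours", {
  # osteoclast square sharing a 3-pixel edge with a bone rectangle
  m <- contact_scene()
  l <- build_layer(m)
  l$objects[["1"]]$class_name <- "osteoclast"
  l$objects[["2"]]$class_name <- "bone"
  l$objects[["3"]]$class_name <- "monocyte"
  net <- build_network(l, voronoi_tessellate(l))
  l <- relational_features(l, net, c("bone", "osteoclast", "monocyte"))
  f1 <- l$objects[["1"]]$features
  expect_equal(f1[["border_to_bone"]], 3)
  expect_equal(f1[["num_touching_bone"]], 1)
  expect_gte(f1[["num_neighbouring_bone"]], 1)
  # isolated object: all touching-relational features are zero
  f3 <- l$objects[["3"]]$features
  expect_equal(f3[["border_to_bone"]], 0)
  expect_equal(f3[["num_touching_bone"]], 0)

  # random classified layers: border_to equals a per-pixel recount over all
  # contour pixels and their 8-neighbourhoods, and never exceeds the
  # contour pixel count
  for (seed in 1:6) {
    layer <- random_classified_layer(seed + 30, 28, 28, 6)
    if (length(layer$objects) < 2L) next
    net <- build_network(layer, voronoi_tessellate(layer))
    layer <- relational_features(layer, net, c("a", "b", "c"))
    lm <- layer$label_map
    class_of <- vapply(layer$objects, `[[`, character(1), "class_name")
    for (o in layer$objects) {
      pts <- o$contour$points
      for (cl in c("a", "b", "c")) {
        cnt <- 0L
        for (i in seq_len(nrow(pts))) {
          hit <- FALSE
          for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0L && dc == 0L) next
            rr <- pts[i, 1] + dr; cc <- pts[i, 2] + dc
            if (rr < 1 || rr > nrow(lm) || cc < 1 || cc > ncol(lm)) next
            nid <- lm[rr, cc]
            if (nid > 0L && nid != o$id &&
                class_of[[as.character(nid)]] == cl) hit <- TRUE
          }
          if (hit) cnt <- cnt + 1L
        }
        got <- o$features[[paste0("border_to_", cl)]]
        expect_equal(got, cnt)
        expect_lte(got, nrow(pts))
      }
    }
  }
})

test_that("feature computation is pure", {
  layer <- random_layer(77, 24, 24, 5)
  set.seed(1); img <- array(runif(24 * 24 * 3, 0, 255), c(24, 24, 3))
  a <- stain_intensity(channel_intensity(morphometry(layer), img), img)
  b <- stain_intensity(channel_intensity(morphometry(layer), img), img)
  expect_identical(lapply(a$objects, `[[`, "features"),
                   lapply(b$objects, `[[`, "features"))
  expect_identical(a$label_map, layer$label_map)
})
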