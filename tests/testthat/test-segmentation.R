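test_that("otsu threshold separates bimodal images and matches exhaustive search", {
  # two-valued image: threshold falls in [50, 200) and separates the modes
  ch <- matrix(c(rep(50, 50), rep(200, 50)), 10, 10)
  t <- otsu_threshold(ch)
  expect_gte(t, 50)
  expect_lt(t, 200)
  mask <- threshold_segment(ch, t, "above")
  expect_equal(sum(mask), 50)

  # constant image has no between-class split
  expect_error(otsu_threshold(matrix(128, 5, 5)),
               class = "objlayer_degenerate_histogram")

  # random bimodal mixtures: the returned threshold achieves the same
  # between-class variance as an exhaustive search over all 256 candidates
  between_var <- function(v, t) {
    v <- floor(v); lo <- v[v <= t]; hi <- v[v > t]
    length(lo) / length(v) * length(hi) / length(v) *
      (mean(lo) - mean(hi))^2
  }
  for (seed in 1:10) {
    set.seed(seed)
    v <- c(rnorm(300, 60, 12), rnorm(200, 190, 18))
    ch <- matrix(pmin(pmax(v, 0), 255), 25, 20)
    t_impl <- otsu_threshold(ch)
    t_oracle <- oracle_otsu(ch)
    expect_equal(between_var(ch, t_impl), between_var(ch, t_oracle),
                 tolerance = 1e-12)
  }
})

test_that("threshold_segment masks partition the image by polarity", {
  expect_false(any(threshold_segment(matrix(0, 4, 4), 10, "above")))
  expect_true(all(threshold_segment(matrix(255, 4, 4), 10, "above")))
  set.seed(3)
  ch <- matrix(runif(64, 0, 255), 8, 8)
  above <- threshold_segment(ch, 120, "above")
  below_or_equal <- !above
  expect_true(all(xor(above, below_or_equal)))
})

test_that("connected components match a flood-fill oracle", {
  # two disjoint 2x2 blocks
  m <- matrix(FALSE, 6, 6); m[1:2, 1:2] <- TRUE; m[5:6, 5:6] <- TRUE
  l <- connected_components(m)
  expect_length(l$objects, 2)
  expect_equal(unname(vapply(l$objects, `[[`, integer(1), "pixel_count")),
               c(4L, 4L))

  # a diagonal chain is one object under 8-connectivity
  d <- matrix(FALSE, 6, 6); diag(d) <- TRUE
  expect_length(connected_components(d)$objects, 1)

  # random masks: identical partition to the oracle, and validate passes
  for (seed in 1:8) {
    set.seed(seed)
    mask <- matrix(runif(48 * 48) < 0.35, 48, 48)
    l <- connected_components(mask)
    expect_equal(validate_layer(l), character(0))
    expect_equal(l$label_map, oracle_flood_fill(mask, 8L))
  }
})

test_that("remove_small filters by area, preserves ids, and is monotone", {
  m <- matrix(0L, 12, 12)
  m[1, 1:3] <- 1L                 # area 3
  m[4:10, 4:10] <- 2L             # area 49 (id preserved)
  l <- build_layer(m)
  f <- remove_small(l, 10L)
  expect_equal(names(f$objects), "2")
  expect_false(any(f$label_map == 1L))
  expect_equal(validate_layer(f), character(0))

  # min_area 1 is the identity
  expect_equal(remove_small(l, 1L)$label_map, l$label_map)

  # survivors equal an independent histogram count; monotone in min_area
  layer <- random_layer(21, 40, 40, 9)
  areas <- tabulate(layer$label_map[layer$label_map > 0L],
                    nbins = max(layer$label_map))
  prev <- length(layer$objects)
  for (cut in c(2L, 6L, 12L, 25L)) {
    surv <- length(remove_small(layer, cut)$objects)
    expect_equal(surv, sum(areas >= cut & areas > 0L))
    expect_lte(surv, prev)
    prev <- surv
  }
})

test_that("channel merging resolves conflicts by priority, not list order", {
  # one pixel bright in both blue and green: bone (priority 0) wins
  img <- array(0, c(8, 8, 3))
  img[2:4, 2:4, 3] <- 220         # blue blob
  img[3:5, 3:5, 2] <- 220         # green blob overlapping at (3:4, 3:4)
  specs <- list(channel_spec(3, "bone", 0), channel_spec(2, "osteoclast", 1))
  l1 <- merge_channel_layers(img, specs)
  cls1 <- vapply(l1$objects, `[[`, character(1), "class_name")
  overlap_id <- l1$label_map[3, 3]
  expect_equal(unname(cls1[as.character(overlap_id)]), "bone")

  # permuting the spec list changes nothing
  l2 <- merge_channel_layers(img, rev(specs))
  expect_equal(l2$label_map, l1$label_map)
  expect_equal(vapply(l2$objects, `[[`, character(1), "class_name"), cls1)

  # degenerate (constant) channel errors propagate
  specs_bad <- c(specs, list(channel_spec(1, "monocyte", 2)))
  expect_error(merge_channel_layers(img, specs_bad),
               class = "objlayer_degenerate_histogram")

  # zero-pixel image gives an empty layer
  l0 <- merge_channel_layers(array(0, c(0, 0, 3)), specs)
  expect_length(l0$objects, 0)
})

test_that("channel merging recovers the fluorescence generator ground truth", {
  fx <- gen_fluor(2, 3, 4, seed = 7)
  specs <- list(channel_spec(3, "bone", 0), channel_spec(2, "osteoclast", 1),
                channel_spec(1, "monocyte", 2))
  l <- merge_channel_layers(fx$image, specs, per_channel_min_area = 20L)
  cls <- vapply(l$objects, `[[`, character(1), "class_name")
  expect_equal(sum(cls == "bone"), 1L)
  expect_equal(sum(cls == "osteoclast"), 5L)
  expect_equal(sum(cls == "monocyte"), 4L)
  # pixel-exact geometry recovery: every recovered object coincides with one
  # ground-truth object of the same class
  for (id in names(l$objects)) {
    truth_ids <- unique(fx$truth$label_map[l$label_map == as.integer(id)])
    expect_length(truth_ids, 1)
    expect_equal(unname(fx$truth$classes[[as.character(truth_ids)]]),
                 unname(cls[[id]]))
  }
})
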