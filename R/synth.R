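## Seeded synthetic-image generators with exact ground truth. These emulate
## the two application scenarios end-to-end testably: a bright-field H-DAB
## IHC scene (white background, hematoxylin-only vs DAB-positive nuclei,
## small spindle-shaped stromal nuclei) and a three-channel fluorescence
## scene (blue bone band, green osteoclasts - some touching bone - and red
## monocytes). Shape realism is not a goal: nuclei are mildly perturbed
## ellipses so that class, count and contact recovery are exact and
## assertable.

# Rasterize a noisy ellipse; returns integer (row, col) pixel matrix.
# Radial noise: r(phi) <= 1 + amp1*sin(3 phi + p1) + amp2*sin(5 phi + p2).
raster_ellipse <- function(cr, cc, a, b, theta, amp1, amp2, p1, p2, nr, nc) {
  reach <- ceiling(max(a, b) * (1 + amp1 + amp2)) + 1L
  rows <- max(1L, cr - reach):min(nr, cr + reach)
  cols <- max(1L, cc - reach):min(nc, cc + reach)
  g <- expand.grid(row = rows, col = cols)
  dx <- g$col - cc; dy <- g$row - cr
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rad <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  lim <- 1 + amp1 * sin(3 * phi + p1) + amp2 * sin(5 * phi + p2)
  as.matrix(g[rad <= lim, c("row", "col"), drop = FALSE])
}

pix_connected <- function(pix, nr, nc) {
  if (nrow(pix) == 0L) return(FALSE)
  m <- matrix(FALSE, nr, nc)
  m[pix] <- TRUE
  max(cpp_label_components(m, 8L)) == 1L
}

new_ground_truth <- function(label_map, classes, params, touching = NULL) {
  structure(list(label_map = label_map, classes = classes,
                 touching = touching, params = params),
            class = "GroundTruth")
}

#' Synthetic H-DAB immunohistochemistry scene
#'
#' White background with three nucleus populations rendered through the
#' exact forward model of the H-DAB stain matrix ([compose_stains()]):
#' Ki67-positive tumor nuclei (hematoxylin + DAB, large ellipses),
#' Ki67-negative tumor nuclei (hematoxylin only, large ellipses) and
#' small high-eccentricity stromal nuclei (hematoxylin only). Nuclei are
#' placed without overlap (>= 3 px gaps) by seeded rejection sampling.
#' Ground-truth classes use the names the packaged Ki67 chain assigns:
#' `"Ki67+"`, `"Ki67-"`, `"normal"`.
#'
#' @param n_ki67_pos,n_ki67_neg,n_stroma nucleus counts (>= 0).
#' @param seed RNG seed; identical calls are bit-identical.
#' @param size image size `c(rows, cols)`.
#' @return list with `image` (H x W x 3, 8-bit-quantized values) and
#'   `truth` (a `GroundTruth`: label map, id -> class map, parameters).
#' @export
gen_ihc <- function(n_ki67_pos, n_ki67_neg, n_stroma, seed,
                    size = c(256L, 256L)) {
  stopifnot(n_ki67_pos >= 0, n_ki67_neg >= 0, n_stroma >= 0)
  params <- list(n_ki67_pos = n_ki67_pos, n_ki67_neg = n_ki67_neg,
                 n_stroma = n_stroma, seed = seed, size = size)
  with_seed(seed, {
    nr <- size[1L]; nc <- size[2L]
    n_total <- n_ki67_pos + n_ki67_neg + n_stroma
    kinds <- rep(c("Ki67+", "Ki67-", "normal"),
                 c(n_ki67_pos, n_ki67_neg, n_stroma))
    grid <- matrix(0L, nr, nc)
    hema <- matrix(0, nr, nc); dab <- matrix(0, nr, nc)
    centers <- matrix(numeric(0), 0L, 2L)
    radii <- numeric(0)
    for (i in seq_len(n_total)) {
      tumor <- kinds[i] != "normal"
      placed <- FALSE
      for (try in seq_len(5000L)) {
        a <- if (tumor) runif(1, 7, 9)   else runif(1, 4.5, 6)
        b <- if (tumor) runif(1, 6, 7.5) else runif(1, 1.7, 2.3)
        reach <- max(a, b) * 1.12 + 1
        cr <- sample.int(nr, 1L); cc <- sample.int(nc, 1L)
        if (cr - reach < 2 || cr + reach > nr - 1 ||
            cc - reach < 2 || cc + reach > nc - 1) next
        if (nrow(centers) &&
            any(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) <
                radii + reach + 3)) next
        pix <- raster_ellipse(cr, cc, a, b, runif(1, 0, pi),
                              0.05, 0.03, runif(1, 0, 2 * pi),
                              runif(1, 0, 2 * pi), nr, nc)
        if (nrow(pix) < 18L || !pix_connected(pix, nr, nc)) next
        grid[pix] <- i
        k_h <- runif(1, 0.45, 0.75)
        k_d <- if (kinds[i] == "Ki67+") runif(1, 0.35, 0.6) else 0
        jit <- runif(nrow(pix), -0.02, 0.02)
        hema[pix] <- k_h + jit
        if (k_d > 0) dab[pix] <- k_d + runif(nrow(pix), -0.02, 0.02)
        centers <- rbind(centers, c(cr, cc))
        radii <- c(radii, reach)
        placed <- TRUE
        break
      }
      if (!placed)
        ol_stop("density", sprintf(
          "could not place nucleus %d of %d without overlap", i, n_total))
    }
    image <- round(compose_stains(list(hema, dab, matrix(0, nr, nc))))
    classes <- stats::setNames(kinds, as.character(seq_len(n_total)))
    list(image = image,
         truth = new_ground_truth(grid, classes, params))
  })
}

#' Synthetic fluorescence bone/osteoclast/monocyte scene
#'
#' Three-channel scene on a dark noisy background: one bone band (blue
#' channel) with a wavy top edge along the image bottom, green osteoclast
#' blobs - exactly `n_osteo_touching` of them placed edge-adjacent to bone
#' and `n_osteo_free` with >= 3 px clearance - and red monocytes placed well
#' away from bone. Object pixels are bright (180-240), background pixels dim
#' (0-25), so per-channel Otsu segmentation recovers the exact geometry.
#'
#' @param n_osteo_touching,n_osteo_free,n_mono object counts (>= 0).
#' @param seed RNG seed; identical calls are bit-identical.
#' @param size image size `c(rows, cols)`.
#' @return list with `image` and `truth`; `truth$touching` is a named
#'   logical vector (by id) that is `TRUE` exactly for the bone-adjacent
#'   osteoclasts, and `truth$classes` maps ids to
#'   `"bone"`/`"osteoclast"`/`"monocyte"`.
#' @export
gen_fluor <- function(n_osteo_touching, n_osteo_free, n_mono, seed,
                      size = c(256L, 256L)) {
  stopifnot(n_osteo_touching >= 0, n_osteo_free >= 0, n_mono >= 0)
  params <- list(n_osteo_touching = n_osteo_touching,
                 n_osteo_free = n_osteo_free, n_mono = n_mono,
                 seed = seed, size = size)
  with_seed(seed, {
    nr <- size[1L]; nc <- size[2L]
    grid <- matrix(0L, nr, nc)
    # bone band: wavy top edge, occupies bone_top(c)..nr in every column
    base <- nr - round(nr * 0.22)
    phase <- runif(1, 0, 2 * pi)
    bone_top <- base + round(6 * sin(2 * pi * seq_len(nc) / nc * 2 + phase))
    for (c in seq_len(nc)) grid[bone_top[c]:nr, c] <- 1L
    classes <- c("1" = "bone")
    touching <- stats::setNames(logical(0), character(0))
    centers <- matrix(numeric(0), 0L, 2L); radii <- numeric(0)
    next_id <- 2L
    kinds <- rep(c("osteo_touch", "osteo_free", "monocyte"),
                 c(n_osteo_touching, n_osteo_free, n_mono))
    for (kind in kinds) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        a <- if (kind == "monocyte") runif(1, 4, 5.5) else runif(1, 6, 8.5)
        b <- if (kind == "monocyte") runif(1, 4, 5.5) else runif(1, 5.5, 8)
        reach <- max(a, b) * 1.1 + 1
        cc <- sample(seq.int(ceiling(reach) + 2L,
                             nc - ceiling(reach) - 2L), 1L)
        top_limit <- min(bone_top) - 1L
        cr <- if (kind == "osteo_touch") {
          top_limit - ceiling(reach) - 12L   # provisional; shifted down below
        } else if (kind == "osteo_free") {
          sample(seq.int(ceiling(reach) + 2L,
                         top_limit - ceiling(reach) - 4L), 1L)
        } else {
          sample(seq.int(ceiling(reach) + 2L,
                         top_limit - ceiling(reach) - 11L), 1L)
        }
        pix <- raster_ellipse(cr, cc, a, b, runif(1, 0, pi),
                              0.05, 0.03, runif(1, 0, 2 * pi),
                              runif(1, 0, 2 * pi), nr, nc)
        if (nrow(pix) < 30L || !pix_connected(pix, nr, nc)) next
        if (kind == "osteo_touch") {
          # shift down until some pixel is edge-adjacent to bone, none inside
          shift <- min(bone_top[pix[, 2L]] - 1L - pix[, 1L])
          pix[, 1L] <- pix[, 1L] + shift
          cr <- cr + shift
        } else if (kind == "osteo_free") {
          if (any(bone_top[pix[, 2L]] - pix[, 1L] < 4L)) next
        } else {
          if (any(bone_top[pix[, 2L]] - pix[, 1L] < 11L)) next
        }
        if (nrow(centers) &&
            any(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) <
                radii + reach + 3)) next
        if (any(grid[pix] != 0L)) next
        grid[pix] <- next_id
        cls <- if (kind == "monocyte") "monocyte" else "osteoclast"
        classes[as.character(next_id)] <- cls
        if (cls == "osteoclast")
          touching[as.character(next_id)] <- (kind == "osteo_touch")
        centers <- rbind(centers, c(cr, cc)); radii <- c(radii, reach)
        next_id <- next_id + 1L
        placed <- TRUE
        break
      }
      if (!placed)
        ol_stop("density", sprintf("could not place a %s blob", kind))
    }
    # render: dim uniform background noise, bright object pixels
    image <- array(0, dim = c(nr, nc, 3L))
    for (k in 1:3) image[, , k] <- sample(0:25, nr * nc, replace = TRUE)
    chan_of <- c(bone = 3L, osteoclast = 2L, monocyte = 1L)
    for (id in names(classes)) {
      idx <- which(grid == as.integer(id))
      k <- chan_of[[classes[[id]]]]
      ch <- image[, , k]
      ch[idx] <- sample(180:240, length(idx), replace = TRUE)
      image[, , k] <- ch
    }
    list(image = image,
         truth = new_ground_truth(grid, classes, params, touching))
  })
}
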