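test_that("size classes use half-open, lower-inclusive intervals", {
  expect_equal(classify_size(7.63), "isolated")       # 2 px
  expect_equal(classify_size(3.815), "isolated")      # 1 px
  expect_equal(classify_size(10), "non_activated")    # boundary joins upper
  expect_equal(classify_size(49.9), "non_activated")
  expect_equal(classify_size(50), "activated")
  expect_equal(classify_size(249.9), "activated")
  expect_equal(classify_size(250), "complex")
  expect_equal(classify_size(251), "complex")
  expect_error(classify_size(0), "positive")
  expect_error(classify_size(-5), "positive")
})

test_that("background suppression keeps exactly the bright pixels", {
  fr <- matrix(0.05, 60, 80)
  fr[10, 20] <- fr[10, 21] <- fr[11, 20] <- 0.9
  mask <- matrix(TRUE, 60, 80)
  bin <- suppress_background(fr, mask, k_sigma = 6)
  expect_equal(sum(bin), 3)
  expect_true(all(bin[cbind(c(10, 10, 11), c(20, 21, 20))]))
  # constant masked region -> all false, not an error
  expect_false(any(suppress_background(matrix(0.05, 60, 80), mask, 6)))
})

test_that("pure speckle yields under 0.1% foreground at k_sigma 6", {
  fracs <- vapply(1:10, function(s) {
    set.seed(s)
    fr <- matrix(0.08 * rgamma(200 * 300, 4, 4), 200, 300)
    mean(suppress_background(fr, matrix(TRUE, 200, 300), 6))
  }, numeric(1))
  expect_true(all(fracs < 0.001))
})

test_that("detection measures areas in pixels and physical units", {
  bin <- matrix(FALSE, 30, 40)
  bin[5:6, 5:6] <- TRUE
  bin[20:21, 30:31] <- TRUE
  fr <- matrix(0.5, 30, 40)
  recs <- detect_opacities(bin, fr)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$area_px, c(4L, 4L))
  expect_equal(recs$area_um2, c(15.26, 15.26))
  expect_equal(recs$mean_intensity, c(0.5, 0.5))

  # single pixel: smallest isolated cell
  bin1 <- matrix(FALSE, 10, 10); bin1[4, 7] <- TRUE
  r1 <- detect_opacities(bin1, matrix(0.9, 10, 10), min_area_px = 1)
  expect_equal(r1$area_um2, 3.815)
  expect_equal(r1$size_class, "isolated")
  expect_equal(r1$eccentricity, 0)
  expect_equal(r1$orientation_deg, 0)
})

test_that("connectivity controls whether diagonal pixels join", {
  bin <- matrix(FALSE, 10, 10)
  bin[3, 3] <- bin[4, 4] <- TRUE
  fr <- matrix(1, 10, 10)
  expect_equal(nrow(detect_opacities(bin, fr, connectivity = 8)), 1)
  expect_equal(nrow(detect_opacities(bin, fr, connectivity = 4)), 2)
})

test_that("shape descriptors match their analytic values", {
  # filled disc: rounded, eccentricity near 0
  disc <- raster_ellipse(15.5, 15.5, 8, 8, 0, 30, 30)
  expect_lte(shape_features(disc)$eccentricity, 0.05)

  # horizontal 1 x 20 line: degenerate ellipse
  line <- cbind(rep(5L, 20), 1:20)
  sf <- shape_features(line)
  expect_gte(sf$eccentricity, 0.99)
  expect_equal(sf$orientation_deg, 0)
  # vertical line maps to the upper end of (-90, 90]
  expect_equal(shape_features(cbind(1:20, rep(5L, 20)))$orientation_deg, 90)

  # filled 20 x 10 ellipse rotated 30 degrees: ecc sqrt(3)/2, angle 30
  ell <- raster_ellipse(30.5, 30.5, 10, 5, 30, 60, 60)
  sf <- shape_features(ell)
  expect_equal(sf$eccentricity, sqrt(3) / 2, tolerance = 0.02 / sf$eccentricity)
  expect_equal(sf$orientation_deg, 30, tolerance = 2 / 30)
})

test_that("orientation is rotation-equivariant for elongated blobs", {
  for (th in c(-60, -30, 0, 15, 45, 75)) {
    px <- raster_ellipse(40.5, 40.5, 12, 12 * sqrt(1 - 0.9^2), th, 80, 80)
    got <- shape_features(px)$orientation_deg
    d <- ((got - th + 90) %% 180) - 90
    expect_lt(abs(d), 2)
  }
})

test_that("eccentricity is invariant to translation and intensity scale", {
  px <- raster_ellipse(20.5, 20.5, 8, 4, 20, 40, 40)
  e0 <- shape_features(px)$eccentricity
  expect_equal(shape_features(px + 37L)$eccentricity, e0)
  # intensity plays no role in binary shape moments: same pixel set from
  # a rescaled frame must give the same features
  bin <- matrix(FALSE, 40, 40); bin[px] <- TRUE
  r1 <- detect_opacities(bin, matrix(0.2, 40, 40))
  r2 <- detect_opacities(bin, matrix(0.9, 40, 40))
  expect_equal(r1$eccentricity, r2$eccentricity)
  expect_equal(r1$orientation_deg, r2$orientation_deg)
})

test_that("labelling and moments match brute force on exhaustive patches", {
  # every 3x3 binary patch, both connectivities
  for (code in 0:511) {
    mask <- matrix(as.logical(bitwAnd(code, 2^(0:8))), 3, 3)
    for (conn in c(4, 8)) {
      got <- label_components(mask, conn)
      ref <- flood_fill_label(mask, conn)
      expect_equal(max(got), max(ref))
      # identical partitions (labels may differ only by renaming)
      if (max(ref) > 0)
        for (l in seq_len(max(ref))) {
          cells <- which(ref == l)
          expect_equal(length(unique(got[cells])), 1L)
        }
    }
  }
})

test_that("labelling and moments match brute force on random 20x20 patches", {
  set.seed(404)
  for (i in 1:40) {
    p <- runif(1, 0.05, 0.6)
    mask <- matrix(runif(400) < p, 20, 20)
    conn <- sample(c(4, 8), 1)
    got <- label_components(mask, conn)
    ref <- flood_fill_label(mask, conn)
    expect_equal(max(got), max(ref))
    if (max(ref) == 0) next
    for (l in seq_len(max(ref))) {
      cells <- which(ref == l)
      expect_equal(length(unique(got[cells])), 1L)
      px <- cbind(((cells - 1) %% 20) + 1, ((cells - 1) %/% 20) + 1)
      sf <- shape_features(px)
      or <- moments_oracle(px)
      expect_equal(sf$eccentricity, or$eccentricity, tolerance = 1e-10)
      if (or$eccentricity > 1e-6) {
        d <- ((sf$orientation_deg - or$orientation_deg + 90) %% 180) - 90
        expect_lt(abs(d), 1e-6)
      }
    }
  }
})

test_that("per-eye summaries aggregate counts, areas and percentages", {
  mk <- function(f, area, ecc = 0.5, int = 0.5, or = 10) {
    px <- max(1L, as.integer(round(area / 3.815)))
    tibble::tibble(
      frame_index = f, centroid_row = 1, centroid_col = 1,
      area_px = px, area_um2 = px * 3.815,
      mean_intensity = int, eccentricity = ecc, orientation_deg = or,
      size_class = classify_size(px * 3.815), pixels = list(cbind(1L, 1L)))
  }
  # 3 frames with 10, 20, 30 opacities
  recs <- do.call(rbind, lapply(1:3, function(f)
    do.call(rbind, replicate(f * 10, mk(f, 30), simplify = FALSE))))
  s <- summarise_eye(recs, n_frames = 3)
  expect_equal(s$mean_n_opacities, 20)

  # one opacity per class -> 25% each
  recs4 <- rbind(mk(1, 5), mk(1, 30), mk(1, 150), mk(1, 500))
  s4 <- summarise_eye(recs4, n_frames = 1)
  expect_equal(unname(s4$class_percent), rep(25, 4))
  expect_equal(sum(s4$class_percent), 100)
  expect_equal(s4$total_area_um2, (1 + 8 + 39 + 131) * 3.815)
  # total area is an integer number of pixels
  expect_equal(s4$total_area_um2 / 3.815,
               round(s4$total_area_um2 / 3.815), tolerance = 1e-9)

  # signed orientations cancel in the class mean
  recs_or <- rbind(mk(1, 30, or = 40), mk(1, 30, or = -40))
  expect_equal(unname(summarise_eye(recs_or, 1)$mean_orientation_deg[
    "non_activated"]), 0)

  # zero opacities: zero aggregates, flagged
  s0 <- summarise_eye(recs[0, ], n_frames = 5)
  expect_true(s0$no_opacities)
  expect_equal(s0$total_area_um2, 0)
  expect_equal(unname(s0$class_percent), rep(0, 4))
})

test_that("summary flattens to a single wide row for export", {
  ph <- generate_phantom(small_phantom(
    9, n_frames = 2, n_per_class = c(activated = 4)))
  segs <- lapply(1:2, function(f) oracle_seg(ph$truth, f))
  recs <- do.call(rbind, lapply(1:2, function(f) {
    fr <- ph$stack$frames[[f]]
    detect_opacities(suppress_background(fr, vitreous_mask(segs[[f]])), fr,
                     frame_index = f, min_area_px = 2)
  }))
  s <- summarise_eye(recs, 2, vit_rpe = eye_vit_rpe(ph$stack, segs),
                     eye_meta = list(animal = "r1", cohort = "MsDx",
                                     eye = "RE", week = 4))
  df <- as.data.frame(s)
  expect_equal(nrow(df), 1)
  expect_true(all(c("animal", "cohort", "week", "vit_rpe", "pct_activated",
                    "mean_ecc_activated") %in% names(df)))
  expect_equal(df$cohort, "MsDx")
})
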