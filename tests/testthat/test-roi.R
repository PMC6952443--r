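# ROI segmentation, compartment classification, trace extraction.

make_disk_stack <- function(n = 64, nt = 10, centers, radius = 6,
                            bright = 150, bg = 20, frames_on = NULL) {
  img <- matrix(bg, n, n)
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  masks <- list()
  for (k in seq_along(centers)) {
    m <- (yy - centers[[k]][1])^2 + (xx - centers[[k]][2])^2 <= radius^2
    masks[[k]] <- m
  }
  stack <- array(bg, c(n, n, nt))
  for (t in seq_len(nt)) {
    fr <- img
    for (k in seq_along(masks)) {
      on <- is.null(frames_on) || t %in% frames_on[[k]]
      if (on) fr[masks[[k]]] <- bright
    }
    stack[, , t] <- fr
  }
  list(stack = stack, masks = masks)
}

test_that("uniform stacks segment to zero ROIs without error", {
  stack <- array(50, c(32, 32, 5))
  rs <- segment_rois(stack)
  expect_equal(nrow(rs$rois), 0)
  expect_true(all(rs$label_image == 0))
  expect_error(segment_rois(array(1, c(8, 8, 1))), "frames")
})

test_that("planted bright disks are recovered with IoU >= 0.7", {
  d <- make_disk_stack(64, 10, list(c(16, 16), c(44, 40), c(20, 50)))
  rs <- segment_rois(d$stack)
  expect_equal(nrow(rs$rois), 3)
  for (m in d$masks) {
    lbl <- unique(rs$label_image[m]); lbl <- lbl[lbl > 0]
    expect_length(lbl, 1)
    dm <- rs$label_image == lbl
    expect_gte(sum(m & dm) / sum(m | dm), 0.7)
  }
})

test_that("the >50% persistence rule keeps 60% and drops 40% regions", {
  d <- make_disk_stack(64, 10, list(c(16, 16), c(44, 44)),
                       frames_on = list(1:6, 1:4))   # 60% vs 40% of frames
  rs <- segment_rois(d$stack)
  in1 <- unique(rs$label_image[d$masks[[1]]])
  in2 <- unique(rs$label_image[d$masks[[2]]])
  expect_true(any(in1 > 0))
  expect_true(all(in2 == 0))
  # exactly-50% persistence is background (strict rule)
  d5 <- make_disk_stack(64, 10, list(c(32, 32)), frames_on = list(1:5))
  rs5 <- segment_rois(d5$stack)
  expect_true(all(rs5$label_image[d5$masks[[1]]] == 0))
})

test_that("segmentation is invariant to affine intensity rescaling", {
  d <- make_disk_stack(48, 6, list(c(14, 14), c(34, 30)))
  p1 <- segmentation_params(contrast_floor = 10)
  rs1 <- segment_rois(d$stack, p1)
  a <- 3.2; b <- 40
  p2 <- segmentation_params(contrast_floor = 10 * a)
  rs2 <- segment_rois(d$stack * a + b, p2)
  expect_identical(rs1$label_image, rs2$label_image)
})

test_that("parameter validation names the offending field", {
  expect_error(segmentation_params(block_size = 10), "odd")
  expect_error(segmentation_params(persistence_fraction = 1), "persistence")
  expect_error(segmentation_params(connectivity = 6), "connectivity")
})

test_that("compartment classes match generator labels", {
  sim <- generate_movie(movie_params(height = 128, width = 128,
                                     n_frames = 60, noise_sd = 5,
                                     rigid_shift_amplitude = 0,
                                     nonrigid_amplitude = 0, seed = 9))
  tr <- sim$truth
  rs <- segment_rois(sim$movie$structural)
  rs <- classify_compartments(rs, vessel_map = tr$vessel_mask)
  agree <- 0; total <- 0
  for (j in seq_len(nrow(rs$rois))) {
    dm <- rs$label_image == rs$rois$label[j]
    tl <- tr$labels[dm]; tl <- tl[tl > 0]
    if (length(tl) == 0) next
    truth_class <- tr$classes[as.integer(names(which.max(table(tl))))]
    total <- total + 1
    agree <- agree + (truth_class == rs$rois$class[j])
  }
  expect_gte(total, 10)
  expect_gte(agree / total, 0.9)
  # no vessel map: endfoot class unavailable, message emitted
  expect_message(rs0 <- classify_compartments(segment_rois(sim$movie$structural)),
                 "vessel")
  expect_false("endfoot" %in% rs0$rois$class)
})

test_that("ROI labels partition the foreground", {
  sim <- cached_movie()
  rs <- segment_rois(sim$movie$structural)
  lab <- rs$label_image
  # every labeled pixel belongs to exactly one ROI by construction of a
  # label image; check labels are 1..n and contiguous under connectivity 8
  expect_setequal(setdiff(unique(as.vector(lab)), 0), rs$rois$label)
  for (l in rs$rois$label)
    expect_equal(max(astroca:::label_components(lab == l, 8)), 1)
})

test_that("trace extraction is exact for single pixels and separates ROIs", {
  nt <- 50
  stack <- array(0, c(16, 16, nt))
  lab <- matrix(0L, 16, 16)
  lab[4, 4] <- 1L; lab[12, 10:12] <- 2L
  t1 <- sin(seq_len(nt) / 3); t2 <- cos(seq_len(nt) / 5)
  stack[4, 4, ] <- t1
  for (c in 10:12) stack[12, c, ] <- t2
  rois <- list(label_image = lab,
               rois = data.frame(label = 1:2, class = NA, area = c(1, 3),
                                 centroid_y = 0, centroid_x = 0))
  tr <- extract_traces(stack, rois)
  expect_equal(tr[, 1], t1)
  expect_equal(tr[, 2], t2)
  expect_gt(cor(tr[, 1], t1), 0.99)
  expect_lt(abs(cor(tr[, 1], t2)), 0.3)
  # all-zero movie gives all-zero traces
  tr0 <- extract_traces(array(0, c(16, 16, nt)), rois)
  expect_true(all(tr0 == 0))
})

test_that("bulk traces report dF/F0 against the pre-stimulus window", {
  nt <- 60
  stack <- array(100, c(20, 20, nt))
  mask <- matrix(FALSE, 20, 20); mask[5:10, 5:10] <- TRUE
  expect_true(all(bulk_trace(stack, mask, 1:20) == 0))
  # +10% step inside the mask from frame 31
  stack2 <- stack
  stack2[5:10, 5:10, 31:60] <- 110
  tr <- bulk_trace(stack2, mask, 1:20)
  expect_equal(tr[45], 0.10, tolerance = 0.01)
  # half-covering mask sees ~half the amplitude
  mask_half <- matrix(FALSE, 20, 20); mask_half[5:10, 5:13] <- TRUE
  frac <- sum(mask_half & mask) / sum(mask_half)
  tr2 <- bulk_trace(stack2, mask_half, 1:20)
  expect_equal(tr2[45], 0.10 * frac * 100 / (100), tolerance = 0.01)
  expect_error(bulk_trace(stack, mask, integer(0)), "pre")
  expect_error(bulk_trace(stack, matrix(FALSE, 20, 20), 1:5), "mask")
})
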