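test_that("illumination correction removes a linear gradient", {
  n <- 256
  grad <- outer(seq(0, 60, length.out = n), seq(0, 40, length.out = n), `+`) + 200
  corr <- correct_illumination(grad)
  expect_lt(stats::sd(corr), 1.5)        # flat after correction
  flat <- matrix(500, n, n)
  expect_true(all(abs(correct_illumination(flat)) < 1e-6))
})

test_that("viability rule uses strict inequalities on both conditions", {
  # craft a label image with four nuclei hitting each side of both thresholds
  lab <- matrix(0L, 220, 220)
  dna <- matrix(0, 220, 220)
  put <- function(lab, dna, r0, c0, npx, val, L) {
    side <- ceiling(sqrt(npx))
    idx <- cbind(rep(r0:(r0 + side - 1), each = side),
                 rep(c0:(c0 + side - 1), side))[seq_len(npx), , drop = FALSE]
    lab[idx] <- L; dna[idx] <- val
    list(lab = lab, dna = dna)
  }
  s <- put(lab, dna, 2, 2, 2001, 1499, 1L)      # above area, below int -> living
  s <- put(s$lab, s$dna, 2, 110, 2000, 100, 2L) # area == threshold -> not living
  s <- put(s$lab, s$dna, 110, 2, 2001, 1500, 3L) # intensity == threshold -> not
  s <- put(s$lab, s$dna, 110, 110, 300, 4000, 4L) # small + bright -> apoptotic
  v <- classify_viability(s$lab, s$dna)
  expect_equal(v$table$living, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(v$n_living, 1L)
})

test_that("segmentation recovers the ground-truth viability split", {
  gt <- fix_field()$ground_truth
  seg <- fix_seg()
  expect_equal(seg$viability$n_living, sum(gt$viable))
  expect_equal(nrow(seg$viability$table), nrow(gt))
})

test_that("compartment algebra is exact: cytoplasm = cell minus nucleus", {
  seg <- fix_seg()
  for (L in setdiff(unique(as.vector(seg$cell)), 0L)) {
    cellL <- seg$cell == L
    nucL <- seg$nucleus == L
    cytoL <- seg$cytoplasm == L
    expect_identical(cytoL, cellL & !nucL)
  }
  # no cytoplasm pixel is a nucleus pixel of the same label
  expect_false(any(seg$cytoplasm > 0 & seg$cytoplasm == seg$nucleus))
})

test_that("membrane is the 5-px inner rim: cell minus its erosion", {
  seg <- fix_seg()
  w <- default_config()$membrane_width_px
  brush <- EBImage::makeBrush(2L * w + 1L, shape = "diamond")
  for (L in setdiff(unique(as.vector(seg$cell)), 0L)) {
    cellL <- seg$cell == L
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(cellL * 1), brush)) > 0
    expect_identical(unname(seg$membrane == L), unname(cellL & !er))
  }
})

test_that("membrane width matches an independent distance-transform oracle", {
  # city-block erosion radius w <=> pixels with L1 distance to the outside <= w
  seg <- fix_seg()
  w <- default_config()$membrane_width_px
  n <- nrow(seg$cell)
  ids <- setdiff(unique(as.vector(seg$cell)), 0L)
  # border-touching cells have ambiguous outside, use an interior cell
  interior <- Filter(function(L) {
    px <- which(seg$cell == L, arr.ind = TRUE)
    all(px > 1 & px < n)
  }, ids)
  L <- (if (length(interior)) interior else ids)[[1]]
  cellL <- seg$cell == L
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(cellL * 1),
                                            metric = "manhattan"))
  oracle <- cellL & dm <= w
  expect_identical(unname(seg$membrane == L), unname(oracle))
})

test_that("thinning reduces a thick line to a unit-width skeleton", {
  m <- matrix(0L, 60, 60)
  m[20:24, 10:50] <- 1L   # 5-px-thick horizontal bar
  sk <- edcprofiler:::skeletonize(m)
  # unit width: no 2x2 block is fully skeleton
  blocks <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -ncol(sk)]
  expect_false(any(blocks))
  # the skeleton still spans the bar interior (ends may recede by the
  # bar half-width) and lies within the bar
  expect_true(all(colSums(sk[, 13:47]) >= 1))
  expect_true(all(m[sk] == 1L))
})

test_that("skeleton length of a straight bar matches its geometry", {
  cfg <- default_config()
  m <- matrix(0, 80, 80)
  m[40:42, 10:70] <- 5000    # bright 3-px bar on black
  res <- extract_neurites(m, matrix(1L, 80, 80), threshold = 1000,
                          soma_radius = 8L, pixel_pitch_um = 1, prune_px = 0L)
  # a 61-px bar thins to ~60 unit steps
  expect_gt(res$total_length_um, 50)
  expect_lt(res$total_length_um, 62)
  expect_equal(res$total_branches, 0L)
})

test_that("a Y-shaped neurite yields one branch point", {
  m <- matrix(0, 100, 100)
  m[50, 10:60] <- 5000
  for (k in 1:30) { m[50 - k, 60 + round(k * 0.7)] <- 5000
                    m[50 + k, 60 + round(k * 0.7)] <- 5000 }
  m <- EBImage::imageData(EBImage::dilate(EBImage::Image((m > 0) * 1),
                                          EBImage::makeBrush(3, "box"))) * 5000
  res <- extract_neurites(m, matrix(1L, 100, 100), threshold = 1000,
                          soma_radius = 2L, pixel_pitch_um = 1, prune_px = 2L)
  expect_equal(res$total_branches, 1L)
})

test_that("spur pruning removes short endpoint twigs only", {
  sk <- matrix(FALSE, 30, 30)
  sk[15, 5:25] <- TRUE
  sk[11:14, 10] <- TRUE       # 4-px spur hanging off the trunk
  pruned <- edcprofiler:::prune_spurs(sk, 3L)
  # three endpoint-peeling passes strip the outer three spur pixels
  expect_false(any(pruned[11:13, 10]))
  expect_true(all(pruned[15, 8:22]))   # trunk interior survives
  # endpoints of the trunk itself recede by at most the pruning depth
  expect_true(sum(pruned) >= sum(sk) - 3 * 2 - 3)
})

test_that("sparse-field neurite length recovers ground truth within 15%", {
  fld <- fix_sparse_field()
  seg <- segment_field(fld$channels, default_config())
  gt_len <- sum(fld$ground_truth$neurite_length_px[fld$ground_truth$viable])
  if (gt_len > 0) {
    meas <- seg$neurites$total_length_um / default_config()$pixel_pitch_um
    expect_gt(meas / gt_len, 0.85)
    expect_lt(meas / gt_len, 1.15)
  } else succeed("fixture drew zero neurite length")
})

test_that("segment_field validates its channel inputs", {
  expect_error(segment_field(list(dna = matrix(0, 4, 4))), "lacks channels")
})

test_that("empty images yield empty segmentations, not errors", {
  z <- matrix(0, 128, 128)
  expect_true(all(segment_nuclei(z, threshold = 350) == 0L))
  v <- classify_viability(matrix(0L, 8, 8), matrix(0, 8, 8))
  expect_equal(v$n_living, 0L)
  res <- extract_neurites(z, matrix(0L, 128, 128), threshold = 1000)
  expect_equal(res$total_length_um, 0)
})
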