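#' Illumination correction by background-surface subtraction
#'
#' Estimates the large-scale background of one channel from a coarse grid of
#' block low-quantiles, fits a quadratic intensity surface (with one robust
#' re-fit that drops gross outlier blocks, i.e. blocks fully covered by
#' cells) and subtracts it, clamping at zero. A constant image is returned
#' shifted to zero (unchanged up to an additive constant); a pure linear or
#' quadratic gradient is removed; the operation is idempotent within noise
#' on already-flat images.
#'
#' @param img numeric matrix of intensities.
#' @param block block edge in px for background sampling.
#' @param q low quantile per block taken as the local background level.
#' @return corrected non-negative matrix.
#' @export
correct_illumination <- function(img, block = 32L, q = 0.05) {
  n <- nrow(img); m <- ncol(img)
  if (n < 2L * block || m < 2L * block) {
    bg <- stats::quantile(img, q, names = FALSE)
    return(pmax(img - bg, 0))
  }
  nb_r <- n %/% block; nb_c <- m %/% block
  a <- array(img[seq_len(nb_r * block), seq_len(nb_c * block)],
             c(block, nb_r, block, nb_c))
  k <- max(1L, as.integer(round(q * (block * block - 1) + 1)))
  z <- apply(a, c(2, 4), function(v) sort(v, partial = k)[k])
  dat <- data.frame(z = as.vector(z),
                    x = rep((seq_len(nb_r) - 0.5) * block, times = nb_c),
                    y = rep((seq_len(nb_c) - 0.5) * block, each = nb_r))
  fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = dat)
  res <- stats::residuals(fit)
  keep <- abs(res) <= 2.5 * stats::mad(res) + 1e-9
  if (sum(keep) >= 8 && any(!keep))
    fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = dat[keep, ])
  co <- stats::coef(fit)
  x <- seq_len(n); y <- seq_len(m)
  rx <- co[1] + co["x"] * x + co["I(x^2)"] * x^2
  ry <- co["y"] * y + co["I(y^2)"] * y^2
  bg <- outer(rx, ry, `+`) + co["I(x * y)"] * outer(x, y)
  pmax(img - bg, 0)
}

# resolve a threshold policy ("otsu" or a number) for one channel
resolve_threshold <- function(img, policy) {
  if (is.numeric(policy)) return(policy)
  if (identical(policy, "otsu")) {
    rng <- range(img)
    if (diff(rng) < 1e-9) return(rng[2] + 1)  # empty foreground on flat image
    return(EBImage::otsu(EBImage::Image(img / 65535), range = c(0, 1)) * 65535)
  }
  stop("unknown threshold policy: ", policy)
}

#' Segment nuclei from the DNA channel
#'
#' Thresholds the (illumination-corrected) DNA channel — fixed value or
#' per-image Otsu — labels connected components and splits touching nuclei
#' by a watershed on the distance transform. Components below
#' `min_area` px are discarded as debris.
#'
#' @param dna numeric matrix (corrected DNA channel).
#' @param threshold `"otsu"` or a fixed numeric intensity.
#' @param min_area minimum component area in px.
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(dna, threshold = "otsu", min_area = 80) {
  th <- resolve_threshold(dna, threshold)
  mask <- dna > th
  if (!any(mask)) return(matrix(0L, nrow(dna), ncol(dna)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = 3, ext = 1)
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel(lab)
}

# compact labels to 1..K preserving order
relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(match(lab, u, nomatch = 0L), nrow(lab), ncol(lab))
  out[lab == 0] <- 0L
  storage.mode(out) <- "integer"
  out
}

#' Viability call per nucleus
#'
#' A nucleus is a living cell iff its area is strictly larger than
#' `min_area_px` AND its mean DNA intensity is strictly lower than
#' `max_mean_intensity`; smaller, brighter (pyknotic) nuclei are classed as
#' apoptotic. A pure function of (area, mean intensity).
#'
#' @param nuc_labels nucleus label matrix.
#' @param dna DNA channel matrix (same scale the thresholds refer to).
#' @param min_area_px area threshold in px (default 2000).
#' @param max_mean_intensity mean-intensity threshold (default 1500).
#' @return list with `table` (label, area_px, mean_intensity, living) and
#'   `n_living`.
#' @export
classify_viability <- function(nuc_labels, dna,
                               min_area_px = 2000,
                               max_mean_intensity = 1500) {
  labs <- nuc_labels[nuc_labels > 0]
  if (!length(labs))
    return(list(table = data.frame(label = integer(0), area_px = numeric(0),
                                   mean_intensity = numeric(0), living = logical(0)),
                n_living = 0L))
  k <- max(labs)
  area <- tabulate(labs, nbins = k)
  tot <- rowsum(as.numeric(dna[nuc_labels > 0]), labs)
  mean_int <- as.numeric(tot) / area[sort(unique(labs))]
  lab_ids <- sort(unique(labs))
  tab <- data.frame(label = lab_ids, area_px = area[lab_ids],
                    mean_intensity = mean_int)
  tab$living <- tab$area_px > min_area_px & tab$mean_intensity < max_mean_intensity
  list(table = tab, n_living = sum(tab$living))
}

#' Segment cells from the MAP2 channel
#'
#' The cell compartment is the MAP2-positive area, partitioned among living
#' nuclei by seeded propagation (geodesic Voronoi) from the nucleus labels.
#' MAP2-positive pixels farther than `max_dist` px from every living nucleus
#' remain background; MAP2 regions containing no living nucleus are dropped.
#' Each living nucleus yields exactly one cell label (the nucleus itself is
#' always part of its cell); apoptotic nuclei yield no cell.
#'
#' @param map2 corrected MAP2 channel matrix.
#' @param nuc_labels nucleus labels.
#' @param living logical vector or label IDs: which nucleus labels are living.
#' @param threshold `"otsu"` or fixed numeric.
#' @param max_dist maximum distance (px) from a living nucleus.
#' @return integer cell label matrix, labels matching nucleus labels.
#' @export
segment_cells <- function(map2, nuc_labels, living, threshold = "otsu",
                          max_dist = 120) {
  living_ids <- if (is.logical(living)) which(living) else as.integer(living)
  seeds <- nuc_labels
  seeds[!(seeds %in% living_ids)] <- 0L
  if (!any(seeds > 0))
    return(matrix(0L, nrow(map2), ncol(map2)))
  th <- resolve_threshold(map2, threshold)
  mask <- map2 > th | seeds > 0
  # distance to the nearest seed pixel caps how far a cell can reach
  dist_to_seed <- EBImage::distmap(EBImage::Image((seeds == 0) * 1))
  mask[EBImage::imageData(dist_to_seed) > max_dist] <- FALSE
  lab <- EBImage::propagate(EBImage::Image(map2 / 65535),
                            EBImage::Image(seeds), mask = mask, lambda = 1e-4)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  lab[seeds > 0] <- seeds[seeds > 0]
  lab
}

#' Derive cytoplasm and membrane compartments
#'
#' For each cell label L: cytoplasm(L) = cell(L) minus nucleus(L);
#' membrane(L) = cell(L) minus the erosion of cell(L) by a city-block ball
#' of radius `width` (a `width`-pixel window inside the cell edge). Labels
#' are carried through one-to-one.
#'
#' @param cell_labels cell label matrix.
#' @param nuc_labels nucleus label matrix (same label IDs).
#' @param width membrane rim width in px (default 5).
#' @return list with `cytoplasm` and `membrane` integer label matrices.
#' @export
derive_compartments <- function(cell_labels, nuc_labels, width = 5L) {
  cyto <- cell_labels
  cyto[nuc_labels > 0 & nuc_labels == cell_labels] <- 0L
  mem <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  brush <- EBImage::makeBrush(2L * as.integer(width) + 1L, shape = "diamond")
  for (L in setdiff(unique(as.vector(cell_labels)), 0L)) {
    px <- which(cell_labels == L, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1]) - 1L); r1 <- min(nrow(cell_labels), max(px[, 1]) + 1L)
    c0 <- max(1L, min(px[, 2]) - 1L); c1 <- min(ncol(cell_labels), max(px[, 2]) + 1L)
    crop <- cell_labels[r0:r1, c0:c1] == L
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(crop * 1), brush)) > 0
    rim <- crop & !er
    sub <- mem[r0:r1, c0:c1]
    sub[rim] <- L
    mem[r0:r1, c0:c1] <- sub
  }
  list(cytoplasm = cyto, membrane = mem)
}

# Zhang-Suen topology-preserving thinning of a binary matrix (compiled)
skeletonize <- function(mask) {
  out <- zhang_suen_thin(mask * 1L)
  out > 0L
}

# count of 8-neighbours within the skeleton, per pixel
skel_neighbor_count <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sk * 1L
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  acc
}

# remove up to `steps` layers of endpoint pixels (spur pruning)
prune_spurs <- function(sk, steps = 3L) {
  for (i in seq_len(steps)) {
    nb <- skel_neighbor_count(sk)
    ends <- sk & nb <= 1
    if (!any(ends)) break
    sk[ends] <- FALSE
  }
  sk
}

#' Extract the neurite skeleton and per-cell morphometry
#'
#' The neurite mask is the MAP2 foreground minus the soma cores (a
#' morphological opening of the MAP2 mask with a disc of radius
#' `soma_radius` px retains the thick somata; the remainder is neurite).
#' The mask is thinned to a 1-px skeleton; length sums inter-pixel steps
#' (1 for 4-neighbours, sqrt(2) for diagonals) times the pixel pitch; branch
#' points are skeleton pixels with >= 3 skeleton neighbours after spur
#' pruning, adjacent branch pixels counted once. Skeleton pixels are
#' attributed to cells through the cell label they lie on.
#'
#' @param map2 corrected MAP2 channel.
#' @param cell_labels cell label matrix (covers neurites).
#' @param threshold `"otsu"` or fixed numeric for the MAP2 foreground.
#' @param soma_radius disc radius (px) of the soma opening.
#' @param pixel_pitch_um physical pixel size.
#' @param prune_px spur-pruning depth in px.
#' @return list with `skeleton` (logical matrix), `per_cell` (label,
#'   neurite_length_um, branch_points), `total_length_um`, `total_branches`.
#' @export
extract_neurites <- function(map2, cell_labels, threshold = "otsu",
                             soma_radius = 8L, pixel_pitch_um = 0.1628,
                             prune_px = 3L) {
  th <- resolve_threshold(map2, threshold)
  mask <- map2 > th
  empty <- list(skeleton = matrix(FALSE, nrow(map2), ncol(map2)),
                per_cell = data.frame(label = integer(0),
                                      neurite_length_um = numeric(0),
                                      branch_points = integer(0)),
                total_length_um = 0, total_branches = 0L)
  if (!any(mask)) return(empty)
  brush <- EBImage::makeBrush(2L * as.integer(soma_radius) + 1L, shape = "disc")
  soma <- EBImage::imageData(EBImage::opening(EBImage::Image(mask * 1), brush)) > 0
  # pad the soma cores so boundary slivers of the opening do not masquerade
  # as neurite fragments
  if (any(soma))
    soma <- EBImage::imageData(EBImage::dilate(EBImage::Image(soma * 1),
                                               EBImage::makeBrush(9, "disc"))) > 0
  neur <- mask & !soma
  if (!any(neur)) return(empty)
  sk <- prune_spurs(skeletonize(neur), prune_px)
  if (!any(sk)) return(empty)

  nr <- nrow(sk); nc <- ncol(sk)
  lab_on_sk <- cell_labels * sk
  # edge counts per cell label for the four unique neighbour offsets
  edge_len <- function(dr, dc) {
    a_rs <- 1:(nr - abs(dr)); a_cs <- 1:(nc - abs(dc))
    b_rs <- a_rs + abs(dr)
    b_cs <- if (dc >= 0) a_cs + dc else a_cs
    a_cs2 <- if (dc >= 0) a_cs else a_cs - dc
    A <- sk[a_rs, a_cs2, drop = FALSE]; B <- sk[b_rs, b_cs, drop = FALSE]
    LA <- lab_on_sk[a_rs, a_cs2, drop = FALSE]; LB <- lab_on_sk[b_rs, b_cs, drop = FALSE]
    both <- A & B
    w <- if (dr != 0 && dc != 0) sqrt(2) else 1
    lab_pair <- ifelse(LA == LB, LA, pmax(LA, LB))  # edge follows the labelled side
    list(total = sum(both) * w,
         per = if (any(both & lab_pair > 0))
           rowsum(rep(w, sum(both & lab_pair > 0)), lab_pair[both & lab_pair > 0])
         else NULL)
  }
  offs <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  total_px <- 0; per <- numeric(0)
  for (o in offs) {
    el <- edge_len(o[1], o[2])
    total_px <- total_px + el$total
    if (!is.null(el$per)) {
      ids <- as.integer(rownames(el$per))
      for (j in seq_along(ids)) {
        key <- as.character(ids[j])
        per[key] <- (if (key %in% names(per)) per[key] else 0) + el$per[j]
      }
    }
  }
  # branch points: clusters of skeleton pixels with >= 3 neighbours
  nb <- skel_neighbor_count(sk)
  bp_mask <- sk & nb >= 3
  n_branch_total <- 0L
  bp_per <- integer(0)
  if (any(bp_mask)) {
    bl <- EBImage::imageData(EBImage::bwlabel(
      EBImage::imageData(EBImage::dilate(EBImage::Image(bp_mask * 1),
                                         EBImage::makeBrush(3, "box"))) > 0))
    bl[!bp_mask] <- 0
    cl_ids <- setdiff(unique(as.vector(bl)), 0)
    n_branch_total <- length(cl_ids)
    for (cid in cl_ids) {
      labs_here <- cell_labels[bl == cid]
      labs_here <- labs_here[labs_here > 0]
      lab <- if (length(labs_here)) as.integer(names(which.max(table(labs_here)))) else 0L
      if (lab > 0) {
        key <- as.character(lab)
        bp_per[key] <- (if (key %in% names(bp_per)) bp_per[key] else 0L) + 1L
      }
    }
  }
  ids <- sort(unique(c(as.integer(names(per)), as.integer(names(bp_per)))))
  per_cell <- data.frame(
    label = ids,
    neurite_length_um = vapply(as.character(ids), function(k)
      (if (k %in% names(per)) per[[k]] else 0) * pixel_pitch_um, 0),
    branch_points = vapply(as.character(ids), function(k)
      if (k %in% names(bp_per)) bp_per[[k]] else 0L, 0L))
  rownames(per_cell) <- NULL
  list(skeleton = sk, per_cell = per_cell,
       total_length_um = total_px * pixel_pitch_um,
       total_branches = n_branch_total)
}

#' Segment one field into compartments
#'
#' Full deterministic segmentation of a 4-channel field: illumination
#' correction, nucleus segmentation and viability call, seeded cell
#' segmentation on MAP2, cytoplasm/membrane derivation and neurite skeleton
#' extraction.
#'
#' @param channels named list of matrices `dna`, `th`, `asyn`, `map2`.
#' @param config pipeline config.
#' @return list with `corrected` channels, `nucleus`, `cell`, `cytoplasm`,
#'   `membrane` label matrices, `viability` table, `neurites` (see
#'   [extract_neurites()]).
#' @export
segment_field <- function(channels, config = default_config()) {
  need <- c("dna", "th", "asyn", "map2")
  if (!all(need %in% names(channels)))
    stop("field lacks channels: ", paste(setdiff(need, names(channels)), collapse = ", "))
  corr <- lapply(channels[need], correct_illumination)
  nuc <- segment_nuclei(corr$dna, config$nucleus_threshold, config$nucleus_min_area_px)
  viab <- classify_viability(nuc, corr$dna,
                             config$viability_min_area_px,
                             config$viability_max_mean_intensity)
  living_ids <- viab$table$label[viab$table$living]
  cell <- segment_cells(corr$map2, nuc, living_ids, config$cell_threshold,
                        config$cell_max_seed_dist_px)
  comp <- derive_compartments(cell, nuc, config$membrane_width_px)
  neur <- extract_neurites(corr$map2, cell, config$cell_threshold,
                           config$soma_opening_radius_px,
                           config$pixel_pitch_um, config$spur_prune_px)
  list(corrected = corr, nucleus = nuc, cell = cell,
       cytoplasm = comp$cytoplasm, membrane = comp$membrane,
       viability = viab, neurites = neur)
}
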