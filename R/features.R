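#' Gray-level co-occurrence matrix of a region
#'
#' Quantizes the region's intensities to `levels` gray levels between its
#' 1st and 99th percentile (configurable), accumulates co-occurrences at
#' distance 1 over the requested directions, symmetrizes and normalizes to
#' a probability distribution. A constant region yields a single co-occurrence
#' cell (ASM = 1, contrast = 0).
#'
#' @param img numeric matrix.
#' @param region logical matrix of the same shape selecting the region.
#' @param levels number of gray levels.
#' @param quantiles length-2 quantile range for the quantization window.
#' @param directions subset of `c("h", "v", "d1", "d2")` (horizontal,
#'   vertical, the two diagonals).
#' @return `levels` x `levels` matrix summing to 1, or `NULL` if the region
#'   has fewer than 2 px or no co-occurring pair.
#' @export
glcm_matrix <- function(img, region, levels = 16L,
                        quantiles = c(0.01, 0.99),
                        directions = c("h", "v", "d1", "d2")) {
  if (sum(region) < 2) return(NULL)
  vals <- img[region]
  qs <- stats::quantile(vals, quantiles, names = FALSE)
  if (diff(qs) < 1e-12) {
    lv <- matrix(NA_integer_, nrow(img), ncol(img))
    lv[region] <- 1L
  } else {
    lv <- matrix(NA_integer_, nrow(img), ncol(img))
    lv[region] <- pmin(levels, pmax(1L, as.integer(
      floor((vals - qs[1]) / (qs[2] - qs[1]) * levels) + 1L)))
  }
  nr <- nrow(img); nc <- ncol(img)
  offs <- list(h = c(0L, 1L), v = c(1L, 0L), d1 = c(1L, 1L), d2 = c(1L, -1L))
  P <- matrix(0, levels, levels)
  for (d in directions) {
    o <- offs[[d]]
    a_rs <- seq_len(nr - o[1])
    b_rs <- a_rs + o[1]
    if (o[2] >= 0) { a_cs <- seq_len(nc - o[2]); b_cs <- a_cs + o[2] }
    else { a_cs <- seq(1 - o[2], nc); b_cs <- a_cs + o[2] }
    A <- lv[a_rs, a_cs, drop = FALSE]; B <- lv[b_rs, b_cs, drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    P <- P + matrix(tabulate(A[ok] + (B[ok] - 1L) * levels, nbins = levels * levels),
                    levels, levels)
  }
  if (sum(P) == 0) return(NULL)
  P <- P + t(P)
  P / sum(P)
}

#' GLCM texture metrics
#'
#' Angular second moment (ASM), contrast, correlation, homogeneity and
#' entropy of a normalized co-occurrence matrix. For degenerate matrices
#' (constant region) correlation is reported as 0.
#'
#' @param P normalized GLCM from [glcm_matrix()], or `NULL`.
#' @return named numeric vector `asm`, `contrast`, `correlation`,
#'   `homogeneity`, `entropy` (zeros if `P` is `NULL`).
#' @export
glcm_stats <- function(P) {
  out <- c(asm = 0, contrast = 0, correlation = 0, homogeneity = 0, entropy = 0)
  if (is.null(P)) return(out)
  k <- nrow(P)
  i <- row(P); j <- col(P)
  out["asm"] <- sum(P^2)
  out["contrast"] <- sum(P * (i - j)^2)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mi <- sum(seq_len(k) * pi_); mj <- sum(seq_len(k) * pj_)
  si <- sqrt(sum((seq_len(k) - mi)^2 * pi_)); sj <- sqrt(sum((seq_len(k) - mj)^2 * pj_))
  out["correlation"] <- if (si > 1e-12 && sj > 1e-12)
    sum(P * (i - mi) * (j - mj)) / (si * sj) else 0
  out["homogeneity"] <- sum(P / (1 + abs(i - j)))
  nz <- P[P > 0]
  out["entropy"] <- -sum(nz * log2(nz))
  out
}

# solidity = region area / area of the convex hull of its pixel squares
region_solidity <- function(rows, cols) {
  if (length(rows) < 3) return(1)
  pts <- cbind(c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
               c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  hull_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (hull_area <= 0) return(1)
  min(1, length(rows) / hull_area)
}

#' Per-cell shape metrics for one compartment
#'
#' Area, perimeter (physical units), eccentricity, solidity and form factor
#' (4*pi*A/P^2) per label of a compartment label matrix.
#'
#' @param labels integer label matrix.
#' @param pixel_pitch_um physical pixel size.
#' @param ids label IDs to report (defaults to all present).
#' @return data.frame keyed by `label` with the five metrics; empty labels
#'   yield zero rows.
#' @export
shape_features <- function(labels, pixel_pitch_um = 0.1628, ids = NULL) {
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (is.null(ids)) ids <- sort(present)
  out <- data.frame(label = ids, area_um2 = 0, perimeter_um = 0,
                    eccentricity = 0, solidity = 0, form_factor = 0)
  if (!length(present)) return(out)
  sh <- EBImage::computeFeatures.shape(labels)
  mo <- EBImage::computeFeatures.moment(labels)
  rn <- as.integer(rownames(sh))
  if (is.null(rn) || any(is.na(rn))) rn <- seq_len(nrow(sh))
  for (i in seq_along(ids)) {
    L <- ids[i]
    k <- match(L, rn)
    if (is.na(k)) next
    A <- sh[k, "s.area"]; P <- sh[k, "s.perimeter"]
    px <- which(labels == L, arr.ind = TRUE)
    out$area_um2[i] <- A * pixel_pitch_um^2
    out$perimeter_um[i] <- P * pixel_pitch_um
    out$eccentricity[i] <- mo[k, "m.eccentricity"]
    out$solidity[i] <- region_solidity(px[, 1], px[, 2])
    out$form_factor[i] <- if (P > 0) 4 * pi * A / P^2 else 0
  }
  out
}

# per-label intensity stats (mean, median, sd, integrated) over a compartment
intensity_stats <- function(labels, channel, ids) {
  res <- matrix(0, length(ids), 4,
                dimnames = list(NULL, c("mean", "median", "sd", "integrated")))
  idx <- which(labels > 0)
  if (!length(idx)) return(res)
  labs <- labels[idx]; v <- channel[idx]
  sp <- split(v, labs)
  for (i in seq_along(ids)) {
    g <- sp[[as.character(ids[i])]]
    if (is.null(g) || !length(g)) next   # empty compartment -> zeros
    res[i, ] <- c(mean(g), stats::median(g), if (length(g) > 1) stats::sd(g) else 0, sum(g))
  }
  res
}

#' Compute the per-cell and field-level features of one segmented field
#'
#' Produces the per-cell block of the catalogue (intensity, shape, texture
#' features for every living cell) and the field-level context block
#' (channel correlations, counts, neurite morphometry, composites).
#' Cells touching the image border keep their intensity and texture features
#' but have shape features withheld (NA), so they do not bias well-level
#' shape averages.
#'
#' @param seg output of [segment_field()].
#' @param config pipeline config.
#' @return list with `cell_table` (one row per living cell), `field_row`
#'   (named vector over the 34 context features), `n_living`, `n_nuclei`.
#' @export
featurize_field <- function(seg, config = default_config()) {
  pitch <- config$pixel_pitch_um
  corr <- seg$corrected
  comp_mats <- list(nucleus = seg$nucleus, cell = seg$cell,
                    cytoplasm = seg$cytoplasm, membrane = seg$membrane)
  living_ids <- sort(setdiff(unique(as.vector(seg$cell)), 0L))
  n_living <- length(living_ids)
  n <- nrow(seg$cell)

  cell_table <- NULL
  if (n_living) {
    feats <- list(label = living_ids)
    # restrict nucleus labels to living cells
    nuc_l <- seg$nucleus
    nuc_l[!(nuc_l %in% living_ids)] <- 0L
    comp_mats$nucleus <- nuc_l
    # intensity: 4 compartments x 3 channels x 4 stats
    for (cp in names(comp_mats)) {
      for (ch in c("th", "asyn", "map2")) {
        st <- intensity_stats(comp_mats[[cp]], corr[[ch]], living_ids)
        for (s in colnames(st))
          feats[[sprintf("int_%s_%s_%s", ch, cp, s)]] <- st[, s]
      }
    }
    # border cells: shape features withheld
    border <- vapply(living_ids, function(L) {
      any(seg$cell[1, ] == L) || any(seg$cell[n, ] == L) ||
        any(seg$cell[, 1] == L) || any(seg$cell[, ncol(seg$cell)] == L)
    }, logical(1))
    for (cp in names(comp_mats)) {
      sf <- shape_features(comp_mats[[cp]], pitch, living_ids)
      for (m in c("area_um2", "perimeter_um", "eccentricity", "solidity", "form_factor")) {
        v <- sf[[m]]
        v[border] <- NA_real_
        feats[[sprintf("shp_%s_%s", cp, m)]] <- v
      }
    }
    # texture: 3 channels x {cell, cytoplasm} x 4 metrics, on bounding crops
    for (ch in c("asyn", "th", "map2")) for (cp in c("cell", "cytoplasm")) {
      mat <- comp_mats[[cp]]
      vals <- matrix(0, n_living, 4,
                     dimnames = list(NULL, c("asm", "contrast", "correlation", "homogeneity")))
      for (i in seq_along(living_ids)) {
        px <- which(mat == living_ids[i], arr.ind = TRUE)
        if (nrow(px) < 2) next
        r0 <- min(px[, 1]); r1 <- max(px[, 1]); c0 <- min(px[, 2]); c1 <- max(px[, 2])
        reg <- mat[r0:r1, c0:c1, drop = FALSE] == living_ids[i]
        g <- glcm_stats(glcm_matrix(corr[[ch]][r0:r1, c0:c1, drop = FALSE], reg,
                                    config$glcm_levels, config$glcm_quantiles))
        vals[i, ] <- g[colnames(vals)]
      }
      for (m in colnames(vals))
        feats[[sprintf("tex_%s_%s_%s", ch, cp, m)]] <- vals[, m]
    }
    cell_table <- as.data.frame(feats)
  }

  # ---- field-level context block ----
  fr <- numeric(0)
  chans4 <- list(dna = corr$dna, th = corr$th, asyn = corr$asyn, map2 = corr$map2)
  pairs <- list(c("dna", "th"), c("dna", "asyn"), c("dna", "map2"),
                c("th", "asyn"), c("th", "map2"), c("asyn", "map2"))
  for (cp in c("cell", "cytoplasm")) {
    idx <- which(comp_mats[[cp]] > 0)
    for (pr in pairs) {
      nm <- sprintf("ctx_corr_%s_%s_%s", pr[1], pr[2], cp)
      fr[nm] <- if (length(idx) >= 2) {
        a <- chans4[[pr[1]]][idx]; b <- chans4[[pr[2]]][idx]
        if (stats::sd(a) > 1e-12 && stats::sd(b) > 1e-12) stats::cor(a, b) else 0
      } else 0
    }
  }
  vt <- seg$viability$table
  n_nuclei <- nrow(vt)
  fr["ctx_n_living_cells"] <- seg$viability$n_living
  fr["ctx_n_nuclei_total"] <- n_nuclei
  fr["ctx_apoptotic_fraction"] <- if (n_nuclei) 1 - seg$viability$n_living / n_nuclei else 0
  area_mm2 <- (n * pitch / 1000) * (ncol(seg$cell) * pitch / 1000)
  fr["ctx_living_density_per_mm2"] <- seg$viability$n_living / area_mm2

  th_pos_ids <- if (n_living)
    living_ids[cell_table$int_th_cell_mean > config$th_pos_threshold] else integer(0)
  fr["ctx_n_th_pos_cells"] <- length(th_pos_ids)
  fr["ctx_fraction_th_pos_cells"] <- if (n_living) length(th_pos_ids) / n_living else 0

  # nearest-neighbour soma distances between living-cell nuclei centroids
  if (n_living >= 2) {
    cent <- t(vapply(living_ids, function(L) {
      px <- which(seg$nucleus == L, arr.ind = TRUE)
      c(mean(px[, 1]), mean(px[, 2]))
    }, numeric(2)))
    D <- as.matrix(stats::dist(cent)) * pitch
    diag(D) <- Inf
    nn <- apply(D, 1, min)
    fr["ctx_nn_soma_dist_mean_um"] <- mean(nn)
    fr["ctx_nn_soma_dist_sd_um"] <- if (length(nn) > 1) stats::sd(nn) else 0
    fr["ctx_nn_soma_dist_min_um"] <- min(nn)
  } else {
    fr["ctx_nn_soma_dist_mean_um"] <- 0
    fr["ctx_nn_soma_dist_sd_um"] <- 0
    fr["ctx_nn_soma_dist_min_um"] <- 0
  }

  pc <- seg$neurites$per_cell
  len_by_cell <- stats::setNames(rep(0, n_living), living_ids)
  bp_by_cell <- stats::setNames(rep(0, n_living), living_ids)
  if (nrow(pc)) {
    hit <- as.character(pc$label) %in% names(len_by_cell)
    len_by_cell[as.character(pc$label[hit])] <- pc$neurite_length_um[hit]
    bp_by_cell[as.character(pc$label[hit])] <- pc$branch_points[hit]
  }
  fr["ctx_neurite_length_per_cell_um"] <- if (n_living) mean(len_by_cell) else 0
  fr["ctx_branch_points_per_cell"] <- if (n_living) mean(bp_by_cell) else 0
  fr["ctx_neurite_length_total_um"] <- seg$neurites$total_length_um
  fr["ctx_branch_points_total"] <- seg$neurites$total_branches
  fr["ctx_branches_per_100um"] <- if (seg$neurites$total_length_um > 0)
    100 * seg$neurites$total_branches / seg$neurites$total_length_um else 0

  fr["ctx_asyn_mean_th_pos_cells"] <- if (length(th_pos_ids))
    mean(cell_table$int_asyn_cell_mean[match(th_pos_ids, living_ids)]) else NA_real_
  dpos <- corr$th > config$th_pos_threshold & corr$asyn > config$th_pos_threshold
  fr["ctx_th_asyn_dpos_integrated"] <- if (any(dpos))
    sum((corr$th[dpos] + corr$asyn[dpos]) / 2) else 0
  fr["ctx_th_asyn_dpos_area_fraction"] <- mean(dpos)
  map2_area_px <- sum(seg$cell > 0)
  fr["ctx_map2_area_per_nucleus_um2"] <- if (n_living)
    map2_area_px * pitch^2 / n_living else NA_real_
  fr["ctx_map2_area_fraction"] <- map2_area_px / length(seg$cell)
  fr["ctx_th_area_fraction"] <- mean(corr$th > config$th_pos_threshold)
  living_rows <- vt[vt$living, , drop = FALSE]
  fr["ctx_nucleus_area_mean_living_um2"] <- if (nrow(living_rows))
    mean(living_rows$area_px) * pitch^2 else 0
  fr["ctx_nucleus_dna_mean_living"] <- if (nrow(living_rows))
    mean(living_rows$mean_intensity) else 0

  list(cell_table = cell_table, field_row = fr,
       n_living = n_living, n_nuclei = n_nuclei)
}

#' Aggregate field features to one well row
#'
#' Per-cell features are averaged (arithmetic mean) over all living cells
#' pooled across the well's fields; field-level context features are
#' averaged over fields. The output row carries exactly the 126 catalogue
#' features in catalogue order, plus metadata.
#'
#' @param field_feats list of [featurize_field()] results.
#' @param meta named list with `plate`, `well`, `compound`, `dose_uM`,
#'   `replicate`.
#' @param config pipeline config.
#' @return one-row data.frame (metadata + 126 features); a well with zero
#'   living cells yields NA features with a warning.
#' @export
featurize_well <- function(field_feats, meta, config = default_config()) {
  cat126 <- feature_catalogue()
  cell_names <- cat126$name[cat126$level == "cell"]
  field_names <- cat126$name[cat126$level == "field"]
  cells <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(field_feats, `[[`, "cell_table")))
  n_living <- sum(vapply(field_feats, `[[`, 0L, "n_living"))
  out <- stats::setNames(rep(NA_real_, 126), cat126$name)
  if (is.null(cells) || nrow(cells) == 0) {
    warning("well ", meta$well, " has zero living cells; features are NA")
  } else {
    for (nm in cell_names) {
      v <- cells[[nm]]
      out[nm] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    fmat <- do.call(rbind, lapply(field_feats, `[[`, "field_row"))
    for (nm in field_names) {
      v <- fmat[, nm]
      out[nm] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  cbind(data.frame(plate = meta$plate %||% "plate1", well = meta$well,
                   compound = meta$compound, dose_uM = meta$dose_uM,
                   replicate = meta$replicate %||% 1L,
                   n_fields = length(field_feats),
                   n_living_cells = n_living,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature columns of a well table
#'
#' @param table a well feature table.
#' @return character vector of the 126 feature column names present.
#' @export
feature_cols <- function(table) {
  intersect(feature_catalogue()$name, names(table))
}
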