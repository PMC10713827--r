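#' Build a 384-well plate layout
#'
#' Assigns conditions to non-edge wells of a 384-well plate (rows B-O,
#' columns 2-23; edge wells are never used). Each compound x dose condition
#' receives `wells_per_condition` wells and the methanol vehicle receives
#' `vehicle_wells` wells; wells are alternately assigned to the biological
#' replicates.
#'
#' @param config an [default_config()] list.
#' @return data.frame with columns `well`, `row`, `col`, `compound`,
#'   `dose_uM`, `replicate`, `fields`.
#' @export
build_plate_layout <- function(config = default_config()) {
  rows <- LETTERS[2:15]   # B..O
  cols <- 2:23
  grid <- expand.grid(row = rows, col = cols, stringsAsFactors = FALSE)
  grid <- grid[order(grid$row, grid$col), ]
  conds <- data.frame(compound = "vehicle", dose_uM = 0)[rep(1, config$vehicle_wells), ]
  for (cmp in config$compounds)
    for (d in config$doses_uM)
      conds <- rbind(conds,
        data.frame(compound = cmp, dose_uM = d)[rep(1, config$wells_per_condition), ])
  if (nrow(conds) > nrow(grid))
    stop("layout needs ", nrow(conds), " wells but only ", nrow(grid),
         " non-edge wells exist")
  layout <- data.frame(
    well = sprintf("%s%02d", grid$row[seq_len(nrow(conds))], grid$col[seq_len(nrow(conds))]),
    row = grid$row[seq_len(nrow(conds))],
    col = grid$col[seq_len(nrow(conds))],
    compound = conds$compound,
    dose_uM = conds$dose_uM,
    replicate = rep_len(seq_len(config$replicates), nrow(conds)),
    fields = config$fields_per_well,
    stringsAsFactors = FALSE)
  validate_layout(layout)
  layout
}

#' Validate a plate layout
#'
#' Checks the layout invariants: no edge wells (row A/P or column 1/24),
#' vehicle wells at dose 0, treated wells at positive dose, positive field
#' counts.
#'
#' @param layout a layout data.frame as from [build_plate_layout()].
#' @return the layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  need <- c("well", "compound", "dose_uM", "replicate", "fields")
  if (!all(need %in% names(layout)))
    stop("layout lacks columns: ", paste(setdiff(need, names(layout)), collapse = ", "))
  rw <- substr(layout$well, 1, 1)
  cl <- as.integer(substr(layout$well, 2, 3))
  if (any(rw %in% c("A", "P") | cl %in% c(1L, 24L)))
    stop("plate edge wells are not used: ",
         paste(layout$well[rw %in% c("A", "P") | cl %in% c(1L, 24L)], collapse = ", "))
  if (any(layout$compound == "vehicle" & layout$dose_uM != 0))
    stop("vehicle wells must have dose 0")
  if (any(layout$compound != "vehicle" & layout$dose_uM <= 0))
    stop("treated wells must have dose > 0")
  if (any(layout$fields < 1)) stop("fields per well must be >= 1")
  if (anyDuplicated(layout$well)) stop("duplicate well IDs")
  invisible(layout)
}

# deterministic fan-out of one plate seed into per-field seeds and
# replicate/well random offsets; shared by the disk and streaming paths
plate_seeds <- function(layout, config, seed) {
  set.seed(seed)
  list(
    replicate_offsets = exp(stats::rnorm(max(layout$replicate), 0, config$replicate_sd)),
    well_offsets = exp(stats::rnorm(nrow(layout), 0, config$well_sd)),
    field_seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                    nrow(layout) * max(layout$fields)),
                         nrow = nrow(layout)))
}

# rasterize an ellipse; returns linear indices into an n x n matrix
# (row = y, col = x); a is the semi-axis along angle theta
ellipse_idx <- function(cx, cy, a, b, theta, n) {
  r <- ceiling(max(a, b))
  ys <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(integer(0))
  Y <- rep(ys, times = length(xs)) - cy
  X <- rep(xs, each = length(ys)) - cx
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  (rep(xs, each = length(ys))[keep] - 1L) * n + rep(ys, times = length(xs))[keep]
}

# stamp a 3x3 block around integer point (x, y); returns linear indices
stamp3_idx <- function(x, y, n) {
  xs <- pmin(pmax(rep(x, each = 9) + rep(-1:1, times = 3), 1L), n)
  ys <- pmin(pmax(rep(y, each = 9) + rep(-1:1, each = 3), 1L), n)
  unique((xs - 1L) * n + ys)
}

# grow branching biased random-walk neurites from the soma edge.
# Returns points (x, y), the count of steps outside the soma (ground-truth
# length in px) and the count of branch events outside the soma.
grow_neurites <- function(cx, cy, sa, sb, stheta, n, length_mult, branch_mult) {
  n_primary <- sample(2:4, 1)
  outside_soma <- function(x, y) {
    u <- (x - cx) * cos(stheta) + (y - cy) * sin(stheta)
    v <- -(x - cx) * sin(stheta) + (y - cy) * cos(stheta)
    (u / sa)^2 + (v / sb)^2 > 1
  }
  p_branch <- 0.012 * branch_mult
  stack <- list()
  for (i in seq_len(n_primary)) {
    phi <- stats::runif(1, 0, 2 * pi)
    stack[[i]] <- list(x = cx + sa * cos(phi), y = cy + sb * sin(phi),
                       h = atan2(sb * sin(phi), sa * cos(phi)),
                       left = stats::runif(1, 70, 140) * length_mult)
  }
  px <- numeric(0); py <- numeric(0)
  len_out <- 0; branches <- 0; n_walks <- n_primary
  while (length(stack)) {
    w <- stack[[1]]; stack[[1]] <- NULL
    x <- w$x; y <- w$y; h <- w$h; left <- w$left
    while (left >= 1) {
      x <- x + cos(h); y <- y + sin(h)
      h <- h + stats::rnorm(1, 0, 0.12)
      left <- left - 1
      if (x < 2 || x > n - 1 || y < 2 || y > n - 1) break
      px <- c(px, x); py <- c(py, y)
      out <- outside_soma(x, y)
      if (out) len_out <- len_out + 1
      if (n_walks < 12 && left > 10 && stats::runif(1) < p_branch) {
        if (out) branches <- branches + 1
        stack[[length(stack) + 1L]] <- list(
          x = x, y = y,
          h = h + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.0),
          left = left * stats::runif(1, 0.4, 0.8))
        n_walks <- n_walks + 1L
      }
    }
  }
  list(x = px, y = py, length_px = len_out, branches = branches)
}

#' Render one synthetic microscope field
#'
#' Renders a 4-channel (DNA, TH, aSyn, MAP2) 16-bit field for one treatment
#' condition. Living neurons are drawn as elliptical nuclei (>2000 px, dim
#' DNA) inside MAP2-positive somata with branching random-walk neurites; TH
#' and aSyn fill the cytoplasm with condition-specific multipliers and TH has
#' an additional rim component at the cell edge. A configurable fraction of
#' apoptotic cells is rendered as small (<2000 px), bright (>1500) pyknotic
#' nuclei without somata. Background carries a linear illumination gradient;
#' Poisson shot noise and Gaussian read noise are added. Output is
#' bit-identical under a fixed seed.
#'
#' @param condition list or one-row data.frame with `compound`, `dose_uM`
#'   and optionally `replicate`.
#' @param effects an effect model, e.g. [default_effect_model()].
#' @param config an [default_config()] list; `replicate_offsets` /
#'   `well_offset` entries (set by [generate_plate()]) are honoured.
#' @param seed integer seed for this field.
#' @return list with `channels` (named list of integer matrices `dna`, `th`,
#'   `asyn`, `map2`), `ground_truth` (one row per rendered cell) and
#'   `pixel_pitch_um`.
#' @export
generate_field <- function(condition, effects, config = default_config(), seed = 1L) {
  n <- as.integer(config$image_size)
  if (n < 128L) stop("image size must be >= 128")
  if (config$cells_per_field * 3500 > 0.5 * n * n)
    stop("overcrowded: ", config$cells_per_field,
         " cells/field exceed the usable area of a ", n, "x", n, " field")
  compound <- as.character(condition$compound)
  dose <- as.numeric(condition$dose_uM)
  if (!(compound %in% c("vehicle", effects$compound)))
    stop("unknown compound: ", compound)
  eff <- effect_for(effects, compound, dose)
  replicate <- if (!is.null(condition$replicate)) condition$replicate else 1L
  rep_off <- if (!is.null(config$replicate_offsets))
    config$replicate_offsets[replicate] else 1
  well_off <- if (!is.null(config$well_offset)) config$well_offset else 1
  gain <- rep_off * well_off

  set.seed(as.integer(seed))
  dna <- matrix(0, n, n); th <- matrix(0, n, n)
  asyn <- matrix(0, n, n); map2 <- matrix(0, n, n)

  # place soma centers with minimum separation
  n_target <- stats::rpois(1, config$cells_per_field)
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(n_target)) {
    for (try in 1:50) {
      x <- stats::runif(1, 40, n - 40); y <- stats::runif(1, 40, n - 40)
      if (!length(cx) || min((cx - x)^2 + (cy - y)^2) > 85^2) {
        cx <- c(cx, x); cy <- c(cy, y); break
      }
    }
  }
  n_cells <- length(cx)
  p_apo <- min(0.95, max(0, config$apoptotic_fraction + eff$apoptotic_delta))
  gt <- vector("list", n_cells)
  masks <- vector("list", n_cells)

  for (i in seq_len(n_cells)) {
    apoptotic <- stats::runif(1) < p_apo
    cmul <- exp(stats::rnorm(4, 0, config$cell_sd))  # dna, th, asyn, map2
    if (apoptotic) {
      r <- stats::runif(1, 10, 14)
      nidx <- ellipse_idx(cx[i], cy[i], r, r, 0, n)
      lvl <- stats::runif(1, 2600, 4000) * cmul[1] * gain
      dna[nidx] <- pmax(dna[nidx], lvl)
      gt[[i]] <- data.frame(cell_id = i, cx = cx[i], cy = cy[i],
        apoptotic = TRUE, nucleus_area_px = length(nidx), th_pos = FALSE,
        neurite_length_px = 0, branch_count = 0,
        asyn_cyto_design = 0, th_cyto_design = 0, th_mem_design = 0,
        map2_soma_design = 0)
      masks[[i]] <- list(nucleus = nidx, cyto = integer(0), rim = integer(0),
                         soma = integer(0))
      next
    }
    na <- stats::runif(1, 29, 35); nb <- stats::runif(1, 26, 31)
    theta <- stats::runif(1, 0, pi)
    nidx <- ellipse_idx(cx[i], cy[i], na, nb, theta, n)
    rs <- stats::runif(1, 7, 11)
    sa <- na + rs; sb <- nb + rs
    sidx <- ellipse_idx(cx[i], cy[i], sa, sb, theta, n)
    # rim: soma minus an inner ellipse 4 px smaller
    inidx <- ellipse_idx(cx[i], cy[i], sa - 4, sb - 4, theta, n)
    rim <- setdiff(sidx, inidx)
    cyto <- setdiff(sidx, nidx)

    dna_lvl <- stats::runif(1, 700, 1000) * cmul[1] * gain
    dna[nidx] <- pmax(dna[nidx], dna_lvl)

    map2_soma <- stats::runif(1, 3000, 4500) * cmul[4] * gain
    map2[sidx] <- pmax(map2[sidx], map2_soma)

    th_pos <- stats::runif(1) < config$th_pos_prob
    th_cyto_lvl <- if (th_pos)
      stats::runif(1, 2600, 3400) * eff$th_cyto_mult * cmul[2] * gain else
      250 * cmul[2] * gain
    th_mem_lvl <- if (th_pos)
      th_cyto_lvl + stats::runif(1, 2000, 2800) * eff$th_mem_mult * cmul[2] * gain else
      th_cyto_lvl
    th[cyto] <- pmax(th[cyto], th_cyto_lvl)
    th[rim] <- pmax(th[rim], th_mem_lvl)
    th[nidx] <- pmax(th[nidx], 300 * cmul[2] * gain)

    asyn_lvl <- stats::runif(1, 2400, 3200) * eff$asyn_mult * cmul[3] * gain
    asyn[cyto] <- pmax(asyn[cyto], asyn_lvl)
    asyn[nidx] <- pmax(asyn[nidx], stats::runif(1, 1000, 1400) * cmul[3] * gain)

    nw <- grow_neurites(cx[i], cy[i], sa, sb, theta, n,
                        eff$neurite_mult, eff$branch_mult)
    if (length(nw$x)) {
      widx <- stamp3_idx(as.integer(round(nw$x)), as.integer(round(nw$y)), n)
      widx <- setdiff(widx, sidx)
      map2[widx] <- pmax(map2[widx], stats::runif(1, 2200, 3000) * cmul[4] * gain)
      asyn[widx] <- pmax(asyn[widx], 700 * cmul[3] * gain)
      if (th_pos) th[widx] <- pmax(th[widx], 500 * cmul[2] * gain)
    }
    gt[[i]] <- data.frame(cell_id = i, cx = cx[i], cy = cy[i],
      apoptotic = FALSE, nucleus_area_px = length(nidx), th_pos = th_pos,
      neurite_length_px = nw$length_px, branch_count = nw$branches,
      asyn_cyto_design = asyn_lvl, th_cyto_design = th_cyto_lvl,
      th_mem_design = th_mem_lvl, map2_soma_design = map2_soma)
    masks[[i]] <- list(nucleus = nidx, cyto = cyto, rim = rim, soma = sidx)
  }

  # background with illumination gradient, shot and read noise
  xn <- matrix(rep((seq_len(n) - 0.5) / n, each = n), n, n)
  yn <- matrix(rep((seq_len(n) - 0.5) / n, times = n), n, n)
  chans <- list(dna = dna, th = th, asyn = asyn, map2 = map2)
  for (ch in names(chans)) {
    g <- stats::runif(2, -config$illumination_gradient, config$illumination_gradient)
    bg <- config$background_level * (1 + g[1] * (xn - 0.5) + g[2] * (yn - 0.5))
    img <- chans[[ch]] + bg
    img <- stats::rpois(n * n, pmax(img, 0)) + stats::rnorm(n * n, 0, config$read_noise_sd)
    chans[[ch]] <- matrix(pmin(pmax(round(img), 0), 65535), n, n)
  }

  if (n_cells) {
    gt <- do.call(rbind, gt)
    # measured (post-noise) means per compartment and the viability call
    gt$nucleus_dna_mean <- vapply(masks, function(m)
      if (length(m$nucleus)) mean(chans$dna[m$nucleus]) else NA_real_, 0)
    gt$asyn_cyto_mean <- vapply(masks, function(m)
      if (length(m$cyto)) mean(chans$asyn[m$cyto]) else NA_real_, 0)
    gt$th_cyto_mean <- vapply(masks, function(m)
      if (length(m$cyto)) mean(chans$th[m$cyto]) else NA_real_, 0)
    gt$th_mem_mean <- vapply(masks, function(m)
      if (length(m$rim)) mean(chans$th[m$rim]) else NA_real_, 0)
    gt$map2_soma_mean <- vapply(masks, function(m)
      if (length(m$soma)) mean(chans$map2[m$soma]) else NA_real_, 0)
    gt$viable <- gt$nucleus_area_px > config$viability_min_area_px &
      gt$nucleus_dna_mean < config$viability_max_mean_intensity
  } else {
    gt <- data.frame(cell_id = integer(0), cx = numeric(0), cy = numeric(0),
      apoptotic = logical(0), nucleus_area_px = integer(0), th_pos = logical(0),
      neurite_length_px = numeric(0), branch_count = integer(0),
      asyn_cyto_design = numeric(0), th_cyto_design = numeric(0),
      th_mem_design = numeric(0), map2_soma_design = numeric(0),
      nucleus_dna_mean = numeric(0), asyn_cyto_mean = numeric(0),
      th_cyto_mean = numeric(0), th_mem_mean = numeric(0),
      map2_soma_mean = numeric(0), viable = logical(0))
  }
  list(channels = chans, ground_truth = gt,
       pixel_pitch_um = config$pixel_pitch_um,
       condition = list(compound = compound, dose_uM = dose, replicate = replicate))
}

#' Generate a full synthetic plate
#'
#' Renders every field of every well in `layout` and (optionally) writes one
#' 16-bit grayscale TIFF per channel plus a machine-readable layout table and
#' the per-cell ground truth. Deterministic: a single plate seed fans out
#' into per-field seeds and plate-level replicate/well random offsets, so a
#' rerun with the same inputs is byte-identical.
#'
#' @param layout plate layout from [build_plate_layout()].
#' @param effects effect model.
#' @param config pipeline config.
#' @param seed integer plate seed.
#' @param out_dir output directory; `NULL` keeps fields in memory instead of
#'   writing TIFFs (only advisable for small layouts).
#' @return list with `layout`, `ground_truth` (all cells, keyed by
#'   well/field), `dir` (or `NULL`) and `fields` (in-memory field list or
#'   `NULL`).
#' @export
generate_plate <- function(layout, effects, config = default_config(),
                           seed = 1L, out_dir = NULL) {
  validate_layout(layout)
  ps <- plate_seeds(layout, config, seed)
  keep <- is.null(out_dir)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(out_dir, "images")))
      stop("cannot create output directory: ", out_dir)
  }
  fields <- if (keep) list() else NULL
  gt_all <- list()
  for (i in seq_len(nrow(layout))) {
    cfg_i <- config
    cfg_i$replicate_offsets <- ps$replicate_offsets
    cfg_i$well_offset <- ps$well_offsets[i]
    for (f in seq_len(layout$fields[i])) {
      fld <- generate_field(layout[i, ], effects, cfg_i, seed = ps$field_seeds[i, f])
      if (nrow(fld$ground_truth)) {
        fld$ground_truth$well <- layout$well[i]
        fld$ground_truth$field <- f
        gt_all[[length(gt_all) + 1L]] <- fld$ground_truth
      }
      if (keep) {
        fields[[sprintf("%s_f%02d", layout$well[i], f)]] <- fld
      } else {
        for (ch in names(fld$channels))
          tiff::writeTIFF(fld$channels[[ch]] / 65535,
                          file.path(out_dir, "images",
                                    sprintf("%s_f%02d_%s.tif", layout$well[i], f, ch)),
                          bits.per.sample = 16L)
      }
    }
  }
  gt <- if (length(gt_all)) do.call(rbind, gt_all) else NULL
  if (!is.null(out_dir)) {
    utils::write.csv(layout, file.path(out_dir, "layout.csv"), row.names = FALSE)
    if (!is.null(gt))
      utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  }
  list(layout = layout, ground_truth = gt, dir = out_dir, fields = fields,
       seed = seed)
}

#' Read one field back from disk
#'
#' @param dir plate directory written by [generate_plate()].
#' @param well well ID, e.g. `"B02"`.
#' @param field field number.
#' @return named list of integer channel matrices.
#' @export
read_field <- function(dir, well, field) {
  chans <- c("dna", "th", "asyn", "map2")
  out <- list()
  for (ch in chans) {
    path <- file.path(dir, "images", sprintf("%s_f%02d_%s.tif", well, field, ch))
    if (!file.exists(path))
      stop("missing channel image for well ", well, " field ", field,
           " channel ", ch, ": ", path)
    out[[ch]] <- round(tiff::readTIFF(path) * 65535)
  }
  out
}
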