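#' Robust scaling by median and interquartile range
#'
#' Per feature: `x' = (x - median(x)) / IQR(x)` with `IQR = Q3 - Q1`
#' (linear-interpolation quantiles). Features with zero IQR are centred only
#' and flagged. Scaling parameters are stored so they can be re-applied to
#' held-out rows (see [apply_robust_scale()]).
#'
#' @param table well feature table (metadata + feature columns).
#' @param cols feature columns to scale (default: all catalogue columns
#'   present).
#' @return the table with scaled feature columns; attributes
#'   `scale_center`, `scale_iqr` (named vectors) and `zero_iqr` (flagged
#'   feature names).
#' @export
robust_scale <- function(table, cols = feature_cols(table)) {
  if (nrow(table) < 2) stop("robust scaling needs at least 2 rows")
  center <- iqr <- stats::setNames(numeric(length(cols)), cols)
  for (nm in cols) {
    v <- table[[nm]]
    center[nm] <- stats::median(v, na.rm = TRUE)
    qs <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    iqr[nm] <- qs[2] - qs[1]
  }
  out <- apply_robust_scale(table, center, iqr, cols)
  attr(out, "scale_center") <- center
  attr(out, "scale_iqr") <- iqr
  attr(out, "zero_iqr") <- cols[iqr == 0]
  out
}

#' Apply stored robust-scaling parameters to new rows
#'
#' @param table well feature table.
#' @param center named vector of medians.
#' @param iqr named vector of IQRs (zero entries: centre only).
#' @param cols columns to transform.
#' @return transformed table.
#' @export
apply_robust_scale <- function(table, center, iqr, cols = names(center)) {
  for (nm in cols) {
    d <- if (iqr[nm] > 0) iqr[nm] else 1
    table[[nm]] <- (table[[nm]] - center[nm]) / d
  }
  table
}

#' Median-aggregate scaled wells into condition profiles
#'
#' One phenotypic profile per treatment condition: the per-feature median of
#' the scaled well rows belonging to that condition.
#'
#' @param scaled scaled well table (from [robust_scale()]).
#' @param by character vector of metadata columns defining a condition.
#' @return matrix: rows = conditions (named `compound_dose`), columns = 126
#'   features.
#' @export
aggregate_profiles <- function(scaled, by = c("compound", "dose_uM")) {
  cols <- feature_cols(scaled)
  key <- do.call(paste, c(scaled[by], sep = "_"))
  u <- unique(key)
  prof <- matrix(NA_real_, length(u), length(cols), dimnames = list(u, cols))
  for (i in seq_along(u)) {
    sub <- scaled[key == u[i], cols, drop = FALSE]
    prof[i, ] <- vapply(sub, stats::median, 0, na.rm = TRUE)
  }
  prof
}

#' Pairwise cosine distances and hierarchical clustering of profiles
#'
#' `d(u, v) = 1 - u.v / (|u| |v|)` for every profile pair, followed by
#' average-linkage agglomerative clustering on the distance matrix. The
#' condition dendrogram is also returned as a Newick string.
#'
#' @param profiles matrix (conditions x features) from [aggregate_profiles()].
#' @param linkage linkage method for [stats::hclust()].
#' @return list: `dist` (symmetric matrix, zero diagonal), `hclust`,
#'   `leaf_order` (condition names in dendrogram order), `newick`.
#' @export
cosine_distance_matrix <- function(profiles, linkage = "average") {
  if (nrow(profiles) < 2) stop("need at least 2 profiles")
  profiles[is.na(profiles)] <- 0
  nrm <- sqrt(rowSums(profiles^2))
  if (any(nrm < 1e-12))
    stop("zero-norm profile vector for condition: ",
         paste(rownames(profiles)[nrm < 1e-12], collapse = ", "))
  U <- profiles / nrm
  D <- 1 - tcrossprod(U)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D[D < 0] <- 0
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  nwk <- if (nrow(profiles) > 2)
    ape::write.tree(ape::as.phylo(hc)) else
    paste0("(", rownames(profiles)[1], ",", rownames(profiles)[2], ");")
  list(dist = D, hclust = hc, leaf_order = rownames(profiles)[hc$order],
       newick = nwk)
}

#' Cosine distance between two vectors
#'
#' @param u,v numeric vectors.
#' @return `1 - cos(u, v)`.
#' @export
cosine_distance <- function(u, v) {
  1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

#' Embed scaled well rows in two dimensions
#'
#' UMAP (via uwot, single-threaded for reproducibility) or PCA of the scaled
#' feature rows. If `labels` are supplied, the mean silhouette width of the
#' grouping on the embedded coordinates is reported as a separation
#' diagnostic.
#'
#' @param scaled scaled well table or numeric matrix.
#' @param method `"umap"` or `"pca"`.
#' @param seed integer seed (recorded in the result).
#' @param labels optional grouping (e.g. treated/control) for the silhouette.
#' @param n_neighbors UMAP neighbourhood size (capped at n-1).
#' @return list: `coords` (n x 2), `method`, `seed`, `silhouette` (or NA).
#' @export
embed_wells <- function(scaled, method = c("umap", "pca"), seed = 1L,
                        labels = NULL, n_neighbors = 15L) {
  method <- match.arg(method)
  X <- if (is.matrix(scaled)) scaled else
    as.matrix(scaled[, feature_cols(scaled), drop = FALSE])
  X[is.na(X)] <- 0
  if (nrow(X) < 10) stop("need at least 10 rows to embed")
  degenerate <- all(apply(X, 2, stats::sd) < 1e-12)
  if (degenerate) {
    warning("embedding input is degenerate (identical rows)")
    coords <- matrix(0, nrow(X), 2)
  } else if (method == "umap") {
    set.seed(seed)
    coords <- uwot::umap(X, n_neighbors = min(n_neighbors, nrow(X) - 1),
                         n_threads = 1, n_sgd_threads = 0)
  } else {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    coords <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  }
  colnames(coords) <- c("dim1", "dim2")
  sil <- NA_real_
  if (!is.null(labels) && length(unique(labels)) > 1 && !degenerate)
    sil <- mean_silhouette(coords, labels)
  list(coords = coords, method = method, seed = seed, silhouette = sil)
}

# mean silhouette width of a labelled embedding (euclidean)
mean_silhouette <- function(coords, labels) {
  D <- as.matrix(stats::dist(coords))
  labels <- as.character(labels)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
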