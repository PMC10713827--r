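#' Normalize well features to plate controls
#'
#' Divides each feature by the mean of the vehicle (control) wells, computed
#' per replicate plate when `by_replicate` is TRUE, so that control-mean
#' values are 1 and effects read as fold changes.
#'
#' @param table well feature table (unscaled).
#' @param cols feature columns to normalize (default: all catalogue columns).
#' @param by_replicate normalize within each replicate plate (default TRUE
#'   when a `replicate` column is present).
#' @return the table with normalized feature columns.
#' @export
normalize_to_control <- function(table, cols = feature_cols(table),
                                 by_replicate = "replicate" %in% names(table)) {
  groups <- if (by_replicate) split(seq_len(nrow(table)), table$replicate)
            else list(seq_len(nrow(table)))
  for (idx in groups) {
    ctrl <- idx[table$compound[idx] == "vehicle"]
    if (length(ctrl) < 2)
      stop("need at least 2 control wells per plate to normalize")
    for (nm in cols) {
      m <- mean(table[[nm]][ctrl], na.rm = TRUE)
      if (!is.finite(m) || m == 0)
        stop("control mean is zero or undefined for feature: ", nm)
      table[[nm]][idx] <- table[[nm]][idx] / m
    }
  }
  table
}

#' Significance-star tier for an adjusted p-value
#'
#' `ns` above 0.05, then `*`, `**`, `***` at the 0.05 / 0.01 / 0.001 tiers.
#'
#' @param p p-value(s).
#' @param tiers the three thresholds (descending).
#' @return character vector of star labels.
#' @export
star_tier <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < tiers[3]) "***"
    else if (pi < tiers[2]) "**"
    else if (pi < tiers[1]) "*"
    else "ns"
  }, "")
}

#' One-way ANOVA with Tukey HSD dose-vs-vehicle contrasts
#'
#' For a single feature and compound: one-way ANOVA of the feature across
#' groups (vehicle plus each dose of the compound). When the ANOVA is
#' significant at `alpha`, Tukey's HSD provides family-wise adjusted
#' p-values for every dose-vs-vehicle contrast; otherwise all contrasts are
#' reported as non-significant with `p_adj = NA`.
#'
#' @param values numeric feature values per well.
#' @param group factor/character group per well; the reference level is
#'   `ref`.
#' @param ref reference group name (default `"vehicle"`).
#' @param alpha ANOVA gate (default 0.05).
#' @return list: `anova_p`, and `contrasts` data.frame with `group`,
#'   `diff`, `p_unadjusted` (pooled-variance t-test on the ANOVA model, no
#'   multiplicity correction — comparable to the Tukey p on the same
#'   model), `p_adj` (Tukey), `stars`.
#' @export
anova_tukey <- function(values, group, ref = "vehicle", alpha = 0.05) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group)[keep]
  if (!ref %in% group) stop("reference group not present: ", ref)
  lv <- c(ref, setdiff(unique(group), ref))
  g <- factor(group, levels = lv)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 wells")
  fit <- stats::aov(values ~ g)
  p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
  others <- lv[-1]
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  p_un <- diffs <- stats::setNames(rep(NA_real_, length(others)), others)
  for (o in others) {
    a <- values[g == o]; b <- values[g == ref]
    diffs[o] <- mean(a) - mean(b)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    p_un[o] <- if (se > 0)
      2 * stats::pt(-abs(diffs[o] / se), fit$df.residual) else NA_real_
  }
  p_adj <- stats::setNames(rep(NA_real_, length(others)), others)
  if (is.finite(p_anova) && p_anova < alpha) {
    tk <- stats::TukeyHSD(fit)$g
    want <- paste0(others, "-", ref)
    hit <- match(want, rownames(tk))
    p_adj[!is.na(hit)] <- tk[hit[!is.na(hit)], "p adj"]
  }
  stars <- star_tier(p_adj)
  stars[is.na(stars)] <- "ns"
  list(anova_p = p_anova,
       contrasts = data.frame(group = others, diff = unname(diffs),
                              p_unadjusted = unname(p_un),
                              p_adj = unname(p_adj), stars = stars,
                              stringsAsFactors = FALSE))
}

#' Dose-response statistics table
#'
#' For each headline feature and compound: control-normalized group means
#' with t-based 95% confidence intervals at every dose, the one-way ANOVA
#' p-value over vehicle + doses, and Tukey-adjusted dose-vs-vehicle
#' p-values with star tiers.
#'
#' @param table well feature table (unscaled; will be control-normalized).
#' @param features feature names to analyse (default [headline_features()]).
#' @param config pipeline config (significance tiers).
#' @return data.frame: `feature`, `compound`, `dose_uM`, `n`,
#'   `mean_norm`, `ci_lo`, `ci_hi`, `anova_p`, `p_adj`, `stars`.
#' @export
dose_response_table <- function(table, features = headline_features(),
                                config = default_config()) {
  features <- intersect(features, names(table))
  table <- normalize_to_control(table, cols = features)
  compounds <- setdiff(unique(table$compound), "vehicle")
  rows <- list()
  for (ft in features) {
    for (cmp in compounds) {
      sub <- table[table$compound %in% c("vehicle", cmp), , drop = FALSE]
      grp <- ifelse(sub$compound == "vehicle", "vehicle",
                    as.character(sub$dose_uM))
      at <- anova_tukey(sub[[ft]], grp, alpha = config$alpha_tiers[1])
      for (d in sort(unique(sub$dose_uM[sub$compound == cmp]))) {
        v <- sub[[ft]][sub$compound == cmp & sub$dose_uM == d]
        n <- sum(!is.na(v)); m <- mean(v, na.rm = TRUE)
        se <- stats::sd(v, na.rm = TRUE) / sqrt(n)
        hw <- if (n > 1) stats::qt(0.975, n - 1) * se else NA_real_
        key <- as.character(d)
        ci <- at$contrasts[at$contrasts$group == key, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          feature = ft, compound = cmp, dose_uM = d, n = n,
          mean_norm = m, ci_lo = m - hw, ci_hi = m + hw,
          anova_p = at$anova_p,
          p_adj = if (nrow(ci)) ci$p_adj else NA_real_,
          stars = if (nrow(ci)) ci$stars else "ns",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
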