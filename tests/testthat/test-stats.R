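stats_table <- function(seed = 1, effect = 0) {
  set.seed(seed)
  n_per <- 6
  groups <- c("vehicle", "0.01", "0.1", "1", "2")
  tab <- data.frame(
    compound = rep(c("vehicle", rep("BPA", 4)), each = n_per),
    dose_uM = rep(c(0, 0.01, 0.1, 1, 2), each = n_per),
    replicate = rep(1:2, length.out = 5 * n_per))
  tab$feat <- stats::rnorm(nrow(tab), mean = 10, sd = 1) +
    effect * tab$dose_uM
  tab
}

test_that("control normalization makes the control mean exactly 1", {
  tab <- stats_table()
  norm <- normalize_to_control(tab, cols = "feat", by_replicate = FALSE)
  expect_equal(mean(norm$feat[norm$compound == "vehicle"]), 1)
  # per-replicate route normalizes within each replicate
  norm2 <- normalize_to_control(tab, cols = "feat", by_replicate = TRUE)
  for (r in 1:2)
    expect_equal(mean(norm2$feat[norm2$compound == "vehicle" &
                                   norm2$replicate == r]), 1)
})

test_that("normalization rejects missing or degenerate controls", {
  tab <- stats_table()
  expect_error(normalize_to_control(tab[tab$compound != "vehicle", ],
                                    cols = "feat", by_replicate = FALSE),
               "control wells")
  tab$feat[tab$compound == "vehicle"] <- 0
  expect_error(normalize_to_control(tab, cols = "feat", by_replicate = FALSE),
               "zero")
})

test_that("star tiers switch exactly at 0.05 / 0.01 / 0.001", {
  expect_equal(star_tier(c(0.2, 0.05, 0.049, 0.01, 0.009, 0.001, 0.0009)),
               c("ns", "ns", "*", "*", "**", "**", "***"))
  expect_true(is.na(star_tier(NA_real_)))
})

test_that("anova_tukey detects a strong dose effect", {
  tab <- stats_table(seed = 2, effect = 2)
  grp <- ifelse(tab$compound == "vehicle", "vehicle", as.character(tab$dose_uM))
  at <- anova_tukey(tab$feat, grp)
  expect_lt(at$anova_p, 0.001)
  top <- at$contrasts[at$contrasts$group == "2", ]
  expect_lt(top$p_adj, 0.001)
  expect_equal(top$stars, "***")
})

test_that("Tukey adjusted p-values are never below the unadjusted ones", {
  for (s in 1:5) {
    tab <- stats_table(seed = 10 + s, effect = 0.5)
    grp <- ifelse(tab$compound == "vehicle", "vehicle",
                  as.character(tab$dose_uM))
    at <- anova_tukey(tab$feat, grp)
    ok <- !is.na(at$contrasts$p_adj)
    expect_true(all(at$contrasts$p_adj[ok] >=
                      at$contrasts$p_unadjusted[ok] - 1e-9))
  }
})

test_that("Tukey matches a direct TukeyHSD oracle", {
  tab <- stats_table(seed = 3, effect = 2)
  grp <- factor(ifelse(tab$compound == "vehicle", "vehicle",
                       as.character(tab$dose_uM)),
                levels = c("vehicle", "0.01", "0.1", "1", "2"))
  at <- anova_tukey(tab$feat, as.character(grp))
  tk <- stats::TukeyHSD(stats::aov(tab$feat ~ grp))$grp
  for (g in at$contrasts$group) {
    expect_equal(at$contrasts$p_adj[at$contrasts$group == g],
                 unname(tk[paste0(g, "-vehicle"), "p adj"]))
  }
})

test_that("non-significant ANOVA gates off the post-hoc contrasts", {
  # identical groups: most seeds give ANOVA p > 0.05 -> p_adj all NA
  found <- FALSE
  for (s in 1:10) {
    tab <- stats_table(seed = 100 + s, effect = 0)
    grp <- ifelse(tab$compound == "vehicle", "vehicle",
                  as.character(tab$dose_uM))
    at <- anova_tukey(tab$feat, grp)
    if (at$anova_p >= 0.05) {
      expect_true(all(is.na(at$contrasts$p_adj)))
      expect_true(all(at$contrasts$stars == "ns"))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("anova_tukey validates its inputs", {
  expect_error(anova_tukey(1:6, rep("a", 6)), "reference group")
  expect_error(anova_tukey(1:2, c("vehicle", "a")), "at least 2 wells")
})

test_that("the dose-response table covers features x compounds x doses", {
  wells <- fix_wells()
  ok <- !is.na(wells$n_living_cells) & wells$n_living_cells > 0
  dr <- dose_response_table(wells[ok, ], features = headline_features()[1:2])
  expect_equal(nrow(dr), 2 * 4 * 4)
  expect_true(all(dr$n >= 2))
  expect_true(all(dr$ci_lo <= dr$mean_norm & dr$mean_norm <= dr$ci_hi))
  expect_true(all(dr$stars %in% c("ns", "*", "**", "***")))
  # stars only when the adjusted p clears a tier
  sig <- !is.na(dr$p_adj) & dr$p_adj < 0.05
  expect_true(all(dr$stars[!sig] == "ns"))
  expect_true(all(dr$stars[sig] != "ns"))
})
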