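make_maps <- function(dims, mk, fa = 0.444, md = 2.735) {
  structure(list(mk = array(mk, dims), fa = array(fa, dims),
                 md = array(md, dims), s0 = array(1000, dims),
                 voxel_size = c(1, 1, 1), affine = diag(4)),
            class = "parameter_maps")
}

test_that("ROI means average non-sentinel voxels over central slices", {
  dims <- c(10, 8, 6)
  lab <- label_map(renaldki:::phantom_labels(dims))
  maps <- make_maps(dims, mk = 0.760)
  rm_ <- roi_means(maps, lab, slice_axis = 2, n_slices = 3)
  expect_equal(rm_$value[rm_$metric == "MK"], rep(0.760, 3))
  expect_setequal(rm_$region, c("CO", "OS", "IS"))
  # half sentinels, half value v -> mean v, with the count reflecting it
  maps2 <- make_maps(dims, mk = 0.5)
  sel <- which(lab$labels == 1)
  maps2$mk[sel[seq(1, length(sel), by = 2)]] <- NA
  rm2 <- roi_means(maps2, lab, n_slices = 6)
  row <- rm2[rm2$region == "CO" & rm2$metric == "MK", ]
  expect_equal(row$value, 0.5)
  expect_lt(row$n_voxels, length(which(lab$labels == 1)))
  # n_slices beyond the extent clips with a warning
  expect_warning(roi_means(maps, lab, n_slices = 99), "extent")
  # a region fully sentinel in the selected slices errors
  maps3 <- make_maps(dims, mk = NA_real_)
  expect_error(roi_means(maps3, lab), "region-missing")
})

test_that("ICC(2,1) matches an independent variance-components oracle", {
  skip_if_not_installed("lme4")
  set.seed(31)
  # fixed 6-subject x 2-rater table with subject and rater effects
  subj_eff <- stats::rnorm(6, 0, 0.05)
  rater_eff <- c(-0.01, 0.01)
  m <- outer(subj_eff, rater_eff, `+`) + 0.76 + stats::rnorm(12, 0, 0.02)
  res <- icc_absolute_agreement(m)
  long <- data.frame(y = as.numeric(m),
                     subject = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  fit <- lme4::lmer(y ~ 1 + (1 | subject) + (1 | rater), data = long,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- stats::setNames(vc$vcov, vc$grp)
  icc_reml <- v[["subject"]] / sum(v)
  expect_equal(res$icc, unname(icc_reml), tolerance = 0.05)
  expect_true(res$lower <= res$icc && res$icc <= res$upper)
  expect_error(icc_absolute_agreement(m[1:2, ]), "insufficient-data")
})

test_that("ICC is invariant to shifts and joint rescaling", {
  set.seed(32)
  m <- matrix(stats::rnorm(20, 10, 2), 10, 2) + stats::rnorm(10, 0, 3)
  base <- icc_absolute_agreement(m)$icc
  expect_equal(icc_absolute_agreement(m + 100)$icc, base, tolerance = 1e-12)
  expect_equal(icc_absolute_agreement(m * 7)$icc, base, tolerance = 1e-12)
})

test_that("one-way ANOVA agrees with stats::aov to 1e-10", {
  set.seed(33)
  values <- stats::rnorm(24, rep(c(0.68, 0.79, 0.70, 0.69), each = 6), 0.03)
  groups <- rep(c("CON", "HUA", "AP", "AP+EM"), each = 6)
  mine <- anova_oneway(values, groups)
  ref <- summary(stats::aov(values ~ factor(groups)))[[1]]
  expect_equal(mine$f, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(mine$df_between, 3)
  expect_equal(mine$df_within, 20)
  # affine invariance of F
  shifted <- anova_oneway(5 + 3 * values, groups)
  expect_equal(shifted$f, mine$f, tolerance = 1e-10)
  # degenerate: all groups identical
  same <- anova_oneway(rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
})

test_that("ANOVA type-I error is calibrated at the null", {
  set.seed(34)
  p <- vapply(1:5000, function(i) {
    anova_oneway(stats::rnorm(24), rep(1:4, each = 6))$p
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("LSD post-hoc equals pooled pairwise t statistics", {
  set.seed(35)
  values <- stats::rnorm(24, rep(c(0.68, 0.79, 0.70, 0.69), each = 6), 0.03)
  groups <- rep(c("CON", "HUA", "AP", "AP+EM"), each = 6)
  a <- anova_oneway(values, groups)
  ph <- lsd_posthoc(values, groups)
  expect_equal(nrow(ph), 6)
  # formula oracle for one pair
  i <- which(ph$group_a == "CON" & ph$group_b == "HUA")
  m <- tapply(values, groups, mean)
  t_direct <- (m[["CON"]] - m[["HUA"]]) / sqrt(a$mse * (1 / 6 + 1 / 6))
  expect_equal(ph$t[i], t_direct, tolerance = 1e-12)
  expect_equal(ph$p[i], 2 * stats::pt(abs(t_direct), 20, lower.tail = FALSE),
               tolerance = 1e-12)
  # k = 2: LSD is exactly the pooled two-sample t test
  v2 <- values[1:12]; g2 <- groups[1:12]
  lsd2 <- lsd_posthoc(v2, g2)
  tt <- stats::t.test(v2[g2 == "CON"], v2[g2 == "HUA"], var.equal = TRUE)
  expect_equal(abs(lsd2$t), abs(unname(tt$statistic)), tolerance = 1e-12)
  expect_equal(lsd2$p, tt$p.value, tolerance = 1e-12)
  # identical groups: t = 0, P = 1
  same <- lsd_posthoc(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Pearson correlation matches stats::cor.test to 1e-12", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1)
  set.seed(36)
  x <- stats::rnorm(10); y <- 0.5 * x + stats::rnorm(10)
  mine <- pearson_cor(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # direct covariance-ratio oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(mine$r, r_direct, tolerance = 1e-15)
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
  # symmetry and affine invariance
  expect_equal(pearson_cor(y, x)$r, mine$r, tolerance = 1e-15)
  expect_equal(pearson_cor(3 * x + 2, y)$r, mine$r, tolerance = 1e-12)
})

test_that("summary report assembles all strata and honors optional inputs", {
  tab <- simulate_cohort(n_subjects = 6, seed = 40)
  raters <- simulate_rater_pair(tab, 0.2, seed = 41)
  mk_rows <- tab[tab$metric == "MK" & tab$region %in% c("OS", "IS") &
                   tab$timepoint %in% c("1d", "5d", "9d"), ]
  fib <- simulate_fibrosis_scores(mk_rows$value, 0.687, seed = 42)
  fib_tab <- data.frame(subject = mk_rows$subject, timepoint = mk_rows$timepoint,
                        region = mk_rows$region, mod = fib$mod)
  rep_ <- summary_report(tab, raters, fib_tab)
  # cell means land within 2 SE of the generator's cell parameters
  ref <- reference_cohort_params()
  m <- merge(rep_$summary_table, ref,
             by = c("group", "timepoint", "region", "metric"))
  z <- abs(m$mean.x - m$mean.y) / (m$sd.y / sqrt(6))
  expect_gt(mean(z <= 2), 0.90)   # ~95% expected within 2 SE
  expect_true(all(z < 5))
  expect_equal(nrow(rep_$anova_table), 6 * 3 * 3)
  expect_true(all(rep_$anova_table$p >= 0 & rep_$anova_table$p <= 1))
  expect_true(all(rep_$icc_table$icc <= 1 & rep_$icc_table$icc >= -1))
  expect_true(all(rep_$icc_table$lower <= rep_$icc_table$icc))
  # correlations exist for MK in OS and IS
  expect_true(all(c("OS", "IS") %in% rep_$correlation_table$region))
  # no fibrosis input -> correlation table absent, rest populated
  rep2 <- summary_report(tab)
  expect_null(rep2$correlation_table)
  expect_null(rep2$icc_table)
  expect_gt(nrow(rep2$summary_table), 0)
  # single-timepoint table -> one ANOVA stratum per region x metric
  one <- tab[tab$timepoint == "9d", ]
  rep3 <- summary_report(one)
  expect_equal(unique(rep3$anova_table$timepoint), "9d")
  expect_equal(nrow(rep3$anova_table), 9)
})
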