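fake_records <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("S%03d", 1:n),
    age = sample(35:90, n, replace = TRUE),
    birads = sample(c("A", "B", "C", "D"), n, replace = TRUE),
    overall_pd = runif(n, 0, 60),
    pd_posterior = runif(n, 0, 60),
    pd_middle = runif(n, 0, 60),
    pd_anterior = runif(n, 0, 60),
    pattern = sample(c("clustered", "scattered"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("age groups split at 65 and BI-RADS collapses to two density groups", {
  expect_equal(age_group(c(35, 64, 65, 90)),
               c("mature", "mature", "older", "older"))
  expect_equal(density_group(c("A", "B", "C", "D")),
               c("less_dense", "less_dense", "denser", "denser"))
  expect_error(density_group("E"), "A, B, C, D")
})

test_that("age-PD correlation reproduces exact and degenerate cases", {
  rec <- data.frame(age = 40:60, overall_pd = 100 - (40:60))
  out <- correlate_age_pd(rec)
  expect_equal(out$r, -1)
  expect_lt(out$p_value, 1e-10)
  expect_error(correlate_age_pd(data.frame(age = c(50, 50, 50),
                                           overall_pd = c(1, 2, 3))),
               "constant")
  expect_error(correlate_age_pd(rec[1:2, ]), "at least 3")
})

test_that("pattern-by-group tables report counts, percentages and chi-square", {
  rec <- data.frame(
    birads = rep(c("A", "B"), each = 20),
    pattern = rep(c("clustered", "scattered", "clustered", "scattered"),
                  each = 10), stringsAsFactors = FALSE)
  out <- pattern_by_group_table(rec, "birads")
  expect_equal(unname(out$statistic), 0)
  expect_equal(out$p_value, 1)
  expect_true(all(abs(rowSums(out$row_pct) - 100) < 1e-12))
  rec$pattern <- "clustered"
  expect_error(pattern_by_group_table(rec, "birads"), "share the pattern")
})

test_that("group comparisons catch empty groups and full ties", {
  rec <- fake_records()
  out <- compare_zonal_across_groups(rec, "middle")
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_error(compare_zonal_across_groups(rec, "middle",
                                           groups = c("A", "B", "E")),
               "E")
  tied <- rec
  tied$pd_middle <- 7
  out0 <- compare_zonal_across_groups(tied, "middle")
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
})

test_that("within-subject zone comparison handles omnibus and pairwise cases", {
  rec <- fake_records(30)
  out <- compare_zonal_within_subject(rec)
  expect_equal(nrow(out$pairwise), 3)
  expect_true(all(out$pairwise$p_bonferroni >= out$pairwise$p_raw))
  expect_true(all(out$pairwise$p_bonferroni <= 1))
  # identical zones per subject: no evidence of any zone effect
  same <- rec
  same$pd_middle <- same$pd_anterior <- same$pd_posterior
  out0 <- compare_zonal_within_subject(same)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
  expect_true(all(out0$pairwise$p_raw == 1))
  # missing zone values are reported with the offending subjects
  broken <- rec
  broken$pd_middle[3] <- NA
  expect_error(compare_zonal_within_subject(broken), "S003")
  expect_error(compare_zonal_within_subject(rec[, -which(names(rec) ==
                                                           "pd_middle")]),
               "three zonal")
})

test_that("age-group Mann-Whitney compares zone medians two-sided", {
  rec <- fake_records(60, seed = 3)
  out <- compare_zonal_between_age_groups(rec, "middle")
  expect_true(out$p_value > 0 && out$p_value <= 1)
  expect_equal(sum(out$n), 60)
  # identical distributions: p near 1
  sym <- data.frame(age = rep(c(40, 80), each = 10),
                    pd_middle = rep(1:10, 2))
  expect_gt(compare_zonal_between_age_groups(sym, "middle")$p_value, 0.9)
  expect_error(compare_zonal_between_age_groups(
    data.frame(age = rep(40, 5), pd_middle = 1:5), "middle"), "nonempty")
  # a large planted shift is detected
  shifted <- data.frame(age = rep(c(40, 80), each = 30),
                        pd_middle = c(rnorm(30, 30, 5), rnorm(30, 10, 5)))
  expect_lt(compare_zonal_between_age_groups(shifted, "middle")$p_value, 0.001)
})

test_that("mean regional heatmaps average cell-wise within groups", {
  x <- matrix(runif(48, 0, 50), 8, 6)
  out <- mean_regional_heatmap(list(x, 2 * x, x), c("g1", "g1", "g2"))
  expect_equal(out$g1, 1.5 * x)
  expect_equal(out$g2, x)
  expect_error(mean_regional_heatmap(list(x, matrix(0, 4, 6)), c("a", "b")),
               "inconsistent")
  expect_error(mean_regional_heatmap(list(x), c("a", "b")), "one group label")
})

test_that("cohort analysis recovers the planted qualitative contrasts", {
  co <- generate_cohort(120, seed = 8,
                        clustered_share_by_group = c(A = 0.85, B = 0.80,
                                                     C = 0.35, D = 0.30))
  res <- analyze_cohort(co)
  rec <- res$records
  # negative age-density correlation
  expect_lt(correlate_age_pd(rec)$r, 0)
  # clustered-pattern share higher in the less dense groups
  tab <- pattern_by_group_table(rec, "density_group")
  expect_gt(tab$row_pct["less_dense", "clustered"],
            tab$row_pct["denser", "clustered"])
  # mature subjects carry the planted middle-zone excess
  mw <- compare_zonal_between_age_groups(rec, "middle")
  expect_gt(mw$medians["mature"], mw$medians["older"])
  # heatmap argmax column band sits in the middle zone for middle placements
  mid <- which(rec$placement == "middle")
  hm <- mean_regional_heatmap(res$grids[mid], rep("middle", length(mid)))
  col_means <- colMeans(hm$middle)
  expect_true(which.max(col_means) %in% 3:4)
})

test_that("zonal summaries report median, IQR and SD per group and zone", {
  rec <- fake_records(50, seed = 6)
  rec$age_group <- age_group(rec$age)
  zs <- zonal_summary(rec, grouping = "age_group")
  expect_equal(nrow(zs), 6)
  row <- zs[zs$group == "mature" & zs$zone == "middle", ]
  v <- rec$pd_middle[rec$age_group == "mature"]
  expect_equal(row$median, median(v))
  expect_equal(row$iqr, IQR(v))
  expect_equal(row$sd, sd(v))
  expect_equal(nrow(zonal_summary(rec)), 3)
})
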