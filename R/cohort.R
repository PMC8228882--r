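#' Age-group and density-group rules
#'
#' `age_group()` labels subjects mature (ages 35-64) or older (65-90);
#' `density_group()` collapses BI-RADS categories into less dense ({A, B})
#' vs. denser ({C, D}) breasts.
#'
#' @param age Numeric ages in years.
#' @param cutoff First age counted as older; default 65.
#' @return Character vector of labels.
#' @export
age_group <- function(age, cutoff = 65) {
  ifelse(age >= cutoff, "older", "mature")
}

#' @rdname age_group
#' @param birads Character/factor vector with levels among A-D.
#' @export
density_group <- function(birads) {
  birads <- as.character(birads)
  if (!all(birads %in% c("A", "B", "C", "D"))) {
    stop("birads labels must be among A, B, C, D", call. = FALSE)
  }
  ifelse(birads %in% c("A", "B"), "less_dense", "denser")
}

#' Pearson correlation of overall percent density with age
#'
#' @param records Data frame with columns `age` and `overall_pd`.
#' @return List with `r`, `p_value`, `n`, and the underlying `htest`.
#' @export
correlate_age_pd <- function(records) {
  x <- records$age; y <- records$overall_pd
  if (length(x) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("age or overall PD is constant: correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x),
       test = ht)
}

#' Spatial-pattern by group contingency table with chi-square test
#'
#' Tabulates the clustered / random / scattered pattern counts per group
#' (BI-RADS category, collapsed density group, or age group) and tests
#' independence with Pearson's chi-square. Row percentages are reported per
#' group; a low-expected-count condition is surfaced as a flag, not a
#' failure.
#'
#' @param records Record table from [analyze_cohort()] (needs `pattern` and
#'   the grouping column).
#' @param grouping `"birads"`, `"density_group"`, or `"age_group"`.
#' @return List: `counts` (groups x patterns), `row_pct`, `statistic`, `df`,
#'   `p_value`, `low_expected`.
#' @export
pattern_by_group_table <- function(records,
                                   grouping = c("birads", "density_group",
                                                "age_group")) {
  grouping <- match.arg(grouping)
  g <- switch(grouping,
              birads = records$birads,
              density_group = records$density_group %||%
                density_group(records$birads),
              age_group = records$age_group %||% age_group(records$age))
  tab <- table(group = g, pattern = records$pattern)
  if (ncol(tab) < 2) {
    stop(sprintf("all subjects share the pattern '%s': independence test undefined",
                 colnames(tab)[1]), call. = FALSE)
  }
  if (nrow(tab) < 2) stop("need at least two groups", call. = FALSE)
  low_expected <- FALSE
  ht <- withCallingHandlers(
    stats::chisq.test(tab, correct = FALSE),
    warning = function(w) {
      low_expected <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(counts = tab, row_pct = 100 * prop.table(tab, margin = 1),
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, low_expected = low_expected)
}

zone_column <- function(zone) {
  zone <- match.arg(zone, c("posterior", "middle", "anterior"))
  paste0("pd_", zone)
}

#' Kruskal-Wallis comparison of a zonal PD across groups
#'
#' @param records Record table with zonal PD columns (`pd_posterior`, ...).
#' @param zone `"posterior"`, `"middle"`, or `"anterior"`.
#' @param grouping Grouping column name (default `"birads"`).
#' @param groups Groups that must be present; defaults to those observed.
#' @return List with `statistic` (H), `df`, `p_value`, `n_per_group`.
#' @export
compare_zonal_across_groups <- function(records, zone, grouping = "birads",
                                        groups = NULL) {
  col <- zone_column(zone)
  g <- as.character(records[[grouping]])
  if (is.null(groups)) groups <- sort(unique(g))
  missing_g <- setdiff(groups, g)
  if (length(missing_g) > 0) {
    stop(sprintf("group(s) with no observations: %s",
                 paste(missing_g, collapse = ", ")), call. = FALSE)
  }
  keep <- g %in% groups
  v <- records[[col]][keep]
  if (length(unique(v)) == 1L) {
    # every observation tied: no evidence of any location shift
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                n_per_group = table(g[keep])))
  }
  ht <- stats::kruskal.test(v, factor(g[keep], levels = groups))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n_per_group = table(g[keep]))
}

#' Within-subject comparison of the three zonal PDs
#'
#' Friedman omnibus test over the posterior / middle / anterior PDs of each
#' subject (each subject is its own block), followed by the three pairwise
#' Wilcoxon signed-rank comparisons. Pairwise p-values are reported raw and
#' Bonferroni-adjusted.
#'
#' @param records Record table with complete `pd_posterior`, `pd_middle`,
#'   `pd_anterior` columns.
#' @return List: `statistic` (Friedman chi-square), `df`, `p_value`,
#'   `medians`, and `pairwise` (data frame: pair, p_raw, p_bonferroni).
#' @export
compare_zonal_within_subject <- function(records) {
  cols <- c("pd_posterior", "pd_middle", "pd_anterior")
  if (!all(cols %in% names(records))) {
    stop("all three zonal PD columns are required", call. = FALSE)
  }
  m <- as.matrix(records[, cols])
  bad <- which(!stats::complete.cases(m))
  if (length(bad) > 0) {
    stop(sprintf("missing zonal PDs for subject(s): %s",
                 paste(utils::head(records$id[bad], 10), collapse = ", ")),
         call. = FALSE)
  }
  ht <- stats::friedman.test(m)
  stat <- unname(ht$statistic); p_om <- ht$p.value
  if (!is.finite(stat)) {          # every subject's zones fully tied
    stat <- 0; p_om <- 1
  }
  pairs <- list(c("anterior", "posterior"), c("anterior", "middle"),
                c("posterior", "middle"))
  p_raw <- vapply(pairs, function(pr) {
    d <- records[[zone_column(pr[1])]] - records[[zone_column(pr[2])]]
    if (all(d == 0)) return(1)     # no nonzero paired differences
    suppressWarnings(stats::wilcox.test(records[[zone_column(pr[1])]],
                                        records[[zone_column(pr[2])]],
                                        paired = TRUE)$p.value)
  }, numeric(1))
  list(statistic = stat, df = unname(ht$parameter),
       p_value = p_om,
       medians = apply(m, 2, stats::median),
       pairwise = data.frame(
         pair = vapply(pairs, paste, character(1), collapse = "-"),
         p_raw = p_raw,
         p_bonferroni = stats::p.adjust(p_raw, method = "bonferroni"),
         stringsAsFactors = FALSE))
}

#' Mann-Whitney comparison of a zonal PD between age groups
#'
#' Two-sided Wilcoxon rank-sum test of the chosen zone's PD between mature
#' (< 65) and older (>= 65) subjects. The exact null distribution is used
#' when both groups have at most 20 observations (and no ties); larger
#' samples use the normal approximation with continuity and tie correction.
#'
#' @param records Record table with `age` (or `age_group`) and zonal PDs.
#' @param zone `"posterior"`, `"middle"`, or `"anterior"`.
#' @return List with `statistic` (U), `p_value`, `n`, `medians`.
#' @export
compare_zonal_between_age_groups <- function(records, zone) {
  col <- zone_column(zone)
  grp <- records$age_group %||% age_group(records$age)
  x <- records[[col]][grp == "mature"]
  y <- records[[col]][grp == "older"]
  if (length(x) == 0 || length(y) == 0) {
    stop("both age groups must be nonempty", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = max(length(x), length(y)) <= 20,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = c(mature = length(x), older = length(y)),
       medians = c(mature = stats::median(x), older = stats::median(y)))
}

#' Group-wise mean regional PD matrices
#'
#' Cell-wise arithmetic mean of the 8 x 6 regional PD matrices within each
#' group — the numbers behind the stratified regional-density heatmaps.
#'
#' @param grids List of `density_grid` objects (or plain matrices).
#' @param group Grouping vector, one entry per grid.
#' @return Named list of mean matrices, one per group level.
#' @export
mean_regional_heatmap <- function(grids, group) {
  mats <- lapply(grids, function(g) if (inherits(g, "density_grid")) g$pd else g)
  if (length(mats) != length(group)) {
    stop("one group label per grid is required", call. = FALSE)
  }
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1) stop("inconsistent grid shapes", call. = FALSE)
  lapply(split(seq_along(mats), group), function(ix) {
    Reduce(`+`, mats[ix]) / length(ix)
  })
}

#' Simulate a null cohort record table
#'
#' Draws a per-subject record table with no planted effects: ages uniform on
#' 35-90, overall and zonal PDs independent of age and of each other (zones
#' exchangeable within subject), BI-RADS groups uniform over A-D, and
#' spatial patterns Bernoulli with the same clustered probability in every
#' group. Used to calibrate the type-I error of the cohort tests, which are
#' functions of the record table alone.
#'
#' @param n Number of subjects.
#' @param seed Integer RNG seed.
#' @param clustered_prob Common clustered-pattern probability.
#' @return Record data frame compatible with the cohort test functions.
#' @export
simulate_null_records <- function(n = 80, seed = 1, clustered_prob = 0.5) {
  with_preserved_seed(seed, {
    rec <- data.frame(
      id = sprintf("N%04d", seq_len(n)),
      age = sample(35:90, n, replace = TRUE),
      birads = sample(c("A", "B", "C", "D"), n, replace = TRUE),
      overall_pd = stats::runif(n, 0, 60),
      pd_posterior = stats::runif(n, 0, 60),
      pd_middle = stats::runif(n, 0, 60),
      pd_anterior = stats::runif(n, 0, 60),
      pattern = ifelse(stats::runif(n) < clustered_prob, "clustered",
                       "scattered"),
      stringsAsFactors = FALSE)
    rec$age_group <- age_group(rec$age)
    rec$density_group <- density_group(rec$birads)
    rec
  })
}

#' Summarize zonal PDs by group
#'
#' Reports median, IQR and SD of each zone's PD, optionally stratified by a
#' grouping column. All three spread conventions are emitted side by side so
#' summaries can be compared against reports that pair medians with either
#' the IQR or the SD.
#'
#' @param records Record table with zonal PD columns.
#' @param grouping Optional grouping column name (e.g. `"age_group"`).
#' @return Data frame with one row per zone (and group).
#' @export
zonal_summary <- function(records, grouping = NULL) {
  zones <- c("posterior", "middle", "anterior")
  groups <- if (is.null(grouping)) list(all = seq_len(nrow(records))) else
    split(seq_len(nrow(records)), records[[grouping]])
  out <- do.call(rbind, lapply(names(groups), function(gn) {
    ix <- groups[[gn]]
    do.call(rbind, lapply(zones, function(z) {
      v <- records[[zone_column(z)]][ix]
      data.frame(group = gn, zone = z, n = length(v),
                 median = stats::median(v), iqr = stats::IQR(v),
                 sd = stats::sd(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
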