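# Subject-level aggregation and cohort group comparisons. Distributions of
# PI and lag across vessels are skewed, so each subject contributes the
# median across its vessels; group inference then runs across subjects.

.vein_classes <- c("small_vein", "surface_vein")

#' Summarize one subject's vessel results
#'
#' Collapses a per-vessel pulsatility table to subject-level summaries:
#' vessel and pulsatile counts, and medians of PI and temporal lag across
#' vessels, for the groupings small veins / surface veins / all veins /
#' arteries. Medians of PI and lag are taken over pulsatile vessels only;
#' empty groups are recorded as missing (NA), not dropped. Mean |v| is
#' reported separately for pulsatile and non-pulsatile veins.
#'
#' @param results per-vessel data frame from
#'   \code{\link{vessel_pulsatility}}.
#' @param subject subject identifier.
#' @return object of class \code{subject_summary}: \code{groups} (counts and
#'   medians per grouping), \code{territories} (per-territory medians for
#'   veins and arteries), and \code{speed} (mean |v| of pulsatile vs
#'   non-pulsatile veins).
#' @export
summarize_subject <- function(results, subject = NA) {
  stopifnot(nrow(results) >= 1)
  is_vein <- results$class_label %in% .vein_classes
  pick <- list(small_vein = results$class_label == "small_vein",
               surface_vein = results$class_label == "surface_vein",
               all_veins = is_vein,
               artery = results$class_label == "artery")
  groups <- do.call(rbind, lapply(names(pick), function(g) {
    r <- results[pick[[g]], ]
    rp <- r[r$pulsatile, ]
    data.frame(group = g, n = nrow(r), n_pulsatile = nrow(rp),
               median_pi = if (nrow(rp)) median(rp$pi) else NA_real_,
               median_lag_ms = if (nrow(rp)) median(rp$lag_ms) else NA_real_)
  }))
  veins <- results[is_vein, ]
  terr <- expand.grid(group = c("veins", "arteries"),
                      territory = .territories,
                      stringsAsFactors = FALSE)
  terr$median_lag_ms <- NA_real_
  terr$median_pi <- NA_real_
  for (i in seq_len(nrow(terr))) {
    r <- if (terr$group[i] == "veins") veins else
      results[results$class_label == "artery", ]
    rp <- r[r$pulsatile & r$territory == terr$territory[i], ]
    if (nrow(rp)) {
      terr$median_lag_ms[i] <- median(rp$lag_ms)
      if (terr$group[i] == "veins") terr$median_pi[i] <- median(rp$pi)
    }
  }
  speed <- data.frame(
    mean_abs_speed_pulsatile =
      if (any(veins$pulsatile)) mean(veins$mean_abs_speed[veins$pulsatile])
      else NA_real_,
    mean_abs_speed_nonpulsatile =
      if (any(!veins$pulsatile)) mean(veins$mean_abs_speed[!veins$pulsatile])
      else NA_real_)
  structure(list(subject = subject, groups = groups, territories = terr,
                 speed = speed),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat("subject_summary:", x$subject, "\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

.pull_group <- function(summaries, group, col) {
  vapply(summaries, function(s) {
    s$groups[[col]][s$groups$group == group]
  }, 0)
}

# one-sample two-tailed t; degenerate zero-variance samples resolve to the
# limit (t = 0, p = 1 when the null is exactly true; |t| = Inf, p = 0 when
# every subject shows the same nonzero effect)
.safe_t <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (sd(x) == 0) {
    m <- mean(x) - mu
    list(statistic = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
         p.value = if (m == 0) 1 else 0)
  } else {
    tt <- t.test(x, mu = mu)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value)
  }
}

.one_sample_row <- function(test, group, vals, n_comparisons) {
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) {
    # a grouping absent from the cohort is reported as missing, not fatal
    return(data.frame(test = test, group = group, statistic = NA_real_,
                      df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                      p_corrected = NA_real_))
  }
  tt <- .safe_t(vals)
  data.frame(test = test, group = group,
             statistic = tt$statistic, df1 = NA_real_,
             df2 = tt$df, p = tt$p.value,
             p_corrected = min(1, tt$p.value * n_comparisons))
}

.anova_row <- function(test, group, df) {
  df <- df[!is.na(df$value), ]
  df$territory <- droplevels(factor(df$territory))
  if (nrow(df) < 3 || nlevels(df$territory) < 2) {
    return(data.frame(test = test, group = group, statistic = NA_real_,
                      df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                      p_corrected = NA_real_))
  }
  fit <- aov(value ~ territory, data = df)
  s <- summary(fit)[[1]]
  data.frame(test = test, group = group, statistic = s[["F value"]][1],
             df1 = s[["Df"]][1], df2 = s[["Df"]][2],
             p = s[["Pr(>F)"]][1], p_corrected = NA_real_)
}

#' Cohort group comparisons
#'
#' Reproduces the study's group statistics across subjects:
#' \itemize{
#'   \item one-sample two-tailed t-tests of median temporal lag against
#'     zero for small veins, surface veins, all veins, and arteries, with
#'     Bonferroni correction for the four comparisons (p multiplied by 4,
#'     capped at 1);
#'   \item a paired t-test of PI between small and surface veins;
#'   \item one-way ANOVAs across the four vascular territories of vein lag,
#'     artery lag, and vein PI, on subject-by-territory medians, with
#'     missing subject-territory cells omitted from the affected ANOVA;
#'   \item a paired t-test of mean |v| between pulsatile and non-pulsatile
#'     veins.
#' }
#'
#' @param summaries list of \code{\link{summarize_subject}} results
#'   (>= 2 subjects).
#' @return data frame with columns test, group, statistic (t or F), df1
#'   (ANOVA numerator df, NA for t-tests), df2, p, p_corrected. Groupings
#'   with fewer than two subjects of data yield NA rows; paired tests with
#'   fewer than two complete pairs are an error.
#' @export
group_tests <- function(summaries) {
  stopifnot(length(summaries) >= 2)
  n_corr <- 4
  out <- do.call(rbind, lapply(
    c("small_vein", "surface_vein", "all_veins", "artery"),
    function(g) .one_sample_row("lag_vs_zero", g,
                                .pull_group(summaries, g, "median_lag_ms"),
                                n_corr)))

  pi_small <- .pull_group(summaries, "small_vein", "median_pi")
  pi_surf <- .pull_group(summaries, "surface_vein", "median_pi")
  ok <- !is.na(pi_small) & !is.na(pi_surf)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs for the PI comparison")
  tt <- .safe_t(pi_small[ok] - pi_surf[ok])
  out <- rbind(out, data.frame(
    test = "pi_small_vs_surface", group = "veins",
    statistic = tt$statistic, df1 = NA_real_,
    df2 = tt$df, p = tt$p.value, p_corrected = NA_real_))

  terr_df <- function(group, col) {
    do.call(rbind, lapply(summaries, function(s) {
      t <- s$territories[s$territories$group == group, ]
      data.frame(subject = s$subject, territory = factor(t$territory),
                 value = t[[col]])
    }))
  }
  out <- rbind(out,
               .anova_row("lag_by_territory", "veins",
                          terr_df("veins", "median_lag_ms")),
               .anova_row("lag_by_territory", "arteries",
                          terr_df("arteries", "median_lag_ms")),
               .anova_row("pi_by_territory", "veins",
                          terr_df("veins", "median_pi")))

  sp <- do.call(rbind, lapply(summaries, function(s) s$speed))
  ok <- !is.na(sp[[1]]) & !is.na(sp[[2]])
  if (sum(ok) < 2) stop("fewer than 2 complete pairs for the |v| comparison")
  tt <- .safe_t(sp[[1]][ok] - sp[[2]][ok])
  out <- rbind(out, data.frame(
    test = "speed_pulsatile_vs_not", group = "veins",
    statistic = tt$statistic, df1 = NA_real_,
    df2 = tt$df, p = tt$p.value, p_corrected = NA_real_))
  rownames(out) <- NULL
  out
}
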