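# hand-built per-vessel results tables for aggregation tests
make_results <- function(class_label, pi, lag_ms, pulsatile = TRUE,
                         territory = "ACA", mean_abs_speed = 1) {
  n <- length(class_label)
  data.frame(cluster = seq_len(n), class_label = class_label,
             territory = rep_len(territory, n), size = 2,
             pcnr = ifelse(rep_len(pulsatile, n), 10, 1),
             delta_v = 0.3, res_sd = 0.03,
             pulsatile = rep_len(pulsatile, n), pi = pi,
             lag_samples = round(lag_ms / 23.1), lag_ms = lag_ms,
             mean_abs_speed = rep_len(mean_abs_speed, n))
}

test_that("subject summary takes medians over pulsatile vessels only", {
  r <- make_results(rep("small_vein", 4), pi = c(0.3, 0.5, 0.7, 9),
                    lag_ms = c(23.1, 46.2, 92.4, 999),
                    pulsatile = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarize_subject(r, "sub-01")
  g <- s$groups[s$groups$group == "small_vein", ]
  expect_equal(g$n, 4)
  expect_equal(g$n_pulsatile, 3)
  expect_equal(g$median_pi, 0.5)
  expect_equal(g$median_lag_ms, 46.2)
})

test_that("a single pulsatile vein yields singleton medians", {
  r <- make_results("surface_vein", pi = 0.3, lag_ms = 23.1)
  s <- summarize_subject(r)
  g <- s$groups[s$groups$group == "surface_vein", ]
  expect_equal(g$median_pi, 0.3)
  expect_equal(g$median_lag_ms, 23.1)
  # groups without vessels are recorded as missing, not dropped
  expect_true(is.na(s$groups$median_pi[s$groups$group == "artery"]))
  expect_equal(s$groups$n[s$groups$group == "artery"], 0)
})

test_that("mean |v| splits by pulsatility across veins", {
  r <- make_results(rep("small_vein", 4), pi = 0.3, lag_ms = 46.2,
                    pulsatile = c(TRUE, TRUE, FALSE, FALSE),
                    mean_abs_speed = c(1.0, 1.2, 0.4, 0.6))
  s <- summarize_subject(r)
  expect_equal(s$speed$mean_abs_speed_pulsatile, 1.1)
  expect_equal(s$speed$mean_abs_speed_nonpulsatile, 0.5)
})

test_that("zero lags across subjects give t = 0 and corrected p = 1", {
  summaries <- lapply(1:4, function(i) {
    summarize_subject(make_results(
      c("small_vein", "surface_vein", "artery"), pi = c(0.3, 0.3, NA),
      lag_ms = 0, territory = c("ACA", "L_MCA", "PCA"),
      mean_abs_speed = c(1, 1.2 + 0.1 * i, 5)), i)
  })
  # add non-pulsatile veins so the speed comparison has both arms
  summaries <- lapply(1:4, function(i) {
    r <- rbind(make_results(
      c("small_vein", "surface_vein", "artery"), pi = c(0.3, 0.32, NA),
      lag_ms = 0, territory = c("ACA", "L_MCA", "PCA"),
      mean_abs_speed = c(1, 1.2 + 0.05 * i, 5)),
      make_results("small_vein", pi = 0.1, lag_ms = 0, pulsatile = FALSE,
                   mean_abs_speed = 0.4 + 0.05 * i))
    summarize_subject(r, i)
  })
  tests <- group_tests(summaries)
  lag_rows <- tests[tests$test == "lag_vs_zero", ]
  expect_equal(lag_rows$statistic, rep(0, 4))
  expect_equal(lag_rows$p_corrected, rep(1, 4))
})

test_that("Bonferroni correction multiplies by four and caps at one", {
  set.seed(20)
  summaries <- lapply(1:6, function(i) {
    summarize_subject(make_results(
      c("small_vein", "surface_vein", "artery"),
      pi = c(0.3, 0.25, NA) + rnorm(3, sd = 0.02),
      lag_ms = c(60, 40, 5) + rnorm(3, sd = 15),
      territory = c("ACA", "L_MCA", "PCA"),
      mean_abs_speed = c(1 + 0.1 * rnorm(1), 1.2, 5)), i)
  })
  summaries <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    s$speed$mean_abs_speed_nonpulsatile <- 0.5 + 0.02 * i
    s
  })
  tests <- group_tests(summaries)
  lag_rows <- tests[tests$test == "lag_vs_zero", ]
  expect_equal(lag_rows$p_corrected, pmin(1, lag_rows$p * 4))
  expect_true(all(tests$p_corrected >= tests$p, na.rm = TRUE))
  # one-sample and paired tests report n - 1 degrees of freedom
  expect_equal(lag_rows$df2, rep(5, 4))
  expect_equal(tests$df2[tests$test == "pi_small_vs_surface"], 5)
})

test_that("ANOVA on identical territory groups gives F near zero", {
  summaries <- lapply(1:4, function(i) {
    r <- rbind(
      make_results(rep("small_vein", 4), pi = 0.3,
                   lag_ms = 40 + 5 * i,  # varies by subject, not territory
                   territory = c("ACA", "L_MCA", "R_MCA", "PCA"),
                   mean_abs_speed = 1),
      make_results("surface_vein", pi = 0.25 + 0.01 * i,
                   lag_ms = 40 + 5 * i, territory = "PCA",
                   mean_abs_speed = 1.5),
      make_results(rep("artery", 4), pi = NA, lag_ms = 5 * i,
                   territory = c("ACA", "L_MCA", "R_MCA", "PCA"),
                   mean_abs_speed = 5),
      make_results("small_vein", pi = 0.1, lag_ms = 0, pulsatile = FALSE,
                   mean_abs_speed = 0.5 + 0.01 * i))
    summarize_subject(r, i)
  })
  tests <- group_tests(summaries)
  f <- tests$statistic[tests$test == "lag_by_territory" &
                         tests$group == "veins"]
  expect_equal(f, 0, tolerance = 1e-9)
  expect_equal(tests$df1[tests$test == "lag_by_territory"], c(3, 3))
})

test_that("missing territory cells are dropped only from the ANOVA", {
  summaries <- lapply(1:5, function(i) {
    terr <- c("ACA", "L_MCA", "R_MCA", "PCA")
    r <- rbind(
      make_results(rep("small_vein", 4), pi = 0.3 + 0.01 * i,
                   lag_ms = c(40, 50, 60, 55) + i, territory = terr),
      make_results("surface_vein", pi = 0.24 + 0.02 * i, lag_ms = 45 + i,
                   territory = "L_MCA", mean_abs_speed = 1.4),
      make_results(rep("artery", 4), pi = NA, lag_ms = c(0, 5, -5, 3) + i,
                   territory = terr),
      make_results("small_vein", pi = 0.1, lag_ms = 0, pulsatile = FALSE,
                   mean_abs_speed = 0.5))
    if (i == 1) r <- r[r$territory != "ACA" | r$class_label != "small_vein", ]
    summarize_subject(r, i)
  })
  tests <- group_tests(summaries)
  vein_lag <- tests[tests$test == "lag_by_territory" &
                      tests$group == "veins", ]
  # 5 subjects x 4 territories minus one missing cell: 19 obs, df2 = 15
  expect_equal(vein_lag$df2, 15)
  art_lag <- tests[tests$test == "lag_by_territory" &
                     tests$group == "arteries", ]
  expect_equal(art_lag$df2, 16)
})

test_that("group tests require at least two subjects", {
  s <- summarize_subject(make_results("small_vein", 0.3, 46.2), 1)
  expect_error(group_tests(list(s)))
})
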