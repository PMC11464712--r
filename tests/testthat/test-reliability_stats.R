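test_that("perfect agreement gives ICC 1 and systematic offsets are penalized", {
  m <- cbind(c(10, 12, 15, 18, 20), c(10, 12, 15, 18, 20), c(10, 12, 15, 18, 20))
  res <- icc_absolute(m)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_equal(res$category, "excellent")

  # identical row profile, large constant column offsets: absolute agreement
  # collapses even though consistency would be perfect
  base <- c(10, 12, 15, 18, 20)
  m_off <- cbind(base, base + 30, base + 60)
  res_off <- icc_absolute(m_off)
  expect_lt(res_off$estimate, 0.05)

  expect_error(icc_absolute(matrix(5, 4, 3)), "zero total variance")
  expect_error(icc_absolute(cbind(c(1, NA, 3), c(1, 2, 3))), "missing")
  expect_error(icc_absolute(matrix(rnorm(3), 3, 1)), "at least 2")
})

test_that("main-path ICC equals the brute-force ANOVA oracle on 200 random tables", {
  set.seed(42)
  worst_s <- worst_a <- 0
  for (i in 1:200) {
    m <- matrix(rnorm(30, mean = 15, sd = 2), 10, 3) +
      rnorm(10, 0, runif(1, 0, 2))
    worst_s <- max(worst_s, abs(icc_absolute(m, "single")$estimate -
                                  icc_oracle_aov(m, "single")))
    worst_a <- max(worst_a, abs(icc_absolute(m, "average")$estimate -
                                  icc_oracle_aov(m, "average")))
  }
  expect_lt(worst_s, 1e-10)
  expect_lt(worst_a, 1e-10)
})

test_that("estimate and confidence interval match an independent reference implementation", {
  # seeded 10 x 3 table with reference values frozen from an established
  # Python implementation (pingouin.intraclass_corr: ICC(A,1)/ICC(A,k))
  m <- matrix(c(
    17.751082, 15.061679, 18.64255,
    16.474714, 10.691515, 11.989226,
    14.743438, 13.855272, 14.454155,
    12.480139, 15.945023, 15.741811,
    15.748041, 17.870462, 16.550998,
    14.410387, 16.866474, 14.211207,
    16.642953, 14.786201, 14.516328,
    12.797984, 16.604926, 13.850785,
    13.318863, 13.471252, 15.240137,
    16.381481, 16.476058, 16.512235), 10, 3, byrow = TRUE)
  single <- icc_absolute(m, "single")
  avg <- icc_absolute(m, "average")
  expect_equal(single$estimate, 0.215051, tolerance = 1e-5)
  expect_equal(avg$estimate, 0.451123, tolerance = 1e-5)
  # the reference prints CIs at 2 decimal places
  expect_equal(round(single$ci_lower, 2), -0.18)
  expect_equal(round(single$ci_upper, 2), 0.67)
  expect_equal(round(avg$ci_lower, 2), -0.82)
  expect_equal(round(avg$ci_upper, 2), 0.86)
  expect_true(single$ci_lower <= single$estimate &&
                single$estimate <= single$ci_upper)
  td <- tidy(single)
  expect_equal(td$estimate, single$estimate)
  expect_equal(td$n_subjects, 10)
})

test_that("reliability categories use the published thresholds", {
  expect_equal(categorize_icc(0.945), "excellent")
  expect_equal(categorize_icc(0.856), "good")
  expect_equal(categorize_icc(0.75), "good")
  expect_equal(categorize_icc(0.6), "moderate")
  expect_equal(categorize_icc(0.49), "poor")
  expect_error(categorize_icc(NaN), "finite")
})

test_that("single-measures ICC recovers the variance-ratio truth at large n", {
  # sigma_s^2 = 4, sigma_r^2 = 0, sigma_e^2 = 1 -> true ICC = 0.8
  r <- generate_ratings(15, n_subjects = 5000, n_raters = 3, n_sessions = 1,
                        var_subject = 4, var_rater = 0, var_error = 1, seed = 8)
  m <- pennation:::ratings_matrix(r, "rater")
  expect_equal(dim(m), c(5000, 3))
  expect_equal(icc_absolute(m, "single")$estimate, 0.8, tolerance = 0.02)
})

test_that("the 95% CI covers the true ICC in at least 93% of simulated tables", {
  true_icc <- 4 / (4 + 0.5 + 1)
  hits <- 0
  n_sim <- 1000
  for (i in seq_len(n_sim)) {
    r <- generate_ratings(15, n_subjects = 10, n_raters = 3, n_sessions = 1,
                          var_subject = 4, var_rater = 0.5, var_error = 1,
                          seed = 10000 + i)
    m <- pennation:::ratings_matrix(r, "rater")
    res <- icc_absolute(m, "single")
    if (res$ci_lower <= true_icc && true_icc <= res$ci_upper) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.93)
})

test_that("aggregation over sessions and readers reproduces the published grand means", {
  cells <- read.csv(system.file("extdata", "table2_cell_means.csv",
                                package = "pennation"))
  for (roi in c("anterior", "posterior")) {
    sub <- cells[cells$roi == roi, ]
    ratings <- tibble::tibble(subject = "cohort", rater = paste0("R", sub$reader),
                              session = sub$session, value = sub$mean_pa_deg)
    agg <- aggregate_ratings(ratings, over = c("sessions", "raters"))
    expected <- if (roi == "anterior") 15.6 else 10.7
    expect_equal(round(agg$grand_mean, 1), expected)
  }
})

test_that("aggregation validates balance and handles constant tables", {
  r <- generate_ratings(12, n_subjects = 4, n_raters = 2, n_sessions = 2, seed = 2)
  agg <- aggregate_ratings(r)
  expect_equal(agg$n_subjects, 4)
  # grand mean equals the mean of per-rater-per-session cell means (balance)
  cell_means <- tapply(r$value, list(r$rater, r$session), mean)
  expect_equal(agg$grand_mean, mean(cell_means), tolerance = 1e-12)

  unbalanced <- r[-1, ]
  expect_error(aggregate_ratings(unbalanced), "unbalanced.*S1")

  const <- r; const$value <- 13.5
  agg_c <- aggregate_ratings(const)
  expect_equal(agg_c$grand_mean, 13.5)
  expect_equal(agg_c$sd, 0)
})

test_that("design slices produce the per-design ICC matrices of the study layout", {
  r <- generate_ratings(15, n_subjects = 10, n_raters = 3, n_sessions = 3, seed = 6,
                        var_subject = 4, var_error = 1)
  slices <- design_slices(r)
  tr <- dplyr::filter(slices, design == "test-retest")
  ir <- dplyr::filter(slices, design == "inter-reader")
  expect_equal(nrow(tr), 3)   # one per rater
  expect_equal(nrow(ir), 3)   # one per session
  expect_true(all(vapply(tr$data, function(m) all(dim(m) == c(10, 3)), logical(1))))
  expect_true(all(vapply(ir$data, function(m) all(dim(m) == c(10, 3)), logical(1))))

  # single session: inter-reader only
  r1 <- dplyr::filter(r, session == 1)
  s1 <- design_slices(r1)
  expect_setequal(unique(s1$design), "inter-reader")

  # single rater, two sessions: test-retest only
  r2 <- dplyr::filter(r, rater == "R1", session %in% 1:2)
  s2 <- design_slices(r2)
  expect_setequal(unique(s2$design), "test-retest")

  # neither axis: error
  expect_error(design_slices(dplyr::filter(r, rater == "R1", session == 1)),
               "no reliability design")

  # occasion column enables the intra-reader design
  r_occ1 <- dplyr::mutate(dplyr::filter(r, rater == "R1"), occasion = 1)
  r_occ2 <- dplyr::mutate(r_occ1, occasion = 2,
                          value = value + rnorm(nrow(r_occ1), 0, 0.3))
  s3 <- design_slices(dplyr::bind_rows(r_occ1, r_occ2))
  intra <- dplyr::filter(s3, design == "intra-reader")
  expect_equal(nrow(intra), 3)  # one per session for the repeated rater
  expect_true(all(vapply(intra$data, function(m) all(dim(m) == c(10, 2)), logical(1))))
})

test_that("reliability_report runs the full design sweep with categories", {
  r <- generate_ratings(15, n_subjects = 10, n_raters = 3, n_sessions = 3,
                        var_subject = 4, var_error = 0.3, seed = 12)
  rep_ <- reliability_report(r)
  expect_true(all(c("design", "stratum", "estimate", "conf_low", "conf_high",
                    "category") %in% names(rep_)))
  expect_equal(nrow(rep_), 6)
  expect_true(all(rep_$conf_low <= rep_$estimate & rep_$estimate <= rep_$conf_high))
  expect_true(all(rep_$estimate > 0.5))  # strong subject signal by construction
})
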