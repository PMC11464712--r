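#' Absolute-agreement intraclass correlation coefficient
#'
#' Two-way model ICC for absolute agreement (McGraw-Wong ICC(A,1) /
#' ICC(A,k)). The subjects x measurements matrix is decomposed by two-way
#' ANOVA into row (subject), column (measurement) and error mean squares;
#' the single-measures estimate is
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k/n)(MSC - MSE))`, and the
#' average-measures analog replaces the denominator by
#' `MSR + (MSC - MSE)/n`. Absolute agreement penalizes systematic offsets
#' between columns, unlike consistency-type ICCs. The 95% confidence
#' interval uses the standard F-based construction with a Satterthwaite
#' approximation to the denominator degrees of freedom; average-measures
#' bounds are the Spearman-Brown transform of the single-measures bounds.
#' Under a mixed model (fixed raters) the estimate is numerically identical
#' to the two-way random-effects absolute-agreement ICC.
#'
#' @param m Numeric matrix, subjects in rows (n >= 2), repeated
#'   measurements (raters or sessions, k >= 2) in columns. No missing
#'   cells.
#' @param variant `"single"` (default) or `"average"` measures.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result` with fields `estimate`,
#'   `ci_lower`, `ci_upper`, `variant`, `n_subjects`, `k_measurements`,
#'   `category` and the ANOVA mean squares.
#' @export
icc_absolute <- function(m, variant = c("single", "average"), conf_level = 0.95) {
  variant <- match.arg(variant)
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("ICC input has missing or non-finite cells (no imputation is performed)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs at least 2 subjects and 2 measurements")

  gm <- mean(m)
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < .Machine$double.eps * max(1, abs(gm))^2) {
    stop("ICC undefined: ratings have zero total variance")
  }

  est_single <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  est_avg <- (msr - mse) / (msr + (msc - mse) / n)

  alpha <- 1 - conf_level
  ci <- icc_a1_confint(msr, msc, mse, n, k, est_single, alpha)
  sb <- function(x) k * x / (1 + (k - 1) * x)
  est <- if (variant == "single") est_single else est_avg
  lo <- if (variant == "single") ci[1] else sb(ci[1])
  hi <- if (variant == "single") ci[2] else sb(ci[2])

  structure(
    list(estimate = est, ci_lower = lo, ci_upper = hi,
         variant = variant, conf_level = conf_level,
         n_subjects = n, k_measurements = k,
         msr = msr, msc = msc, mse = mse,
         category = categorize_icc(est)),
    class = "icc_result"
  )
}

# F-based CI for ICC(A,1) with Satterthwaite degrees of freedom.
icc_a1_confint <- function(msr, msc, mse, n, k, icc, alpha) {
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  c(lower, upper)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(absolute agreement, %s measures) = %.3f [%.3f, %.3f] (%s; n = %d, k = %d)\n",
    x$variant, x$estimate, x$ci_lower, x$ci_upper, x$category,
    x$n_subjects, x$k_measurements
  ))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, estimate = x$estimate,
    conf_low = x$ci_lower, conf_high = x$ci_upper,
    category = x$category, n_subjects = x$n_subjects,
    k_measurements = x$k_measurements
  )
}

#' @export
glance.icc_result <- function(x, ...) tidy(x)

#' Categorize an ICC estimate
#'
#' Conventional reliability categories: above 0.90 excellent, 0.75 to 0.90
#' good, 0.50 to below 0.75 moderate, below 0.50 poor.
#'
#' @param estimate Finite ICC estimate.
#' @return One of `"excellent"`, `"good"`, `"moderate"`, `"poor"`.
#' @export
categorize_icc <- function(estimate) {
  if (!is.finite(estimate)) stop("ICC estimate must be finite")
  if (estimate > 0.90) "excellent"
  else if (estimate >= 0.75) "good"
  else if (estimate >= 0.50) "moderate"
  else "poor"
}

#' Aggregate ratings across sessions and/or readers
#'
#' Averages each subject's pennation-angle measurements over the requested
#' axes (examination sessions, readers, or both), then summarizes across
#' subjects: the grand mean is the mean of the per-subject means and the SD
#' is taken across subjects. The design must be balanced (equal cell counts
#' per subject); with balanced data the grand mean also equals the mean of
#' the per-reader-per-session cell means.
#'
#' @param ratings Ratings tibble (columns subject, rater, session, value).
#' @param over Character vector of axes to average over: any of
#'   `"sessions"`, `"raters"`.
#' @return A list of class `pa_aggregate` with `subject_means` (tibble),
#'   `grand_mean`, `sd` and `n_subjects`.
#' @export
aggregate_ratings <- function(ratings, over = c("sessions", "raters")) {
  over <- match.arg(over, several.ok = TRUE)
  ratings <- validate_ratings(tibble::as_tibble(ratings))
  counts <- dplyr::count(ratings, .data$subject)
  if (length(unique(counts$n)) != 1) {
    bad <- counts$subject[counts$n != stats::median(counts$n)]
    stop("unbalanced design: subject(s) with deviating cell counts: ",
         paste(bad, collapse = ", "))
  }
  keep <- c("subject",
            if (!"raters" %in% over) "rater",
            if (!"sessions" %in% over) "session")
  subject_means <- ratings |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keep))) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
  per_subject <- subject_means |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(mean_value = mean(.data$mean_value), .groups = "drop")
  structure(
    list(subject_means = subject_means,
         grand_mean = mean(per_subject$mean_value),
         sd = stats::sd(per_subject$mean_value),
         n_subjects = nrow(per_subject)),
    class = "pa_aggregate"
  )
}

#' @export
print.pa_aggregate <- function(x, ...) {
  cat(sprintf("Grand mean %.2f +/- %.2f deg over %d subjects\n",
              x$grand_mean, x$sd, x$n_subjects))
  invisible(x)
}

#' @export
glance.pa_aggregate <- function(x, ...) {
  tibble::tibble(grand_mean = x$grand_mean, sd = x$sd, n_subjects = x$n_subjects)
}

#' Slice a ratings table into the ICC design matrices
#'
#' Builds the complete-matrix inputs of each reliability design:
#' test-retest (per rater, subjects x sessions), inter-reader (per
#' session, subjects x raters) and — when an `occasion` column with two or
#' more reading occasions is present — intra-reader (per session for the
#' repeated rater, subjects x occasions).
#'
#' @param ratings Ratings tibble; an optional `occasion` column marks
#'   repeated reading sessions of the same rater.
#' @return A tibble with columns `design`, `stratum` and a list-column
#'   `data` of subjects x measurements matrices.
#' @export
design_slices <- function(ratings) {
  ratings <- validate_ratings(tibble::as_tibble(ratings))
  has_occ <- "occasion" %in% names(ratings) && length(unique(ratings$occasion)) >= 2
  base <- if (has_occ) {
    dplyr::filter(ratings, .data$occasion == sort(unique(ratings$occasion))[1])
  } else ratings
  n_sessions <- length(unique(base$session))
  n_raters <- length(unique(base$rater))
  if (n_sessions < 2 && n_raters < 2 && !has_occ) {
    stop("ratings table has neither >= 2 sessions nor >= 2 raters: no reliability design available")
  }
  out <- list()
  if (n_sessions >= 2) {
    for (r in sort(unique(base$rater))) {
      sub <- dplyr::filter(base, .data$rater == r)
      out[[length(out) + 1]] <- tibble::tibble(
        design = "test-retest", stratum = as.character(r),
        data = list(ratings_matrix(sub, "session"))
      )
    }
  }
  if (n_raters >= 2) {
    for (s in sort(unique(base$session))) {
      sub <- dplyr::filter(base, .data$session == s)
      out[[length(out) + 1]] <- tibble::tibble(
        design = "inter-reader", stratum = as.character(s),
        data = list(ratings_matrix(sub, "rater"))
      )
    }
  }
  if (has_occ) {
    rep_raters <- ratings |>
      dplyr::distinct(.data$rater, .data$occasion) |>
      dplyr::count(.data$rater) |>
      dplyr::filter(.data$n >= 2)
    for (r in rep_raters$rater) {
      sub <- dplyr::filter(ratings, .data$rater == r)
      for (s in sort(unique(sub$session))) {
        ss <- dplyr::filter(sub, .data$session == s)
        out[[length(out) + 1]] <- tibble::tibble(
          design = "intra-reader", stratum = sprintf("%s/session %s", r, s),
          data = list(ratings_matrix(ss, "occasion"))
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

ratings_matrix <- function(df, col) {
  wide <- tidyr::pivot_wider(df[, c("subject", col, "value")],
                             names_from = dplyr::all_of(col),
                             values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("incomplete design: missing (subject, ", col, ") cells")
  m
}

#' Full reliability report for a ratings table
#'
#' Runs [design_slices] and [icc_absolute] over every design stratum.
#'
#' @param ratings Ratings tibble.
#' @param variant `"single"` or `"average"` measures.
#' @return A tibble: design, stratum, variant, estimate, conf_low,
#'   conf_high, category, n_subjects, k_measurements.
#' @export
reliability_report <- function(ratings, variant = "single") {
  slices <- design_slices(ratings)
  dplyr::bind_rows(lapply(seq_len(nrow(slices)), function(i) {
    res <- tidy(icc_absolute(slices$data[[i]], variant = variant))
    dplyr::bind_cols(slices[i, c("design", "stratum")], res)
  }))
}
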