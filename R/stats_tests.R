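# Chi-squared goodness-of-fit for diet-type proportions and the sex-ratio
# test. No continuity correction: the printed df = 1 statistic for the
# balanced-sex-ratio test equals the uncorrected value.

#' Chi-squared goodness-of-fit test
#'
#' `X2 = sum((O - E)^2 / E)` with `E = sum(O) * p`, df = k - 1, upper-tail
#' p-value. Default expectation is uniform. No continuity correction is
#' applied. An expected cell of zero is an error (merge categories); an
#' expected cell below 5 triggers a warning (an exact test is the usual
#' fallback and is out of scope here).
#'
#' @param observed Non-negative integer vector of counts (sum > 0).
#' @param expected_proportions Probability vector summing to 1, or `NULL`
#'   for uniform.
#' @return List of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`.
#' @export
chisq_goodness_of_fit <- function(observed, expected_proportions = NULL) {
  stopifnot(all(observed >= 0), sum(observed) > 0)
  k <- length(observed)
  if (k < 2L) stop("need at least two categories", call. = FALSE)
  p <- if (is.null(expected_proportions)) rep(1 / k, k) else expected_proportions
  if (length(p) != k || abs(sum(p) - 1) > 1e-8) {
    stop("expected_proportions must match observed in length and sum to 1",
         call. = FALSE)
  }
  expected <- sum(observed) * p
  if (any(expected == 0)) {
    stop("expected cell count of zero; merge categories before testing",
         call. = FALSE)
  }
  if (any(expected < 5)) {
    warning("expected cell count < 5; an exact test is the usual fallback",
            call. = FALSE)
  }
  statistic <- sum((observed - expected)^2 / expected)
  df <- k - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Chi-squared goodness of fit: X2(%d) = %.3f, p = %.3f\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Sex ratio of a cohort
#'
#' Proportion of males among field individuals, overall and per year, with
#' the chi-squared test of a balanced (1:1) ratio on the overall
#' female/male counts.
#'
#' @param metadata Metadata data frame.
#' @param sample_ids Optional subset of sample ids (default: all field
#'   samples with known sex).
#' @return List of class `sex_ratio_result`: `proportion_male`, `by_year`
#'   (data frame `year`, `n_female`, `n_male`, `proportion_male`),
#'   `n_female`, `n_male`, `test` (a `chisq_result`).
#' @export
sex_ratio <- function(metadata, sample_ids = NULL) {
  df <- metadata[metadata$sample_class == "field" &
                   metadata$sex %in% c("F", "M"), , drop = FALSE]
  if (!is.null(sample_ids)) df <- df[df$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(df) == 0L) stop("sex_ratio(): empty subset", call. = FALSE)
  n_f <- sum(df$sex == "F"); n_m <- sum(df$sex == "M")
  by_year <- do.call(rbind, lapply(split(df, df$year), function(y) {
    data.frame(year = y$year[1], n_female = sum(y$sex == "F"),
               n_male = sum(y$sex == "M"),
               proportion_male = sum(y$sex == "M") / nrow(y))
  }))
  rownames(by_year) <- NULL
  structure(list(proportion_male = n_m / (n_f + n_m),
                 n_female = n_f, n_male = n_m, by_year = by_year,
                 test = chisq_goodness_of_fit(c(n_f, n_m), c(0.5, 0.5))),
            class = "sex_ratio_result")
}

#' @export
print.sex_ratio_result <- function(x, ...) {
  cat(sprintf("Sex ratio (proportion male): %.2f (%d F / %d M)\n",
              x$proportion_male, x$n_female, x$n_male))
  for (i in seq_len(nrow(x$by_year))) {
    cat(sprintf("  %d: %.2f\n", x$by_year$year[i],
                x$by_year$proportion_male[i]))
  }
  print(x$test)
  invisible(x)
}
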