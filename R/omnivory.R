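# The coefficient of omnivory CO = P/(P + Z) places an omnivorous population
# on the phytozoophagous continuum: each detected individual contributes a
# phytophagy score s (1 plant-only, 0.5 both, 0 animal-only), P = sum(s),
# Z = sum(1 - s). Because p + z = 1 per detected individual, CO equals the
# mean of s, so stratified bootstrap replicates reduce to stratified means.

stratum_key <- function(states, scheme) {
  switch(scheme,
         month_x_year = paste(states$year, states$month, sep = "-"),
         month_x_sex = paste(states$month, states$sex, sep = "-"),
         month_only = as.character(states$month),
         none = rep("all", nrow(states)),
         stop("unknown stratification scheme: ", scheme, call. = FALSE))
}

detected_states <- function(states) {
  states[!is.na(states$s), , drop = FALSE]
}

#' Coefficient of omnivory (point estimate)
#'
#' `CO = P / (P + Z)` with `P = sum(s)` and `Z = sum(1 - s)` over detected
#' individuals; undetected individuals (no plant nor animal detection) are
#' excluded and reported in `n_undetected`. CO ranges from 1 (strictly
#' phytophagous) to 0 (strictly zoophagous).
#'
#' @param states Diet-state data frame with a numeric `s` column (NA =
#'   undetected), e.g. from [classify_diet_state()].
#' @return List of class `co_estimate`: `co`, `n_detected`, `n_undetected`,
#'   `P_total`, `Z_total`.
#' @export
compute_co <- function(states) {
  det <- detected_states(states)
  if (nrow(det) == 0L) {
    stop("compute_co(): no detected individuals", call. = FALSE)
  }
  stopifnot(all(det$s %in% c(0, 0.5, 1)))
  P <- sum(det$s)
  Z <- sum(1 - det$s)
  structure(list(co = P / (P + Z),
                 n_detected = nrow(det),
                 n_undetected = nrow(states) - nrow(det),
                 P_total = P, Z_total = Z),
            class = "co_estimate")
}

#' @export
print.co_estimate <- function(x, ...) {
  cat(sprintf("Coefficient of omnivory: %.3f (P = %.1f, Z = %.1f, n = %d)\n",
              x$co, x$P_total, x$Z_total, x$n_detected))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  95%% bootstrap CI [%s, B = %d, seed = %s]: %.3f-%.3f\n",
                x$scheme, x$B, format(x$seed), x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Stratified bootstrap confidence interval for CO
#'
#' Resamples detected individuals with replacement *within* each stratum at
#' that stratum's size (so the temporal/sex design is preserved), recomputes
#' CO on each of the B unions, and reports the percentile interval
#' (2.5th-97.5th). The seed fully determines the output.
#'
#' @param states Diet-state data frame.
#' @param scheme Stratification: `"month_x_year"` (default),
#'   `"month_x_sex"`, `"month_only"`, or `"none"`.
#' @param B Number of bootstrap iterations (default 2000).
#' @param seed Integer seed (required).
#' @param conf Confidence level (default 0.95).
#' @return `co_estimate` with `ci_low`, `ci_high`, `B`, `scheme`, `seed`,
#'   `replicates` (the B bootstrap COs) and `qc` (see [stratum_qc()]).
#' @export
bootstrap_co <- function(states, scheme = c("month_x_year", "month_x_sex",
                                            "month_only", "none"),
                         B = 2000, seed, conf = 0.95) {
  scheme <- match.arg(scheme)
  stopifnot(B >= 1)
  if (missing(seed)) stop("bootstrap_co(): seed is required", call. = FALSE)
  det <- detected_states(states)
  est <- compute_co(states)
  if (scheme == "month_x_sex" && any(det$sex == "unknown")) {
    stop("bootstrap_co(): scheme month_x_sex requires known sex for all ",
         "detected individuals", call. = FALSE)
  }
  key <- stratum_key(det, scheme)
  set.seed(as.integer(seed))
  n <- nrow(det)
  total <- numeric(B)
  for (v in split(det$s, key)) {
    nh <- length(v)
    idx <- sample.int(nh, nh * B, replace = TRUE)
    total <- total + rowSums(matrix(v[idx], nrow = B))
  }
  reps <- total / n            # CO of a replicate = mean of resampled scores
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  est$ci_low <- ci[1]; est$ci_high <- ci[2]
  est$B <- as.integer(B); est$scheme <- scheme; est$seed <- as.integer(seed)
  est$conf <- conf
  est$replicates <- reps
  est$qc <- stratum_qc(states, scheme)
  est
}

#' Month-constrained permutation test for sex differences in CO
#'
#' Tests `T = CO(F) - CO(M)` against the null of no sex-diet association
#' while preserving temporal structure: sex labels are shuffled only within
#' each constraint stratum. Two-sided Monte-Carlo p-value with add-one
#' correction, `p = (1 + #(|T_b| >= |T_obs|)) / (B + 1)`; with
#' `exact = TRUE` all distinct within-stratum label assignments are
#' enumerated instead and `p = #(|T| >= |T_obs|) / N`.
#'
#' @param states Diet-state data frame; individuals with unknown sex are
#'   dropped with a warning, undetected individuals are excluded.
#' @param constraint `"month_x_year"` (default: the two seasons are distinct
#'   temporal strata) or `"month_only"` (shuffle within calendar months
#'   across years).
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed (required unless `exact`).
#' @param exact Enumerate all assignments (feasible for tiny strata only;
#'   guarded at 2e5 combinations).
#' @return List of class `permutation_result`: `observed_diff`, `p_value`,
#'   `B` (or `n_enumerated`), `constraint`, `seed`, `co_female`, `co_male`.
#' @export
permutation_sex_test <- function(states, constraint = c("month_x_year",
                                                        "month_only"),
                                 B = 10000, seed, exact = FALSE) {
  constraint <- match.arg(constraint)
  det <- detected_states(states)
  if (any(det$sex == "unknown")) {
    warning("dropping individuals with unknown sex", call. = FALSE)
    det <- det[det$sex != "unknown", , drop = FALSE]
  }
  if (!all(c("F", "M") %in% det$sex)) {
    stop("permutation_sex_test(): both sexes must be present", call. = FALSE)
  }
  key <- stratum_key(det, constraint)
  s <- det$s
  is_f <- det$sex == "F"
  t_stat <- function(f) mean(s[f]) - mean(s[!f])
  t_obs <- t_stat(is_f)
  strata <- split(seq_along(s), key)
  single_sex <- vapply(strata, function(i) length(unique(is_f[i])) == 1L,
                       logical(1))
  if (any(single_sex)) {
    message(sum(single_sex),
            " stratum(s) contain one sex only and contribute no ",
            "permutation variation")
  }
  eps <- 1e-12
  if (exact) {
    per_stratum <- lapply(strata, function(i) {
      k <- sum(is_f[i])
      combos <- utils::combn(length(i), k)
      lapply(seq_len(ncol(combos)), function(j) i[combos[, j]])
    })
    n_total <- prod(vapply(per_stratum, length, numeric(1)))
    if (n_total > 2e5) {
      stop("exact enumeration infeasible: ", n_total, " assignments",
           call. = FALSE)
    }
    grid <- expand.grid(lapply(per_stratum, seq_along))
    tvals <- vapply(seq_len(nrow(grid)), function(r) {
      f <- rep(FALSE, length(s))
      for (g in seq_along(per_stratum)) {
        f[per_stratum[[g]][[grid[r, g]]]] <- TRUE
      }
      t_stat(f)
    }, numeric(1))
    p <- sum(abs(tvals) >= abs(t_obs) - eps) / n_total
    res <- list(observed_diff = t_obs, p_value = p,
                n_enumerated = as.integer(n_total), B = NA_integer_,
                constraint = constraint, seed = NA_integer_, exact = TRUE)
  } else {
    if (missing(seed)) {
      stop("permutation_sex_test(): seed is required", call. = FALSE)
    }
    set.seed(as.integer(seed))
    exceed <- 0L
    for (b in seq_len(B)) {
      f <- is_f
      for (i in strata) f[i] <- is_f[i][sample.int(length(i))]
      if (abs(t_stat(f)) >= abs(t_obs) - eps) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (B + 1)
    res <- list(observed_diff = t_obs, p_value = p, B = as.integer(B),
                constraint = constraint, seed = as.integer(seed),
                exact = FALSE)
  }
  res$co_female <- mean(s[is_f])
  res$co_male <- mean(s[!is_f])
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Sex difference in CO (F - M): %.3f (CO_F = %.3f, CO_M = %.3f)\n",
              x$observed_diff, x$co_female, x$co_male))
  cat(sprintf("  %s permutation test [%s]: p = %.3f\n",
              if (x$exact) "exact" else sprintf("Monte-Carlo (B = %d)", x$B),
              x$constraint, x$p_value))
  invisible(x)
}

#' Stratum quality control for CO estimation
#'
#' Per-stratum sample sizes with flags (`ok` n >= 5, `acceptable`
#' 3 <= n < 5, `small` n < 3), plus design-guideline checks: at least 3
#' sampling dates, at least 50 detected individuals, and both sexes
#' represented.
#'
#' @param states Diet-state data frame.
#' @param scheme Stratification scheme (see [bootstrap_co()]).
#' @return List of class `stratum_qc`: `strata` (data frame with `stratum`,
#'   `n`, `flag`) and `guidelines` (named logical vector).
#' @export
stratum_qc <- function(states, scheme = "month_x_year") {
  det <- detected_states(states)
  key <- stratum_key(det, scheme)
  n <- vapply(split(key, key), length, integer(1))
  flag <- ifelse(n >= 5, "ok", ifelse(n >= 3, "acceptable", "small"))
  strata <- data.frame(stratum = names(n), n = unname(n),
                       flag = unname(flag), stringsAsFactors = FALSE,
                       row.names = NULL)
  dates <- unique(paste(det$year, det$month))
  guidelines <- c(min_3_dates = length(dates) >= 3,
                  min_50_individuals = nrow(det) >= 50,
                  both_sexes = all(c("F", "M") %in% det$sex))
  structure(list(strata = strata[order(strata$stratum), , drop = FALSE],
                 guidelines = guidelines),
            class = "stratum_qc")
}

#' @export
print.stratum_qc <- function(x, ...) {
  print(x$strata, row.names = FALSE)
  unmet <- names(x$guidelines)[!x$guidelines]
  if (length(unmet)) cat("Guidelines unmet:", paste(unmet, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a CO estimate (with QC) to JSON
#'
#' @param est `co_estimate` from [bootstrap_co()].
#' @param path Output path.
#' @param perm Optional `permutation_result` to include.
#' @return Invisibly `path`.
#' @export
write_co_report <- function(est, path, perm = NULL) {
  obj <- unclass(est)
  obj$replicates <- NULL
  if (!is.null(obj$qc)) obj$qc <- unclass(obj$qc)
  if (!is.null(perm)) obj$sex_test <- unclass(perm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
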