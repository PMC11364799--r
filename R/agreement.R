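# Measurement-agreement analytics: Pearson correlation with concordance
# labels, Bland-Altman limits of agreement, and two-way random-effects ICC
# for observer reproducibility. All sds use the n-1 denominator.

concordance_label <- function(r) {
  cut(abs(r), breaks = c(-Inf, 0.4, 0.6, 0.8, Inf),
      labels = c("poor", "moderate", "good", "excellent"))
}

#' Pearson agreement between a measurement and its reference
#'
#' Pairwise-complete Pearson correlation, overall and (optionally) within
#' subgroups, with concordance labels at the conventional 0.8 / 0.6 / 0.4
#' thresholds (excellent / good / moderate / poor).
#'
#' @param x,y paired numeric vectors (mm). Pairs with a missing member are
#'   dropped.
#' @param subgroup optional labels (e.g. tumor morphology); per-group r is
#'   reported as `NA` when a group has fewer than 3 complete pairs.
#' @return data.frame with columns `group`, `n`, `r`, `label`; the first row
#'   is the overall estimate.
#' @export
pearson_agreement <- function(x, y, subgroup = NULL) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  one <- function(xx, yy) {
    if (length(xx) < 3L) return(NA_real_)
    if (sd(xx) == 0 || sd(yy) == 0)
      stop("correlation undefined: zero variance", call. = FALSE)
    cor(xx, yy)
  }
  r_all <- one(x[ok], y[ok])
  out <- data.frame(group = "overall", n = sum(ok), r = r_all,
                    label = as.character(concordance_label(r_all)),
                    stringsAsFactors = FALSE)
  if (!is.null(subgroup)) {
    for (g in unique(as.character(subgroup[ok]))) {
      sel <- ok & as.character(subgroup) == g
      r_g <- if (sum(sel) < 3L) NA_real_ else one(x[sel], y[sel])
      out <- rbind(out, data.frame(
        group = g, n = sum(sel), r = r_g,
        label = if (is.na(r_g)) NA_character_
                else as.character(concordance_label(r_g)),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Bland-Altman agreement analysis
#'
#' Mean bias and 95% limits of agreement for paired measurements:
#' `bias = mean(x - y)`, `LoA = bias +/- 1.96 * sd(x - y)` with the n-1
#' denominator.
#'
#' @param x,y paired numeric vectors (mm); pairs with a missing member are
#'   dropped.
#' @return list with `bias`, `sd`, `lower_loa`, `upper_loa`, `n`,
#'   `differences`, `means`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  if (sum(ok) < 2L) stop("need >= 2 complete pairs", call. = FALSE)
  d <- x[ok] - y[ok]
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd = s,
       lower_loa = bias - 1.96 * s, upper_loa = bias + 1.96 * s,
       n = sum(ok), differences = d, means = (x[ok] + y[ok]) / 2)
}

#' Bland-Altman plot
#'
#' @param ba result of [bland_altman()].
#' @param main plot title.
#' @return `ba`, invisibly.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman") {
  plot(ba$means, ba$differences, xlab = "Mean of pair (mm)",
       ylab = "Difference (mm)", main = main)
  graphics::abline(h = c(ba$bias, ba$lower_loa, ba$upper_loa), lty = 2)
  invisible(ba)
}

#' Intraclass correlation coefficient for observer agreement
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC(2,1)
#' (Shrout & Fleiss; McGraw & Wong "ICC(A,1)"), the form appropriate when
#' both subjects and raters/occasions are treated as random and systematic
#' rater offsets should count against agreement. A consistency form
#' ICC(3,1) is available via `model = "consistency"`. The 95% CI follows the
#' McGraw-Wong F-based construction. Negative point estimates are clipped to
#' 0 and flagged.
#'
#' @param ratings numeric matrix, subjects in rows, raters/occasions in
#'   columns; rows with missing cells are dropped.
#' @param model `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @param conf_level confidence level for the CI.
#' @return list with `estimate`, `lower`, `upper`, `model`, `n`, `k`,
#'   `clipped` (TRUE when a negative estimate was clipped),
#'   `high_reproducibility` (estimate > 0.75).
#' @export
icc <- function(ratings, model = c("agreement", "consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  ratings <- ratings[complete.cases(ratings), , drop = FALSE]
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2L) stop("need >= 2 raters/occasions", call. = FALSE)
  if (n < 5L) stop("need >= 5 subjects", call. = FALSE)
  if (sd(as.vector(ratings)) == 0)
    stop("degenerate ratings: no variance", call. = FALSE)

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (model == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    f_l <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # McGraw & Wong (1996) CI for ICC(A,1)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_star <- qf(1 - alpha / 2, n - 1, v)
    lower <- n * (msr - f_star * mse) /
      (f_star * (k * msc + (k * n - k - n) * mse) + n * msr)
    f_star2 <- qf(1 - alpha / 2, v, n - 1)
    upper <- n * (f_star2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_star2 * msr)
  }
  clipped <- FALSE
  if (is.finite(est) && est < 0) {
    est <- 0
    clipped <- TRUE
  }
  lower <- max(min(lower, 1), 0)
  upper <- max(min(upper, 1), 0)
  list(estimate = min(est, 1), lower = lower, upper = upper, model = model,
       n = n, k = k, clipped = clipped,
       high_reproducibility = est > 0.75)
}

#' Full measurement-agreement report for a cohort
#'
#' For every radiological measurement column: Pearson r against the
#' pathological reference (overall and per morphology subgroup), Bland-Altman
#' bias and limits of agreement, and — where replicate columns exist —
#' intra-observer (`repeat_*`) and inter-observer (`observer2_*`) ICC(2,1).
#'
#' @param cohort a `cohort_table`.
#' @param reference column name of the pathological reference (default
#'   `"pDOI"`).
#' @param measurements measurement columns to report; defaults to the
#'   non-derived measurement columns in the cohort roles.
#' @param subgroup optional subgroup column name (default `"morphology"`
#'   when present).
#' @return an object of class `agreement_report`: named list per measurement
#'   with `pearson`, `bland_altman`, `icc_intra`, `icc_inter`.
#' @export
agreement_report <- function(cohort, reference = "pDOI",
                             measurements = NULL, subgroup = NULL) {
  roles <- cohort_roles(cohort)
  measurements <- measurements %||%
    setdiff(roles$measurements, c("rTTmax", "rDOImax", "LDmax"))
  if (is.null(subgroup) && "morphology" %in% names(cohort))
    subgroup <- "morphology"
  sg <- if (!is.null(subgroup)) cohort[[subgroup]] else NULL
  out <- lapply(measurements, function(nm) {
    res <- list(
      pearson = pearson_agreement(cohort[[nm]], cohort[[reference]], sg),
      bland_altman = bland_altman(cohort[[nm]], cohort[[reference]]))
    rep_col <- paste0("repeat_", nm)
    obs_col <- paste0("observer2_", nm)
    if (rep_col %in% names(cohort)) {
      m <- cbind(cohort[[nm]], cohort[[rep_col]])
      res$icc_intra <- tryCatch(icc(m), error = function(e) NULL)
    }
    if (obs_col %in% names(cohort)) {
      m <- cbind(cohort[[nm]], cohort[[obs_col]])
      res$icc_inter <- tryCatch(icc(m), error = function(e) NULL)
    }
    res
  })
  names(out) <- measurements
  structure(out, class = "agreement_report", reference = reference)
}

#' Serialize an agreement report to JSON
#'
#' @param report an `agreement_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  slim <- lapply(report, function(m) {
    list(pearson = m$pearson,
         bland_altman = m$bland_altman[c("bias", "sd", "lower_loa",
                                         "upper_loa", "n")],
         icc_intra = if (!is.null(m$icc_intra))
           m$icc_intra[c("estimate", "lower", "upper",
                         "high_reproducibility")],
         icc_inter = if (!is.null(m$icc_inter))
           m$icc_inter[c("estimate", "lower", "upper",
                         "high_reproducibility")])
  })
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
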