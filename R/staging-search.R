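# Cutoff-count selection via restricted cubic splines + AIC, and exhaustive
# confounder-adjusted Cox search over ascending cutoff tuples.

#' Define a staging scheme
#'
#' An ordered cutoff vector on a named measurement defines ordinal risk
#' groups `rT1 .. rT(q+1)` with the boundary convention "value <= cutoff
#' belongs to the lower group": group i collects values in
#' `(c[i-1], c[i]]`, with `c[0] = -Inf` and `c[q+1] = +Inf`.
#'
#' @param measurement measurement column name (e.g. `"rDOI_aCE"`).
#' @param cutoffs strictly ascending numeric cutoffs (mm).
#' @param labels optional group labels; defaults to `rT1..rT(q+1)`.
#' @return an object of class `staging_scheme`.
#' @export
staging_scheme <- function(measurement, cutoffs, labels = NULL) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) < 1L || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending", call. = FALSE)
  labels <- labels %||% paste0("rT", seq_len(length(cutoffs) + 1L))
  stopifnot(length(labels) == length(cutoffs) + 1L)
  structure(list(measurement = measurement, cutoffs = cutoffs,
                 labels = labels),
            class = "staging_scheme")
}

#' @export
print.staging_scheme <- function(x, ...) {
  bounds <- c(paste0("<= ", x$cutoffs), paste0("> ", x$cutoffs[length(x$cutoffs)]))
  cat("<staging_scheme> ", x$measurement, ": ",
      paste(sprintf("%s (%s mm)", x$labels, bounds), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Ordinal group index for values under the "<= cutoff -> lower group"
# convention. Missing values map to NA.
cut_by_scheme <- function(x, cutoffs) {
  findInterval(x, cutoffs, left.open = TRUE) + 1L
}

#' Choose the number of cutoffs by spline flexibility and AIC
#'
#' Fits a Cox model of the outcome on a restricted cubic spline of the
#' measurement at each candidate knot count and picks the count with the
#' lowest AIC; near-ties (within `tie_tol`) resolve to the smallest knot
#' count (parsimony). `k` knots imply `k - 1` cutoffs is the flexibility
#' reading used by change-point pipelines; here 3 knots map to 2 cutoffs,
#' i.e. 3 risk groups.
#'
#' @param x complete measurement vector (mm), post-imputation.
#' @param time,event outcome vectors.
#' @param knot_options candidate knot counts (subset of 3:5).
#' @param tie_tol AIC difference treated as a tie (default 2).
#' @return list with `n_cutoffs`, `n_knots`, `aic` (named by knot count).
#' @export
select_n_cutoffs <- function(x, time, event, knot_options = 3:5,
                             tie_tol = 2) {
  if (anyNA(x)) stop("measurement must be complete (impute first)",
                     call. = FALSE)
  stopifnot(all(knot_options %in% 3:5))
  aics <- vapply(knot_options, function(k) {
    basis <- rcs_basis(x, n_knots = k)
    cox_fit(as.data.frame(basis$basis), time, event)$aic
  }, 0)
  names(aics) <- knot_options
  best <- min(aics)
  # smallest knot count within tie_tol of the optimum wins
  k_sel <- knot_options[which(aics <= best + tie_tol)[1]]
  list(n_cutoffs = k_sel - 1L, n_knots = k_sel, aic = aics)
}

#' Exhaustive confounder-adjusted search for optimal cutoffs
#'
#' Enumerates every strictly ascending cutoff tuple on a grid, fits an
#' adjusted Cox model `Surv ~ stage category + confounders` for each, and
#' returns the admissible tuple optimizing the chosen criterion: maximal
#' partial log-likelihood (default; equivalent to minimal AIC at fixed df)
#' or maximal Harrell C-index of the adjusted model. Tuples leaving any
#' group below `min_group_frac` of subjects are inadmissible.
#'
#' @param cohort a `cohort_table` (or plain data.frame with the columns).
#' @param measurement measurement column name; must be complete.
#' @param confounders character vector of confounder column names (complete).
#' @param n_cutoffs number of cutoffs (default 2, i.e. 3 groups).
#' @param grid numeric vector of candidate cutoff locations; default is a
#'   `grid_step`-spaced grid spanning the 5th-95th percentile of the
#'   measurement.
#' @param grid_step grid spacing in mm (default 0.5).
#' @param min_group_frac minimum fraction of subjects per group (default
#'   0.10).
#' @param criterion `"loglik"` (default) or `"cindex"`.
#' @return an object of class `search_result`: `scheme` (the selected
#'   [staging_scheme()]), `candidates` (data.frame, one row per enumerated
#'   tuple: cutoffs, admissibility, loglik, aic, cindex, group sizes),
#'   `criterion`, `n_evaluated`.
#' @export
exhaustive_search <- function(cohort, measurement, confounders = character(),
                              n_cutoffs = 2, grid = NULL, grid_step = 0.5,
                              min_group_frac = 0.10,
                              criterion = c("loglik", "cindex")) {
  criterion <- match.arg(criterion)
  dat <- as.data.frame(cohort)
  x <- dat[[measurement]]
  if (anyNA(x)) stop("measurement must be complete (impute first)",
                     call. = FALSE)
  time <- dat$time; event <- dat$event
  if (is.null(grid)) {
    rng <- quantile(x, c(0.05, 0.95), names = FALSE)
    grid <- seq(ceiling(rng[1] / grid_step) * grid_step, rng[2],
                by = grid_step)
  }
  grid <- sort(unique(grid))
  if (length(grid) < n_cutoffs + 1L)
    stop("grid needs >= n_cutoffs + 1 points", call. = FALSE)
  conf_mm <- if (length(confounders)) {
    if (anyNA(dat[, confounders, drop = FALSE]))
      stop("confounders must be complete", call. = FALSE)
    model.matrix(~ ., dat[, confounders, drop = FALSE])[, -1, drop = FALSE]
  } else NULL

  tuples <- combn(grid, n_cutoffs)
  n <- length(x)
  min_n <- ceiling(min_group_frac * n)
  srv <- Surv(time, event)

  eval_one <- function(cuts) {
    g <- cut_by_scheme(x, cuts)
    sizes <- tabulate(g, nbins = n_cutoffs + 1L)
    admissible <- all(sizes >= min_n)
    if (!admissible)
      return(list(admissible = FALSE, sizes = sizes, loglik = NA_real_,
                  aic = NA_real_, cindex = NA_real_))
    gm <- model.matrix(~ factor(g, levels = seq_len(n_cutoffs + 1L)))[, -1,
                                                                      drop = FALSE]
    xx <- if (is.null(conf_mm)) gm else cbind(gm, conf_mm)
    fit <- tryCatch(
      suppressWarnings(coxph(srv ~ xx, ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit)))
      return(list(admissible = FALSE, sizes = sizes, loglik = NA_real_,
                  aic = NA_real_, cindex = NA_real_))
    ll <- fit$loglik[2]
    k <- length(coef(fit))
    ci <- if (criterion == "cindex")
      concordance_index(fit$linear.predictors, time, event)
    else NA_real_
    list(admissible = TRUE, sizes = sizes, loglik = ll,
         aic = -2 * ll + 2 * k, cindex = ci)
  }

  recs <- apply(tuples, 2L, eval_one)
  cand <- data.frame(t(tuples))
  names(cand) <- paste0("c", seq_len(n_cutoffs))
  cand$admissible <- vapply(recs, `[[`, TRUE, "admissible")
  cand$loglik <- vapply(recs, `[[`, 0, "loglik")
  cand$aic <- vapply(recs, `[[`, 0, "aic")
  cand$cindex <- vapply(recs, `[[`, 0, "cindex")
  sizes <- t(vapply(recs, `[[`, integer(n_cutoffs + 1L), "sizes"))
  colnames(sizes) <- paste0("n_g", seq_len(n_cutoffs + 1L))
  cand <- cbind(cand, sizes)

  if (!any(cand$admissible))
    stop("no admissible cutoff tuple under the constraints", call. = FALSE)
  score <- if (criterion == "loglik") cand$loglik else cand$cindex
  score[!cand$admissible] <- -Inf
  best <- which.max(score)
  scheme <- staging_scheme(measurement,
                           as.numeric(tuples[, best]))
  structure(list(scheme = scheme, candidates = cand, criterion = criterion,
                 n_evaluated = ncol(tuples), best_index = best,
                 grid = grid, min_group_frac = min_group_frac),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> evaluated", x$n_evaluated, "tuples; criterion:",
      x$criterion, "\n")
  print(x$scheme)
  invisible(x)
}

#' Apply a staging scheme to a cohort
#'
#' Assigns ordinal group labels and builds a per-group summary: n, %,
#' 5-year overall survival from the group Kaplan-Meier curve (survival at
#' 60 months, last value carried forward), and unadjusted plus (optionally)
#' confounder-adjusted hazard ratios versus the lowest group.
#'
#' @param scheme a [staging_scheme()].
#' @param cohort a `cohort_table` or data.frame with the measurement,
#'   `time` and `event` columns.
#' @param confounders optional confounder column names for adjusted HRs.
#' @param horizon months for the "h-year" survival summary (default 60).
#' @return list with `groups` (factor per subject, `NA` for missing
#'   measurement), `summary` (data.frame per group), `n_missing`,
#'   `violations` (labels of empty groups, if any).
#' @export
apply_scheme <- function(scheme, cohort, confounders = character(),
                         horizon = 60) {
  stopifnot(inherits(scheme, "staging_scheme"))
  dat <- as.data.frame(cohort)
  if (!scheme$measurement %in% names(dat))
    stop("measurement column '", scheme$measurement, "' not present",
         call. = FALSE)
  x <- dat[[scheme$measurement]]
  gi <- cut_by_scheme(x, scheme$cutoffs)
  groups <- factor(scheme$labels[gi], levels = scheme$labels)
  n_missing <- sum(is.na(gi))
  ok <- !is.na(gi)
  sizes <- table(groups[ok])
  violations <- names(sizes)[sizes == 0]
  if (length(violations))
    warning("empty group(s): ", paste(violations, collapse = ", "),
            call. = FALSE)

  surv_h <- vapply(scheme$labels, function(lv) {
    sel <- ok & groups == lv
    if (sum(sel) == 0L) return(NA_real_)
    km_surv_at(kaplan_meier(dat$time[sel], dat$event[sel]), horizon)
  }, 0)

  hr_unadj <- rep(NA_real_, length(scheme$labels))
  hr_adj <- rep(NA_real_, length(scheme$labels))
  hr_unadj[1] <- 1; hr_adj[1] <- 1
  if (length(violations) == 0L && sum(dat$event[ok]) > 0) {
    gfac <- droplevels(groups[ok])
    if (nlevels(gfac) > 1L) {
      fu <- tryCatch(suppressWarnings(
        coxph(Surv(dat$time[ok], dat$event[ok]) ~ gfac, ties = "breslow")),
        error = function(e) NULL)
      if (!is.null(fu)) hr_unadj[-1] <- exp(coef(fu))[seq_len(
        length(scheme$labels) - 1L)]
      if (length(confounders)) {
        cm <- model.matrix(~ ., dat[ok, confounders,
                                    drop = FALSE])[, -1, drop = FALSE]
        fa <- tryCatch(suppressWarnings(
          coxph(Surv(dat$time[ok], dat$event[ok]) ~ gfac + cm,
                ties = "breslow")), error = function(e) NULL)
        if (!is.null(fa))
          hr_adj[-1] <- exp(coef(fa))[seq_len(length(scheme$labels) - 1L)]
      }
    }
  }
  summary <- data.frame(
    group = scheme$labels,
    bound = c(paste0("<= ", scheme$cutoffs, " mm"),
              paste0("> ", scheme$cutoffs[length(scheme$cutoffs)], " mm")),
    n = as.integer(table(factor(groups[ok], levels = scheme$labels))),
    pct = as.numeric(table(factor(groups[ok], levels = scheme$labels))) /
      max(sum(ok), 1L) * 100,
    surv_at_horizon = surv_h * 100,
    hr_unadjusted = hr_unadj,
    hr_adjusted = if (length(confounders)) hr_adj else NA_real_,
    stringsAsFactors = FALSE)
  list(groups = groups, summary = summary, n_missing = n_missing,
       violations = violations, horizon = horizon)
}
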