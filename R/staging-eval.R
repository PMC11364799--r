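# Multi-criteria evaluation of staging schemes: concordance comparison,
# staging quality criteria (hazard consistency, hazard discrimination,
# sample-size balance, outcome prediction vs a recursive-partitioning
# benchmark), and decision curve analysis for time-to-event outcomes.

#' Survival recursive partitioning (log-rank tree)
#'
#' Greedy binary splitting: at each node, every candidate threshold of every
#' predictor is scored by the two-sample log-rank statistic; the best split
#' is kept if its Bonferroni-adjusted p-value (chi-square with 1 df, times
#' the number of candidate splits examined at the node) is below `alpha` and
#' both children hold at least `min_leaf` subjects. Growth also stops at
#' `max_depth`.
#'
#' @param data data.frame of continuous predictors.
#' @param time,event outcome vectors.
#' @param min_leaf minimum subjects per leaf (default 20).
#' @param max_depth maximum depth (default 3; root = depth 0).
#' @param alpha significance level for the adjusted split p (default 0.05).
#' @param max_candidates per-variable cap on candidate thresholds; when a
#'   variable has more distinct values, candidates are thinned to quantiles.
#' @return an object of class `rpa_tree`; see [rpa_leaves()] for leaf
#'   assignment.
#' @export
rpa_tree <- function(data, time, event, min_leaf = 20, max_depth = 3,
                     alpha = 0.05, max_candidates = 100) {
  data <- as.data.frame(data)
  stopifnot(nrow(data) == length(time), ncol(data) >= 1L)
  leaf_counter <- new.env()
  leaf_counter$next_id <- 1L

  grow <- function(idx, depth) {
    node <- list(n = length(idx), depth = depth,
                 n_event = sum(event[idx]))
    if (depth >= max_depth || length(idx) < 2 * min_leaf ||
        sum(event[idx]) < 2L)
      return(make_leaf(node, leaf_counter))
    best <- NULL
    n_tested <- 0L
    for (v in names(data)) {
      x <- data[[v]][idx]
      ux <- sort(unique(x[!is.na(x)]))
      if (length(ux) < 2L) next
      thr <- (ux[-1] + ux[-length(ux)]) / 2
      if (length(thr) > max_candidates)
        thr <- unique(quantile(x, seq(0.02, 0.98,
                                      length.out = max_candidates),
                               names = FALSE))
      for (tt in thr) {
        left <- idx[x <= tt]
        right <- idx[x > tt]
        if (length(left) < min_leaf || length(right) < min_leaf) next
        if (sum(event[left]) + sum(event[right]) < 1L) next
        n_tested <- n_tested + 1L
        g <- x <= tt
        chisq <- tryCatch(
          survdiff(Surv(time[idx], event[idx]) ~ g)$chisq,
          error = function(e) NA_real_)
        if (is.na(chisq)) next
        if (is.null(best) || chisq > best$chisq)
          best <- list(var = v, threshold = tt, chisq = chisq)
      }
    }
    if (is.null(best) || n_tested == 0L)
      return(make_leaf(node, leaf_counter))
    p_raw <- pchisq(best$chisq, 1L, lower.tail = FALSE)
    p_adj <- min(1, p_raw * n_tested)
    if (p_adj >= alpha) return(make_leaf(node, leaf_counter))
    x <- data[[best$var]][idx]
    node$split <- c(best, list(p_raw = p_raw, p_adj = p_adj,
                               n_tested = n_tested))
    node$left <- grow(idx[x <= best$threshold], depth + 1L)
    node$right <- grow(idx[x > best$threshold], depth + 1L)
    node
  }
  root <- grow(seq_len(nrow(data)), 0L)
  structure(list(root = root, variables = names(data),
                 n_leaves = leaf_counter$next_id - 1L,
                 min_leaf = min_leaf, max_depth = max_depth, alpha = alpha),
            class = "rpa_tree")
}

make_leaf <- function(node, counter) {
  node$leaf_id <- counter$next_id
  counter$next_id <- counter$next_id + 1L
  node
}

#' Leaf membership of a fitted survival tree
#'
#' @param tree an `rpa_tree`.
#' @param data data.frame with the tree's predictor columns.
#' @return integer leaf id per row.
#' @export
rpa_leaves <- function(tree, data) {
  stopifnot(inherits(tree, "rpa_tree"))
  data <- as.data.frame(data)
  assign_one <- function(node, row) {
    if (!is.null(node$leaf_id)) return(node$leaf_id)
    if (data[[node$split$var]][row] <= node$split$threshold)
      assign_one(node$left, row) else assign_one(node$right, row)
  }
  vapply(seq_len(nrow(data)), function(i) assign_one(tree$root, i), 1L)
}

#' @export
print.rpa_tree <- function(x, ...) {
  cat("<rpa_tree>", x$n_leaves, "leaves\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (!is.null(node$leaf_id)) {
      cat(pad, "leaf ", node$leaf_id, ": n=", node$n,
          " events=", node$n_event, "\n", sep = "")
    } else {
      cat(pad, node$split$var, " <= ", round(node$split$threshold, 2),
          " (chisq=", round(node$split$chisq, 1), ")\n", sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$root, 1)
  invisible(x)
}

#' Staging quality criteria (consistency, discrimination, balance,
#' outcome prediction)
#'
#' Bootstrap mean +/- sd of four staging-scheme quality metrics, each
#' normalized so that lower is better for the first three and higher is
#' better for outcome prediction:
#' \describe{
#'   \item{hazard consistency}{within-stage heterogeneity of outcome: each
#'     stage is split into sub-bins of the underlying measurement `x` (at
#'     the within-stage median), and the size-weighted mean absolute
#'     deviation of sub-bin mortality at `horizon` from the stage mean is
#'     averaged over stages and normalized by its maximum (0.5) to lie in
#'     [0, 1]. 0 = perfectly homogeneous stages.}
#'   \item{hazard discrimination}{1 minus the range of stage-level
#'     mortality at `horizon`; 0 = stages span the full mortality range
#'     (best), 1 = no separation (worst).}
#'   \item{balance}{normalized deviation of stage occupancy from uniform,
#'     `sum(|n_g/n - 1/G|) / (2 (1 - 1/G))`; exactly 0 for equal group
#'     sizes.}
#'   \item{outcome prediction}{the stage labels' Cox likelihood-ratio gain
#'     as a percentage of the gain achieved by the recursive-partitioning
#'     benchmark partition (grown once on the full data and held fixed over
#'     resamples).}
#' }
#'
#' @param labels stage assignment per subject (factor or character).
#' @param time,event outcome vectors.
#' @param x continuous measurement underlying the staging (needed for
#'   hazard consistency; `NA` returned for that metric when absent).
#' @param benchmark integer/factor benchmark partition per subject for
#'   outcome prediction; when `NULL` and `x` is given, an [rpa_tree()] on
#'   `x` provides it.
#' @param horizon months for the mortality summaries (default 60).
#' @param n_boot bootstrap resamples for the +/- sd (default 1000).
#' @param seed integer seed for the resamples.
#' @return list of four components (`hazard_consistency`,
#'   `hazard_discrimination`, `balance`, `outcome_prediction`), each
#'   `c(mean, sd)` over resamples, plus `point` (the full-sample values)
#'   and `flags`.
#' @export
groome_criteria <- function(labels, time, event, x = NULL, benchmark = NULL,
                            horizon = 60, n_boot = 1000, seed = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need >= 2 stages", call. = FALSE)
  flags <- character(0)
  ev_per_stage <- tapply(event, labels, sum)
  if (any(ev_per_stage == 0))
    flags <- c(flags, "stage with zero events; horizon mortality may be 0")
  if (is.null(benchmark) && !is.null(x)) {
    tree <- rpa_tree(data.frame(x = x), time, event,
                     min_leaf = max(10L, floor(0.05 * length(time))))
    benchmark <- rpa_leaves(tree, data.frame(x = x))
  }
  if (!is.null(benchmark)) benchmark <- as.integer(as.factor(benchmark))

  compute <- function(idx) {
    lab <- droplevels(labels[idx])
    tt <- time[idx]; ee <- event[idx]
    G <- nlevels(lab)
    if (G < 2L) return(rep(NA_real_, 4))
    n <- length(idx)
    sizes <- as.numeric(table(lab))
    balance <- sum(abs(sizes / n - 1 / G)) / (2 * (1 - 1 / G))
    mort <- vapply(levels(lab), function(g) {
      sel <- lab == g
      if (sum(ee[sel]) == 0L) return(0)
      1 - km_surv_at(kaplan_meier(tt[sel], ee[sel]), horizon)
    }, 0)
    discrimination <- 1 - (max(mort) - min(mort))
    consistency <- NA_real_
    if (!is.null(x)) {
      xx <- x[idx]
      per_stage <- vapply(levels(lab), function(g) {
        sel <- which(lab == g)
        if (length(sel) < 4L) return(0)
        med <- median(xx[sel])
        bin <- xx[sel] <= med
        if (length(unique(bin)) < 2L) return(0)
        mb <- vapply(c(TRUE, FALSE), function(b) {
          s2 <- sel[bin == b]
          if (sum(ee[s2]) == 0L) return(0)
          1 - km_surv_at(kaplan_meier(tt[s2], ee[s2]), horizon)
        }, 0)
        wb <- c(mean(bin), 1 - mean(bin))
        mbar <- sum(wb * mb)
        sum(wb * abs(mb - mbar))
      }, 0)
      wg <- sizes / n
      consistency <- sum(wg * per_stage) / 0.5
    }
    op <- NA_real_
    if (!is.null(benchmark)) {
      lr <- function(g) {
        g <- droplevels(as.factor(g))
        if (nlevels(g) < 2L) return(0)
        f <- tryCatch(suppressWarnings(
          coxph(Surv(tt, ee) ~ g, ties = "breslow")),
          error = function(e) NULL)
        if (is.null(f)) return(0)
        max(2 * (f$loglik[2] - f$loglik[1]), 0)
      }
      lr_stage <- lr(lab)
      lr_bench <- lr(benchmark[idx])
      op <- if (lr_bench > 1e-8) 100 * lr_stage / lr_bench else NA_real_
    }
    c(consistency, discrimination, balance, op)
  }

  point <- compute(seq_along(time))
  boots <- with_seed(child_seed(seed, "groome"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(time), replace = TRUE)
      compute(idx)
    }, numeric(4))
  })
  summarize <- function(i) {
    v <- boots[i, ]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(v), sd = sd(v))
  }
  list(hazard_consistency = summarize(1),
       hazard_discrimination = summarize(2),
       balance = summarize(3),
       outcome_prediction = summarize(4),
       point = setNames(point, c("hazard_consistency",
                                 "hazard_discrimination", "balance",
                                 "outcome_prediction")),
       flags = flags, n_boot = n_boot, horizon = horizon)
}

#' Decision curve analysis for a time-to-event risk model
#'
#' Net benefit over a grid of threshold probabilities at a fixed horizon,
#' with censoring handled by Kaplan-Meier: among subjects whose predicted
#' risk meets the threshold, the true- and false-positive fractions use the
#' KM event probability at the horizon rather than raw event counts.
#' `NB(p) = TP/n - FP/n * p/(1-p)`. Treat-all and treat-none references are
#' included; treat-none is identically 0 and treat-all tends to the overall
#' KM event probability as the threshold tends to 0.
#'
#' @param risk predicted event probability by `horizon`, per subject, in
#'   `[0, 1]`.
#' @param time,event outcome vectors.
#' @param horizon months (must not exceed the largest observed time).
#' @param thresholds threshold probabilities in (0, 1).
#' @return data.frame with `threshold`, `net_benefit`, `nb_all`, `nb_none`.
#' @export
dca_survival <- function(risk, time, event, horizon,
                         thresholds = seq(0.05, 0.6, by = 0.05)) {
  stopifnot(length(risk) == length(time))
  if (any(risk < 0 | risk > 1)) stop("risks must be in [0, 1]", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (horizon > max(time))
    stop("horizon exceeds follow-up", call. = FALSE)
  n <- length(risk)
  ev_all <- 1 - km_surv_at(kaplan_meier(time, event), horizon)
  nb <- vapply(thresholds, function(p) {
    sel <- risk >= p
    if (!any(sel)) return(0)
    s_sel <- km_surv_at(kaplan_meier(time[sel], event[sel]), horizon)
    tp <- (1 - s_sel) * mean(sel)
    fp <- s_sel * mean(sel)
    tp - fp * p / (1 - p)
  }, 0)
  nb_all <- vapply(thresholds, function(p)
    ev_all - (1 - ev_all) * p / (1 - p), 0)
  data.frame(threshold = thresholds, net_benefit = nb, nb_all = nb_all,
             nb_none = 0)
}

#' Full evaluation battery for a staging scheme
#'
#' Compares a staging scheme against a comparator (default: the pathological
#' depth-of-invasion scheme with 5 and 10 mm cutoffs, the 8th-edition AJCC
#' T-category convention) on: Harrell C-index with paired bootstrap
#' difference, the four staging quality criteria, decision curves at the
#' requested horizons, and per-group Kaplan-Meier summaries.
#'
#' Risk ordering for the C-index uses the Cox linear predictor of the stage
#' factor; decision-curve risks are the per-group KM event probabilities at
#' each horizon. Subjects missing either scheme's measurement are dropped
#' (complete-pair analysis).
#'
#' @param scheme a [staging_scheme()].
#' @param cohort a `cohort_table`.
#' @param comparator comparator scheme; default
#'   `staging_scheme("pDOI", c(5, 10))`.
#' @param confounders confounder columns for adjusted per-group HRs.
#' @param horizons months for DCA (default `c(36, 60)`).
#' @param n_boot bootstrap resamples for C-comparison and quality criteria.
#' @param seed integer seed.
#' @return an object of class `scheme_evaluation`.
#' @export
evaluate_scheme <- function(scheme, cohort,
                            comparator = staging_scheme("pDOI", c(5, 10)),
                            confounders = character(),
                            horizons = c(36, 60), n_boot = 1000, seed = 1) {
  stopifnot(inherits(scheme, "staging_scheme"),
            inherits(comparator, "staging_scheme"))
  dat <- as.data.frame(cohort)
  ok <- complete.cases(dat[, unique(c(scheme$measurement,
                                      comparator$measurement)),
                           drop = FALSE])
  dat <- dat[ok, , drop = FALSE]
  time <- dat$time; event <- dat$event

  app_a <- apply_scheme(scheme, dat, confounders = confounders,
                        horizon = max(horizons))
  app_b <- apply_scheme(comparator, dat, confounders = confounders,
                        horizon = max(horizons))
  if (nlevels(droplevels(app_a$groups)) < 2L)
    stop("degenerate scheme: a single occupied group", call. = FALSE)

  lp_of <- function(groups) {
    g <- droplevels(groups)
    if (nlevels(g) < 2L) return(rep(0, length(g)))
    unname(coxph(Surv(time, event) ~ g, ties = "breslow")$linear.predictors)
  }
  lp_a <- lp_of(app_a$groups)
  lp_b <- lp_of(app_b$groups)
  cc <- compare_c(lp_a, lp_b, time, event, n_boot = n_boot,
                  seed = child_seed(seed, "eval_c"))

  groome_a <- groome_criteria(app_a$groups, time, event,
                              x = dat[[scheme$measurement]],
                              horizon = max(horizons), n_boot = n_boot,
                              seed = child_seed(seed, "groome_a"))
  groome_b <- groome_criteria(app_b$groups, time, event,
                              x = dat[[comparator$measurement]],
                              horizon = max(horizons), n_boot = n_boot,
                              seed = child_seed(seed, "groome_b"))

  risk_at <- function(app, horizon) {
    dat_groups <- app$groups
    r <- vapply(levels(dat_groups), function(lv) {
      sel <- dat_groups == lv
      if (sum(sel) == 0L) return(NA_real_)
      1 - km_surv_at(kaplan_meier(time[sel], event[sel]), horizon)
    }, 0)
    unname(r[as.integer(dat_groups)])
  }
  dca <- lapply(horizons, function(h) {
    list(horizon = h,
         scheme = dca_survival(risk_at(app_a, h), time, event, h),
         comparator = dca_survival(risk_at(app_b, h), time, event, h))
  })
  names(dca) <- paste0("m", horizons)

  structure(list(scheme = scheme, comparator = comparator,
                 n = nrow(dat), n_dropped = sum(!ok),
                 c_index = cc$c_a, c_index_comparator = cc$c_b,
                 delta_c = cc$delta_c, delta_c_p = cc$p,
                 groome = groome_a, groome_comparator = groome_b,
                 dca = dca,
                 groups = app_a$summary, groups_comparator = app_b$summary,
                 seed = seed, n_boot = n_boot),
            class = "scheme_evaluation")
}

#' @export
print.scheme_evaluation <- function(x, ...) {
  cat("<scheme_evaluation> n =", x$n, "\n")
  cat("  C-index:", round(x$c_index, 3), "vs",
      round(x$c_index_comparator, 3),
      sprintf("(delta %+0.3f, p = %.3g)\n", x$delta_c, x$delta_c_p))
  fmt <- function(v) sprintf("%.2f +/- %.2f", v[1], v[2])
  cat("  quality criteria (scheme vs comparator):\n")
  for (nm in c("hazard_consistency", "hazard_discrimination", "balance",
               "outcome_prediction"))
    cat("   ", nm, ":", fmt(x$groome[[nm]]), "vs",
        fmt(x$groome_comparator[[nm]]), "\n")
  invisible(x)
}

#' Serialize a scheme evaluation to JSON
#'
#' @param evaluation a `scheme_evaluation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scheme_evaluation <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "scheme_evaluation"))
  e <- evaluation
  out <- list(
    scheme = list(measurement = e$scheme$measurement,
                  cutoffs = e$scheme$cutoffs),
    comparator = list(measurement = e$comparator$measurement,
                      cutoffs = e$comparator$cutoffs),
    n = e$n, n_dropped = e$n_dropped,
    c_index = num(e$c_index), c_index_comparator = num(e$c_index_comparator),
    delta_c = num(e$delta_c), delta_c_p = num(e$delta_c_p),
    groome = lapply(e$groome[c("hazard_consistency", "hazard_discrimination",
                               "balance", "outcome_prediction")],
                    function(v) list(mean = num(v[1]), sd = num(v[2]))),
    groome_comparator = lapply(
      e$groome_comparator[c("hazard_consistency", "hazard_discrimination",
                            "balance", "outcome_prediction")],
      function(v) list(mean = num(v[1]), sd = num(v[2]))),
    groups = e$groups, groups_comparator = e$groups_comparator,
    dca = lapply(e$dca, function(d)
      list(horizon = d$horizon, scheme = d$scheme,
           comparator = d$comparator)),
    seed = e$seed, n_boot = e$n_boot)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
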