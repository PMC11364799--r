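# Survival primitives shared by every pipeline stage. Model fitting is
# delegated to the survival package; wrappers expose the exact contracts the
# staging pipeline relies on (Breslow ties, Harrell concordance counting,
# Harrell-style restricted cubic spline bases).

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicator.
#' @return an object of class `km_curve` with components `time` (ascending
#'   event times), `survival`, `n_risk`, `n_event`, `median` (months, `NA`
#'   when the curve never crosses 0.5), and `n`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  if (any(time <= 0)) stop("all times must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "none")
  structure(list(time = fit$time, survival = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = unname(summary(fit)$table["median"]),
                 n = length(time)),
            class = "km_curve")
}

#' Survival probability S(t) from a Kaplan-Meier curve
#'
#' Right-continuous step-function lookup; beyond the last observed time the
#' last value is carried forward.
#'
#' @param curve a `km_curve`.
#' @param t time(s) in months.
#' @return survival probabilities.
#' @export
km_surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1 else curve$survival[max(idx)]
  }, 0)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, ", events =", sum(x$n_event),
      ", median =", round(x$median %||% NA, 1), "months\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival", ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * length(x$survival))])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Log-rank test across groups
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `chisq`, `df` (groups - 1), `p`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L)
    stop("log-rank test needs >= 2 groups", call. = FALSE)
  sd <- survdiff(Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Thin wrapper around [survival::coxph()] with Breslow tie handling,
#' returning the quantities the staging pipeline consumes. Constant columns
#' are dropped with a warning; non-convergence and separation diagnostics
#' from the underlying fitter are surfaced as warnings with a `flagged`
#' marker.
#'
#' @param x design matrix or data.frame of covariates (no missing cells).
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return an object of class `cox_fit`: `coefficients` (data.frame with
#'   `coef`, `se`, `hr`, `lower`, `upper`, `p`), `loglik`, `loglik_null`,
#'   `aic`, `linear_predictor`, `fit` (the underlying `coxph`).
#' @export
cox_fit <- function(x, time, event, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.data.frame(x)
  if (anyNA(x)) stop("design matrix has missing cells", call. = FALSE)
  mm <- model.matrix(~ ., data = x)[, -1, drop = FALSE]
  keep <- apply(mm, 2L, function(col) length(unique(col)) > 1L)
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(mm)[!keep], collapse = ", "), call. = FALSE)
    mm <- mm[, keep, drop = FALSE]
  }
  if (ncol(mm) > 0 && sum(event) < ncol(mm))
    stop("fewer events than model terms", call. = FALSE)
  flagged <- FALSE
  if (ncol(mm) == 0L) {
    fit <- coxph(Surv(time, event) ~ 1, ties = ties)
    coefs <- data.frame(coef = numeric(0), se = numeric(0), hr = numeric(0),
                        lower = numeric(0), upper = numeric(0),
                        p = numeric(0))
    lp <- rep(0, length(time))
    ll <- fit$loglik[1]
    ll0 <- ll
    k <- 0L
  } else {
    dat <- data.frame(.time = time, .event = event, mm, check.names = FALSE)
    fml <- as.formula(paste("Surv(.time, .event) ~",
                            paste(sprintf("`%s`", colnames(mm)),
                                  collapse = " + ")))
    fit <- withCallingHandlers(
      coxph(fml, data = dat, ties = ties),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (flagged)
      warning("Cox fit flagged: possible non-convergence or separation",
              call. = FALSE)
    s <- summary(fit)
    coefs <- data.frame(coef = coef(fit),
                        se = s$coefficients[, "se(coef)"],
                        hr = exp(coef(fit)),
                        lower = exp(coef(fit) - 1.96 *
                                      s$coefficients[, "se(coef)"]),
                        upper = exp(coef(fit) + 1.96 *
                                      s$coefficients[, "se(coef)"]),
                        p = s$coefficients[, "Pr(>|z|)"])
    lp <- unname(fit$linear.predictors)
    ll <- fit$loglik[2]
    ll0 <- fit$loglik[1]
    k <- length(coef(fit))
  }
  structure(list(coefficients = coefs, loglik = ll, loglik_null = ll0,
                 aic = -2 * ll + 2 * k, n = length(time),
                 n_event = sum(event), linear_predictor = lp,
                 flagged = flagged, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, ", events =", x$n_event,
      ", loglik =", round(x$loglik, 3), ", AIC =", round(x$aic, 2), "\n")
  if (nrow(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Restricted cubic spline basis (Harrell truncated-power parameterization)
#'
#' Builds the natural cubic spline basis that is linear beyond the boundary
#' knots: a linear column plus `k - 2` nonlinear columns for `k` knots, each
#' nonlinear column normalized by the squared boundary-knot span. Knots are
#' placed at the standard quantiles (3 knots: 0.10/0.50/0.90; 4 knots:
#' 0.05/0.35/0.65/0.95; 5 knots: 0.05/0.275/0.50/0.725/0.95) unless given.
#'
#' @param x numeric vector (mm).
#' @param n_knots 3, 4 or 5.
#' @param knots optional explicit knot locations (ascending).
#' @return an object of class `spline_basis`: `basis` (matrix with
#'   `n_knots - 1` columns), `knots`. Use [rcs_eval()] to evaluate the basis
#'   at new points.
#' @export
rcs_basis <- function(x, n_knots = 3, knots = NULL) {
  if (is.null(knots)) {
    if (!n_knots %in% 3:5) stop("n_knots must be 3, 4 or 5", call. = FALSE)
    qq <- switch(as.character(n_knots),
                 "3" = c(0.10, 0.50, 0.90),
                 "4" = c(0.05, 0.35, 0.65, 0.95),
                 "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
    knots <- unname(quantile(x, qq, na.rm = TRUE, type = 7))
  }
  if (length(unique(knots)) != length(knots))
    stop("insufficient distinct values to place ", length(knots),
         " distinct knots", call. = FALSE)
  if (length(unique(x[!is.na(x)])) < length(knots))
    stop("fewer distinct values than knots", call. = FALSE)
  structure(list(basis = rcs_eval_at(x, knots), knots = knots),
            class = "spline_basis")
}

#' @rdname rcs_basis
#' @param basis a `spline_basis`.
#' @export
rcs_eval <- function(basis, x) {
  stopifnot(inherits(basis, "spline_basis"))
  rcs_eval_at(x, basis$knots)
}

# Truncated-power RCS columns: x, then for j = 1..k-2
#   [(x-t_j)+^3 - (x-t_{k-1})+^3 (t_k-t_j)/(t_k-t_{k-1})
#                + (x-t_k)+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2
rcs_eval_at <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; span2 <- (tk - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pos3(x - tj) - pos3(x - tk1) * (tk - tj) / (tk - tk1) +
       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / span2
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2)))
  out
}

#' Harrell's concordance index
#'
#' Probability that, over usable pairs under right censoring, the subject
#' with the higher risk score experiences the event earlier; prediction ties
#' count 1/2. Pair counting is delegated to [survival::concordance()] with
#' `reverse = TRUE` so that larger scores mean higher risk.
#'
#' @param lp risk score (linear predictor) per subject; larger = higher risk.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @return the concordance index in `[0, 1]`.
#' @export
concordance_index <- function(lp, time, event) {
  if (length(lp) < 2L || sum(event) < 1L)
    stop("need >= 2 subjects and >= 1 event", call. = FALSE)
  cc <- concordance(Surv(time, event) ~ lp, reverse = TRUE,
                    timewt = "n")$count
  usable <- cc[["concordant"]] + cc[["discordant"]] + cc[["tied.x"]]
  if (usable == 0) stop("no usable pairs", call. = FALSE)
  unname((cc[["concordant"]] + 0.5 * cc[["tied.x"]]) / usable)
}

#' Paired bootstrap comparison of two concordance indices
#'
#' Resamples subjects with replacement, recomputes both C-indices on each
#' resample, and reports the observed difference with a two-sided bootstrap
#' p-value (proportion of resampled differences crossing zero, doubled and
#' capped at 1).
#'
#' @param pred_a,pred_b risk scores on the same subjects.
#' @param time,event outcome.
#' @param n_boot bootstrap resamples (default 1000; below 100 warns).
#' @param seed integer seed for the resample indices.
#' @return list with `c_a`, `c_b`, `delta_c`, `p`, `boot_delta` (vector).
#' @export
compare_c <- function(pred_a, pred_b, time, event, n_boot = 1000, seed = 1) {
  stopifnot(length(pred_a) == length(pred_b),
            length(pred_a) == length(time))
  if (n_boot < 100) warning("n_boot < 100: p-value will be unstable",
                            call. = FALSE)
  c_a <- concordance_index(pred_a, time, event)
  c_b <- concordance_index(pred_b, time, event)
  n <- length(time)
  boot_delta <- with_seed(child_seed(seed, "compare_c"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(event[idx]) < 1L) return(NA_real_)
      ca <- tryCatch(concordance_index(pred_a[idx], time[idx], event[idx]),
                     error = function(e) NA_real_)
      cb <- tryCatch(concordance_index(pred_b[idx], time[idx], event[idx]),
                     error = function(e) NA_real_)
      ca - cb
    }, 0)
  })
  boot_delta <- boot_delta[!is.na(boot_delta)]
  delta <- c_a - c_b
  # two-sided p: how often the bootstrap distribution crosses 0
  p_lo <- mean(boot_delta <= 0)
  p_hi <- mean(boot_delta >= 0)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(c_a = c_a, c_b = c_b, delta_c = delta, p = p, boot_delta = boot_delta)
}

#' Stepwise Cox model selection with forced-in terms
#'
#' Two-stage confounder selection: candidates are first screened by
#' univariate Cox Wald p-value (entry pool at `p_enter`, default 0.10), then
#' a bidirectional stepwise search by AIC runs over the screened pool.
#' Forced-in terms are always retained and never screened out.
#'
#' @param data data.frame holding the candidate columns.
#' @param candidates character vector of candidate column names.
#' @param time,event outcome vectors.
#' @param forced character vector of column names kept in every model.
#' @param p_enter univariate screening threshold.
#' @return list with `selected` (character, includes forced terms),
#'   `univariate_p` (named), `fit` (final `cox_fit`), `trace` (data.frame of
#'   steps).
#' @export
stepwise_cox <- function(data, candidates, time, event, forced = character(),
                         p_enter = 0.10) {
  if (length(candidates) == 0L && length(forced) == 0L)
    stop("empty candidate set", call. = FALSE)
  data <- as.data.frame(data)
  stopifnot(all(c(candidates, forced) %in% names(data)))
  candidates <- setdiff(candidates, forced)

  uni_p <- vapply(candidates, function(nm) {
    f <- tryCatch(cox_fit(data[, nm, drop = FALSE], time, event),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(f) || nrow(f$coefficients) == 0L) return(NA_real_)
    min(f$coefficients$p)
  }, 0)
  pool <- candidates[!is.na(uni_p) & uni_p < p_enter]

  current <- character()
  fit_aic <- function(terms) {
    cols <- c(forced, terms)
    if (length(cols) == 0L) {
      f0 <- coxph(Surv(time, event) ~ 1, ties = "breslow")
      return(-2 * f0$loglik[1])
    }
    cox_fit(data[, cols, drop = FALSE], time, event)$aic
  }
  best_aic <- fit_aic(current)
  trace <- data.frame(step = 0L, action = "start",
                      term = NA_character_, aic = best_aic,
                      stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    moves <- list()
    for (tm in setdiff(pool, current))
      moves[[paste0("+", tm)]] <- c(current, tm)
    for (tm in current)
      moves[[paste0("-", tm)]] <- setdiff(current, tm)
    if (length(moves) == 0L) break
    aics <- vapply(moves, fit_aic, 0)
    if (min(aics) >= best_aic - 1e-9) break
    pick <- names(which.min(aics))
    current <- moves[[pick]]
    best_aic <- min(aics)
    trace <- rbind(trace, data.frame(step = step_i,
                                     action = substr(pick, 1, 1),
                                     term = substring(pick, 2),
                                     aic = best_aic,
                                     stringsAsFactors = FALSE))
  }
  selected <- c(forced, current)
  final <- if (length(selected))
    cox_fit(data[, selected, drop = FALSE], time, event)
  else NULL
  list(selected = selected, univariate_p = uni_p, fit = final, trace = trace)
}
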