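# Fully conditional specification (chained-equation) multiple imputation
# for the measurement columns, with predictive mean matching, plus Rubin's
# rules for pooling Cox estimates across completed tables.

#' Nelson-Aalen cumulative hazard per subject
#'
#' Used to represent the censored outcome in the imputation predictor set
#' (event indicator + cumulative hazard at the observed time), the standard
#' encoding for imputation with survival outcomes.
#'
#' @param time,event outcome vectors.
#' @return cumulative hazard evaluated at each subject's observed time.
#' @export
nelson_aalen <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  n <- length(time)
  uniq <- unique(t_s[e_s == 1])
  haz <- vapply(uniq, function(tt) {
    sum(e_s == 1 & t_s == tt) / sum(t_s >= tt)
  }, 0)
  cumhaz <- cumsum(haz)
  vapply(time, function(tt) {
    idx <- which(uniq <= tt)
    if (length(idx) == 0L) 0 else cumhaz[max(idx)]
  }, 0)
}

#' Multiple imputation of measurement columns by chained equations
#'
#' Iteratively regresses each incomplete measurement column on all other
#' measurement columns, the (numerically coded) covariates, the event
#' indicator and the Nelson-Aalen cumulative hazard, cycling `iterations`
#' times per chain; `m` independent chains give `m` completed tables.
#' Continuous columns are imputed by predictive mean matching: a Bayesian
#' draw of the regression coefficients produces predictions for the missing
#' rows, each matched to its `donors` nearest observed predictions, one of
#' which donates its observed value. Deterministic given `seed`.
#'
#' Columns missing in more than 80% of rows are excluded from every
#' predictor set (with a warning) but are still imputed themselves; an
#' all-missing column is an error. Derived row-maximum columns (`rTTmax`,
#' `rDOImax`, `LDmax`) are recomputed from the completed members rather than
#' imputed.
#'
#' @param cohort a `cohort_table` (missingness confined to measurement
#'   columns).
#' @param m number of completed tables (default 5).
#' @param iterations FCS cycles per chain (default 10).
#' @param seed integer seed.
#' @param donors donor-pool size for predictive mean matching (default 5).
#' @return an object of class `imputation_result`: `tables` (list of `m`
#'   complete `cohort_table`s), `m`, `iterations`, `seed`,
#'   `chain_diagnostics` (per chain x iteration x variable mean of imputed
#'   values), `missing_summary`.
#' @export
fcs_impute <- function(cohort, m = 5, iterations = 10, seed = 1,
                       donors = 5) {
  stopifnot(inherits(cohort, "cohort_table"))
  roles <- cohort_roles(cohort)
  derived <- intersect(c("rTTmax", "rDOImax", "LDmax"), names(cohort))
  meas <- setdiff(intersect(roles$measurements, names(cohort)), derived)
  n <- nrow(cohort)

  miss_frac <- vapply(meas, function(nm) mean(is.na(cohort[[nm]])), 0)
  if (any(miss_frac >= 1))
    stop("column(s) entirely missing: ",
         paste(meas[miss_frac >= 1], collapse = ", "), call. = FALSE)
  heavy <- meas[miss_frac > 0.8]
  if (length(heavy))
    warning("excluding >80%-missing column(s) from predictor sets: ",
            paste(heavy, collapse = ", "), call. = FALSE)
  incomplete <- meas[miss_frac > 0]

  # auxiliary predictors: numerically coded covariates + outcome encoding
  aux <- data.frame(row.names = seq_len(n))
  for (nm in intersect(roles$covariates, names(cohort))) {
    v <- cohort[[nm]]
    if (is.factor(v) || is.character(v)) {
      mm <- model.matrix(~ f, data.frame(f = factor(v)))[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, "_", seq_len(ncol(mm)))
      aux <- cbind(aux, mm)
    } else aux[[nm]] <- as.numeric(v)
  }
  aux$.event <- cohort[[roles$event]]
  aux$.cumhaz <- nelson_aalen(cohort[[roles$time]], cohort[[roles$event]])

  if (length(incomplete) == 0L) {
    tables <- replicate(m, cohort, simplify = FALSE)
    return(structure(list(tables = tables, m = m, iterations = iterations,
                          seed = seed, chain_diagnostics = NULL,
                          missing_summary = miss_frac),
                     class = "imputation_result"))
  }

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      work <- as.data.frame(cohort)[, meas, drop = FALSE]
      # initialize missing cells by random draws from the observed values
      for (nm in incomplete) {
        obs <- work[[nm]][!is.na(work[[nm]])]
        idx <- is.na(work[[nm]])
        work[[nm]][idx] <- sample(obs, sum(idx), replace = TRUE)
      }
      diag <- matrix(NA_real_, iterations, length(incomplete),
                     dimnames = list(NULL, incomplete))
      for (it in seq_len(iterations)) {
        for (nm in incomplete) {
          mis <- is.na(cohort[[nm]])
          preds <- setdiff(setdiff(meas, heavy), nm)
          x <- cbind(as.matrix(work[, preds, drop = FALSE]), as.matrix(aux))
          work[[nm]][mis] <- pmm_draw(y = cohort[[nm]], x = x, mis = mis,
                                      donors = donors)
          diag[it, nm] <- mean(work[[nm]][mis])
        }
      }
      list(work = work, diag = diag)
    })
  }

  chains <- lapply(seq_len(m), function(i)
    run_chain(child_seed(seed, paste0("impute_chain_", i))))
  tables <- lapply(chains, function(ch) {
    out <- as.data.frame(cohort)
    out[, meas] <- ch$work
    out <- recompute_max_columns(out)
    as_cohort_table(out, measurement_cols = meas, roles = roles,
                    config = attr(cohort, "config"))
  })
  structure(list(tables = tables, m = m, iterations = iterations,
                 seed = seed,
                 chain_diagnostics = lapply(chains, `[[`, "diag"),
                 missing_summary = miss_frac),
            class = "imputation_result")
}

# One predictive-mean-matching update for a single target column.
# y: original column (with NAs); x: predictor matrix (current completed
# values); mis: logical missing mask. Returns imputed values for mis rows.
pmm_draw <- function(y, x, mis, donors = 5) {
  obs <- !mis
  x_obs <- cbind(1, x[obs, , drop = FALSE])
  # drop collinear columns via QR pivoting inside lm.fit
  fit <- stats::lm.fit(x_obs, y[obs])
  keep <- !is.na(fit$coefficients)
  beta_hat <- fit$coefficients[keep]
  x_obs_k <- x_obs[, keep, drop = FALSE]
  x_mis_k <- cbind(1, x[mis, , drop = FALSE])[, keep, drop = FALSE]
  df <- max(length(fit$residuals) - length(beta_hat), 1L)
  sigma2 <- sum(fit$residuals^2) / rchisq(1, df)
  xtx <- crossprod(x_obs_k)
  # ridge epsilon guards against numerically singular crossproducts
  chol_xtx <- tryCatch(chol(xtx),
                       error = function(e)
                         chol(xtx + diag(1e-8 * diag(xtx))))
  beta_star <- beta_hat + sqrt(sigma2) *
    backsolve(chol_xtx, rnorm(length(beta_hat)))
  yhat_obs <- drop(x_obs_k %*% beta_hat)
  yhat_mis <- drop(x_mis_k %*% beta_star)
  y_obs <- y[obs]
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[pool[sample.int(length(pool), 1L)]]
  }, 0)
}

#' Pool Cox estimates across imputed tables by Rubin's rules
#'
#' Pooled coefficient = mean of the per-table coefficients; total variance =
#' mean within-table variance + (1 + 1/m) x between-table variance. CIs and
#' p-values use the t reference with the classical Rubin degrees of freedom.
#'
#' @param fits list of per-table fits; each element either a `cox_fit` or a
#'   list with `coef` and `se` (named numeric vectors on an identical model
#'   specification).
#' @param conf_level confidence level.
#' @return data.frame with one row per coefficient: `coef`, `se`, `hr`,
#'   `lower`, `upper`, `p`, `df`, `between_var`, `within_var`.
#' @export
pool_cox <- function(fits, conf_level = 0.95) {
  if (length(fits) < 2L) stop("need m >= 2 fits", call. = FALSE)
  get_cs <- function(f) {
    if (inherits(f, "cox_fit"))
      list(coef = setNames(f$coefficients$coef, rownames(f$coefficients)),
           se = setNames(f$coefficients$se, rownames(f$coefficients)))
    else f
  }
  cs <- lapply(fits, get_cs)
  nm <- names(cs[[1]]$coef)
  for (f in cs)
    if (!identical(names(f$coef), nm))
      stop("mismatched coefficient vectors across fits", call. = FALSE)
  m <- length(cs)
  coef_mat <- do.call(rbind, lapply(cs, `[[`, "coef"))
  se_mat <- do.call(rbind, lapply(cs, `[[`, "se"))
  qbar <- colMeans(coef_mat)
  w <- colMeans(se_mat^2)
  b <- apply(coef_mat, 2L, var)
  t_var <- w + (1 + 1 / m) * b
  se <- sqrt(t_var)
  # Rubin (1987) df; infinite when between-variance is zero
  r <- (1 + 1 / m) * b / w
  df <- ifelse(b > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  alpha <- 1 - conf_level
  tcrit <- ifelse(is.finite(df), qt(1 - alpha / 2, df), qnorm(1 - alpha / 2))
  stat <- qbar / se
  p <- ifelse(is.finite(df), 2 * pt(-abs(stat), df), 2 * pnorm(-abs(stat)))
  data.frame(coef = qbar, se = se, hr = exp(qbar),
             lower = exp(qbar - tcrit * se), upper = exp(qbar + tcrit * se),
             p = p, df = df, between_var = b, within_var = w,
             row.names = nm)
}

#' Write completed tables as indexed CSVs plus diagnostics JSON
#'
#' @param result an `imputation_result`.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
write_imputation_result <- function(result, dir) {
  stopifnot(inherits(result, "imputation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(result$tables)) {
    p <- file.path(dir, sprintf("imp_%d.csv", i))
    write.csv(as.data.frame(result$tables[[i]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  dj <- file.path(dir, "imputation_diagnostics.json")
  jsonlite::write_json(
    list(m = result$m, iterations = result$iterations, seed = result$seed,
         missing_summary = as.list(result$missing_summary),
         chain_means = lapply(result$chain_diagnostics, function(d)
           if (is.null(d)) NULL else as.data.frame(d))),
    dj, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(c(paths, dj))
}
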