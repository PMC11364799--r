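#' Generate a synthetic right-censored staging cohort
#'
#' Simulates one row per subject: a latent pathological depth of invasion
#' (`pDOI`, mm, truncated normal), per-sequence radiological measurement
#' columns (latent anchor + sequence bias + Gaussian noise, floored at
#' 0.1 mm), correlated clinicopathological covariates, and an overall
#' survival outcome drawn from a Weibull proportional-hazards model whose
#' linear predictor combines the depth effect (linear per-mm log hazard
#' ratio, or a step function of depth when `config$step_hazard` is set) with
#' the covariate effects. Observed time is the minimum of the event time and
#' a uniform administrative censoring time. Missing measurement cells are
#' then punched per the configured per-sequence mechanism, and the derived
#' `rTTmax` / `rDOImax` / `LDmax` columns (row-wise maxima over non-missing
#' members of each measurement family) are recomputed afterwards.
#'
#' The generator is fully deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()] object.
#' @return a `cohort_table`: a `data.frame` with columns `subject_id`,
#'   `pDOI`, the measurement columns named in `config$sequence_bias`,
#'   `rTTmax`, `rDOImax`, `LDmax`, `morphology`, the covariates, `time`
#'   (months) and `event` (0/1). Column roles are attached as
#'   `attr(, "roles")`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects = 50, seed = 1))
#' mean(cohort$event)
#' @export
generate_cohort <- function(config) {
  config <- validate_synthetic_config(config)
  n <- as.integer(config$n_subjects)
  with_seed(child_seed(config$seed, "cohort"), {
    d <- config$true_doi_dist
    doi <- rtruncnorm(n, d[["mean"]], d[["sd"]], d[["min"]], d[["max"]])

    morph_levels <- names(config$morphology_mix)
    morphology <- sample(morph_levels, n, replace = TRUE,
                         prob = config$morphology_mix)
    noise_infl <- config$morphology_noise_factor[morphology]

    ld <- config$ld_latent
    ld_latent <- ld[["base"]] + ld[["scale"]] * doi +
      rnorm(n, 0, ld[["sd"]])

    meas <- lapply(names(config$sequence_bias), function(nm) {
      b <- config$sequence_bias[[nm]]
      anchor <- if (startsWith(nm, "LD")) ld_latent else doi
      pmax(anchor + b[[1]] + rnorm(n, 0, b[[2]]) * noise_infl, 0.1)
    })
    names(meas) <- names(config$sequence_bias)

    covs <- draw_covariates(config$covariate_spec, n)

    lp <- depth_linear_predictor(doi, config) + covs$lp
    bh <- config$baseline_hazard
    # Weibull PH: S(t | lp) = exp(-(t/scale)^shape * exp(lp))
    u <- runif(n)
    t_event <- bh[["scale"]] * (-log(u) / exp(lp))^(1 / bh[["shape"]])
    cens <- runif(n, config$censor_dist[["min"]], config$censor_dist[["max"]])
    time <- pmax(pmin(t_event, cens), 1e-6)
    event <- as.integer(t_event <= cens)

    tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      pDOI = doi, meas, morphology = morphology,
                      covs$values, time = time, event = event,
                      stringsAsFactors = FALSE)
    tab <- apply_missingness(tab, config)
    tab <- recompute_max_columns(tab)
    as_cohort_table(tab, measurement_cols = names(config$sequence_bias),
                    config = config)
  })
}

# Inverse-CDF truncated normal draw (deterministic given the RNG state).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

depth_linear_predictor <- function(doi, config) {
  if (is.null(config$step_hazard)) {
    config$log_hr_per_mm * (doi - config$true_doi_dist[["mean"]])
  } else {
    grp <- cut_by_scheme(doi, config$step_hazard$cutoffs)
    config$step_hazard$log_hrs[grp]
  }
}

draw_covariates <- function(spec, n) {
  values <- list()
  lp <- numeric(n)
  for (nm in names(spec)) {
    cv <- spec[[nm]]
    if (cv$dist == "normal") {
      x <- rnorm(n, cv$mean, cv$sd)
      lp <- lp + cv$log_hr * (x - (cv$center %||% cv$mean))
      values[[nm]] <- x
    } else if (cv$dist == "bernoulli") {
      x <- rbinom(n, 1L, cv$prob)
      lp <- lp + cv$log_hr * (x - cv$prob)
      values[[nm]] <- x
    } else if (cv$dist == "categorical") {
      idx <- sample(seq_along(cv$levels), n, replace = TRUE, prob = cv$probs)
      lp <- lp + cv$log_hr[idx] - sum(cv$log_hr * cv$probs)
      values[[nm]] <- factor(cv$levels[idx], levels = cv$levels)
    } else stop("unknown covariate dist '", cv$dist, "'", call. = FALSE)
  }
  list(values = as.data.frame(values, stringsAsFactors = FALSE), lp = lp)
}

apply_missingness <- function(tab, config) {
  n <- nrow(tab)
  for (nm in names(config$missingness)) {
    if (!nm %in% names(tab)) next
    ms <- config$missingness[[nm]]
    if (ms$prob <= 0) next
    if (ms$mechanism == "MCAR" || is.null(ms$covariate)) {
      p <- rep(ms$prob, n)
    } else {
      z <- as.numeric(tab[[ms$covariate]])
      z <- (z - mean(z)) / max(sd(z), 1e-12)
      p <- stats::plogis(stats::qlogis(ms$prob) + (ms$delta %||% 0) * z)
    }
    tab[[nm]][runif(n) < p] <- NA_real_
  }
  tab
}

# Row-wise maxima over the non-missing members of each measurement family;
# NA when every member is missing.
recompute_max_columns <- function(tab) {
  fam <- list(rTTmax = grep("^rTT_", names(tab), value = TRUE),
              rDOImax = grep("^rDOI_", names(tab), value = TRUE),
              LDmax = grep("^LD_", names(tab), value = TRUE))
  for (nm in names(fam)) {
    if (length(fam[[nm]]) == 0L) next
    m <- as.matrix(tab[, fam[[nm]], drop = FALSE])
    mx <- apply(m, 1L, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    tab[[nm]] <- mx
  }
  tab
}

as_cohort_table <- function(tab, measurement_cols, config = NULL,
                            roles = NULL) {
  if (is.null(roles)) {
    derived <- intersect(c("rTTmax", "rDOImax", "LDmax"), names(tab))
    covariates <- setdiff(names(tab),
                          c("subject_id", "pDOI", measurement_cols, derived,
                            "time", "event",
                            grep("^(observer2|repeat)_", names(tab),
                                 value = TRUE)))
    roles <- list(id = "subject_id", truth = "pDOI",
                  measurements = c(measurement_cols, derived),
                  covariates = covariates, time = "time", event = "event")
  }
  structure(tab, roles = roles, config = config,
            class = c("cohort_table", "data.frame"))
}

#' @export
as.data.frame.cohort_table <- function(x, ...) {
  attr(x, "roles") <- NULL
  attr(x, "config") <- NULL
  attr(x, "replicate_subjects") <- NULL
  class(x) <- "data.frame"
  x
}

#' Column roles of a cohort table
#'
#' @param cohort a `cohort_table`.
#' @return the named list of column roles (id, truth, measurements,
#'   covariates, time, event).
#' @export
cohort_roles <- function(cohort) attr(cohort, "roles")

#' Add second-observer and repeat-measurement replicate columns
#'
#' Re-reads the radiological measurements for a randomly selected fraction of
#' subjects, emulating an intra-observer repeat (same reader, later session)
#' and an independent second observer. Each replicate equals the subject's
#' original measurement plus Gaussian reading noise of sd
#' `config$observer_noise_sd` (so with zero noise the replicate columns
#' reproduce the originals exactly on the selected subjects). Non-selected
#' subjects carry `NA` in the replicate columns.
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param config the [synthetic_config()] used to build the cohort.
#' @param fraction fraction of subjects re-measured, in (0, 1]. Default 0.1.
#' @param columns measurement columns to replicate; defaults to all
#'   columns named in `config$sequence_bias`.
#' @return the cohort with added `repeat_<col>` (intra-observer) and
#'   `observer2_<col>` (inter-observer) columns.
#' @export
generate_observer_replicates <- function(cohort, config, fraction = 0.1,
                                         columns = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  columns <- columns %||% intersect(names(config$sequence_bias),
                                    names(cohort))
  n <- nrow(cohort)
  n_sel <- max(1L, round(fraction * n))
  with_seed(child_seed(config$seed, "replicates"), {
    sel <- sort(sample.int(n, n_sel))
    for (nm in columns) {
      for (prefix in c("repeat_", "observer2_")) {
        col <- rep(NA_real_, n)
        col[sel] <- pmax(cohort[[nm]][sel] +
                           rnorm(n_sel, 0, config$observer_noise_sd), 0.1)
        cohort[[paste0(prefix, nm)]] <- col
      }
    }
  })
  attr(cohort, "replicate_subjects") <- sel <- which(
    !is.na(cohort[[paste0("repeat_", columns[1])]]))
  cohort
}
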