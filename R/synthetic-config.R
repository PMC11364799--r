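#' Configuration for the synthetic cohort generator
#'
#' Builds a validated parameter set for [generate_cohort()]. The defaults
#' emulate a surgical oral-tongue cancer cohort: a latent pathological depth
#' of invasion (pDOI) around 8.3 +/- 4.8 mm, MR measurement columns that read
#' that depth with a per-sequence additive bias of about 3-3.4 mm and 4 mm
#' Gaussian noise (the radiological-vs-pathological disagreement typically
#' reported for this disease), a per-mm hazard ratio of 1.08 on overall
#' survival, and uniform administrative censoring yielding roughly a quarter
#' of subjects with events over a 36-156 month follow-up window.
#'
#' @param n_subjects number of subjects to simulate.
#' @param true_doi_dist latent depth distribution: named vector with `mean`,
#'   `sd`, `min`, `max` (mm). Depth is a truncated normal on `[min, max]`.
#' @param sequence_bias named list mapping each radiological measurement
#'   column to `c(bias, sd)` in mm: the additive offset and Gaussian noise of
#'   that sequence's reading. Depth-type columns (`rTT_*`, `rDOI_*`) are
#'   anchored to the latent depth; diameter columns (`LD_*`) to a latent
#'   in-plane diameter (see `ld_latent`).
#' @param ld_latent in-plane largest-diameter latent: `c(base, scale, sd)`
#'   so that LD_latent = base + scale * depth + N(0, sd).
#' @param morphology_mix proportions of `flat`, `ulcerative`, `exophytic`
#'   tumors (must sum to 1).
#' @param morphology_noise_factor multiplicative noise-sd inflation per
#'   morphology; the ulcerative default (1.5) reproduces the weaker
#'   radiology-pathology correlation seen in ulcerated lesions.
#' @param log_hr_per_mm log hazard ratio per mm of latent depth
#'   (default `log(1.08)`), used when `step_hazard` is `NULL`.
#' @param step_hazard optional step-function risk in depth instead of the
#'   linear term: `list(cutoffs = c(...), log_hrs = c(...))` with
#'   `length(log_hrs) == length(cutoffs) + 1`. Groups follow the
#'   "value <= cutoff belongs to the lower group" convention.
#' @param baseline_hazard Weibull baseline: named vector with `shape` and
#'   `scale` (months), for the hazard of a subject at covariate means.
#' @param censor_dist administrative censoring window: `c(min, max)` months,
#'   uniform.
#' @param covariate_spec named list of covariate generators; each element is
#'   `list(dist = "normal"|"bernoulli"|"categorical", ...params, log_hr)`.
#'   See defaults for the expected shapes.
#' @param missingness named list per measurement column:
#'   `list(prob, mechanism = "MCAR"|"MAR", covariate, delta)`. Under MAR the
#'   missingness log-odds shift by `delta` per standardized unit of the
#'   named covariate.
#' @param observer_noise_sd mm; reading noise added to build second-observer
#'   and repeat-measurement replicate columns.
#' @param seed integer master seed; all generator randomness derives from it.
#'
#' @return an object of class `synthetic_config` (a validated named list).
#' @seealso [generate_cohort()], [generate_observer_replicates()]
#' @export
synthetic_config <- function(n_subjects = 280,
                             true_doi_dist = c(mean = 8.3, sd = 4.8,
                                               min = 0, max = 36),
                             sequence_bias = NULL,
                             ld_latent = c(base = 4, scale = 2.1, sd = 3),
                             morphology_mix = c(flat = 0.882,
                                                ulcerative = 0.079,
                                                exophytic = 0.039),
                             morphology_noise_factor = c(flat = 1,
                                                         ulcerative = 1.5,
                                                         exophytic = 0.8),
                             log_hr_per_mm = log(1.08),
                             step_hazard = NULL,
                             baseline_hazard = c(shape = 1.1, scale = 230),
                             censor_dist = c(min = 12, max = 120),
                             covariate_spec = NULL,
                             missingness = NULL,
                             observer_noise_sd = 1.2,
                             seed = 1L) {
  if (is.null(sequence_bias)) sequence_bias <- default_sequence_bias()
  if (is.null(covariate_spec)) covariate_spec <- default_covariate_spec()
  if (is.null(missingness)) missingness <- default_missingness()
  cfg <- structure(
    list(n_subjects = n_subjects,
         true_doi_dist = true_doi_dist,
         sequence_bias = sequence_bias,
         ld_latent = ld_latent,
         morphology_mix = morphology_mix,
         morphology_noise_factor = morphology_noise_factor,
         log_hr_per_mm = log_hr_per_mm,
         step_hazard = step_hazard,
         baseline_hazard = baseline_hazard,
         censor_dist = censor_dist,
         covariate_spec = covariate_spec,
         missingness = missingness,
         observer_noise_sd = observer_noise_sd,
         seed = seed),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
}

# Per-sequence (bias, noise sd) in mm. Depth-type defaults follow the
# reported Bland-Altman radiology-pathology differences (about 3 +/- 4 mm);
# diameter columns are anchored to the LD latent with small offsets.
default_sequence_bias <- function() {
  list(
    rTT_aT2  = c(bias = 3.1, sd = 4.0),
    rTT_aCE  = c(bias = 3.1, sd = 4.0),
    rTT_cCE  = c(bias = 3.4, sd = 4.2),
    rTT_sCE  = c(bias = 7.1, sd = 4.5),
    rDOI_aT2 = c(bias = 3.0, sd = 3.9),
    rDOI_aCE = c(bias = 3.3, sd = 4.0),
    rDOI_cCE = c(bias = 3.4, sd = 4.1),
    LD_aT2   = c(bias = 0.0, sd = 4.5),
    LD_aCE   = c(bias = 0.2, sd = 4.5),
    LD_cCE   = c(bias = -2.0, sd = 4.3),
    LD_sCE   = c(bias = -0.6, sd = 4.4)
  )
}

# Clinicopathological covariates with prevalences matching a typical
# non-metastatic pT1-3 oral tongue cohort; log hazard ratios are moderate
# conditional effects. Continuous covariates are centered at `center` in the
# linear predictor so the baseline hazard refers to an average subject.
default_covariate_spec <- function() {
  list(
    age = list(dist = "normal", mean = 53, sd = 13, center = 53,
               log_hr = log(1.02)),
    sex_female = list(dist = "bernoulli", prob = 0.343, log_hr = log(0.5)),
    smoking = list(dist = "bernoulli", prob = 0.361, log_hr = log(1.5)),
    alcohol = list(dist = "bernoulli", prob = 0.196, log_hr = log(1.6)),
    betel = list(dist = "bernoulli", prob = 0.05, log_hr = log(1.8)),
    pN_stage = list(dist = "categorical",
                    levels = c("N0", "N1", "N2", "N3"),
                    probs = c(0.732, 0.086, 0.157, 0.025),
                    log_hr = c(0, log(2.0), log(3.0), log(4.0))),
    margin_positive = list(dist = "bernoulli", prob = 0.011,
                           log_hr = log(3.0)),
    extranodal_extension = list(dist = "bernoulli", prob = 0.029,
                                log_hr = log(3.5))
  )
}

# Sequence-specific missing probabilities (MCAR by default). The sagittal
# acquisition is most often unavailable; axial sequences rarely are.
default_missingness <- function() {
  probs <- c(rTT_aT2 = 0.04, rTT_aCE = 0.03, rTT_cCE = 0.08, rTT_sCE = 0.12,
             rDOI_aT2 = 0.04, rDOI_aCE = 0.03, rDOI_cCE = 0.08,
             LD_aT2 = 0.04, LD_aCE = 0.03, LD_cCE = 0.08, LD_sCE = 0.12)
  lapply(as.list(probs), function(p)
    list(prob = unname(p), mechanism = "MCAR", covariate = NULL, delta = 0))
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  n_subjects:", x$n_subjects, " seed:", x$seed, "\n")
  cat("  latent depth: mean", x$true_doi_dist[["mean"]], "sd",
      x$true_doi_dist[["sd"]], "mm, truncated [",
      x$true_doi_dist[["min"]], ",", x$true_doi_dist[["max"]], "]\n")
  if (is.null(x$step_hazard)) {
    cat("  risk: linear, HR/mm =", round(exp(x$log_hr_per_mm), 3), "\n")
  } else {
    cat("  risk: step at (", paste(x$step_hazard$cutoffs, collapse = ", "),
        ") mm, HRs (", paste(round(exp(x$step_hazard$log_hrs), 2),
                             collapse = ", "), ")\n")
  }
  cat("  measurements:", length(x$sequence_bias), "columns;",
      length(x$covariate_spec), "covariates\n")
  invisible(x)
}

validate_synthetic_config <- function(cfg) {
  reject <- function(name, msg)
    stop("invalid synthetic_config parameter '", name, "': ", msg,
         call. = FALSE)
  finite_num <- function(x, name) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      reject(name, "must be finite numeric")
  }
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1L ||
      !is.finite(cfg$n_subjects) || cfg$n_subjects < 1)
    reject("n_subjects", "must be a single number >= 1")
  finite_num(cfg$true_doi_dist, "true_doi_dist")
  d <- cfg$true_doi_dist
  if (!all(c("mean", "sd", "min", "max") %in% names(d)))
    reject("true_doi_dist", "needs named mean, sd, min, max")
  if (d[["sd"]] < 0) reject("true_doi_dist", "sd must be >= 0")
  if (d[["min"]] >= d[["max"]]) reject("true_doi_dist", "min must be < max")
  for (nm in names(cfg$sequence_bias)) {
    b <- cfg$sequence_bias[[nm]]
    finite_num(b, paste0("sequence_bias$", nm))
    if (length(b) != 2L) reject(paste0("sequence_bias$", nm),
                                "needs (bias, sd)")
    if (b[[2]] < 0) reject(paste0("sequence_bias$", nm), "sd must be >= 0")
  }
  finite_num(cfg$ld_latent, "ld_latent")
  if (cfg$ld_latent[["sd"]] < 0) reject("ld_latent", "sd must be >= 0")
  finite_num(cfg$morphology_mix, "morphology_mix")
  if (any(cfg$morphology_mix < 0) || any(cfg$morphology_mix > 1))
    reject("morphology_mix", "proportions must be in [0, 1]")
  if (abs(sum(cfg$morphology_mix) - 1) > 1e-8)
    reject("morphology_mix", "must sum to 1")
  finite_num(cfg$morphology_noise_factor, "morphology_noise_factor")
  if (any(cfg$morphology_noise_factor < 0))
    reject("morphology_noise_factor", "must be >= 0")
  finite_num(cfg$log_hr_per_mm, "log_hr_per_mm")
  if (!is.null(cfg$step_hazard)) {
    finite_num(cfg$step_hazard$cutoffs, "step_hazard$cutoffs")
    finite_num(cfg$step_hazard$log_hrs, "step_hazard$log_hrs")
    if (is.unsorted(cfg$step_hazard$cutoffs, strictly = TRUE))
      reject("step_hazard$cutoffs", "must be strictly ascending")
    if (length(cfg$step_hazard$log_hrs) !=
        length(cfg$step_hazard$cutoffs) + 1L)
      reject("step_hazard$log_hrs", "needs one more entry than cutoffs")
  }
  finite_num(cfg$baseline_hazard, "baseline_hazard")
  if (any(cfg$baseline_hazard <= 0))
    reject("baseline_hazard", "shape and scale must be > 0")
  finite_num(cfg$censor_dist, "censor_dist")
  if (cfg$censor_dist[["min"]] <= 0 ||
      cfg$censor_dist[["min"]] > cfg$censor_dist[["max"]])
    reject("censor_dist", "need 0 < min <= max")
  for (nm in names(cfg$covariate_spec)) {
    cv <- cfg$covariate_spec[[nm]]
    finite_num(cv$log_hr, paste0("covariate_spec$", nm, "$log_hr"))
    if (cv$dist == "bernoulli") check_prob(cv$prob, paste0(nm, "$prob"))
    if (cv$dist == "categorical") {
      finite_num(cv$probs, paste0(nm, "$probs"))
      if (abs(sum(cv$probs) - 1) > 1e-8)
        reject(paste0("covariate_spec$", nm), "probs must sum to 1")
      if (length(cv$log_hr) != length(cv$levels))
        reject(paste0("covariate_spec$", nm),
               "log_hr must match number of levels")
    }
  }
  for (nm in names(cfg$missingness)) {
    ms <- cfg$missingness[[nm]]
    check_prob(ms$prob, paste0("missingness$", nm, "$prob"))
    if (!ms$mechanism %in% c("MCAR", "MAR"))
      reject(paste0("missingness$", nm), "mechanism must be MCAR or MAR")
  }
  check_scalar(cfg$observer_noise_sd, "observer_noise_sd", lower = 0)
  check_scalar(cfg$seed, "seed")
  cfg
}

#' Read or write a generator configuration as YAML
#'
#' @param cfg a `synthetic_config` object.
#' @param path file path.
#' @return `read_synthetic_config` returns a validated `synthetic_config`;
#'   `write_synthetic_config` returns `path` invisibly.
#' @export
write_synthetic_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synthetic_config"))
  # YAML sequences drop vector names: emit named vectors as maps
  friendly <- function(x) {
    if (is.list(x)) lapply(x, friendly)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(friendly(unclass(cfg)), path, precision = 15)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML represents named numeric vectors as maps and vectors as sequences;
  # collapse homogeneous scalar lists back to atomic vectors, recursively,
  # then revalidate through the constructor.
  normalize <- function(x) {
    if (!is.list(x) || length(x) == 0L) return(x)
    kids <- lapply(x, normalize)
    scalar <- vapply(kids, function(k)
      is.atomic(k) && !is.list(k) && length(k) == 1L && !is.null(k), TRUE)
    if (all(scalar)) {
      types <- vapply(kids, function(k) class(k)[1], "")
      if (length(unique(types)) == 1L && types[1] %in%
          c("numeric", "integer", "character", "logical"))
        return(unlist(kids))
    }
    kids
  }
  raw <- lapply(raw, normalize)
  raw <- raw[!vapply(raw, is.null, TRUE)]
  do.call(synthetic_config, raw)
}
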