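# End-to-end staging workflow: agreement -> imputation -> confounder
# selection -> cutoff-count selection -> exhaustive search per measurement
# -> scheme evaluation -> final comparison, with seeded determinism and
# file artifacts per stage.

#' Read a subject-level cohort CSV with declared column roles
#'
#' @param path CSV file with a header row.
#' @param role_map named list declaring column roles: `time`, `event`
#'   (mandatory), `measurements` (character vector, mandatory), and
#'   optionally `covariates`, `id`, `truth`. A sidecar
#'   `<path>.schema.json` written by [write_cohort()] is used when
#'   `role_map` is `NULL`.
#' @param dec decimal separator (default `"."`).
#' @return a validated `cohort_table`.
#' @export
read_cohort <- function(path, role_map = NULL, dec = ".") {
  if (is.null(role_map)) {
    schema <- paste0(path, ".schema.json")
    if (!file.exists(schema))
      stop("role_map not given and no sidecar schema found at ", schema,
           call. = FALSE)
    role_map <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  for (mandatory in c("time", "event", "measurements"))
    if (is.null(role_map[[mandatory]]))
      stop("role_map is missing mandatory role '", mandatory, "'",
           call. = FALSE)
  dat <- read.csv(path, dec = dec, stringsAsFactors = FALSE)
  referenced <- unlist(role_map[c("time", "event", "measurements",
                                  "covariates", "id", "truth")],
                       use.names = FALSE)
  absent <- setdiff(referenced, names(dat))
  if (length(absent))
    stop("columns referenced in role_map are absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  tt <- dat[[role_map$time]]
  if (any(!is.finite(tt) | tt <= 0))
    stop("non-positive or non-finite time at row(s): ",
         paste(head(which(!is.finite(tt) | tt <= 0), 5), collapse = ", "),
         call. = FALSE)
  ev <- dat[[role_map$event]]
  if (!all(ev %in% c(0, 1)))
    stop("event outside {0,1} at row(s): ",
         paste(head(which(!ev %in% c(0, 1)), 5), collapse = ", "),
         call. = FALSE)
  for (nm in role_map$measurements) {
    v <- dat[[nm]]
    if (any(v[!is.na(v)] < 0))
      stop("negative measurement in '", nm, "' at row(s): ",
           paste(head(which(!is.na(v) & v < 0), 5), collapse = ", "),
           call. = FALSE)
  }
  names(dat)[names(dat) == role_map$time] <- "time"
  names(dat)[names(dat) == role_map$event] <- "event"
  roles <- list(id = role_map$id %||% NULL, truth = role_map$truth %||% NULL,
                measurements = role_map$measurements,
                covariates = role_map$covariates %||% character(),
                time = "time", event = "event")
  as_cohort_table(dat, measurement_cols = role_map$measurements,
                  roles = roles)
}

#' Write a cohort as CSV plus a sidecar JSON schema of column roles
#'
#' @param cohort a `cohort_table`.
#' @param path CSV destination; the schema goes to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  roles <- cohort_roles(cohort)
  jsonlite::write_json(roles, paste0(path, ".schema.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param cohort an existing `cohort_table`, or `NULL` to simulate one from
#'   `synthetic`.
#' @param synthetic a [synthetic_config()] used when `cohort` is `NULL`.
#' @param measurements measurement columns to search over; default: the
#'   radiological depth columns plus their row-maximum.
#' @param confounder_candidates covariate columns screened for confounding;
#'   default: all covariate-role columns.
#' @param forced_confounders covariates always kept (clinical significance
#'   overrides statistics); default `c("sex_female", "betel")` when present.
#' @param impute run chained-equation imputation when measurements have
#'   missing cells (default `TRUE`); when `FALSE`, complete-case analysis.
#' @param m,iterations imputation chains and cycles.
#' @param grid_step,min_group_frac,criterion exhaustive-search settings
#'   (see [exhaustive_search()]).
#' @param n_boot bootstrap resamples for the evaluation battery.
#' @param horizons DCA horizons in months (default `c(36, 60)`).
#' @param comparator comparator scheme for the final evaluation; default
#'   pathological depth at 5 and 10 mm.
#' @param seed master seed; every stochastic stage derives an independent
#'   child stream from it.
#' @param out_dir output directory for artifacts (`NULL`: no files).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, synthetic = synthetic_config(),
                            measurements = NULL,
                            confounder_candidates = NULL,
                            forced_confounders = NULL,
                            impute = TRUE, m = 5, iterations = 10,
                            grid_step = 0.5, min_group_frac = 0.10,
                            criterion = "loglik", n_boot = 200,
                            horizons = c(36, 60),
                            comparator = staging_scheme("pDOI", c(5, 10)),
                            seed = 1, out_dir = NULL) {
  stopifnot(all(horizons > 0))
  check_scalar(seed, "seed")
  structure(list(cohort = cohort, synthetic = synthetic,
                 measurements = measurements,
                 confounder_candidates = confounder_candidates,
                 forced_confounders = forced_confounders,
                 impute = impute, m = m, iterations = iterations,
                 grid_step = grid_step, min_group_frac = min_group_frac,
                 criterion = criterion, n_boot = n_boot,
                 horizons = horizons, comparator = comparator,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full staging pipeline
#'
#' Executes, in order: cohort acquisition (load or simulate, with observer
#' replicates), measurement agreement, chained-equation imputation (when
#' enabled and needed), stepwise confounder selection, spline-based
#' cutoff-count selection, exhaustive cutoff search per candidate
#' measurement, and the full evaluation of the best scheme against the
#' comparator. Identical config + seed reproduce identical results and
#' byte-identical artifacts. Any stage failure aborts with an error naming
#' the stage; artifacts already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result`: `cohort`, `agreement`,
#'   `imputation`, `confounders`, `cutoff_count`, `searches` (per
#'   measurement), `selected` (best `search_result`), `evaluation`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (is.null(config$cohort)) {
      cfg <- config$synthetic
      cfg$seed <- child_seed(config$seed, "pipeline_cohort")
      ch <- generate_cohort(cfg)
      ch <- generate_observer_replicates(ch, cfg)
      note("simulated cohort: n = ", nrow(ch), ", events = ",
           sum(ch$event))
      ch
    } else {
      note("loaded cohort: n = ", nrow(config$cohort))
      config$cohort
    }
  })
  if (!is.null(out_dir))
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  roles <- cohort_roles(cohort)
  has_truth <- !is.null(roles$truth) && roles$truth %in% names(cohort)

  agreement <- stage("agreement", {
    if (has_truth) agreement_report(cohort) else NULL
  })
  if (!is.null(agreement) && !is.null(out_dir))
    write_agreement_report(agreement, file.path(out_dir, "agreement.json"))

  measurements <- config$measurements %||%
    intersect(c("rDOI_aT2", "rDOI_aCE", "rDOI_cCE", "rDOImax"),
              names(cohort))
  if (length(measurements) == 0L)
    stop("pipeline stage 'search' failed: no candidate measurements",
         call. = FALSE)

  miss_any <- anyNA(as.data.frame(cohort)[, setdiff(roles$measurements,
                                                    c("rTTmax", "rDOImax",
                                                      "LDmax")),
                                          drop = FALSE])
  imputation <- NULL
  work <- cohort
  if (miss_any) {
    if (config$impute) {
      imputation <- stage("imputation",
        fcs_impute(cohort, m = config$m, iterations = config$iterations,
                   seed = child_seed(config$seed, "pipeline_impute")))
      work <- imputation$tables[[1]]
      note("imputed ", sum(imputation$missing_summary > 0),
           " incomplete column(s); m = ", config$m)
      if (!is.null(out_dir))
        write_imputation_result(imputation, file.path(out_dir, "imputed"))
    } else {
      keep <- complete.cases(as.data.frame(cohort)[, measurements,
                                                   drop = FALSE])
      work <- cohort[keep, , drop = FALSE]
      attributes(work)$roles <- roles
      class(work) <- c("cohort_table", "data.frame")
      note("complete-case subset: n = ", nrow(work), " of ", nrow(cohort))
    }
  }
  wdat <- as.data.frame(work)

  confounders <- stage("confounders", {
    cands <- config$confounder_candidates %||% roles$covariates
    forced <- config$forced_confounders %||%
      intersect(c("sex_female", "betel"), names(work))
    cands <- setdiff(intersect(cands, names(work)), forced)
    sw <- stepwise_cox(wdat, cands, wdat$time, wdat$event, forced = forced)
    note("selected confounders: ", paste(sw$selected, collapse = ", "))
    sw$selected
  })

  cutoff_count <- stage("cutoff_count", {
    cc <- select_n_cutoffs(wdat[[measurements[1]]], wdat$time, wdat$event)
    note("cutoff count: ", cc$n_cutoffs, " (", cc$n_knots, " knots)")
    cc
  })

  searches <- stage("search", {
    res <- lapply(measurements, function(mm)
      exhaustive_search(work, mm, confounders = confounders,
                        n_cutoffs = cutoff_count$n_cutoffs,
                        grid_step = config$grid_step,
                        min_group_frac = config$min_group_frac,
                        criterion = config$criterion))
    names(res) <- measurements
    res
  })
  if (!is.null(out_dir))
    for (mm in measurements)
      write.csv(searches[[mm]]$candidates,
                file.path(out_dir, paste0("search_", mm, ".csv")),
                row.names = FALSE)

  selected <- stage("selection", {
    # rank candidate measurements by the C-index of their selected scheme
    cidx <- vapply(measurements, function(mm) {
      sch <- searches[[mm]]$scheme
      app <- apply_scheme(sch, work)
      g <- droplevels(app$groups)
      if (nlevels(g) < 2L) return(NA_real_)
      lp <- coxph(Surv(wdat$time, wdat$event) ~ g,
                  ties = "breslow")$linear.predictors
      concordance_index(lp, wdat$time, wdat$event)
    }, 0)
    best <- measurements[which.max(cidx)]
    note("selected measurement: ", best, " (C = ",
         round(max(cidx, na.rm = TRUE), 3), ")")
    searches[[best]]
  })

  evaluation <- stage("evaluation", {
    comp <- config$comparator
    if (!comp$measurement %in% names(work)) comp <- NULL
    if (is.null(comp)) NULL
    else evaluate_scheme(selected$scheme, work, comparator = comp,
                         confounders = confounders,
                         horizons = config$horizons,
                         n_boot = config$n_boot,
                         seed = child_seed(config$seed, "pipeline_eval"))
  })

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(measurement = selected$scheme$measurement,
           cutoffs = selected$scheme$cutoffs,
           labels = selected$scheme$labels,
           criterion = config$criterion,
           confounders = confounders,
           n_cutoffs = cutoff_count$n_cutoffs,
           seed = config$seed),
      file.path(out_dir, "selected_scheme.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = 10)
    if (!is.null(evaluation))
      write_scheme_evaluation(evaluation,
                              file.path(out_dir, "evaluation.json"))
    writeLines(pipeline_report_md(selected, evaluation, confounders, log),
               file.path(out_dir, "report.md"))
  }

  structure(list(cohort = cohort, agreement = agreement,
                 imputation = imputation, confounders = confounders,
                 cutoff_count = cutoff_count, searches = searches,
                 selected = selected, evaluation = evaluation, log = log,
                 config = config),
            class = "pipeline_result")
}

pipeline_report_md <- function(selected, evaluation, confounders, log) {
  sch <- selected$scheme
  lines <- c("# Staging pipeline report", "",
             paste0("Selected measurement: **", sch$measurement, "**"),
             paste0("Cutoffs: ", paste(sch$cutoffs, collapse = ", "),
                    " mm (groups ", paste(sch$labels, collapse = "/"),
                    ")"),
             paste0("Adjusted for: ", paste(confounders, collapse = ", ")),
             "")
  if (!is.null(evaluation)) {
    lines <- c(lines, "## Comparison with comparator scheme", "",
               sprintf("C-index %0.3f vs %0.3f (delta %+0.3f, p = %.3g)",
                       evaluation$c_index, evaluation$c_index_comparator,
                       evaluation$delta_c, evaluation$delta_c_p), "",
               "| group | bound | n | % | surv@h (%) | HR (unadj) |",
               "|---|---|---|---|---|---|")
    g <- evaluation$groups
    for (i in seq_len(nrow(g)))
      lines <- c(lines, sprintf("| %s | %s | %d | %0.1f | %0.1f | %0.2f |",
                                g$group[i], g$bound[i], g$n[i], g$pct[i],
                                g$surv_at_horizon[i], g$hr_unadjusted[i]))
    lines <- c(lines, "")
  }
  c(lines, "## Log", "", paste0("- ", log))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (l in x$log) cat("  -", l, "\n")
  invisible(x)
}
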