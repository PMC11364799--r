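test_that("the survival tree finds a single strong change-point", {
  set.seed(40)
  n <- 500
  x <- runif(n, 0, 20)
  lp <- ifelse(x > 8, log(4), 0)
  tt <- rexp(n, 0.03 * exp(lp))
  cens <- runif(n, 10, 80)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  tree <- rpa_tree(data.frame(x = x), time, ev, max_depth = 1)
  expect_null(tree$root$leaf_id)
  expect_lt(abs(tree$root$split$threshold - 8), 1)
  leaves <- rpa_leaves(tree, data.frame(x = x))
  expect_equal(sort(unique(leaves)), 1:2)
  expect_equal(as.integer(table(leaves)[1]), sum(x <= tree$root$split$threshold))
})

test_that("the survival tree refuses to split pure noise or tiny leaves", {
  set.seed(41)
  n <- 300
  x <- runif(n)
  time <- rexp(n, 0.05); ev <- rbinom(n, 1, 0.7)
  tree <- rpa_tree(data.frame(x = x), time, ev)
  expect_equal(tree$n_leaves, 1)
  tree2 <- rpa_tree(data.frame(x = rnorm(n)), time, ev, min_leaf = n)
  expect_equal(tree2$n_leaves, 1)
})

test_that("balance is exactly zero for equal groups and the quality metrics
           hit their best ends on well-separated groups", {
  set.seed(42)
  n_g <- 60
  labels <- rep(c("rT1", "rT2", "rT3"), each = n_g)
  rates <- c(0.005, 0.05, 0.4)
  time <- unlist(lapply(rates, function(r) rexp(n_g, r)))
  time <- pmin(time, 100)
  ev <- as.integer(time < 100)
  time[time == 100] <- 100
  x <- rep(c(4, 10, 16), each = n_g) + runif(3 * n_g, -1, 1)
  g <- groome_criteria(labels, time, ev, x = x, n_boot = 60, seed = 1)
  expect_equal(unname(g$point["balance"]), 0)
  expect_lt(g$point["hazard_discrimination"], 0.35)
  expect_lt(g$point["hazard_consistency"], 0.35)
  expect_true(all(c(g$hazard_consistency["sd"], g$balance["sd"]) >= 0))
})

test_that("permuted stage labels lose discrimination and outcome
           prediction", {
  set.seed(43)
  ch <- generate_cohort(step_config(n = 500, seed = 44))
  sch <- staging_scheme("pDOI", c(8, 12))
  app <- apply_scheme(sch, ch)
  g_true <- groome_criteria(app$groups, ch$time, ch$event, x = ch$pDOI,
                            n_boot = 40, seed = 2)
  perm <- sample(app$groups)
  g_perm <- groome_criteria(perm, ch$time, ch$event, x = ch$pDOI,
                            benchmark = rpa_leaves(
                              rpa_tree(data.frame(x = ch$pDOI), ch$time,
                                       ch$event),
                              data.frame(x = ch$pDOI)),
                            n_boot = 40, seed = 2)
  expect_gt(g_perm$point["hazard_discrimination"],
            g_true$point["hazard_discrimination"])
  expect_lt(g_perm$point["outcome_prediction"], 10)
  expect_gt(g_true$point["outcome_prediction"], 50)
})

test_that("merging two stages never increases outcome prediction", {
  for (s in 1:4) {
    ch <- generate_cohort(step_config(n = 300, seed = 50 + s))
    app <- apply_scheme(staging_scheme("pDOI", c(8, 12)), ch)
    bench <- rpa_leaves(rpa_tree(data.frame(x = ch$pDOI), ch$time,
                                 ch$event),
                        data.frame(x = ch$pDOI))
    fine <- groome_criteria(app$groups, ch$time, ch$event, x = ch$pDOI,
                            benchmark = bench, n_boot = 2, seed = 1)
    merged_labels <- as.character(app$groups)
    merged_labels[merged_labels == "rT3"] <- "rT2"
    merged <- groome_criteria(merged_labels, ch$time, ch$event, x = ch$pDOI,
                              benchmark = bench, n_boot = 2, seed = 1)
    expect_lte(merged$point["outcome_prediction"],
               fine$point["outcome_prediction"] + 1e-8)
  }
})

test_that("decision curves satisfy the reference identities", {
  set.seed(45)
  ch <- generate_cohort(synthetic_config(n_subjects = 400, seed = 46))
  km60 <- 1 - km_surv_at(kaplan_meier(ch$time, ch$event), 60)
  risk <- pmin(pmax(km60 + rnorm(400, 0, 0.05), 0), 1)
  dca <- dca_survival(risk, ch$time, ch$event, horizon = 60,
                      thresholds = c(0.001, seq(0.05, 0.6, 0.05)))
  expect_true(all(dca$nb_none == 0))
  # threshold -> 0: treat-all tends to the KM event probability
  expect_equal(dca$nb_all[1], km60, tolerance = 0.005)
  # no model beats treat-all at vanishing threshold
  expect_lte(dca$net_benefit[1], dca$nb_all[1] + 1e-10)
  # net benefit never exceeds the event prevalence
  expect_true(all(dca$net_benefit <= km60 + 1e-10))
  expect_error(dca_survival(risk, ch$time, ch$event, 60, thresholds = 1.2),
               "thresholds")
  expect_error(dca_survival(risk * 200, ch$time, ch$event, 60), "risks")
})

test_that("decision-curve arithmetic matches the hand confusion matrix when
           censoring is absent before the horizon", {
  time <- c(10, 20, 30, 70, 80, 90, 95, 99)
  ev <- c(1, 1, 1, 0, 0, 0, 0, 0)
  risk <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.1, 0.1, 0.1)
  p <- 0.5
  dca <- dca_survival(risk, time, ev, horizon = 60, thresholds = p)
  sel <- risk >= p  # subjects 1, 2, 4
  tp <- 2 / 8; fp <- 1 / 8
  expect_equal(dca$net_benefit, tp - fp * p / (1 - p), tolerance = 1e-10)
})

test_that("a scheme evaluated against itself is a tie and the battery is
           reproducible", {
  ch <- generate_cohort(complete_config(n = 250, seed = 47))
  sch <- staging_scheme("pDOI", c(5, 10))
  ev1 <- evaluate_scheme(sch, ch, comparator = sch, n_boot = 40, seed = 8)
  expect_equal(ev1$delta_c, 0)
  expect_gte(ev1$delta_c_p, 0.99)
  expect_equal(ev1$groome$point, ev1$groome_comparator$point)
  ev2 <- evaluate_scheme(sch, ch, comparator = sch, n_boot = 40, seed = 8)
  ev1$seed <- ev2$seed <- NULL
  expect_equal(ev1[c("c_index", "delta_c", "groome", "dca")],
               ev2[c("c_index", "delta_c", "groome", "dca")])
})

test_that("staging on the true risk variable beats a noisy surrogate", {
  sb <- synthetic_config()$sequence_bias
  sb$rDOI_aCE <- c(bias = 0, sd = 8)   # badly degraded surrogate
  ch <- generate_cohort(step_config(n = 800, seed = 48, sequence_bias = sb))
  true_sch <- staging_scheme("pDOI", c(8, 12))
  noisy_sch <- staging_scheme("rDOI_aCE", c(8, 12))
  ev <- evaluate_scheme(true_sch, ch, comparator = noisy_sch,
                        n_boot = 60, seed = 9)
  expect_gt(ev$delta_c, 0)
  expect_s3_class(ev, "scheme_evaluation")
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme_evaluation(ev, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$scheme$measurement, "pDOI")
})

test_that("degenerate schemes are refused", {
  ch <- generate_cohort(complete_config(n = 100, seed = 49))
  far <- staging_scheme("pDOI", c(200, 300))
  expect_error(suppressWarnings(
    evaluate_scheme(far, ch, n_boot = 20, seed = 1)), "degenerate")
})
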