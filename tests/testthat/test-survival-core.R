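test_that("Kaplan-Meier matches hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  cens <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_surv_at(cens, c(1, 2, 3, 10)) == 1))

  toy <- toy_surv()
  km2 <- kaplan_meier(toy$time, toy$event)
  expect_equal(km_surv_at(km2, 1), 4 / 5)
  expect_equal(km_surv_at(km2, 3.5), 4 / 5 * 2 / 3)
  expect_equal(km_surv_at(km2, 4), 4 / 5 * 2 / 3 * 1 / 2)
  expect_equal(km_surv_at(km2, 100), km_surv_at(km2, 4))  # carry-forward

  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(0, 1), c(1, 1)), "> 0")
})

test_that("Kaplan-Meier with no censoring equals the empirical survival
           function, and agrees with the independent oracle", {
  set.seed(6)
  tt <- sample(1:40, 60, replace = TRUE)
  km <- kaplan_meier(tt, rep(1, 60))
  for (q in c(5, 17, 33))
    expect_equal(km_surv_at(km, q), mean(tt > q))
  ev <- rbinom(60, 1, 0.6)
  km2 <- kaplan_meier(tt, ev)
  for (q in c(5, 17, 33))
    expect_equal(km_surv_at(km2, q), oracle_km(tt, ev, q))
})

test_that("log-rank equals the hand hypergeometric oracle", {
  toy <- rbind(toy_surv(), toy_surv())
  g <- rep(c("a", "b"), each = 5)
  same <- logrank(toy$time, toy$event, g)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  set.seed(7)
  tt <- c(rexp(25, 0.1), rexp(25, 0.25))
  ev <- rbinom(50, 1, 0.8)
  grp <- rep(1:2, each = 25)
  lr <- logrank(tt, ev, grp)
  expect_equal(lr$chisq, oracle_logrank2(tt, ev, grp), tolerance = 1e-8)
  expect_equal(lr$df, 1)

  lr3 <- logrank(c(tt, rexp(10, 0.5)), c(ev, rep(1, 10)),
                 c(grp, rep(3, 10)))
  expect_equal(lr3$df, 2)
  expect_error(logrank(tt, ev, rep(1, 50)), "2 groups")
})

test_that("Cox null log-likelihood equals the Breslow closed form", {
  set.seed(8)
  tt <- rexp(30); ev <- rbinom(30, 1, 0.7)
  fit <- cox_fit(data.frame(x = rep(1, 30)), tt, ev,
                 ties = "breslow") |> suppressWarnings()
  # each event contributes -log(risk-set size)
  ll0 <- -sum(vapply(which(ev == 1), function(i)
    log(sum(tt >= tt[i])), 0))
  expect_equal(fit$loglik, ll0, tolerance = 1e-10)
})

test_that("single-covariate Cox matches a brute-force likelihood search and
           solves the score equation", {
  set.seed(9)
  x <- rbinom(40, 1, 0.5)
  tt <- rexp(40, 0.1 * exp(0.8 * x))
  ev <- rbinom(40, 1, 0.8)
  fit <- cox_fit(data.frame(x = x), tt, ev)
  opt <- optimize(function(b) -oracle_breslow_loglik(b, x, tt, ev),
                  c(-4, 4), tol = 1e-9)
  expect_equal(fit$coefficients$coef, opt$minimum, tolerance = 1e-4)
  expect_lt(abs(oracle_breslow_score(fit$coefficients$coef, x, tt, ev)),
            1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 2)
})

test_that("constant covariates are dropped with a warning", {
  set.seed(10)
  tt <- rexp(30); ev <- rep(1, 30)
  expect_warning(fit <- cox_fit(data.frame(x = rnorm(30), z = rep(2, 30)),
                                tt, ev),
                 "constant")
  expect_equal(nrow(fit$coefficients), 1)
})

test_that("restricted cubic spline basis has the Harrell structure", {
  set.seed(11)
  x <- runif(200, 0, 30)
  b3 <- rcs_basis(x, 3)
  expect_equal(ncol(b3$basis), 2)
  expect_equal(length(b3$knots), 3)
  expect_equal(b3$knots, unname(quantile(x, c(0.1, 0.5, 0.9))))
  b5 <- rcs_basis(x, 5)
  expect_equal(ncol(b5$basis), 4)

  # nonlinear columns match the literal truncated-power formula
  grid <- seq(0, 30, by = 0.25)
  eval5 <- rcs_eval(b5, grid)
  for (j in 1:3)
    expect_equal(eval5[, j + 1], oracle_rcs_term(grid, b5$knots, j),
                 tolerance = 1e-10)

  # linear beyond the boundary knots: second differences vanish
  outside <- c(seq(-20, min(b5$knots) - 0.1, by = 0.5),
               seq(max(b5$knots) + 0.1, 60, by = 0.5))
  for (j in seq_len(ncol(eval5))) {
    lo <- rcs_eval(b5, seq(-30, min(b5$knots) - 1, length.out = 20))[, j]
    hi <- rcs_eval(b5, seq(max(b5$knots) + 1, 90, length.out = 20))[, j]
    expect_lt(max(abs(diff(diff(lo)))), 1e-8)
    expect_lt(max(abs(diff(diff(hi)))), 1e-8)
  }
  expect_error(rcs_basis(rep(1:2, 10), 4), "distinct")
})

test_that("concordance equals exhaustive pair enumeration", {
  # perfect ordering and constant predictor
  tt <- c(5, 4, 3, 2, 1); ev <- rep(1, 5)
  expect_equal(concordance_index(1:5, tt, ev), 1)
  expect_equal(concordance_index(rep(0, 5), tt, ev), 0.5)

  toy <- data.frame(time = c(3, 5, 2, 7, 7, 4),
                    event = c(1, 0, 1, 1, 0, 1),
                    lp = c(1.2, -0.5, 2, 0, 0.3, 1.2))
  expect_equal(concordance_index(toy$lp, toy$time, toy$event),
               oracle_concordance(toy$lp, toy$time, toy$event))

  set.seed(12)
  for (rep_i in 1:5) {
    n <- 30
    lp <- round(rnorm(n), 1)            # induce prediction ties
    tt <- sample(1:15, n, replace = TRUE)  # induce time ties
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1
    expect_equal(concordance_index(lp, tt, ev),
                 oracle_concordance(lp, tt, ev))
  }
})

test_that("paired bootstrap C comparison behaves at the null and is seeded", {
  set.seed(13)
  n <- 120
  lp <- rnorm(n)
  tt <- rexp(n, exp(0.8 * lp)); ev <- rbinom(n, 1, 0.7)
  same <- suppressWarnings(compare_c(lp, lp, tt, ev, n_boot = 150, seed = 3))
  expect_equal(same$delta_c, 0)
  expect_gte(same$p, 0.99)
  again <- suppressWarnings(compare_c(lp, lp, tt, ev, n_boot = 150, seed = 3))
  expect_identical(same$boot_delta, again$boot_delta)
  expect_warning(compare_c(lp, rnorm(n), tt, ev, n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("an informative predictor beats noise decisively in the C
           comparison", {
  set.seed(14)
  n <- 500
  risk <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(1.2 * risk))
  cens <- runif(n, 0, 40)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  res <- compare_c(risk, rnorm(n), time, ev, n_boot = 300, seed = 5)
  expect_gt(res$delta_c, 0.1)
  expect_lt(res$p, 0.01)
})

test_that("stepwise selection keeps forced terms and finds a strong
           covariate among noise", {
  set.seed(15)
  n <- 500
  dat <- data.frame(real = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), forced_cov = rnorm(n))
  tt <- rexp(n, 0.05 * exp(1.0 * dat$real))
  cens <- runif(n, 0, 50)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  sw <- stepwise_cox(dat, c("real", "n1", "n2", "n3"), time, ev,
                     forced = "forced_cov")
  expect_true("forced_cov" %in% sw$selected)
  expect_true("real" %in% sw$selected)

  # AIC must drop when the true risk variable joins the null model
  aic_null <- -2 * coxph(Surv(time, ev) ~ 1)$loglik[1]
  aic_real <- cox_fit(dat[, "real", drop = FALSE], time, ev)$aic
  expect_lt(aic_real, aic_null)
})

test_that("with pure-noise candidates only forced terms usually survive", {
  kept_extra <- vapply(1:5, function(r) {
    set.seed(100 + r)
    n <- 300
    dat <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                      forced_cov = rnorm(n))
    time <- rexp(n, 0.05); ev <- rbinom(n, 1, 0.6)
    sw <- stepwise_cox(dat, c("n1", "n2", "n3"), time, ev,
                       forced = "forced_cov")
    length(setdiff(sw$selected, "forced_cov"))
  }, 0)
  expect_gte(sum(kept_extra == 0), 3)
})
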