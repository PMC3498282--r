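# Diversification likelihoods, ML fits and AIC bookkeeping.

test_that("pure-birth log-likelihood matches hand evaluation and oracle", {
  bt <- as_branching_times(fixture_ages$three)
  expect_equal(loglik_pure_birth(1, bt), log(2) - 5, tolerance = 1e-12)
  expect_error(loglik_pure_birth(0, bt), "positive")
  expect_error(loglik_pure_birth(-1, bt), "positive")
  # lambda -> 0+ diverges to -Inf through the event terms
  expect_lt(loglik_pure_birth(1e-12, bt), -20)

  for (ages in fixture_ages) {
    bt <- as_branching_times(ages)
    for (lam in c(0.05, 0.2, 1, 3))
      expect_equal(loglik_pure_birth(lam, bt), oracle_pb_lnl(lam, ages),
                   tolerance = 1e-10)
  }
})

test_that("per-interval kernel matches hand value and reduces to pure birth", {
  bt <- as_branching_times(c(2, 1))
  expect_equal(loglik_rate_per_interval(c(0.1, 0.3), bt), log(0.2) - 1.1,
               tolerance = 1e-12)
  for (ages in fixture_ages) {
    bt <- as_branching_times(ages)
    n <- length(ages) + 1
    expect_equal(loglik_rate_per_interval(rep(0.31, n - 1), bt),
                 loglik_pure_birth(0.31, bt), tolerance = 1e-12)
    rates <- seq(0.1, 0.5, length.out = n - 1)
    expect_equal(loglik_rate_per_interval(rates, bt), oracle_rpi_lnl(rates, ages),
                 tolerance = 1e-10)
  }
  bt3 <- as_branching_times(c(2, 1))
  expect_error(loglik_rate_per_interval(c(0.1, -0.3), bt3), "positive")
  expect_error(loglik_rate_per_interval(0.1, bt3), "one rate per interval")
})

test_that("birth-death likelihood matches its oracle and collapses at a = 0", {
  for (ages in fixture_ages) {
    bt <- as_branching_times(ages)
    for (r in c(0.1, 0.4)) {
      expect_equal(loglik_birth_death(r, 0, bt), loglik_pure_birth(r, bt),
                   tolerance = 1e-12)
      for (a in c(0.2, 0.5, 0.9))
        expect_equal(loglik_birth_death(r, a, bt), oracle_bd_lnl(r, a, ages),
                     tolerance = 1e-10)
    }
  }
  bt <- as_branching_times(c(2, 1))
  expect_equal(loglik_birth_death(0.2, 0.5, bt), oracle_bd_lnl(0.2, 0.5, c(2, 1)),
               tolerance = 1e-10)
  # a -> 1- diverges through n log(1 - a)
  expect_lt(loglik_birth_death(0.2, 1 - 1e-12, bt), -60)
  expect_error(loglik_birth_death(0.2, 1, bt), "\\[0, 1\\)")
  expect_error(loglik_birth_death(-0.1, 0.2, bt), "positive")
})

test_that("two-rate likelihood agrees with the segment-splitting oracle", {
  for (ages in fixture_ages) {
    bt <- as_branching_times(ages)
    sts <- c(ages[1] * 0.3, ages[1] * 0.7, if (length(ages) > 1) ages[2])
    for (st in sts)
      expect_equal(loglik_yule2rate(0.35, 0.08, st, bt),
                   oracle_y2r_lnl(0.35, 0.08, st, ages), tolerance = 1e-10)
  }
  bt <- as_branching_times(c(2, 1))
  # constant rates reduce to pure birth for any shift position
  expect_equal(loglik_yule2rate(0.2, 0.2, 1.3, bt), loglik_pure_birth(0.2, bt),
               tolerance = 1e-12)
  expect_error(loglik_yule2rate(0.2, 0.1, 5, bt), "crown")
})

test_that("pure-birth MLE is the closed form and scales inversely with time", {
  bt <- as_branching_times(c(2, 1))
  fit <- mle_pure_birth(bt)
  expect_equal(fit$params$r1, 0.2, tolerance = 1e-12)
  expect_equal(fit$n_params, 1)
  expect_equal(fit$lnL, loglik_pure_birth(0.2, bt), tolerance = 1e-12)

  bt2 <- branching_times(simulate_yule(n_tips = 30, lambda = 0.2, seed = 17))
  lam <- mle_pure_birth(bt2)$params$r1
  for (c_ in c(0.1, 3)) {
    scaled <- as_branching_times(bt2$ages * c_)
    expect_equal(mle_pure_birth(scaled)$params$r1, lam / c_, tolerance = 1e-10)
  }
})

test_that("closed-form pure-birth MLE matches a fine grid search", {
  bt <- branching_times(simulate_yule(n_tips = 30, lambda = 0.5, seed = 23))
  grid <- seq(1e-4, 5, by = 1e-5)
  b <- bt$ages
  S <- b[1] + sum(b)
  lnl <- (bt$n_tips - 2) * log(grid) - grid * S   # constant dropped: same argmax
  expect_equal(mle_pure_birth(bt)$params$r1, grid[which.max(lnl)],
               tolerance = 1.5e-5)
})

test_that("AIC conventions and their consistency identity", {
  expect_equal(aic(0, 1, "standard"), 2)
  expect_equal(aic(14.668, 3, "table5"), -35.336, tolerance = 1e-9)
  expect_equal(aic(10.201, 2, "table5"), -24.402, tolerance = 1e-9)
  for (lnl in c(-12.3, 0, 16.6))
    for (k in 1:3) {
      expect_equal(aic(lnl, k, "standard") - aic(lnl, k, "table5"), 4 * k)
      expect_equal(aic(lnl, k, "standard") + aic(lnl, k, "table5"), -4 * lnl)
    }
  expect_error(aic(1, 0), ">= 1")
})

test_that("birth-death fit handles boundary and interior optima stably", {
  # pure-birth data: expect the a = 0 boundary with lnL equal to pure birth
  bt <- branching_times(simulate_yule(n_tips = 25, lambda = 0.2, seed = 2))
  pb <- mle_pure_birth(bt)
  fit <- fit_birth_death(bt)
  expect_true(fit$params$a >= 0 && fit$params$a < 1)
  if (fit$params$a == 0) {
    expect_equal(fit$lnL, pb$lnL, tolerance = 1e-12)
    expect_equal(fit$params$r1, pb$params$r1, tolerance = 1e-12)
  }
  # custom start grids must reach the same optimum
  alt <- fit_birth_death(bt, starts = cbind(r = pb$params$r1 * c(0.1, 1, 10),
                                            a = c(0.9, 0.5, 0.1)))
  expect_equal(alt$lnL, fit$lnL, tolerance = 1e-6)

  # strong-extinction data: interior a with lnL above pure birth
  bt2 <- branching_times(simulate_birth_death(40, 0.4, 0.3, seed = 61))
  fit2 <- fit_birth_death(bt2)
  expect_gte(fit2$lnL, mle_pure_birth(bt2)$lnL - 1e-9)
  alt2 <- fit_birth_death(bt2, starts = cbind(r = fit2$params$r1 * c(0.2, 1, 5),
                                              a = c(0.05, 0.45, 0.85)))
  expect_equal(alt2$lnL, fit2$lnL, tolerance = 1e-6)
})

test_that("DDX reduces to pure birth at x = 0 and nests it at the optimum", {
  bt <- branching_times(simulate_yule(n_tips = 20, lambda = 0.15, seed = 12))
  pb <- mle_pure_birth(bt)
  expect_equal(loglik_ddx(pb$params$r1, 0, bt), pb$lnL, tolerance = 1e-12)
  fit <- fit_ddx(bt)
  expect_gte(fit$lnL, pb$lnL)
  expect_equal(fit$n_params, 2)
  expect_equal(loglik_ddx(fit$params$r1, fit$params$x, bt), fit$lnL,
               tolerance = 1e-9)
})

test_that("DDL profile fit is self-consistent and reports collapse", {
  bt <- branching_times(simulate_yule(n_tips = 20, lambda = 0.15, seed = 12))
  pb <- mle_pure_birth(bt)
  fit <- fit_ddl(bt)
  expect_gte(fit$lnL, pb$lnL)
  if (is.infinite(fit$params$k)) {
    expect_match(fit$note, "collapsed")
    expect_equal(fit$lnL, pb$lnL, tolerance = 1e-12)
  } else {
    expect_gt(fit$params$k, bt$n_tips)
    expect_equal(loglik_ddl(fit$params$r1, fit$params$k, bt), fit$lnL,
                 tolerance = 1e-9)
  }
  expect_error(loglik_ddl(0.2, 10, bt), "exceed")
})

test_that("yule2rate fit maximises over admissible shift candidates", {
  bt <- branching_times(simulate_rate_shift(20, 0.2, 0.02, shift_age = 5,
                                            crown_age = 15, seed = 5))
  fit <- fit_yule2rate(bt)
  expect_named(fit$params, c("r1", "r2", "st"))
  expect_equal(fit$n_params, 3)
  expect_gt(fit$params$st, 0)
  expect_lt(fit$params$st, bt$crown_age)
  expect_equal(loglik_yule2rate(fit$params$r1, fit$params$r2, fit$params$st, bt),
               fit$lnL, tolerance = 1e-9)
  # nesting: never below pure birth
  expect_gte(fit$lnL, mle_pure_birth(bt)$lnL)
  # exhaustive check: no candidate beats the reported optimum
  cands <- c(bt$ages[-1], (c(bt$ages, 0)[-1] + bt$ages) / 2)
  cands <- cands[cands > 0 & cands < bt$crown_age]
  best <- max(vapply(cands, function(st) {
    tryCatch(max(stats::optim(c(log(0.2), log(0.02)), function(p)
      -loglik_yule2rate(exp(p[1]), exp(p[2]), st, bt))$value * -1, -Inf),
      error = function(e) -Inf)
  }, numeric(1)))
  expect_gte(fit$lnL, best - 1e-4)
  expect_error(fit_yule2rate(as_branching_times(c(2, 1))), "at least 4")
})

test_that("fit_all_models assembles the five-model table with nesting intact", {
  bt <- branching_times(simulate_yule(n_tips = 18, lambda = 0.12, seed = 77))
  tab <- fit_all_models(bt, clade_label = "demo")
  expect_identical(names(tab$fits), c("pureBirth", "BD", "DDL", "DDX", "yule2rate"))
  lnl_pb <- tab$fits$pureBirth$lnL
  for (m in names(tab$fits)) {
    f <- tab$fits[[m]]
    expect_gte(f$lnL, lnl_pb - 1e-8)
    expect_equal(f$aic_standard - f$aic_table5, 4 * f$n_params)
  }
  expect_equal(tab$fits$pureBirth$delta_aic_vs_purebirth, 0)
  expect_true(tab$best_constant %in% c("pureBirth", "BD"))
  expect_true(tab$best_variable %in% c("DDL", "DDX", "yule2rate"))

  df <- as.data.frame(tab)
  expect_identical(colnames(df), c("pureBirth", "BD", "DDL", "DDX", "yule2rate"))
  expect_identical(rownames(df), c("Parameters", "Ln(L)", "AIC", "dAIC"))
  # rounded TSV agrees with full-precision values after rounding
  expect_equal(as.numeric(df["AIC", "pureBirth"]),
               round(tab$fits$pureBirth$aic_standard, 3))
})

test_that("time rescaling transforms estimates covariantly", {
  bt <- branching_times(simulate_yule(n_tips = 16, lambda = 0.3, seed = 41))
  tab <- fit_all_models(bt)
  for (c_ in c(0.25, 4)) {
    scaled <- as_branching_times(bt$ages * c_)
    tab2 <- fit_all_models(scaled)
    shift <- (bt$n_tips - 2) * log(1 / c_)
    for (m in names(tab$fits)) {
      f1 <- tab$fits[[m]]; f2 <- tab2$fits[[m]]
      expect_equal(f2$lnL, f1$lnL + shift, tolerance = 1e-6)
      expect_equal(f2$params$r1, f1$params$r1 / c_, tolerance = 1e-5)
    }
    expect_equal(tab2$fits$BD$params$a, tab$fits$BD$params$a, tolerance = 1e-5)
    expect_equal(tab2$fits$DDX$params$x, tab$fits$DDX$params$x, tolerance = 1e-5)
    expect_equal(tab2$fits$yule2rate$params$st,
                 tab$fits$yule2rate$params$st * c_, tolerance = 1e-8)
  }
})

test_that("tied node ages (zero-length intervals) are handled", {
  bt <- as_branching_times(fixture_ages$tied)
  expect_equal(loglik_pure_birth(0.3, bt), oracle_pb_lnl(0.3, fixture_ages$tied),
               tolerance = 1e-10)
  tab <- fit_all_models(bt)
  expect_true(all(vapply(tab$fits, function(f) is.finite(f$lnL), logical(1))))
})

test_that("density-dependent fits recover their generating parameters", {
  # ages drawn directly from the per-interval exponential law of each model
  sim_ages <- function(rates) {
    i <- seq_along(rates) + 1
    rev(cumsum(rev(stats::rexp(length(rates), rate = i * rates))))
  }
  set.seed(3001)
  k_hat <- replicate(100, {
    fit_ddl(as_branching_times(sim_ages(0.5 * (1 - (2:20) / 25))))$params$k
  })
  expect_gt(stats::median(k_hat), 25 / 2)
  expect_lt(stats::median(k_hat), 25 * 2)

  set.seed(3002)
  x_hat <- replicate(100, {
    fit_ddx(as_branching_times(sim_ages(0.6 * (2:30)^(-0.5))))$params$x
  })
  expect_lt(abs(stats::median(x_hat) - 0.5), 0.25)
})
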