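# Joint nonlinear least-squares fitting.

test_that("noiseless hyperbolic data is recovered essentially exactly", {
  spec <- edq_design()
  pars <- data.frame(amount = spec$amounts, l = c(0.01, 0.005, 0.001))
  ips <- exact_ips("hyperbolic", spec, pars)
  fit <- disc_fit(ips, "hyperbolic", spec)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$params$l, pars$l, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_false(fit$clamped)
  expect_true(fit$converged)
  expect_equal(fit$n, 15L)
  expect_equal(fit$p, 3L)
})

test_that("noiseless two-parameter data is recovered for the profiled models", {
  spec <- edq_design()
  pars <- data.frame(amount = spec$amounts,
                     l = c(0.08, 0.03, 5e-4), s = c(1.3, 1.8, 2.9))
  fit <- disc_fit(exact_ips("power", spec, pars), "power", spec)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$params$l, pars$l, tolerance = 1e-4)
  expect_equal(fit$params$s, pars$s, tolerance = 1e-4)
  expect_equal(fit$p, 6L)
  pars2 <- data.frame(amount = spec$amounts,
                      l = c(0.02, 0.015, 0.01), s = c(10, 50, 400))
  fit2 <- disc_fit(exact_ips("exp2", spec, pars2), "exp2", spec)
  expect_lt(fit2$sse, 1e-6)
  expect_equal(fit2$params$s, pars2$s, tolerance = 1e-3)
})

test_that("the joint SSe equals the sum of independent per-magnitude fits", {
  spec <- edq_design()
  set.seed(2024)
  base <- exact_ips("power", spec,
                    data.frame(amount = spec$amounts,
                               l = c(0.07, 0.03, 6e-4), s = c(1.4, 1.8, 3)))
  base$ip <- pmin(pmax(base$ip + rnorm(nrow(base), 0, 0.05 * base$amount), 0),
                  base$amount)
  for (m in disc_models()$model) {
    joint <- disc_fit(base, m, spec)
    split_sse <- sum(vapply(spec$amounts, function(a) {
      rows <- base[base$amount == a, ]
      fit_magnitude(m, a, rows$effort_level, rows$ip)$sse
    }, 0))
    expect_equal(joint$sse, split_sse, tolerance = 1e-8,
                 label = paste("joint SSe for", m))
  }
})

test_that("anti-discounting data is clamped with missing parameters", {
  spec <- edq_design()
  ips <- expand.grid(effort_level = spec$effort_levels, amount = spec$amounts,
                     KEEP.OUT.ATTRS = FALSE)
  # subjective value rising steeply with effort in every magnitude, with
  # magnitude means aligned: the grand mean beats any non-increasing curve
  # under the pooled total-sum-of-squares convention
  ips$ip <- 10 + 60 * ips$effort_level / 150
  fit <- disc_fit(ips, "hyperbolic", spec)
  expect_true(fit$clamped)
  expect_equal(fit$r2, 0)
  expect_true(all(is.na(fit$params$l)))
})

test_that("the mean-beats-model convention is applied as specified", {
  vals <- c(10, 20, 30, 40)
  sst <- sum((vals - mean(vals))^2)
  expect_equal(r_squared(0, vals), list(r2 = 1, clamped = FALSE))
  expect_equal(r_squared(sst, vals), list(r2 = 0, clamped = FALSE))
  expect_equal(r_squared(sst * 1.01, vals), list(r2 = 0, clamped = TRUE))
  expect_equal(r_squared(1, c(5, 5, 5)), list(r2 = 0, clamped = TRUE))
  expect_equal(r_squared(sst / 2, vals)$r2, 0.5)
})

test_that("adding the second parameter never increases the SSe (nesting)", {
  spec <- edq_design()
  set.seed(77)
  base <- exact_ips("power", spec,
                    data.frame(amount = spec$amounts,
                               l = c(0.07, 0.03, 6e-4), s = c(1.4, 1.8, 3)))
  base$ip <- pmin(pmax(base$ip + rnorm(nrow(base), 0, 0.04 * base$amount), 0),
                  base$amount)
  tol <- 1e-6
  sse <- function(m) disc_fit(base, m, spec)$sse
  expect_lte(sse("power"), sse("parabolic") * (1 + tol))
  expect_lte(sse("myerson_green"), sse("hyperbolic") * (1 + tol))
  expect_lte(sse("exp2"), sse("exponential") * (1 + tol))
})

test_that("fits are deterministic and batch fitting counts are right", {
  sc <- small_cohort(n = 1)
  f1 <- disc_fit_all(sc$ips, models = c("power", "hyperbolic"), spec = sc$spec)
  f2 <- disc_fit_all(sc$ips, models = c("power", "hyperbolic"), spec = sc$spec)
  expect_length(f1, 4L)   # 1 participant x 2 domains x 2 models
  expect_equal(as.data.frame(f1), as.data.frame(f2))
  both <- disc_fit_all(sc$ips, models = "power", spec = sc$spec, units = "both")
  df <- as.data.frame(both)
  expect_true("MEDIAN" %in% df$unit)
  expect_equal(length(both), 4L)  # (1 participant + median) x 2 domains
})

test_that("input contracts are enforced", {
  spec <- edq_design()
  ips <- expand.grid(effort_level = spec$effort_levels, amount = spec$amounts,
                     KEEP.OUT.ATTRS = FALSE)
  ips$ip <- ips$amount / 2
  expect_error(disc_fit(ips[-1, ], "power", spec), class = "effdisc_input_error")
  with_zero <- rbind(ips, data.frame(effort_level = 0, amount = 80, ip = 80))
  expect_error(disc_fit(with_zero, "power", spec), class = "effdisc_input_error")
  two_units <- cbind(ips, participant_id = rep(c("a", "b"), length.out = nrow(ips)))
  expect_error(disc_fit(two_units, "power", spec), class = "effdisc_input_error")
})

test_that("fit methods expose coefficients, predictions and residuals coherently", {
  spec <- edq_design()
  pars <- data.frame(amount = spec$amounts,
                     l = c(0.07, 0.03, 6e-4), s = c(1.4, 1.8, 3))
  ips <- exact_ips("power", spec, pars)
  fit <- disc_fit(ips, "power", spec)
  cf <- coef(fit)
  expect_named(cf, c("l_80", "l_400", "l_3000", "s_80", "s_400", "s_3000"))
  expect_equal(unname(cf[1:3]), pars$l, tolerance = 1e-4)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), ips$ip - fitted(fit), ignore_attr = TRUE)
  nd <- data.frame(amount = 80, effort_level = 0)
  expect_equal(predict(fit, nd), 80, tolerance = 1e-6)
  expect_error(predict(fit, data.frame(amount = 99, effort_level = 10)),
               class = "effdisc_input_error")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_true(all(sims[[1]]$ip >= 0 & sims[[1]]$ip <= sims[[1]]$amount))
})
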