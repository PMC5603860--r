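test_that("noiseless data are recovered exactly", {
  sim <- simulate_qsar_data(n_compounds = 15, n_descriptors = 4,
                            n_active = 2, true_coefficients = c(2, -1),
                            intercept = 3, noise_sd = 0,
                            n_collinear_pairs = 0, n_constant = 0, seed = 1)
  fit <- fit_mlr(sim$data, sim$active_names)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-12)
  expect_equal(fit$stats$se, 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(2, -1), tolerance = 1e-10)
  expect_equal(fit$stats$q2_loo, 1, tolerance = 1e-10)
  expect_equal(fit$stats$press, 0, tolerance = 1e-16)
  sr <- standardized_residuals(fit)
  expect_true(all(sr$std_residual == 0))
  expect_false(any(sr$flagged))
})

test_that("coefficients land within 3 standard errors of the planted truth", {
  sim <- simulate_qsar_data(seed = 1)  # n=46, 8 active, noise 0.3
  fit <- fit_mlr(sim$data, sim$active_names)
  z <- abs(unname(fit$coefficients) - sim$true_coefficients) /
    unname(fit$coefficient_ses)
  expect_true(all(z < 3))
})

test_that("fit_mlr agrees with stats::lm on every statistic", {
  sim <- small_sim(seed = 13)
  fit <- fit_mlr(sim$data, sim$active_names)
  df <- data.frame(y = sim$data$pIC50,
                   as.data.frame(sim$data[sim$active_names]))
  ref <- lm(y ~ ., data = df)
  s <- summary(ref)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficient_ses),
               unname(s$coefficients[-1, 2]), tolerance = 1e-8)
  expect_equal(fit$stats$r2, s$r.squared, tolerance = 1e-10)
  expect_equal(fit$stats$r2_adj, s$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$stats$f_stat, unname(s$fstatistic[1]), tolerance = 1e-8)
  expect_equal(fit$stats$se, s$sigma, tolerance = 1e-10)
  expect_equal(fit$leverages, unname(hatvalues(ref)), tolerance = 1e-10)
})

test_that("regression on pure noise explains almost nothing", {
  set.seed(17)
  d <- tibble::tibble(compound_id = sprintf("c%02d", 1:46),
                      junk = rnorm(46), pIC50 = rnorm(46))
  fit <- fit_mlr(d, "junk")
  expect_lt(fit$stats$r2, 0.2)
  expect_lt(fit$stats$q2_loo, fit$stats$r2)
})

test_that("rank-deficient and undersized designs raise typed errors", {
  sim <- small_sim(seed = 2, n = 10, p = 4, n_active = 2, coefs = c(1, 1))
  dup <- sim$data
  dup$X002 <- dup$X001
  expect_error(fit_mlr(dup, c("X001", "X002")),
               class = "qsar_modeling_error")
  expect_error(fit_mlr(sim$data[1:3, ], c("X001", "X002")),
               class = "qsar_config_error")
})

test_that("hat-matrix PRESS shortcut equals explicit leave-one-out refits", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(15:50, 1)
    k <- sample(2:10, 1)
    x <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("X", seq_len(k))))
    y <- rnorm(n)
    d <- tibble::as_tibble(as.data.frame(x))
    d$compound_id <- as.character(seq_len(n))
    d$pIC50 <- y
    got <- loo_cv(d, colnames(x))
    expect_equal(got$press, oracle_press(x, y), tolerance = 1e-10)
  }
})

test_that("Q2 never exceeds R2 and the hat trace equals k + 1", {
  set.seed(29)
  for (rep in 1:10) {
    sim <- small_sim(seed = rep, n = sample(20:46, 1),
                     noise_sd = runif(1, 0.1, 1))
    fit <- fit_mlr(sim$data, sim$active_names)
    expect_lte(fit$stats$q2_loo, fit$stats$r2)
    expect_lte(fit$stats$r2_adj, fit$stats$r2)
    expect_equal(sum(fit$leverages), length(sim$active_names) + 1,
                 tolerance = 1e-10)
  }
})

test_that("shuffling the activity destroys cross-validated predictivity", {
  sim <- small_sim(seed = 31)
  shuffled <- sim$data
  set.seed(31)
  shuffled$pIC50 <- sample(shuffled$pIC50)
  fit <- fit_mlr(shuffled, sim$active_names)
  expect_lt(fit$stats$q2_loo, fit$stats$r2)
  expect_lt(fit$stats$q2_loo, 0.3)
})

test_that("VIF matches the auxiliary-regression oracle and handles collinearity", {
  # centred, exactly orthogonal columns: all VIF 1
  set.seed(37)
  x <- qr.Q(qr(cbind(1, matrix(rnorm(35 * 4), 35, 4))))[, -1]
  d <- tibble::as_tibble(as.data.frame(x))
  names(d) <- paste0("X", 1:4)
  d$compound_id <- as.character(1:35)
  d$pIC50 <- rnorm(35)
  expect_equal(vif(d, paste0("X", 1:4))$vif, rep(1, 4), tolerance = 1e-10)

  # duplicated column: infinite for both twins
  d$X5 <- d$X1
  v <- vif(d, c("X1", "X5"))
  expect_true(all(is.infinite(v$vif)))

  # random 35 x 8: agree with per-column lm oracle
  x8 <- matrix(rnorm(35 * 8), 35, 8,
               dimnames = list(NULL, paste0("V", 1:8)))
  d8 <- tibble::as_tibble(as.data.frame(x8))
  d8$compound_id <- as.character(1:35)
  d8$pIC50 <- rnorm(35)
  got <- vif(d8, paste0("V", 1:8))$vif
  want <- vapply(1:8, function(j) {
    r2 <- summary(lm(x8[, j] ~ x8[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("an injected outlier is flagged by the 2.5-sigma rule, strictly", {
  sim <- small_sim(seed = 41)
  corrupted <- sim$data
  corrupted$pIC50[7] <- corrupted$pIC50[7] + 5
  fit <- fit_mlr(corrupted, sim$active_names)
  sr <- standardized_residuals(fit)
  expect_true(sr$flagged[7])
  # strict inequality: a threshold equal to the largest |residual| flags nothing
  top <- max(abs(sr$std_residual))
  expect_false(any(standardized_residuals(fit, threshold = top)$flagged))
})

test_that("broom-style accessors expose the fit consistently", {
  sim <- small_sim(seed = 43)
  fit <- fit_mlr(sim$data, sim$active_names)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", sim$active_names))
  expect_equal(td$estimate[-1], unname(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$stats$r2)
  expect_equal(gl$q2.loo, fit$stats$q2_loo)
  au <- augment(fit)
  expect_equal(au$fitted + au$residual, au$observed, tolerance = 1e-10)
  # tidy p-values agree with lm
  df <- data.frame(y = sim$data$pIC50,
                   as.data.frame(sim$data[sim$active_names]))
  ref <- summary(lm(y ~ ., data = df))
  expect_equal(td$p.value, unname(ref$coefficients[, 4]), tolerance = 1e-8)
})
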