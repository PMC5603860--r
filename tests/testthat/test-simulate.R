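test_that("noiseless construction gives an exact linear response", {
  sim <- simulate_qsar_data(n_compounds = 12, n_descriptors = 4,
                            n_active = 1, true_coefficients = 2,
                            intercept = 1, noise_sd = 0,
                            n_collinear_pairs = 0, n_constant = 0, seed = 5)
  x <- sim$data[[sim$active_names]]
  expect_equal(sim$data$pIC50, 2 * x + 1)
  # regressing on the active column reproduces the coefficients exactly
  fit <- fit_mlr(sim$data, sim$active_names)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
})

test_that("generation is deterministic for a fixed seed and leaves the RNG alone", {
  a <- simulate_qsar_data(n_compounds = 10, n_descriptors = 6, n_active = 2,
                          true_coefficients = c(1, -1), seed = 42,
                          n_collinear_pairs = 1, n_constant = 1)
  set.seed(99); before <- runif(1)
  b <- simulate_qsar_data(n_compounds = 10, n_descriptors = 6, n_active = 2,
                          true_coefficients = c(1, -1), seed = 42,
                          n_collinear_pairs = 1, n_constant = 1)
  set.seed(99); after <- runif(1)
  expect_identical(a$data, b$data)
  expect_identical(a$noise, b$noise)
  expect_identical(before, after)  # global RNG state restored
})

test_that("the default study conditions carry a recoverable signal", {
  sim <- simulate_qsar_data(seed = 1)  # 46 x 300, 8 active, noise 0.3
  expect_equal(dim(sim$data), c(46, 302))
  fit <- fit_mlr(sim$data, sim$active_names)
  expect_gte(fit$stats$r2, 0.8)
})

test_that("planted collinear pairs land near the target correlation", {
  for (s in 1:20) {
    sim <- simulate_qsar_data(n_compounds = 46, n_descriptors = 12,
                              n_active = 2, true_coefficients = c(1, -1),
                              n_collinear_pairs = 3, collinear_r = 0.95,
                              n_constant = 0, seed = s)
    for (r in seq_len(nrow(sim$collinear_pairs))) {
      obs <- cor(sim$data[[sim$collinear_pairs[r, 1]]],
                 sim$data[[sim$collinear_pairs[r, 2]]])
      expect_lt(abs(obs - 0.95), 0.05)
    }
  }
})

test_that("constant columns have zero variance and survive the round trip to the filter", {
  sim <- simulate_qsar_data(n_compounds = 20, n_descriptors = 10,
                            n_active = 2, true_coefficients = c(1, 1),
                            n_collinear_pairs = 0, n_constant = 3, seed = 3)
  vars <- vapply(sim$constant_names, function(nm) var(sim$data[[nm]]),
                 numeric(1))
  expect_true(all(vars == 0))
  filtered <- remove_constant(sim$data)
  expect_setequal(removed_descriptors(filtered), sim$constant_names)
})

test_that("invalid specifications fail with informative configuration errors", {
  expect_error(simulate_qsar_data(n_compounds = 10, n_descriptors = 5,
                                  n_active = 4, true_coefficients = rep(1, 4),
                                  n_collinear_pairs = 1, n_constant = 1),
               class = "qsar_config_error")
  expect_error(simulate_qsar_data(n_compounds = 10, n_descriptors = 5,
                                  n_active = 1, true_coefficients = 1,
                                  noise_sd = -0.1, n_collinear_pairs = 0,
                                  n_constant = 0),
               class = "qsar_config_error")
  expect_error(simulate_qsar_data(n_compounds = 10, n_descriptors = 8,
                                  n_active = 1, true_coefficients = 1,
                                  n_collinear_pairs = 1, collinear_r = 0.5,
                                  n_constant = 0),
               class = "qsar_config_error")
})

test_that("toy molecules match their stated constructions", {
  pair <- toy_molecule("pair", distance = 2)
  expect_equal(unname(dist(pair$coordinates)[1]), 2)
  path3 <- toy_molecule("path3", weights = c(1, 2, 3))
  expect_equal(nrow(path3$bonds), 2)
  expect_equal(path3$custom, c(1, 2, 3))
  expect_equal(c005_count(toy_molecule("methyl_probe", name = "methane")), 0L)
  expect_equal(c005_count(toy_molecule("methyl_probe",
                                       name = "dimethyl ether")), 2L)
  expect_error(toy_molecule("methyl_probe", name = "nope"),
               class = "qsar_config_error")
})

test_that("CSV + ground-truth sidecar round-trip", {
  sim <- simulate_qsar_data(n_compounds = 8, n_descriptors = 5, n_active = 1,
                            true_coefficients = 1.5, n_collinear_pairs = 1,
                            n_constant = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_qsar_sim(sim, path)
  back <- utils::read.csv(path)
  expect_equal(names(back)[1], "compound_id")
  expect_equal(names(back)[ncol(back)], "pIC50")
  expect_equal(back$pIC50, sim$data$pIC50)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$active_names, sim$active_names)
  expect_equal(truth$true_coefficients, sim$true_coefficients)
})
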