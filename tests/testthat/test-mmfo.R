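test_that("population initialization respects the learning-rate size rule", {
  cfg <- mmfo_config(NM = 6, NI = 1, LM = 0.5, seed = 3)
  pop <- init_population(10, cfg)
  expect_length(pop$moths, 6)
  for (m in pop$moths) {
    expect_length(m, 5)
    expect_identical(m, sort(unique(m)))
    expect_true(all(m >= 1 & m <= 10))
  }

  full <- init_population(7, mmfo_config(LM = 1, seed = 1))
  for (m in full$moths) expect_identical(m, 1:7)

  again <- init_population(10, cfg)
  expect_identical(pop$moths, again$moths)

  expect_warning(init_population(3, mmfo_config(LM = 0.01, seed = 1)),
                 "clamping")
})

test_that("variance fitness reproduces the published worked value", {
  x <- matrix(c(2, 4, 4, 4, 5, 5, 7, 9), ncol = 1)
  expect_identical(variance_fitness(1L, x), 2)

  # constant features contribute zero; aggregation is the mean
  x2 <- cbind(a = c(2, 4, 4, 4, 5, 5, 7, 9), b = rep(1, 8))
  expect_identical(variance_fitness(1:2, x2), 1)

  # per-feature stds 1 and 3 average to 2
  x3 <- cbind(scale(rnorm(50)) * sqrt(50 / 49),
              scale(rnorm(50)) * 3 * sqrt(50 / 49))
  expect_equal(variance_fitness(1:2, x3), 2, tolerance = 1e-10)

  expect_error(variance_fitness(5L, x), "out-of-range")
})

test_that("fitness values match direct-formula oracles on random matrices", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- matrix(rnorm(40 * 8, sd = runif(1, 0.5, 3)), 40, 8)
      y <- rep(0:3, each = 10)
      idx <- sort(sample(8, 4))
      expect_equal(variance_fitness(idx, x),
                   oracle_variance_fitness(x, idx), tolerance = 1e-10)
      expect_equal(inter_class_fitness(idx, x, labels = y),
                   oracle_interclass_fitness(x, y, idx), tolerance = 1e-10)
    }
  })
})

test_that("inter-class fitness measures dispersion of spreads, not means", {
  x <- matrix(c(0, 0, 4, 4), ncol = 1)
  y <- c("A", "A", "B", "B")
  expect_identical(inter_class_fitness(1L, x, labels = y), 0)

  x2 <- matrix(c(0, 2, 0, 0), ncol = 1)
  expect_equal(inter_class_fitness(1L, x2, labels = y), 1, tolerance = 1e-12)

  # identical class distributions score zero
  x3 <- matrix(c(1, 5, 1, 5), ncol = 1)
  expect_identical(inter_class_fitness(1L, x3, labels = y), 0)

  expect_error(inter_class_fitness(1L, matrix(1:3, ncol = 1),
                                   labels = c("A", "B", "B")),
               "fewer than 2")
})

test_that("the threshold is the learning-rate-scaled mean", {
  expect_equal(fitness_threshold(c(1, 2, 3), 0.6), 1.2)
  expect_identical(fitness_threshold(rep(4, 7), 1), 4)
  expect_error(fitness_threshold(numeric(0), 0.5))
})

test_that("update step re-randomizes exactly the below-threshold moths", {
  pop <- init_population(10, mmfo_config(NM = 2, LM = 0.5, seed = 9))
  pop$fitness <- c(0, 10)     # threshold at LM = 1 is 5
  before <- pop$moths
  upd <- withr::with_seed(1, update_population(pop, LM = 1))
  expect_identical(upd$moths[[2]], before[[2]])  # survivor untouched
  expect_true(is.na(upd$fitness[1]))
  expect_identical(upd$fitness[2], 10)
  expect_identical(upd$iteration, 1L)
  expect_length(upd$moths[[1]], 5)

  # all above threshold: nothing but the counter moves
  pop$fitness <- c(10, 10)
  upd2 <- withr::with_seed(1, update_population(pop, LM = 1))
  expect_identical(upd2$moths, pop$moths)

  # replacements are seeded
  pop$fitness <- c(0, 10)
  upd3 <- withr::with_seed(1, update_population(pop, LM = 1))
  upd4 <- withr::with_seed(1, update_population(pop, LM = 1))
  expect_identical(upd3$moths, upd4$moths)
})

test_that("run_phase returns the union of surviving subsets", {
  # NM = 2, NI = 1, both moths above the LM-scaled mean: plain union
  x <- matrix(rnorm(60), 20, 3)
  cfg <- mmfo_config(NM = 2, NI = 1, LM = 0.9, seed = 5)
  res <- run_phase(x, "variance", cfg)
  pop <- init_population(3, cfg)
  fits <- vapply(pop$moths, variance_fitness, 0, matrix = x)
  th <- fitness_threshold(fits, 0.9)
  expected <- sort(unique(unlist(pop$moths[fits >= th])))
  expect_identical(as.integer(res), expected)

  expect_identical(as.vector(res), sort(unique(as.vector(res))))
  expect_true(all(res >= 1 & res <= 3))
})

test_that("selection nests phases and is reproducible", {
  withr::with_seed(17, {
    x <- cbind(matrix(rnorm(60 * 6), 60, 6),
               matrix(rnorm(60 * 2, sd = 0.01), 60, 2))
    colnames(x) <- paste0("f", 1:8)
    df <- data.frame(grade = rep(0:2, each = 20), x)
  })
  cfg <- mmfo_config(NM = 8, NI = 5, LM = 0.5, seed = 23)
  sel <- select_features(df, cfg)
  expect_s3_class(sel, "selected_features")
  expect_true(all(sel$indices %in% sel$phase1_indices))
  expect_lte(sel$final_size, sel$phase1_size)
  expect_lte(sel$phase1_size, 8)
  expect_gte(sel$final_size, 1)
  expect_identical(sel$descriptors, paste0("f", 1:8)[sel$indices])

  sel2 <- select_features(df, cfg)
  expect_identical(sel$indices, sel2$indices)

  path <- withr::local_tempfile(fileext = ".json")
  write_selected_json(sel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(as.integer(back$indices), sel$indices)
})
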