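test_that("threshold_binarize compares pixels against the level directly", {
  const <- matrix(0.5, 4, 6)
  expect_identical(threshold_binarize(const, 0.4, "bright"),
                   matrix(1L, 4, 6))
  expect_identical(threshold_binarize(const, 0.4, "dark"),
                   matrix(0L, 4, 6))

  two <- matrix(c(0.2, 0.9, 0.9, 0.2, 0.2, 0.9), 2, 3)
  got <- threshold_binarize(two, 0.6, "bright")
  expect_identical(got, (two == 0.9) + 0L)  # exhaustive pixel oracle
  expect_error(threshold_binarize(matrix(numeric(0), 0, 0), 0.5), "empty")
})

test_that("polarity duality and level monotonicity hold", {
  withr::with_seed(42, {
    for (i in 1:10) {
      img <- matrix(runif(30 * 20), 30, 20)
      v <- runif(1)
      expect_identical(threshold_binarize(img, v, "dark"),
                       threshold_binarize(1 - img, 1 - v, "bright"))
      lo <- threshold_binarize(img, max(0, v - 0.2), "bright")
      hi <- threshold_binarize(img, v, "bright")
      expect_true(all(hi <= lo))  # raising the level never adds pixels
    }
  })
})

test_that("opening and closing behave as disc-structuring morphology", {
  ones <- matrix(1L, 40, 40)
  expect_identical(morph_open(ones, 5), ones)
  expect_identical(morph_close(ones, 5), ones)

  # radius-12 disc survives opening with radius 10, radius-4 disc does not
  m <- matrix(0L, 80, 80)
  m[(row(m) - 30)^2 + (col(m) - 30)^2 <= 12^2] <- 1L
  m[(row(m) - 64)^2 + (col(m) - 64)^2 <= 4^2] <- 1L
  expect_identical(n_components(m), 2L)
  opened <- morph_open(m, 10)
  expect_identical(n_components(opened), 1L)

  # closing bridges nearby discs into one component
  g <- matrix(0L, 60, 60)
  g[(row(g) - 30)^2 + (col(g) - 20)^2 <= 6^2] <- 1L
  g[(row(g) - 30)^2 + (col(g) - 37)^2 <= 6^2] <- 1L  # 4-px gap
  expect_identical(n_components(g), 2L)
  expect_identical(n_components(morph_close(g, 5)), 1L)
})

test_that("opening is anti-extensive, closing extensive, both idempotent", {
  for (s in 1:8) {
    m <- random_blob_mask(48, seed = s)
    r <- 1 + (s %% 3)
    op <- morph_open(m, r)
    cl <- morph_close(m, r)
    expect_true(all(op <= m))
    expect_true(all(cl >= m))
    expect_identical(morph_open(op, r), op)
    expect_identical(morph_close(cl, r), cl)
  }
})

test_that("preset rules carry the published levels and polarities", {
  p <- segmentation_presets()
  expect_named(p, c("od", "macula", "vessels", "exudates", "hemorrhages"))
  expect_equal(vapply(p, `[[`, 0, "level"),
               c(od = 0.4, macula = 0.6, vessels = 0.5,
                 exudates = 0.3, hemorrhages = 0.7))
  expect_identical(p$hemorrhages$polarity, "dark")
  expect_identical(p$vessels$close_radius, 5)
  expect_identical(p$exudates$open_radius, 10)
  expect_identical(p$hemorrhages$open_radius, 3)
  expect_error(segment_structure(matrix(0.5, 8, 8), "lens"), "unknown")
})

test_that("the optic disc preset recovers an isolated planted disc", {
  px <- matrix(0.2, 96, 96)
  px[(row(px) - 48)^2 + (col(px) - 48)^2 <= 12^2] <- 0.9
  truth <- ((row(px) - 48)^2 + (col(px) - 48)^2 <= 12^2) + 0L
  mask <- segment_structure(fundus_image(px), "od")
  expect_gte(dice(mask, truth), 0.9)
})

test_that("exudate preset is empty on a sub-threshold background image", {
  # constant background, no structures, no noise: nothing crosses the level
  px <- matrix(0.25, 64, 64)
  mask <- segment_structure(fundus_image(px), "exudates")
  expect_identical(sum(mask), 0L)
})

test_that("segment_all returns aligned masks and recovers disc and macula", {
  it <- generate_fundus_image(default_grade_profile(2), seed = 31)
  ms <- segment_all(it$image)
  for (m in ms) expect_identical(dim(m), dim(it$image$pixels))
  expect_gte(dice(ms$od, it$masks$od), 0.8)
  expect_gte(dice(ms$macula, it$masks$macula), 0.8)

  # closing merges, never splits: vessel preset component count
  raw <- threshold_binarize(normalize_minmax(it$image$pixels), 0.5, "bright")
  expect_lte(n_components(segment_structure(it$image, "vessels")),
             n_components(raw))
})

test_that("windowed variant finds locally bright strokes a global rule misses", {
  # smooth intensity ramp hides a locally bright stroke from the global rule
  px <- matrix(rep(seq(0.1, 0.7, length.out = 64), each = 64), 64, 64)
  px[30:32, ] <- pmin(1, px[30:32, ] + 0.25)
  rule <- threshold_rule(0.7, "bright")
  windowed <- segment_structure(fundus_image(px), rule, method = "windowed",
                                window = 15)
  expect_gt(mean(windowed[31, ]), 0.9)       # stroke found everywhere
  global <- segment_structure(fundus_image(px), rule)
  expect_lt(mean(global[31, 1:32]), 0.5)     # global rule misses the dim half
})
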