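test_that("DFT follows the 1-based phase convention", {
  # constant signal: all bins cancel except the DC term in the last slot
  const <- dft_features(rep(2, 8))
  expect_lt(max(const$magnitude[1:7]), 1e-10)
  expect_equal(const$magnitude[8], 16, tolerance = 1e-12)

  # impulse: flat magnitude spectrum
  imp <- dft_features(c(1, 0, 0, 0))
  expect_equal(imp$magnitude, rep(1, 4), tolerance = 1e-12)

  withr::with_seed(1, {
    x <- rnorm(37)
    got <- dft_features(x)$spectrum
    want <- oracle_dft(x)
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-10)
  })
  expect_error(dft_features(numeric(0)), "empty")
})

test_that("DCT-II is orthonormal and matches the direct cosine sum", {
  const <- dct_features(rep(3, 16))
  expect_equal(const[1], 3 * sqrt(16))  # DC carries all the energy
  expect_lt(max(abs(const[-1])), 1e-12)

  withr::with_seed(2, {
    for (n in c(2, 5, 16, 33)) {
      x <- rnorm(n)
      got <- dct_features(x)
      expect_lt(max(abs(got - oracle_dct(x))), 1e-10)
      expect_equal(sum(got^2), sum(x^2), tolerance = 1e-10)  # Parseval
    }
  })
  expect_error(dct_features(numeric(0)), "empty")
})

test_that("Gabor kernel and response behave like an oriented band-pass", {
  k <- gabor_kernel(8, 4, 0.5, 0)
  ctr <- (dim(k) + 1) / 2
  expect_equal(k[ctr[1], ctr[2]], 1)

  img <- matrix(0.3, 64, 64)
  resp <- gabor_response(img, 8, 4, 0.5, 0)
  inner <- resp[20:44, 20:44]
  expect_lt(diff(range(inner)), 1e-10)
  expect_equal(inner[1, 1], 0.3 * sum(k), tolerance = 1e-8)

  # vertical grating of period lambda: theta = 0 responds, theta = 90 does not
  grating <- matrix(rep(sin(2 * pi * seq_len(64) / 8), each = 64), 64, 64)
  r0 <- gabor_response(grating, 8, 4, 0.5, 0)
  r90 <- gabor_response(grating, 8, 4, 0.5, pi / 2)
  expect_gt(mean(abs(r0)), 5 * mean(abs(r90)))

  expect_error(gabor_kernel(-1, 4), "positive")
  expect_error(gabor_kernel(8, 0), "positive")
})

test_that("Haar pair wavelet is the stated pairwise average/difference", {
  hw <- haar_pair_wavelet(c(6, 2))
  expect_identical(hw$approx, 4)
  expect_identical(hw$detail, 2)

  expect_equal(haar_pair_wavelet(rep(5, 10))$detail, rep(0, 5))

  # dyadic-valued signals reconstruct bit-exactly
  xd <- c(3, 7, -2, 0.5, 1.25, 8)
  hwd <- haar_pair_wavelet(xd)
  expect_identical(as.vector(rbind(hwd$approx + hwd$detail,
                                   hwd$approx - hwd$detail)), xd)
  withr::with_seed(3, {
    x <- rnorm(40)
    hw <- haar_pair_wavelet(x)
    rec <- as.vector(rbind(hw$approx + hw$detail, hw$approx - hw$detail))
    expect_equal(rec, x, tolerance = 1e-14)  # algebraic inverse
  })

  # odd length: last sample duplicated
  hw <- haar_pair_wavelet(c(1, 3, 7))
  expect_equal(hw$approx, c(2, 7))
  expect_equal(hw$detail, c(-1, 0))
})

test_that("Shannon entropy spans [0, log2(bins)]", {
  expect_identical(shannon_entropy(rep(4.2, 100), 32), 0)
  expect_equal(shannon_entropy(c(0, 0, 1, 1), 2), 1.0)
  u <- rep(seq(0, 1, length.out = 32), 5) # uniform occupancy
  expect_equal(shannon_entropy(u, 32), 5, tolerance = 1e-12)
  expect_error(shannon_entropy(numeric(0)), "empty")
})

test_that("the DRFV has a fixed 120-descriptor grid and is deterministic", {
  it <- generate_fundus_image(small_scene(2), seed = 8)
  fv1 <- build_drfv(it$image, it$masks)
  fv2 <- build_drfv(it$image, it$masks)
  expect_identical(fv1$values, fv2$values)
  expect_length(fv1$values, 120)
  expect_length(fv1$descriptors, 120)
  expect_true(all(is.finite(fv1$values)))
  expect_identical(fv1$descriptors, drfv_descriptors())
  expect_true("od.dft.energy" %in% fv1$descriptors)

  # empty masks zero their channel blocks; the whole-image block is unchanged
  zero <- matrix(0L, 96, 96)
  empty <- mask_set(zero, zero, zero, zero, zero)
  fv0 <- build_drfv(it$image, empty)
  expect_identical(fv0$values[1:20], fv1$values[1:20])
  expect_identical(fv0$values[21:120], rep(0, 100))

  bad <- mask_set(zero[1:50, 1:50], zero[1:50, 1:50], zero[1:50, 1:50],
                  zero[1:50, 1:50], zero[1:50, 1:50])
  expect_error(build_drfv(it$image, bad), "misaligned")
})

test_that("feature matrices keep descriptor order and survive CSV round trips", {
  ds <- generate_fundus_dataset(1, profile = small_profile, seed = 14)
  fm <- featurize_images(ds, masks = "provided")
  expect_identical(dim(fm), c(5L, 122L))
  expect_identical(names(fm)[1:2], c("id", "grade"))
  expect_identical(names(fm)[-(1:2)], drfv_descriptors())

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_identical(names(back), names(fm))
  expect_equal(back$od.dft.energy, fm$od.dft.energy, tolerance = 1e-12)
})
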