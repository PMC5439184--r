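test_that("rate encoding is faithful and respects the silent interval", {
  # a full-intensity pixel emits ~ f_max * active spikes on average
  n <- vapply(1:200, function(k) {
    length(encode_image(matrix(255, 1, 1), seed = k)$trains[[1]])
  }, 0)
  expect_equal(mean(n), 25, tolerance = 0.1)

  st <- encode_image(matrix(c(0, 255), 1, 2), seed = 1)
  expect_length(st$trains[[1]], 0)                 # zero pixel, no spikes
  expect_true(all(st$trains[[2]] < 0.5))           # active window only
  expect_equal(st$duration, 1.0)

  # regular mode gives exact spike counts
  str <- encode_image(matrix(255, 1, 1), mode = "regular", seed = 1)
  expect_length(str$trains[[1]], 25)
  expect_equal(diff(str$trains[[1]])[1], 1 / 50)

  expect_error(encode_image(matrix(300, 1, 1)), "255")

  # determinism by seed
  a <- encode_image(matrix(128, 3, 3), seed = 9)
  b <- encode_image(matrix(128, 3, 3), seed = 9)
  expect_identical(a$trains, b$trains)
})

test_that("scrambling permutes pixels and preserves intensities", {
  img <- matrix(runif(100, 0, 255), 10, 10)
  sc <- scramble_image(img, seed = 4)
  expect_equal(sort(as.vector(sc)), sort(as.vector(img)))
  expect_equal(mean(sc), mean(img))
  expect_equal(sum(sc), sum(img))
  expect_identical(scramble_image(img, seed = 4), sc)
  expect_false(identical(sc, img))
  # expected total spike count is unchanged under scrambling
  expect_equal(sum(img) / 255 * 50 * 0.5, sum(sc) / 255 * 50 * 0.5)
})

test_that("upscaling replicates pixels and pads with void", {
  pat <- matrix(0, 20, 20)
  pat[1, 1] <- 200
  up <- upscale_pattern(pat)
  expect_equal(dim(up), c(50, 50))
  expect_true(all(up[1:2, 1:2] == 200))
  expect_true(all(up[41:50, ] == 0))
  expect_true(all(up[, 41:50] == 0))
  expect_equal(sum(up > 0), 4)
  expect_error(upscale_pattern(matrix(0, 10, 10)), "20x20")
})

test_that("preprocessing downsamples, detects edges and clips the range", {
  face <- matrix(runif(200 * 200, 0, 255), 200, 200)
  out <- preprocess_image(face, c(20, 20), mode = "edge")
  expect_equal(dim(out), c(20, 20))
  expect_true(all(out >= 0 & out <= 255))

  flat <- matrix(128, 50, 50)
  expect_true(all(preprocess_image(flat, c(10, 10), mode = "edge") == 0))

  gray <- preprocess_image(face, c(25, 25), mode = "grayscale")
  expect_equal(dim(gray), c(25, 25))
  expect_error(preprocess_image(matrix(numeric(0), 0, 0), c(5, 5)), "empty")
})

test_that("synthetic face sets have class structure and optional features", {
  imgs <- generate_synthetic_faces(3, 6, size = 16, feature_classes = 1,
                                   seed = 11)
  expect_length(imgs, 18)
  expect_true(all(vapply(imgs, function(i) all(i >= 0 & i <= 255), TRUE)))
  cls <- vapply(imgs, function(i) attr(i, "class_id"), 0L)
  expect_equal(sort(unique(cls)), 1:3)

  # within-class correlation exceeds between-class correlation
  v <- vapply(imgs, as.vector, numeric(256))
  cc <- cor(v)
  same <- outer(cls, cls, "==") & upper.tri(cc)
  diff_ <- outer(cls, cls, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff_]))

  # the feature block brightens the designated class only
  rows <- seq(floor(0.7 * 16), 16)
  colsel <- seq(floor(0.25 * 16), ceiling(0.75 * 16))
  block_mean <- vapply(imgs, function(i) mean(i[rows, colsel]), 0)
  expect_gt(min(block_mean[cls == 1]), max(block_mean[cls != 1]))

  expect_identical(generate_synthetic_faces(2, 3, size = 12, seed = 3),
                   generate_synthetic_faces(2, 3, size = 12, seed = 3))
  expect_error(generate_synthetic_faces(0, 5), "degenerate")
})

test_that("baseline normalization equalizes responses within tolerance", {
  net <- tiny_net()
  imgs <- generate_synthetic_faces(1, 5, size = 5, seed = 20)
  nr <- normalize_image_set(imgs, net, tolerance = 0.10, max_iters = 15,
                            n_probes = 3)
  if (nr$converged) {
    tgt <- mean(nr$responses)
    expect_lte(max(abs(nr$responses - tgt)), 0.10 * tgt + 1e-9)
  }
  expect_true(is.data.frame(nr$log))
  expect_true(all(vapply(nr$images, function(i) all(i >= 0 & i <= 255), TRUE)))

  # a single image is returned unchanged
  one <- normalize_image_set(imgs[1], net)
  expect_identical(one$images[[1]], imgs[[1]])
  expect_true(one$converged)
})

test_that("PGM round-trip preserves patterns", {
  pat <- matrix(round(runif(30, 0, 255)), 5, 6)
  f <- tempfile(fileext = ".pgm")
  write_pgm(pat, f)
  back <- famlsm:::read_pgm(f)
  expect_equal(unname(back), pat, tolerance = 1e-8)
  unlink(f)
})
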