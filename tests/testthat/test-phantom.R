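test_that("phantom generation is bit-reproducible from its seed", {
  a <- generate_phantom(tiny_tube_spec(seed = 5))
  b <- generate_phantom(tiny_tube_spec(seed = 5))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$label$data, b$label$data)
  c <- generate_phantom(tiny_tube_spec(seed = 6))
  expect_false(identical(a$image$data, c$image$data))
})

test_that("labelled voxels carry lumen intensities when noise is off", {
  spec <- phantom_spec(shape = c(64, 48, 48), radius_profile = 7,
                       aneurysm = NULL, distractors = 0, noise_sd = 0,
                       seed = 2)
  ph <- generate_phantom(spec)
  lum <- ph$image$data[ph$label$data > 0]
  expect_true(all(lum >= spec$lumen_hu[1] & lum <= spec$lumen_hu[2]))
  bg <- ph$image$data[ph$label$data == 0]
  expect_true(all(bg >= spec$background_hu[1] & bg <= spec$background_hu[2]))
})

test_that("a straight tube voxelizes to the analytic cylinder volume", {
  r <- 5
  spec <- phantom_spec(shape = c(128, 40, 40),
                       centerline_ctrl_points = cbind(z = c(20, 50, 80, 108),
                                                      y = rep(20.3, 4),
                                                      x = rep(20.6, 4)),
                       radius_profile = r, aneurysm = NULL, distractors = 0,
                       noise_sd = 0, seed = 3)
  ph <- generate_phantom(spec)
  # restrict to the purely cylindrical section (away from the end caps)
  zs <- (20 + r + 1):(108 - r - 1)
  count <- sum(ph$label$data[zs, , ])
  expect_equal(count, pi * r^2 * length(zs), tolerance = 0.05)
})

test_that("distractor blobs are bright but never overlap the lumen", {
  spec <- phantom_spec(shape = c(64, 64, 64), radius_profile = 7,
                       aneurysm = NULL, distractors = 4, noise_sd = 0, seed = 8)
  ph <- generate_phantom(spec)
  lum <- ph$image$data[ph$label$data > 0]
  expect_true(all(lum >= spec$lumen_hu[1] & lum <= spec$lumen_hu[2]))
  # bright voxels outside the label exist (the distractors)
  bright_bg <- ph$image$data >= spec$lumen_hu[1] & ph$label$data == 0
  expect_gt(sum(bright_bg), 50)
  # and they are spatially separated from the lumen surface
  d_bg <- sqrt(mvseg:::cpp_edt_sq(ph$label$data, spec$spacing))
  expect_gt(min(d_bg[bright_bg]), 1)
})

test_that("lumen/background contrast stays above 150 HU at default noise", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  sep <- mean(ph$image$data[ph$label$data > 0]) -
    mean(ph$image$data[ph$label$data == 0])
  expect_gte(sep, 150)
})

test_that("an oversized tube is rejected with a clear message", {
  expect_error(generate_phantom(phantom_spec(shape = c(32, 24, 24),
                                             radius_profile = 40)),
               "exceeds volume bounds")
})

test_that("generate_dataset writes a reproducible split with sane masks", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  m1 <- generate_dataset(2, 1, 1, td1, seed = 31)
  m2 <- generate_dataset(2, 1, 1, td2, seed = 31)
  expect_length(m1$cases, 4)
  expect_identical(vapply(m1$cases, `[[`, "", "split"),
                   c("train", "train", "val", "test"))
  files <- list.files(td1, pattern = "nii.gz$")
  expect_length(files, 8)   # image + mask per case
  # same seed -> identical manifests and identical volume files
  expect_identical(jsonlite::read_json(file.path(td1, "manifest.json")),
                   jsonlite::read_json(file.path(td2, "manifest.json")))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(td1, f))),
                     unname(tools::md5sum(file.path(td2, f))))
  # every mask nonempty with a thin-structure foreground fraction
  for (cs in read_manifest(td1)$cases) {
    msk <- read_volume(cs$mask, role = "label")
    frac <- mean(msk$data)
    expect_gt(frac, 0.001)
    expect_lt(frac, 0.10)
  }
})
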