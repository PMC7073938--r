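test_that("spot layout is a deterministic lattice with disjoint discs", {
  g <- locateSpots(4, 3, radiusPx = 12, spacing = 48)
  expect_identical(nrow(g@centers), 12L)
  expect_identical(g@centers, locateSpots(4, 3, radiusPx = 12, spacing = 48)@centers)
  # row-major ordering: first grid row first, columns left to right
  expect_true(all(diff(g@centers[1:3, 2]) == 48))
  expect_true(all(g@centers[1:3, 1] == g@centers[1, 1]))

  g1 <- locateSpots(1, 1, radiusPx = 5, margin = c(20, 30))
  expect_equal(g1@centers, matrix(c(20, 30), 1))

  expect_error(locateSpots(2, 2, radiusPx = 12, spacing = 24), "overlap")
})

test_that("disc mask size is a fixed documented constant", {
  expect_identical(discPixelCount(12), 441L)
  expect_identical(discPixelCount(0), 1L)
  # identical across spots and images: the mask depends only on the radius
  g <- locateSpots()
  img <- randomImage(200, 160)
  counts <- vapply(seq_len(12), function(i) {
    off <- chromanose:::.discOffsets(g@radiusPx)
    nrow(off)
  }, integer(1))
  expect_true(all(counts == 441L))
})

test_that("spot mean colour matches a brute-force pixel scan", {
  # uniform field
  uni <- SensorArrayImage(array(rep(c(100, 50, 0), each = 900),
                                dim = c(30, 30, 3)), "before")
  expect_equal(unname(spotMeanColor(uni, c(15, 15), 5)), c(100, 50, 0))

  # radius 0 returns the centre pixel (0-based coords)
  set.seed(7)
  img <- randomImage(64, 64)
  expect_equal(unname(spotMeanColor(img, c(10, 20), 0)),
               unname(img@pixels[11, 21, ]))

  for (rad in c(3, 5, 12)) {
    ctr <- c(31, 30)
    expect_equal(unname(spotMeanColor(img, ctr, rad)),
                 unname(bruteSpotMean(img, ctr, rad)), tolerance = 1e-12)
  }

  expect_error(spotMeanColor(img, c(2, 2), 5), "outside")
})

test_that("difference profiles implement |after - before| symmetrically", {
  set.seed(3)
  g <- locateSpots(2, 2, radiusPx = 4, spacing = 12, margin = c(6, 6))
  # keep 10 units of headroom so the add-a-constant property does not clamp
  A <- SensorArrayImage(array(sample(0:245, 24 * 24 * 3, TRUE), c(24, 24, 3)), "before")
  B <- SensorArrayImage(array(sample(0:245, 24 * 24 * 3, TRUE), c(24, 24, 3)), "after")
  pAB <- differenceProfile(A, B, g)
  pBA <- differenceProfile(B, A, g)
  expect_identical(pAB, pBA)
  expect_length(pAB, 12L)
  expect_true(all(pAB >= 0))

  # identical images give the zero profile
  expect_equal(unname(differenceProfile(A, A, g)), rep(0, 12))

  # adding a constant to both images leaves the profile unchanged
  A2 <- SensorArrayImage(A@pixels + 10, "before")
  B2 <- SensorArrayImage(B@pixels + 10, "after")
  expect_equal(differenceProfile(A2, B2, g), pAB)

  # hand case: uniform discs with known means
  before <- SensorArrayImage(array(93, dim = c(20, 20, 3)), "before")
  after <- SensorArrayImage(array(100, dim = c(20, 20, 3)), "after")
  g1 <- locateSpots(1, 1, radiusPx = 4, margin = c(10, 10))
  expect_equal(unname(differenceProfile(before, after, g1)), rep(7, 3))

  small <- randomImage(10, 24)
  expect_error(differenceProfile(A, small, g), "size")
})

test_that("a 12-spot grid yields the 36-dimensional profile of the standard array", {
  g <- locateSpots()
  m <- dyeResponseModel(noiseSd = 0, seed = 2)
  pair <- renderArrayPair(responseCurve(m, 0.5), g, m@baseline)
  prof <- differenceProfile(pair$before, pair$after, g)
  expect_length(prof, 36L)
  expect_identical(names(prof), chromanose:::.featureNames(12L))
})

test_that("PNG image files round trip at 8-bit depth", {
  img <- randomImage(32, 40, "after")
  path <- withr::local_tempfile(fileext = ".png")
  writeArrayImage(img, path)
  back <- readArrayImage(path, "after")
  expect_equal(back@pixels, img@pixels)
})

test_that("profile tables validate their header", {
  ds <- generateDataset(levels = c(0, 1), nPerLevel = 2L, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  writeProfileTable(ds, path)

  df <- read.csv(path, check.names = FALSE)

  # 35 feature columns: arity error
  bad1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -ncol(df)], bad1, row.names = FALSE)
  expect_error(readProfileTable(bad1), "multiple of 3")

  # misnamed feature column: format error naming the offender
  bad2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- df
  names(df2)[4] <- "dye99_dR"
  write.csv(df2, bad2, row.names = FALSE)
  expect_error(readProfileTable(bad2), "dye99_dR")
})

test_that("the published example profiles load as 36-feature mixture samples", {
  path <- system.file("extdata", "example_profiles.csv", package = "chromanose")
  ex <- readProfileTable(path)
  expect_identical(dim(ex), c(36L, 4L))
  expect_equal(adulterationLevel(ex), c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(sampleCategory(ex) == "mixture"))
  # spot-check two printed values: first dye's red change at the 20% level,
  # last dye's blue change at the 80% level
  expect_equal(profileMatrix(ex)["EX1", "dye01_dR"], 7.2)
  expect_equal(profileMatrix(ex)["EX4", "dye12_dB"], 0.31)
})
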