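test_that("binarization splits the voxels exactly at the threshold", {
  v <- CTVolume(array(c(10, 200, 105, 106), c(4, 1, 1)))
  m <- binarize(v, 105)
  expect_equal(as.vector(maskValues(m)), c(TRUE, FALSE, TRUE, FALSE))

  # a threshold at or above the maximum marks everything foreground
  expect_equal(foregroundCount(binarize(v, 200)), 4)

  # foreground and background always partition the voxel set
  set.seed(5)
  v2 <- CTVolume(array(sample(0:255, 60, TRUE), c(5, 4, 3)))
  for (k in c(0, 17, 128.5, 255)) {
    fg <- foregroundCount(binarize(v2, k))
    bg <- foregroundCount(binarize(v2, k, polarity = "bright"))
    expect_equal(fg + bg, 60)
  }
})

test_that("erosion peels exactly the boundary ring of a square", {
  sq <- array(FALSE, c(7, 7, 1)); sq[2:6, 2:6, 1] <- TRUE
  out <- erodeMask(BinaryMask(sq), structuringElement("cross"))
  expected <- array(FALSE, c(7, 7, 1)); expected[3:5, 3:5, 1] <- TRUE
  expect_identical(maskValues(out), expected)
  # brute-force neighborhood oracle agrees
  expect_identical(maskValues(out),
                   bruteErode(sq, elementOffsets(structuringElement("cross"))))
})

test_that("erosion has the identity element, is anti-extensive and
           translation-equivariant", {
  idElem <- structuringElement(offsets = matrix(0, 1, 3))
  set.seed(42)
  for (i in 1:20) {
    m <- rndMask()
    bm <- BinaryMask(m)
    expect_identical(maskValues(erodeMask(bm, idElem)), m)
    for (type in c("cross", "square", "cross3d")) {
      er <- maskValues(erodeMask(bm, structuringElement(type)))
      expect_true(all(m[er]))               # output foreground within input
      expect_identical(er, bruteErode(m, elementOffsets(structuringElement(type))))
    }
  }
  # translating the input translates the output (away from the border)
  m <- array(FALSE, c(12, 12, 3)); m[4:7, 4:7, 2] <- TRUE
  shifted <- array(FALSE, c(12, 12, 3)); shifted[6:9, 5:8, 2] <- TRUE
  a <- maskValues(erodeMask(BinaryMask(m)))
  b <- maskValues(erodeMask(BinaryMask(shifted)))
  expect_identical(b[3:12, 2:12, ], a[1:10, 1:11, ])
})

test_that("erosion agrees with the EBImage reference on interior masks", {
  # compare slice-wise 3x3-square erosion on a mask clear of the border,
  # where boundary conventions cannot differ
  set.seed(9)
  m <- array(FALSE, c(16, 16, 2))
  m[4:13, 4:13, ] <- runif(200) < 0.6
  ours <- maskValues(erodeMask(BinaryMask(m), structuringElement("square")))
  kern <- matrix(1, 3, 3)
  ref <- array(FALSE, dim(m))
  for (z in 1:2)
    ref[, , z] <- EBImage::erode(m[, , z] + 0, kern) > 0.5
  expect_identical(ours, ref)
})

test_that("lumen extraction keeps one component with deterministic rules", {
  m <- array(FALSE, c(10, 10, 4))
  m[2:6, 2:6, 1:4] <- TRUE                  # 100-voxel blob
  m[9:10, 9:10, 1] <- TRUE                  # small corner blob ...
  m[9, 9, 2] <- TRUE                        # ... of 5 voxels total
  out <- extractLumen(BinaryMask(m), "largest")
  expect_equal(foregroundCount(out), 100)
  expect_false(any(maskValues(out)[9:10, 9:10, ]))

  # a single component passes through unchanged
  single <- array(FALSE, c(5, 5, 2)); single[2:4, 2:4, ] <- TRUE
  expect_identical(maskValues(extractLumen(BinaryMask(single))), single)

  # exact ties resolve to the component with the smallest coordinate
  tie <- array(FALSE, c(9, 3, 1))
  tie[1:2, 1, 1] <- TRUE; tie[8:9, 1, 1] <- TRUE
  kept <- extractLumen(BinaryMask(tie), "largest")
  expect_true(all(which(maskValues(kept)) %in% c(1, 2)))

  # seeded extraction and its error cases
  expect_equal(foregroundCount(extractLumen(BinaryMask(m), c(9, 9, 1))), 5)
  expect_error(extractLumen(BinaryMask(m), c(1, 1, 1)), "seed not in foreground")
  expect_error(extractLumen(BinaryMask(array(FALSE, c(3, 3, 1)))),
               "no foreground")
})

test_that("26- and 6-connectivity differ on diagonal contact", {
  m <- array(FALSE, c(4, 4, 1))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  expect_equal(foregroundCount(extractLumen(BinaryMask(m), connectivity = 26L)), 2)
  expect_equal(foregroundCount(extractLumen(BinaryMask(m), connectivity = 6L)), 1)
})

test_that("the full segmentation recovers a noise-free tube and is
           deterministic", {
  spec <- phantomSpec(noiseSD = 0, wobbleAmplitude = 0, waist = 0)
  vol <- generatePhantom(spec, "deep_end_expiration")
  seg <- segmentAirway(vol)
  expect_identical(finalThreshold(seg$trace), 120)

  # compare each tube slice with the analytic disc of radius r - p
  gt <- groundTruth(vol)
  zTube <- which(!is.na(gt$radius_mm))
  inner <- setdiff(zTube, range(zTube))   # axial ends lack an eroded rim only in-plane
  for (z in inner[c(1, length(inner) %/% 2, length(inner))]) {
    expected <- pi * (gt$radius_mm[z] - 0.5)^2
    expect_lt(abs(sliceArea(seg$mask, z) - expected) / expected, 0.1)
  }

  seg2 <- segmentAirway(generatePhantom(spec, "deep_end_expiration"))
  expect_identical(maskValues(seg$mask), maskValues(seg2$mask))

  # noisy volumes are equally deterministic given the same spec seed
  sp <- phantomSpec(seed = 77L)
  m1 <- segmentAirway(generatePhantom(sp, "muller"))$mask
  m2 <- segmentAirway(generatePhantom(sp, "muller"))$mask
  expect_identical(maskValues(m1), maskValues(m2))
})
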