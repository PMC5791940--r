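test_that("co-occurrence matrix on closed-form cases", {
  # uniform 3x3x3 mask: all pair mass at (1,1)
  q <- as_quantized(array(1L, dim = c(3, 3, 3)), L = 1L)
  M <- build_cooccurrence(q)
  expect_equal(M$normalized[1, 1], 1)
  expect_equal(sum(M$normalized), 1)
  expect_equal(co_entropy(M), 0)
  expect_equal(co_homogeneity(M), 1)

  # 2x1x1 with levels (1,2): one symmetric pair
  q2 <- as_quantized(array(c(1L, 2L), dim = c(2, 1, 1)), L = 2L)
  M2 <- build_cooccurrence(q2)
  expect_equal(M2$normalized[1, 2], 0.5)
  expect_equal(M2$normalized[2, 1], 0.5)
  expect_equal(co_entropy(M2), 1.0)
  expect_equal(co_homogeneity(M2), 0.5)

  # single voxel: no pairs
  q3 <- as_quantized(array(1L, dim = c(1, 1, 1)), L = 1L)
  expect_error(build_cooccurrence(q3), "NoPairs")
})

test_that("co-occurrence counts equal the exhaustive pair enumeration", {
  for (s in 1:25) {
    lev <- random_blob(s, dm = c(5L, 5L, 5L), L = 4L)
    if (sum(lev > 0) < 2) next
    q <- as_quantized(lev, L = 4L)
    M <- build_cooccurrence(q)
    expect_equal(unname(M$counts), unname(glcm_oracle(lev)), ignore_attr = TRUE)
    expect_true(isSymmetric(unname(M$counts)))
    expect_equal(sum(M$normalized), 1, tolerance = 1e-9)
    # maximum-entropy bound
    expect_lte(co_entropy(M), log2(sum(M$normalized > 0)) + 1e-12)
    expect_gte(co_entropy(M), 0)
    h <- co_homogeneity(M)
    expect_true(h > 0 && h <= 1)
  }
})

test_that("NGTDM busyness and contrast on the 2x2 checker and vs oracle", {
  lev <- array(c(1L, 2L, 2L, 1L), dim = c(2, 2, 1))
  q <- as_quantized(lev, L = 2L)
  f <- nid_features(q)
  expect_equal(f$busyness, 4 / 3)
  expect_equal(f$contrast, 1 / 6)

  # uniform mask: zero-denominator convention
  qu <- as_quantized(array(1L, dim = c(3, 3, 2)), L = 1L)
  fu <- nid_features(qu)
  expect_equal(fu$busyness, 0)
  expect_equal(fu$contrast, 0)

  for (s in 1:25) {
    lev <- random_blob(100 + s, dm = c(5L, 4L, 4L), L = 5L)
    if (sum(lev > 0) < 2) next
    q <- as_quantized(lev, L = 5L)
    f <- nid_features(q)
    o <- nid_oracle(lev)
    expect_equal(f$busyness, o$busyness, tolerance = 1e-12)
    expect_equal(f$contrast, o$contrast, tolerance = 1e-12)
    expect_gte(f$busyness, 0)
    expect_gte(f$contrast, 0)
    nm <- build_nid(q)
    expect_equal(sum(nm$p), 1, tolerance = 1e-12)
    expect_equal(nm$n_voxels, o$n_voxels)
  }
})

test_that("run-length matrix on closed-form cases", {
  # single voxel: one length-1 run per direction
  q1 <- as_quantized(array(1L, dim = c(1, 1, 1)), L = 1L)
  R1 <- build_runlength(q1)
  expect_equal(R1$n_runs, 13)
  expect_equal(va_features(R1)$intensity_variability, 13)
  expect_equal(va_features(R1)$short_run_emphasis, 1)

  # alternating line: every run has length 1 in every direction
  lev <- array(rep(c(1L, 2L), length.out = 7), dim = c(7, 1, 1))
  Ra <- build_runlength(as_quantized(lev, L = 2L))
  expect_equal(ncol(Ra$counts), 1L)
  expect_equal(va_features(Ra)$short_run_emphasis, 1)
})

test_that("run-length features follow their defining sums", {
  # runs {(g=1, r=2): 1, (g=2, r=1): 2}
  R <- structure(list(counts = matrix(c(0, 1, 2, 0), nrow = 2, byrow = TRUE),
                      n_runs = 3),
                 class = "run_length_matrix")
  f <- va_features(R)
  expect_equal(f$short_run_emphasis, (1 / 4 + 2) / 3)
  expect_equal(f$intensity_variability, 5 / 3)
})

test_that("run-length counts equal the naive run enumeration", {
  for (s in 1:25) {
    lev <- random_blob(200 + s, dm = c(5L, 5L, 4L), L = 3L)
    if (sum(lev > 0) < 1) next
    R <- build_runlength(as_quantized(lev, L = 3L))
    o <- runs_oracle(lev)
    expect_equal(R$n_runs, nrow(o))
    tab <- table(factor(o$level, levels = 1:3),
                 factor(o$length, levels = seq_len(ncol(R$counts))))
    expect_equal(unname(R$counts), unname(unclass(as.matrix(tab))),
                 ignore_attr = TRUE)
    # voxel-length conservation over 13 directions
    r <- seq_len(ncol(R$counts))
    expect_equal(sum(sweep(R$counts, 2, r, "*")), 13 * sum(lev > 0))
  }
})

test_that("size-zone matrix on closed-form cases and vs flood fill", {
  # uniform mask: a single zone of the mask's size
  qu <- as_quantized(array(2L, dim = c(3, 3, 3)) * 0L + 1L, L = 1L)
  Zu <- build_sizezone(qu)
  expect_equal(Zu$n_zones, 1)
  expect_equal(Zu$zones$size, 27)
  fu <- isz_features(Zu)
  expect_equal(fu$intensity_variability, 1)
  expect_equal(fu$high_intensity_zone_emphasis, 1)

  # two separated single-voxel islands of level 3
  lev <- array(0L, dim = c(5, 1, 1))
  lev[1] <- 3L
  lev[5] <- 3L
  Z2 <- build_sizezone(as_quantized(lev, L = 3L))
  expect_equal(Z2$n_zones, 2)
  expect_equal(Z2$zones$count[Z2$zones$level == 3 & Z2$zones$size == 1], 2L)
  f2 <- isz_features(Z2)
  expect_equal(f2$intensity_variability, 2)   # 2^2 / 2

  # one zone at level 2 and one at level 4 -> HIZE = (4 + 16)/2
  lev3 <- array(0L, dim = c(5, 1, 1))
  lev3[1:2] <- 2L
  lev3[4:5] <- 4L
  f3 <- isz_features(build_sizezone(as_quantized(lev3, L = 4L)))
  expect_equal(f3$high_intensity_zone_emphasis, 10)

  for (s in 1:25) {
    lev <- random_blob(300 + s, dm = c(5L, 5L, 5L), L = 3L)
    if (sum(lev > 0) < 1) next
    Z <- build_sizezone(as_quantized(lev, L = 3L))
    o <- zones_oracle(lev)
    got <- Z$zones[rep(seq_len(nrow(Z$zones)), Z$zones$count),
                   c("level", "size")]
    expect_equal(unname(as.matrix(got[order(got$level, got$size), ])),
                 unname(as.matrix(o[order(o$level, o$size), ])),
                 ignore_attr = TRUE)
    # zone sizes account for every mask voxel
    expect_equal(sum(Z$zones$size * Z$zones$count), sum(lev > 0))
  }
})

test_that("extract_features populates all fields and is deterministic", {
  ph <- make_phantom(phantom_spec(grid_size = c(24L, 24L, 16L),
                                  semi_axes_mm = c(18, 16, 12),
                                  mixing_amplitude = 1.5, seed = 5))
  m <- segment_tumor(ph$volume, seed = round(dim(ph$volume) / 2))
  f1 <- extract_features(ph$volume, m)
  f2 <- extract_features(ph$volume, m)
  expect_identical(unclass(f1), unclass(f2))
  expect_true(all(is.finite(f1)))
  expect_setequal(unique(attr(f1, "parents")),
                  c("Co", "VA", "NID", "ISZ", "global", "conventional"))
})

test_that("uniform lesion yields zero local heterogeneity", {
  ph <- make_phantom(phantom_spec(grid_size = c(24L, 24L, 16L),
                                  semi_axes_mm = c(18, 16, 12),
                                  mixing_amplitude = 0, noise_sd = 0,
                                  seed = 3))
  m <- segment_tumor(ph$volume, seed = round(dim(ph$volume) / 2))
  f <- extract_features(ph$volume, m)
  expect_equal(unname(f["co_entropy"]), 0)
  expect_equal(unname(f["nid_busyness"]), 0)
  expect_equal(unname(f["co_homogeneity"]), 1)
  expect_lt(unname(f["va_short_run_emphasis"]), 1)
})

test_that("texture features are invariant to affine SUV rescaling", {
  ph <- make_phantom(phantom_spec(grid_size = c(24L, 24L, 16L),
                                  semi_axes_mm = c(18, 16, 12),
                                  mixing_amplitude = 1.5, seed = 9))
  m <- segment_tumor(ph$volume, seed = round(dim(ph$volume) / 2))
  f1 <- extract_features(ph$volume, m)
  doubled <- pet_volume(ph$volume$values * 2, spacing = ph$volume$spacing)
  f2 <- extract_features(doubled, m)
  texture <- names(which(attr(f1, "parents") %in% c("Co", "VA", "NID", "ISZ")))
  expect_equal(unclass(f1)[texture], unclass(f2)[texture], tolerance = 1e-12)
  expect_equal(unname(f2["suv_max"]), 2 * unname(f1["suv_max"]))
})

test_that("single-voxel masks flag missing co-occurrence features", {
  vol <- uniform_volume(6, dm = c(3L, 3L, 3L))
  mask <- array(FALSE, dim = c(3, 3, 3))
  mask[2, 2, 2] <- TRUE
  f <- extract_features(vol, mask)
  expect_true(attr(f, "no_pairs"))
  expect_true(is.na(f["co_entropy"]))
  expect_equal(unname(f["va_intensity_variability"]), 13)
})
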