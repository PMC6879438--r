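test_that("first-order features follow their arithmetic definitions", {
  # voxel volume 10 x 5 x 2 mm = 0.1 mL; two masked voxels with SUV 2 and 4
  g <- array(0, c(2, 2, 2)); g[1, 1, 1] <- 2; g[2, 1, 1] <- 4
  v <- pet_volume(g, c(10, 5, 2))
  m <- g > 0
  fo <- first_order(v, m)
  expect_equal(fo$suv_mean, 3)
  expect_equal(fo$suv_max, 4)
  expect_equal(fo$tmtv_ml, 0.2)
  expect_equal(fo$tlg, 0.6)
  expect_identical(fo$tlg, fo$tmtv_ml * fo$suv_mean)  # bit-wise identity
})

test_that("SUVpeak equals the sphere-mean definition", {
  # uniform volume: peak equals the value
  v <- pet_volume(array(3.7, c(6, 6, 6)), c(5.5, 5.5, 3.3))
  expect_equal(first_order(v, array(TRUE, c(6, 6, 6)))$suv_peak, 3.7)
  # single hot voxel amid 1s: enumerate the 1 mL sphere voxel set directly
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  offs <- expand.grid(x = -2:2, y = -2:2, z = -2:2)
  inside <- sqrt((offs$x * 5.5)^2 + (offs$y * 5.5)^2 + (offs$z * 3.3)^2) <= r
  k <- sum(inside)
  g <- array(1, c(9, 9, 9)); g[5, 5, 5] <- 10
  v2 <- pet_volume(g, c(5.5, 5.5, 3.3))
  fo <- first_order(v2, g > 0)
  expect_equal(fo$suv_peak, (10 + (k - 1)) / k)
})

test_that("quantization maps the masked range onto 1..G", {
  v <- pet_volume(array(5, c(3, 3, 3)), c(1, 1, 1))
  q <- quantize(v, array(TRUE, c(3, 3, 3)), 16)
  expect_true(all(q$levels == 1))

  g <- array(0, c(4, 1, 1)); g[] <- c(0, 1, 2, 3)
  v2 <- pet_volume(g, c(1, 1, 1))
  q2 <- quantize(v2, array(TRUE, dim(g)), 2)
  expect_equal(as.vector(q2$levels), c(1, 1, 2, 2))

  set.seed(7)
  g3 <- array(runif(8 * 8 * 8, 0, 12), c(8, 8, 8))
  v3 <- pet_volume(g3, c(1, 1, 1))
  m3 <- array(runif(512) < 0.6, c(8, 8, 8)); m3[1] <- TRUE
  q3 <- quantize(v3, m3, 64)
  lv <- q3$levels[m3]
  expect_true(all(lv >= 1 & lv <= 64))
  expect_equal(lv[which.max(g3[m3])], 64)
  expect_equal(lv[which.min(g3[m3])], 1)
  expect_true(all(is.na(q3$levels[!m3])))
})

test_that("GLCM counts a two-voxel pair in exactly one direction", {
  lv <- array(NA_integer_, c(2, 1, 1)); lv[1, 1, 1] <- 1L; lv[2, 1, 1] <- 2L
  q <- structure(list(levels = lv, n_bins = 2L, range = c(0, 1)),
                 class = "quantized_volume")
  g <- glcm_3d(q, min_pairs = 1)
  along_x <- which(apply(g$directions, 1, function(d) all(d == c(1, 0, 0))))
  M <- g$matrices[[along_x]]
  expect_equal(M[1, 2], 1); expect_equal(M[2, 1], 1)
  expect_equal(sum(M), 2)                       # symmetrized
  expect_equal(g$pair_counts[along_x], 1)       # unsymmetrized
  expect_true(all(g$pair_counts[-along_x] == 0))
})

test_that("constant region yields the degenerate single-cell GLCM", {
  v <- pet_volume(array(4, c(4, 4, 4)), c(1, 1, 1))
  m <- array(TRUE, c(4, 4, 4))
  q <- quantize(v, m, 32)
  g <- glcm_3d(q)
  for (d in which(g$valid)) {
    P <- g$matrices[[d]] / sum(g$matrices[[d]])
    expect_equal(P[1, 1], 1)
  }
  tx <- texture_features(g)
  expect_equal(unname(tx["entropy"]), 0)
  expect_equal(unname(tx["angular_second_moment"]), 1)
  expect_equal(unname(tx["contrast"]), 0)
  expect_equal(unname(tx["homogeneity"]), 1)
  expect_equal(unname(tx["maximum_probability"]), 1)
  expect_equal(unname(tx["cluster_shade"]), 0)
})

test_that("GLCM counts equal brute-force pair enumeration on random fixtures", {
  set.seed(11)
  for (rep in 1:12) {
    dims <- sample(3:6, 3, replace = TRUE)
    G <- sample(2:8, 1)
    q <- random_quantized(dims, G)
    g <- glcm_3d(q, min_pairs = 1)
    for (d in seq_len(nrow(g$directions))) {
      bf <- brute_glcm(q$levels, G, g$directions[d, ])
      expect_equal(g$matrices[[d]], bf + t(bf))
      expect_equal(g$pair_counts[d], sum(bf))
    }
  }
})

test_that("texture features reproduce closed-form values on a 2-cell matrix", {
  # p(1,2) = p(2,1) = 0.5
  lv <- array(NA_integer_, c(2, 1, 1)); lv[1, 1, 1] <- 1L; lv[2, 1, 1] <- 2L
  q <- structure(list(levels = lv, n_bins = 2L, range = c(0, 1)),
                 class = "quantized_volume")
  tx <- texture_features(glcm_3d(q, min_pairs = 1), min_pairs = 1)
  expect_equal(unname(tx["entropy"]), 1)                 # 1 bit
  expect_equal(unname(tx["contrast"]), 1)
  expect_equal(unname(tx["angular_second_moment"]), 0.5)
  expect_equal(unname(tx["maximum_probability"]), 0.5)
  expect_equal(unname(tx["sum_average"]), 3)
})

test_that("all 16 features match the literal-formula oracle to 1e-10", {
  set.seed(21)
  for (rep in 1:20) {
    G <- sample(c(2:8), 1)
    P <- random_sym_p(G)
    got <- mclrad:::haralick_features(P, log_base = 2)
    want <- haralick_oracle(P)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
  # invariant ranges on valid matrices
  P <- random_sym_p(8)
  f <- mclrad:::haralick_features(P)
  expect_true(f["entropy"] >= 0)
  expect_true(f["angular_second_moment"] > 0 && f["angular_second_moment"] <= 1)
  expect_true(f["homogeneity"] > 0 && f["homogeneity"] <= 1)
  expect_true(f["imc1"] >= -1 && f["imc1"] <= 0)
  expect_true(f["imc2"] >= 0 && f["imc2"] < 1)
})

test_that("grey-level reversal preserves symmetric features, flips cluster shade", {
  set.seed(5)
  G <- 6
  P <- random_sym_p(G)
  Prev <- P[G:1, G:1]
  a <- mclrad:::haralick_features(P)
  b <- mclrad:::haralick_features(Prev)
  for (f in c("entropy", "angular_second_moment", "contrast", "homogeneity",
              "maximum_probability"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  expect_equal(a[["cluster_shade"]], -b[["cluster_shade"]], tolerance = 1e-12)
})

test_that("each valid direction's normalized matrix sums to one", {
  set.seed(31)
  q <- random_quantized(c(6, 6, 6), 5)
  g <- glcm_3d(q, min_pairs = 1)
  for (d in which(g$valid)) {
    s <- sum(g$matrices[[d]])
    expect_true(s > 0)
    expect_equal(sum(g$matrices[[d]] / s), 1, tolerance = 1e-12)
  }
})

test_that("features below the 20-pair minimum are excluded, all-invalid errors", {
  lv <- array(NA_integer_, c(2, 1, 1)); lv[1, 1, 1] <- 1L; lv[2, 1, 1] <- 2L
  q <- structure(list(levels = lv, n_bins = 2L, range = c(0, 1)),
                 class = "quantized_volume")
  g <- glcm_3d(q)   # default min_pairs = 20
  expect_false(any(g$valid))
  expect_error(texture_features(g), "20")
})

test_that("extract_all is deterministic and respects the homogeneous limit", {
  v <- block_volume(value = 6)
  tm <- build_tmtv(v, rbind(c(4, 4, 3)))
  f1 <- extract_all(v, tm, min_pairs = 1)
  f2 <- extract_all(v, tm, min_pairs = 1)
  expect_identical(f1, f2)
  expect_equal(f1$entropy, 0)
  expect_equal(f1$angular_second_moment, 1)
  expect_equal(f1$suv_mean, 6)
  expect_identical(f1$tlg, f1$tmtv_ml * f1$suv_mean)
})
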