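test_that("tiny windows give the hand-enumerated co-occurrence matrices", {
  w <- gray_image(matrix(c(0L, 1L, 0L, 1L), 2, 2))   # rows (0,0) and (1,1)
  m <- cooccurrence(w, c(0L, 1L), symmetric = TRUE)
  expect_equal(m$p[1, 1], 0.5)   # p(0,0)
  expect_equal(m$p[2, 2], 0.5)   # p(1,1)
  expect_equal(sum(m$p), 1)
  expect_equal(sum(m$p != 0), 2L)

  const <- gray_image(matrix(42L, 5, 5))
  mc <- cooccurrence(const)
  expect_equal(mc$p[43, 43], 1)
  expect_equal(sum(mc$p), 1)

  expect_error(cooccurrence(gray_image(matrix(1L, 3, 1))), "too small")
})

test_that("co-occurrence matches the brute-force pair counter on random windows", {
  set.seed(21)
  for (rep in 1:3) {
    w <- gray_image(matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64))
    for (off in list(c(0L, 1L), c(1L, 0L), c(-1L, 1L))) {
      m <- cooccurrence(w, off, symmetric = TRUE)
      expect_equal(m$p, naive_cooccurrence(w, off, TRUE), tolerance = 1e-14)
    }
    m1 <- cooccurrence(w, c(0L, 1L), symmetric = FALSE)
    expect_equal(m1$p, naive_cooccurrence(w, c(0L, 1L), FALSE),
                 tolerance = 1e-14)
  }
})

test_that("co-occurrence invariants hold: normalisation, symmetry, marginals", {
  set.seed(8)
  w <- gray_image(matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32))
  m <- cooccurrence(w)
  expect_lt(abs(sum(m$p) - 1), 1e-12)
  expect_equal(m$p, t(m$p))
  expect_equal(m$mu_x, m$mu_y)
  expect_equal(m$sd_x, m$sd_y)
  expect_lt(abs(sum(m$p_sum) - 1), 1e-12)
  expect_lt(abs(sum(m$p_diff) - 1), 1e-12)
  # transposing the window while reversing the offset leaves features fixed
  wt <- gray_image(t(unclass(w)))
  expect_equal(haralick(cooccurrence(w, c(0L, 1L))),
               haralick(cooccurrence(wt, c(1L, 0L))))
})

test_that("degenerate and two-level matrices give the closed-form features", {
  f <- haralick(cooccurrence(gray_image(matrix(9L, 8, 8))))
  expect_true(attr(f, "degenerate"))
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["idm"]), 1)
  expect_equal(unname(f["correlation"]), 0)

  cb <- gray_image(matrix(rep(c(0L, 255L), each = 8, times = 4), 8, 8)) # stripes
  m <- cooccurrence(cb, c(0L, 1L), symmetric = TRUE)
  expect_equal(m$p[1, 256], 0.5)
  expect_equal(m$p[256, 1], 0.5)
  f2 <- haralick(m)
  expect_equal(unname(f2["contrast"]), 255^2)
  expect_equal(unname(f2["asm"]), 0.5)
  expect_equal(unname(f2["entropy"]), log(2))
})

test_that("all features agree with the literal-summation oracle", {
  set.seed(33)
  for (rep in 1:10) {
    w <- gray_image(matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16))
    m <- cooccurrence(w)
    got <- haralick(m)
    want <- naive_haralick(m$p)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-10)
    # entropy is bounded by the log number of occupied cells
    expect_lte(got[["entropy"]], log(sum(m$p > 0)) + 1e-12)
    expect_equal(got[["asm"]], sum(m$p^2))
  }
})

test_that("a constant gray-level shift moves only the sum average", {
  set.seed(4)
  base <- matrix(sample(40:160, 24 * 24, replace = TRUE), 24, 24)
  shift <- 30L
  f0 <- haralick(cooccurrence(gray_image(base)))
  f1 <- haralick(cooccurrence(gray_image(base + shift)))
  for (nm in c("asm", "contrast", "idm", "entropy", "diff_variance")) {
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-12)
  }
  expect_equal(f1[["sum_average"]], f0[["sum_average"]] + 2 * shift,
               tolerance = 1e-9)
})

test_that("extended mode appends difference entropy and the correlation measure", {
  set.seed(12)
  w <- gray_image(matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16))
  m <- cooccurrence(w)
  f <- haralick(m, extended = TRUE)
  expect_named(f, c(oratex:::haralick_feature_names,
                    oratex:::haralick_extra_names))
  expect_equal(unname(f["diff_entropy"]),
               -sum(ifelse(m$p_diff > 0, m$p_diff * log(m$p_diff), 0)))
  expect_lte(abs(f[["info_correlation"]]), 1 + 1e-9)
})

test_that("feature tables carry one row per valid labelled window", {
  img <- gray_image(matrix(sample(0:255, 128 * 128, replace = TRUE), 128, 128))
  mask <- label_mask(matrix(0, 128, 128), img)
  g <- label_superpixels(quadtree_divide(img, 64), mask)
  tab <- extract_features(img, g, image_id = "x", group_id = 2L)
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("image_id", "group_id", "window_row", "window_col",
                      "label", oratex:::haralick_feature_names))

  g$windows$valid[2] <- FALSE
  g$windows$label[2] <- "unlabeled"
  expect_equal(nrow(extract_features(img, g)), 3L)

  g$windows$valid <- FALSE
  g$windows$label <- factor("unlabeled",
                            levels = levels(g$windows$label))
  expect_warning(empty <- extract_features(img, g), "no valid")
  expect_equal(nrow(empty), 0L)
})

test_that("lesion windows show higher contrast than background windows", {
  sc <- generate_scene(scene_spec(seed = 2, size = 256))
  g <- label_superpixels(quadtree_divide(sc$image), sc$mask)
  tab <- extract_features(sc$image, g)
  a <- tab$label == "anomalous"
  expect_gt(sum(a), 0)
  expect_gt(mean(tab$contrast[a]), mean(tab$contrast[!a]))
})
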