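make_table <- function(values, labels, feature = "contrast",
                       image_id = "img", group_id = 1L) {
  tab <- data.frame(image_id = image_id, group_id = group_id,
                    window_row = seq_along(values), window_col = 1L,
                    label = labels, stringsAsFactors = FALSE)
  tab[[feature]] <- values
  tab
}

test_that("knn_fit stores standardised vectors and validates inputs", {
  tab <- make_table(1:10, rep(c("standard", "anomalous"), 5))
  m <- knn_fit(tab, "contrast", k = 1)
  expect_equal(nrow(m$X), 10L)
  expect_equal(mean(m$X), 0, tolerance = 1e-12)
  expect_equal(sd(m$X), 1, tolerance = 1e-12)
  expect_error(knn_fit(tab[0, ], "contrast"), "empty")
  expect_error(knn_fit(tab, "contrast", k = 11), "k")
})

test_that("zero-variance features are dropped with a warning", {
  tab <- make_table(1:10, rep(c("standard", "anomalous"), 5))
  tab$variance <- 5
  expect_warning(m <- knn_fit(tab, c("contrast", "variance")), "zero-variance")
  expect_equal(m$features, "contrast")
  tab$contrast <- 7
  expect_warning(expect_error(knn_fit(tab, c("contrast", "variance")),
                              "no usable"))
})

test_that("nearest-neighbour voting follows distances, majorities and ties", {
  tab <- make_table(c(0, 10), c("standard", "anomalous"))
  m1 <- knn_fit(tab, "contrast", k = 1)
  expect_equal(unname(knn_predict(m1, 2)), "standard")
  expect_equal(unname(knn_predict(m1, 9)), "anomalous")
  # training points classify as themselves at k = 1
  tab2 <- make_table(c(1, 4, 9, 12, 20), c("standard", "anomalous", "standard",
                                           "anomalous", "standard"))
  m2 <- knn_fit(tab2, "contrast", k = 1)
  expect_equal(unname(knn_predict(m2, tab2)), tab2$label)
  # k = 3 majority: neighbours of 8 are {4, 9, 12} -> 2 anomalous
  m3 <- knn_fit(tab2, "contrast", k = 3)
  expect_equal(unname(knn_predict(m3, 8)), "anomalous")
  # neighbours of 2 are {1, 4, 9} -> 2 standard
  expect_equal(unname(knn_predict(m3, 2)), "standard")
  # even k splits break toward anomalous
  m4 <- knn_fit(tab, "contrast", k = 2)
  expect_equal(unname(knn_predict(m4, 5)), "anomalous")
  expect_error(knn_predict(m1, c(1, 2)), "dimension")
})

test_that("predictions agree with class::knn on separable data", {
  skip_if_not_installed("class")
  set.seed(19)
  n <- 60
  tab <- make_table(c(rnorm(n / 2, 0), rnorm(n / 2, 6)),
                    rep(c("standard", "anomalous"), each = n / 2))
  tab$variance <- c(rnorm(n / 2, 2), rnorm(n / 2, -3))
  m <- knn_fit(tab, c("contrast", "variance"), k = 1)
  q <- data.frame(contrast = rnorm(20, 3, 4), variance = rnorm(20, 0, 3))
  qs <- sweep(sweep(as.matrix(q), 2, m$center), 2, m$scale, `/`)
  ref <- as.character(class::knn(m$X, qs, factor(m$labels), k = 1))
  expect_equal(unname(knn_predict(m, q)), ref)
})

test_that("confusion metrics follow the defining ratios", {
  m <- classification_metrics(1, 0, 1, 0)
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, accuracy = 1))
  m2 <- classification_metrics(3, 1, 4, 2)
  expect_equal(unlist(m2),
               c(sensitivity = 0.6, specificity = 0.8, accuracy = 0.7))
  m3 <- classification_metrics(0, 0, 5, 5)
  expect_equal(unlist(m3),
               c(sensitivity = 0, specificity = 1, accuracy = 0.5))
  # zero denominators are undefined, not zero
  m4 <- classification_metrics(0, 2, 3, 0)
  expect_true(is.na(m4$sensitivity))
  expect_equal(m4$specificity, 0.6)
})

test_that("confusion counts are permutation-invariant and complete", {
  set.seed(23)
  truth <- sample(c("standard", "anomalous"), 50, replace = TRUE)
  pred <- sample(c("standard", "anomalous"), 50, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 50L)
  perm <- sample(50)
  cc2 <- confusion_counts(truth[perm], pred[perm])
  expect_equal(cc[c("TP", "FP", "TN", "FN")], cc2[c("TP", "FP", "TN", "FN")])
})

test_that("grouped CV tests each image once within its own group", {
  set.seed(25)
  mk_img <- function(id, grp) {
    make_table(rnorm(8, ifelse(id %% 2 == 0, 0, 5)),
               rep(c("standard", "anomalous"), 4),
               image_id = paste0("img", id), group_id = grp)
  }
  tab1 <- do.call(rbind, lapply(1:5, mk_img, grp = 1))
  rep1 <- grouped_cv(tab1, "contrast", k = 1)
  expect_equal(nrow(rep1$folds), 5L)
  expect_setequal(rep1$folds$image_id, paste0("img", 1:5))

  tab2 <- rbind(tab1, do.call(rbind, lapply(6:10, mk_img, grp = 2)))
  rep2 <- grouped_cv(tab2, "contrast", k = 1)
  expect_equal(nrow(rep2$folds), 10L)

  two <- do.call(rbind, lapply(1:2, mk_img, grp = 1))
  expect_equal(nrow(grouped_cv(two, "contrast")$folds), 2L)

  single <- mk_img(1, 1)
  expect_error(grouped_cv(single, "contrast"), ">= 2 images")
})

test_that("held-out images never contribute to their own training fold", {
  # each image carries one unique feature value; labels alternate by image so
  # the nearest *other* image always has the opposite label. Training on the
  # test image itself would classify every window perfectly; the leak-free
  # protocol must get every window wrong.
  tabs <- lapply(1:4, function(i) {
    make_table(rep(i * 10, 6),
               rep(ifelse(i %% 2 == 0, "anomalous", "standard"), 6),
               image_id = paste0("img", i), group_id = 1L)
  })
  rep <- grouped_cv(do.call(rbind, tabs), "contrast", k = 1)
  expect_equal(sum(rep$folds$TP + rep$folds$TN), 0L)
})

test_that("fold aggregates summarise per-fold metrics", {
  set.seed(26)
  tabs <- lapply(1:4, function(i) {
    make_table(c(rnorm(6, 0), rnorm(2, 20)),
               c(rep("standard", 6), rep("anomalous", 2)),
               image_id = paste0("img", i), group_id = (i > 2) + 1L)
  })
  rep <- grouped_cv(do.call(rbind, tabs), "contrast", k = 1)
  expect_equal(rep$summary$metric, c("sensitivity", "specificity", "accuracy"))
  expect_equal(rep$summary$mean[3], mean(rep$folds$accuracy))
  expect_equal(rep$pooled$accuracy,
               sum(rep$folds$TP + rep$folds$TN) /
                 sum(rep$folds$TP + rep$folds$TN + rep$folds$FP + rep$folds$FN))
})
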