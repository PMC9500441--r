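test_that("plane export counts and orientations are exact", {
  arr <- array(runif(40 * 30 * 150), c(40, 30, 150))
  vol <- voxel_volume(arr, 2)
  horiz <- export_planes(vol, "horizontal", stride = 10)
  expect_equal(nrow(horiz), 15)
  expect_identical(horiz$pixels[[1]], arr[, , 1])

  sag <- export_planes(vol, "sagittal", stride = 1)
  expect_equal(nrow(sag), 30)
  expect_identical(sag$pixels[[7]], arr[, 7, ])

  empty <- voxel_volume(array(numeric(0), c(4, 0, 4)), 2)
  expect_error(export_planes(empty, "sagittal"), "empty")
})

test_that("preprocessing crops sagittal planes centrally and rescales to [0, 1]", {
  img <- matrix(runif(300 * 500, 0, 255), 300, 500)
  out <- preprocess_plane(img, "sagittal")
  expect_equal(dim(out), c(256, 256))
  expect_true(all(out >= 0 & out <= 1))
  # the centred 300x300 crop covers columns 101..400
  manual <- EBImage::imageData(EBImage::resize(
    EBImage::Image(img[, 101:400]), 256, 256)) / 255
  expect_equal(out, manual, tolerance = 1e-12)

  expect_true(all(preprocess_plane(matrix(255, 64, 64), "horizontal") == 1))
  expect_error(preprocess_plane(matrix(1, 4, 400), "sagittal"), "8 px")

  # idempotent (up to resampling) on an already preprocessed image
  once <- preprocess_plane(img, "sagittal")
  twice <- preprocess_plane(once, "sagittal", max_value = 1)
  expect_lt(mean(abs(twice - once)), 0.02)
})

test_that("augmentation is seeded, flips self-invert, and erasing stays in bounds", {
  img <- preprocess_plane(matrix(runif(256 * 256, 0, 255), 256, 256), "horizontal")
  expect_identical(augment_plane(img, 42), augment_plane(img, 42))
  expect_false(identical(augment_plane(img, 42), augment_plane(img, 43)))

  # forced double flip with no rotation and no erasing is the identity
  f1 <- augment_plane(img, 1, rotation_range = c(0, 0), erase_frac = c(0, 0), p_flip = 1)
  f2 <- augment_plane(f1, 2, rotation_range = c(0, 0), erase_frac = c(0, 0), p_flip = 1)
  expect_identical(f2, img)

  # erased-region fraction honours the configured bounds
  fr <- vapply(1:100, function(s) {
    er <- augment_plane(img, s, rotation_range = c(0, 0), p_flip = 0)
    mean(er != img)
  }, numeric(1))
  expect_true(all(fr >= 0.015 & fr <= 0.21))

  # rotation keeps the full intensity range (reflective padding, no gaps)
  rot <- augment_plane(img, 7, erase_frac = c(0, 0), p_flip = 0)
  expect_true(min(rot) >= 0 && max(rot) <= 1)
})

test_that("stratified-group folds never split a specimen and stay balanced", {
  imgs <- tibble::tibble(
    specimen_id = rep(sprintf("s%02d", 1:63), each = 4),
    class_label = rep(rep(c("UC", "CD", "non-IBD"), c(27, 17, 19)), each = 4)
  )
  fa <- stratified_group_kfold(imgs, 10)
  split_check <- tapply(fa$fold, fa$specimen_id, function(f) length(unique(f)))
  expect_true(all(split_check == 1))
  per_fold <- table(dplyr::distinct(fa, .data$specimen_id, .data$class_label,
                                    .data$fold)[, c("fold", "class_label")])
  expect_true(all(apply(per_fold, 2, function(x) max(x) - min(x)) <= 1))

  # leave-one-specimen-out
  solo <- tibble::tibble(specimen_id = letters[1:8], class_label = rep(c("A", "B"), 4))
  expect_equal(sort(unique(stratified_group_kfold(solo, 8)$fold)), 0:7)
  expect_error(stratified_group_kfold(solo, 9), "exceeds")
  bad <- tibble::tibble(specimen_id = c("a", "a"), class_label = c("A", "B"))
  expect_error(stratified_group_kfold(bad, 2), "more than one class")

  # property: random cohorts never split a group
  set.seed(20)
  for (i in 1:10) {
    n <- sample(12:40, 1)
    ims <- tibble::tibble(
      specimen_id = rep(sprintf("x%02d", 1:n), sample(1:5, n, replace = TRUE)),
      class_label = NA
    )
    cls <- setNames(sample(c("A", "B", "C"), n, replace = TRUE), sprintf("x%02d", 1:n))
    ims$class_label <- cls[ims$specimen_id]
    k <- sample(2:min(10, n), 1)
    fo <- stratified_group_kfold(ims, k)
    expect_true(all(tapply(fo$fold, fo$specimen_id,
                           function(f) length(unique(f))) == 1))
  }
})

test_that("evaluation reproduces the printed worked example and basic identities", {
  f1 <- round_half_up(f1_score(c(81.88, 73.88, 91.62), c(93.97, 69.69, 74.00)), 3)
  expect_equal(f1, c(0.875, 0.717, 0.819))
  expect_equal(round_half_up(mean(c(0.95, 0.92, 0.95)), 2), 0.94)
  expect_equal(f1_score(0, 0), 0)

  truth <- c("a", "a", "b", "b", "c", "c")
  rep_perfect <- evaluate_classification(truth, truth)
  expect_true(all(rep_perfect$per_class$accuracy_pct == 100))
  expect_true(all(rep_perfect$per_class$f1_3dp == 1))

  pred <- c("a", "b", "b", "b", "c", "a")
  sc <- matrix(runif(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  r1 <- evaluate_classification(truth, pred, sc)
  expect_true(all(with(r1$per_class, tp + fp + tn + fn) == 6))
  # invariant to simultaneous permutation
  p <- sample(6)
  r2 <- evaluate_classification(truth[p], pred[p], sc[p, ])
  expect_equal(r1$per_class, r2$per_class)
  # a class absent from truth reports NA sensitivity, not zero
  r3 <- evaluate_classification(c("a", "a", "b"), c("a", "c", "b"))
  expect_true(is.na(r3$per_class$sensitivity[r3$per_class$class == "c"]))
})

test_that("rank-statistic AUC equals brute-force pair counting with tie credit", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # heavy ties
    lab <- runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    brute <- mean(outer(s[lab], s[!lab], function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc_rank(s, lab), brute, tolerance = 1e-12)
  }
  expect_true(is.na(auc_rank(runif(5), rep(TRUE, 5))))
})

test_that("the centroid baseline separates well-separated groups and not shuffled ones", {
  co <- generate_cohort(c(UC = 10, CD = 8, "non-IBD" = 9), seed = 23)
  tab <- sample_crypts(co$truth, n = 5, seed = 23)
  rep_good <- crossval_baseline(tab, k = 5)
  expect_gt(rep_good$macro_auc, 0.9)

  expect_error(
    baseline_classifier(tibble::tibble(class_label = "A", volume_um3 = 1,
                                       ellipticity_prolate = 1, tortuosity = 1),
                        tibble::tibble(volume_um3 = 1, ellipticity_prolate = 1,
                                       tortuosity = 1)),
    "2 classes"
  )

  # permutation null: shuffled labels give chance-level macro-AUC
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    shuf <- tab
    spec_labels <- unique(tab[, c("specimen_id", "group")])
    spec_labels$group <- sample(spec_labels$group)
    shuf$group <- spec_labels$group[match(shuf$specimen_id, spec_labels$specimen_id)]
    crossval_baseline(shuf, k = 5)$macro_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
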