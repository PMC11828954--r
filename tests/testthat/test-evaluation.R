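test_that("cost reduction is the fraction of decisions avoiding the second modality", {
  dec <- tibble::tibble(used_model = rep(c("uni", "multi"), c(96, 132)))
  expect_equal(cost_reduction(dec), 96 / 228)
  expect_equal(sprintf("%.0f%%", 100 * cost_reduction(dec)), "42%")
  expect_equal(cost_reduction(tibble::tibble(used_model = rep("uni", 5))), 1)
  expect_equal(cost_reduction(tibble::tibble(used_model = rep("multi", 5))), 0)
  expect_error(cost_reduction(tibble::tibble(used_model = character(0))), "non-empty")
})

test_that("threshold sweeps hit the pure-model endpoints exactly", {
  m <- tiny_models()
  cv <- sweep_thresholds(m$test, m$f, m$h, thresholds = c(0, 0.3, 0.6, 1),
                         uncertainty = "edl")
  uni_acc <- mean(predict(m$f, m$test, type = "class")$.pred_class == m$test$label)
  multi_acc <- mean(predict(m$h, m$test, type = "class")$.pred_class == m$test$label)
  expect_equal(cv$accuracy[cv$threshold == 1], uni_acc)
  expect_equal(cv$cost_reduction[cv$threshold == 1], 1)
  expect_equal(cv$accuracy[cv$threshold == 0], multi_acc)
  expect_equal(cv$cost_reduction[cv$threshold == 0], 0)
  expect_equal(attr(cv, "uni_accuracy"), uni_acc)
  expect_equal(attr(cv, "multi_accuracy"), multi_acc)
  # exact complementarity and monotone referral along the grid
  expect_identical(cv$cost_reduction + cv$referral_fraction, rep(1, nrow(cv)))
  expect_true(all(diff(cv$referral_fraction) <= 0))
  expect_error(sweep_thresholds(m$test, m$f, m$h, thresholds = numeric(0)),
               "non-empty")
})

test_that("region masking zeroes exactly the requested columns", {
  v <- 1:10 * 1.0
  expect_identical(mask_regions(v, k = 0), structure(v, masked_regions = integer(0)))
  expect_equal(as.numeric(mask_regions(v, k = 10, seed = 1)), rep(0, 10))
  m2 <- mask_regions(v, regions = c(1, 6))
  expect_equal(as.numeric(m2), c(0, 2:5, 0, 7:10))
  expect_error(mask_regions(v, regions = 11), "out of range")
  expect_error(mask_regions(v, k = 11), "0, 10")

  co <- tiny_cohort()[1:4, ]
  masked <- mask_regions(co, k = 5, seed = 3)
  idx <- attr(masked, "masked_regions")
  expect_length(idx, 5)
  reg <- grep("^region_", names(co), value = TRUE)
  expect_true(all(as.matrix(masked[reg[idx]]) == 0))
  expect_equal(masked[reg[-idx]], co[reg[-idx]], ignore_attr = TRUE)
  # seeded draw is reproducible
  expect_identical(attr(mask_regions(co, k = 5, seed = 3), "masked_regions"), idx)
})

test_that("image rotation follows the clockwise top-left convention", {
  n <- 9
  img <- array(0, c(n, n, 3))
  img[1, 1, ] <- 1
  expect_identical(rotate_image(img, 0), img)
  r90 <- rotate_image(img, 90)
  expect_equal(r90[1, n, ], c(1, 1, 1), tolerance = 1e-6)
  expect_lt(sum(r90) - 3, 1e-6)
  withr::with_seed(8, {
    noisy <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
    expect_lt(max(abs(rotate_image(noisy, 360) - noisy)), 2 / 255)
    # out-of-frame fill is zero
    r45 <- rotate_image(noisy, 45)
    expect_equal(r45[1, 1, 1], 0)
  })
  expect_error(rotate_image(img, Inf), "finite")
})

test_that("OOD reports pair each in-distribution instance with its perturbed copy", {
  m <- tiny_models()
  rep0 <- ood_report(m$f, m$test, method = "edl", levels = c(0, 10), seed = 2)
  expect_equal(rep0$mu_ood[1], rep0$mu_ind[1])              # identity level
  expect_identical(rep0$u_ood[[1]], rep0$u_ind[[1]])
  expect_length(rep0$u_ood[[2]], nrow(m$test))
  # shuffling the InD records permutes the OOD uncertainties identically
  perm <- rev(seq_len(nrow(m$test)))
  rep_p <- ood_report(m$f, m$test[perm, ], method = "edl", levels = c(0, 10),
                      seed = 2)
  expect_equal(rep_p$u_ood[[2]], rep0$u_ood[[2]][perm])
  expect_error(ood_report(m$f, m$test, method = "edl", levels = 500), "0, 138")
})

test_that("a dropout-free model has zero MC uncertainty at every perturbation level", {
  tr <- dplyr::filter(tiny_cohort(), split == "train")
  f0 <- train_unimodal(tr, tiny_train_config("cross_entropy", dropout = 0))
  rep0 <- ood_report(f0, dplyr::filter(tiny_cohort(), split == "test"),
                     method = "mc", levels = c(0, 20, 138), passes = 10, seed = 1)
  expect_true(all(unlist(rep0$u_ind) == 0))
  expect_true(all(unlist(rep0$u_ood) == 0))
})

test_that("multi-modal OOD levels combine masking with rotation", {
  m <- tiny_models()
  lv <- data.frame(k = c(0, 10), degrees = c(0, 25))
  rep2 <- ood_report(m$h, m$test, method = "edl", levels = lv, seed = 4)
  expect_equal(rep2$k_masked, c(0, 10))
  expect_equal(rep2$rotation_deg, c(0, 25))
  expect_equal(rep2$mu_ood[1], rep2$mu_ind[1])
})

test_that("result plots build without error", {
  m <- tiny_models()
  cv <- sweep_thresholds(m$test, m$f, m$h, thresholds = c(0.2, 0.5, 0.8),
                         uncertainty = "edl")
  expect_s3_class(autoplot(cv), "ggplot")
  rep0 <- ood_report(m$f, m$test, method = "edl", levels = c(0, 30), seed = 1)
  expect_s3_class(autoplot(rep0), "ggplot")
})
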