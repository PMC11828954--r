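test_that("the generator honours configured shapes and flags", {
  co <- generate_cohort(synth_config(n_subjects = 24, n_train = 12,
                                     image_size = 16, seed = 1))
  expect_equal(nrow(co), 24)
  expect_length(grep("^region_\\d+$", names(co)), 138)
  expect_equal(sum(co$split == "train"), 12)
  expect_equal(dim(co$image_left[[1]]), c(16, 16, 3))
  expect_setequal(levels(co$label), c("cn", "ad"))
  meta <- attr(co, "meta")
  expect_length(meta$affected_down, 10)
  expect_length(meta$affected_up, 4)
  expect_length(intersect(meta$affected_down, meta$affected_up), 0)

  co_amb <- generate_cohort(synth_config(n_subjects = 20, n_train = 10,
                                         image_size = 8,
                                         ambiguous_fraction = 1, seed = 2))
  expect_true(all(co_amb$is_ambiguous))
  expect_error(synth_config(n_subjects = 10, n_train = 20), "n_train")
  expect_error(synth_config(ambiguous_fraction = 1.2), "0, 1")
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_subjects = 16, n_train = 8, image_size = 8, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("a zero tabular effect leaves class-conditional volumes exchangeable", {
  cfg0 <- synth_config(n_subjects = 600, n_train = 300, image_size = 8,
                       delta_t = 0, ambiguous_fraction = 0, seed = 5)
  co <- generate_cohort(cfg0)
  aff <- attr(co, "meta")$affected_down
  reg <- grep("^region_", names(co), value = TRUE)[aff]
  lv <- log(as.matrix(co[reg]))
  d <- colMeans(lv[co$label == "ad", , drop = FALSE]) -
    colMeans(lv[co$label == "cn", , drop = FALSE])
  # standardized group differences of ~N(0, sqrt(4/n)) under no effect
  expect_lt(max(abs(d)) / cfg0$sigma_log, 4 * sqrt(4 / 600))
})

test_that("a strong tabular effect makes the cohort linearly separable", {
  co <- generate_cohort(synth_config(n_subjects = 400, n_train = 180,
                                     image_size = 8, delta_t = 3, delta_i = 0,
                                     ambiguous_fraction = 0, seed = 6))
  tr <- co[co$split == "train", ]
  te <- co[co$split == "test", ]
  reg <- grep("^region_", names(co), value = TRUE)
  fit <- glmnet::cv.glmnet(log(as.matrix(tr[reg])), tr$label,
                           family = "binomial", nfolds = 5)
  pred <- predict(fit, log(as.matrix(te[reg])), type = "class")
  expect_gte(mean(pred == as.character(te$label)), 0.95)
})

test_that("ambiguous subjects carry no tabular class signal but keep the image signal", {
  co <- generate_cohort(synth_config(n_subjects = 800, n_train = 400,
                                     image_size = 16, ambiguous_fraction = 0.5,
                                     delta_t = 2, delta_i = 2, seed = 7))
  meta <- attr(co, "meta")
  reg <- grep("^region_", names(co), value = TRUE)[meta$affected_down]
  lv <- log(as.matrix(co[reg]))
  amb <- co$is_ambiguous
  gap <- function(rows) {
    mean(colMeans(lv[rows & co$label == "cn", , drop = FALSE]) -
           colMeans(lv[rows & co$label == "ad", , drop = FALSE]))
  }
  expect_gt(gap(!amb), 1.5 * attr(co, "meta")$config$sigma_log)
  expect_lt(abs(gap(amb)), 0.5 * attr(co, "meta")$config$sigma_log)
  # image patch intensity separates classes for ambiguous subjects too
  p <- meta$patch$left
  patch_mean <- vapply(co$image_left, function(im) {
    mean(im[round(p["cy"]) + (-2:2), round(p["cx"]) + (-2:2), 1])
  }, numeric(1))
  expect_gt(mean(patch_mean[amb & co$label == "ad"]),
            mean(patch_mean[amb & co$label == "cn"]))
})

test_that("a cohort round-trips through its on-disk format", {
  co <- generate_cohort(synth_config(n_subjects = 10, n_train = 5,
                                     image_size = 8, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  tab <- utils::read.csv(file.path(dir, "tabular.csv"))
  expect_equal(ncol(tab), 3 + 138)
  expect_length(list.files(file.path(dir, "images"), pattern = "\\.png$"), 20)

  back <- read_cohort(dir)
  expect_equal(back$subject_id, co$subject_id)
  expect_identical(back$label, co$label)
  expect_identical(back$split, co$split)
  expect_identical(back$is_ambiguous, co$is_ambiguous)
  reg <- grep("^region_", names(co), value = TRUE)
  expect_equal(as.matrix(back[reg]), as.matrix(co[reg]), tolerance = 1e-9)
  for (i in c(1, 10)) {
    expect_identical(back$image_left[[i]], co$image_left[[i]])
    expect_identical(back$image_right[[i]], co$image_right[[i]])
  }
  expect_error(read_cohort(file.path(dir, "nope")), "not found")
})

test_that("written cohorts are byte-identical across repeated writes", {
  co <- generate_cohort(synth_config(n_subjects = 6, n_train = 3,
                                     image_size = 8, seed = 10))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co, d2)
  md5 <- function(d) unname(tools::md5sum(c(file.path(d, "tabular.csv"),
                                            file.path(d, "images", "S0001_left.png"))))
  expect_identical(md5(d1), md5(d2))
})
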