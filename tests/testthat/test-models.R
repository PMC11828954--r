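test_that("a linearly separable set is fit to training accuracy 1", {
  rec <- separable_records(n_per_class = 4, seed = 1)
  f <- train_unimodal(rec, train_config("edl_sos", epochs = 200, lr = 1e-2,
                                        hidden = c(16, 8), embed_dim = 8,
                                        seed = 1))
  expect_equal(mean(predict(f, rec, type = "class")$.pred_class == rec$label), 1)
  expect_equal(nrow(f$history), 200)
})

test_that("training history length equals the configured epochs", {
  rec <- separable_records(seed = 2)
  f <- train_unimodal(rec, train_config(epochs = 7, hidden = c(8), embed_dim = 4,
                                        seed = 2))
  expect_equal(f$history$epoch, 1:7)
  expect_true(all(is.finite(f$history$loss)))
})

test_that("seeded training is bit-reproducible", {
  rec <- separable_records(seed = 3)
  cfg <- train_config(epochs = 10, hidden = c(8), embed_dim = 4, seed = 5)
  f1 <- train_unimodal(rec, cfg)
  f2 <- train_unimodal(rec, cfg)
  expect_identical(f1$net, f2$net)
  expect_identical(f1$history, f2$history)
})

test_that("an evidential model is maximally uncertain on zero-information input", {
  # all features identical across classes: nothing to earn evidence from
  rec <- tibble::tibble(label = factor(rep(c("cn", "ad"), 20), levels = c("cn", "ad")))
  for (j in 1:6) rec[[sprintf("region_%03d", j)]] <- 5
  f <- train_unimodal(rec, train_config("edl_sos", epochs = 50, hidden = c(16, 8),
                                        embed_dim = 8, seed = 3))
  u <- predict(f, rec, type = "opinion")$.uncertainty
  # matches the opinion obtained from near-zero evidence
  expect_gt(mean(u), 0.9)
  expect_lt(abs(mean(u) - opinion_from_evidence(c(0, 0))$uncertainty), 0.1)
})

test_that("degenerate training sets are rejected", {
  rec <- separable_records(seed = 4)
  expect_error(train_unimodal(rec[rec$label == "cn", ], train_config(epochs = 1)),
               "each class")
  f <- tiny_models()$f
  expect_error(predict(f, separable_records(seed = 5)))  # 2 regions vs 138
})

test_that("the multi-modal model outperforms the uni-modal one when the class signal lives in the images", {
  wins <- sapply(1:3, function(s) {
    co <- generate_cohort(synth_config(n_subjects = 80, n_train = 40,
                                       image_size = 32, ambiguous_fraction = 1,
                                       delta_i = 2, seed = 300 + s))
    tr <- dplyr::filter(co, split == "train")
    te <- dplyr::filter(co, split == "test")
    cfg <- train_config("cross_entropy", epochs = 60, hidden = c(32, 16),
                        embed_dim = 16, img_channels = c(8, 16),
                        img_embed_dim = 16, seed = s)
    fu <- train_unimodal(tr, cfg)
    hm <- train_multimodal(tr, cfg)
    c(uni = mean(predict(fu, te, type = "class")$.pred_class == te$label),
      multi = mean(predict(hm, te, type = "class")$.pred_class == te$label))
  })
  expect_gt(mean(wins["multi", ] - wins["uni", ]), 0.2)
  expect_true(all(wins["multi", ] > wins["uni", ]))
})

test_that("branch embeddings concatenate into the fused embedding", {
  m <- tiny_models()
  E <- embed(m$h, m$test[1:3, ])
  cfg <- m$h$config
  expect_equal(ncol(E), cfg$embed_dim + cfg$img_embed_dim)
  Ef <- embed(m$f, m$test[1:3, ])
  expect_equal(ncol(Ef), cfg$embed_dim)
})

test_that("embeddings are deterministic and ignore the label", {
  m <- tiny_models()
  te <- m$test[1:2, ]
  expect_identical(embed(m$f, te), embed(m$f, te))
  te_flipped <- te
  te_flipped$label <- rev(te_flipped$label)
  expect_identical(embed(m$f, te), embed(m$f, te_flipped))
})

test_that("the tabular branches of both models share one architecture", {
  m <- tiny_models()
  shape <- function(layers) lapply(layers, function(l) {
    c(kind = l$kind, if (!is.null(l$W)) paste(dim(l$W), collapse = "x"))
  })
  expect_identical(shape(m$f$net$trunk), shape(m$h$net$tab))
})

test_that("zeroing the image branch output makes predictions image-invariant", {
  m <- tiny_models()
  h0 <- m$h
  nl <- length(h0$net$img)
  h0$net$img[[nl - 1]]$W[] <- 0  # final dense of the image branch
  h0$net$img[[nl - 1]]$b[] <- 0
  te <- m$test[1:4, ]
  te_scrambled <- te
  te_scrambled$image_left <- lapply(te$image_left, function(im) im * 0)
  te_scrambled$image_right <- lapply(te$image_right, function(im) im * 0 + 1)
  expect_equal(predict(h0, te, type = "prob"),
               predict(h0, te_scrambled, type = "prob"))
})

test_that("opinion predictions require an evidential head", {
  m_ce <- tiny_models("cross_entropy")
  expect_error(predict(m_ce$f, m_ce$test[1:2, ], type = "opinion"), "evidential")
})

test_that("glance and tidy summarise a fitted model", {
  m <- tiny_models()
  g <- glance(m$f)
  expect_equal(g$loss_type, "edl_sos")
  expect_gt(g$n_parameters, 1000)
  expect_equal(nrow(tidy(m$f)), m$f$config$epochs)
})
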