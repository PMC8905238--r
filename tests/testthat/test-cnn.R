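# a small shared network: full 224 input, narrow channels so tests run fast
tiny_net <- function() fixture("tiny_net", function()
  corn_seed_net(arch_spec(width_multiplier = 0.05), rng_seed = 1))

test_that("softmax matches the direct formula and its symmetries", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  for (c0 in c(-3, 0, 7))
    expect_equal(softmax(rep(c0, 3)), rep(1 / 3, 3))
  z <- c(1, 2, 3)
  expect_equal(softmax(z), softmax_brute(z), tolerance = 1e-12)
  expect_equal(sum(softmax(c(100, -100, 5))), 1)
  set.seed(1)
  for (i in 1:20) {
    z <- rnorm(5, sd = 3)
    expect_lt(max(abs(softmax(z) - softmax_brute(z))), 1e-10)
    expect_equal(softmax(z + 17), softmax(z), tolerance = 1e-10)
  }
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("cross-entropy matches closed forms and a brute-force batch oracle", {
  expect_equal(cross_entropy(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)),
               log(2))
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), matrix(c(0, 1), 1)),
               log(2))
  set.seed(2)
  probs <- t(apply(matrix(rnorm(40), 10), 1, softmax))
  hot <- t(vapply(sample(1:4, 10, TRUE), function(k) as.numeric(1:4 == k),
                  numeric(4)))
  expect_lt(abs(cross_entropy(probs, hot) - cross_entropy_brute(probs, hot)),
            1e-10)
  expect_equal(cross_entropy(probs, hot, reduce = "mean"),
               cross_entropy(probs, hot) / 10)
  expect_error(cross_entropy(probs, hot[1:5, ]), "identical shapes")
  expect_error(cross_entropy(probs * 2, hot), "sum to 1")
})

test_that("the architecture matches its printed configuration", {
  lt <- describe_net(tiny_net())
  # VGG branch trunk: exactly 13 3x3 convolutions and 5 pools
  vgg_trunk <- lt[lt$branch == "vgg" & lt$stage == "trunk", ]
  expect_equal(sum(vgg_trunk$type == "conv"), 13)
  expect_true(all(vgg_trunk$kernel[vgg_trunk$type == "conv"] == 3))
  expect_equal(sum(vgg_trunk$type == "maxpool"), 5)
  # VGG head: one 7x7 valid conv + two dense layers
  vgg_head <- lt[lt$branch == "vgg" & lt$stage == "head", ]
  expect_equal(sum(vgg_head$type == "conv"), 1)
  expect_equal(vgg_head$kernel[vgg_head$type == "conv"], 7)
  expect_equal(sum(vgg_head$type == "dense"), 2)
  # ResNet branch: the 50-layer arithmetic 1 + 3*(3+4+6+3) + 1
  res <- lt[lt$branch == "resnet", ]
  n_proj <- sum(res$type == "conv" & res$note == "projection")
  n_conv <- sum(res$type == "conv")
  expect_equal(n_proj, 4)
  expect_equal(n_conv - n_proj, 1 + 3 * (3 + 4 + 6 + 3))
  expect_equal(sum(res$type == "dense"), 1)
  expect_equal((n_conv - n_proj) + 1, 50)
  # fusion head: one dense layer to 2 classes
  expect_equal(lt$out_channels[lt$branch == "fusion"], 2)
})

test_that("residual blocks add their input to the transformed output", {
  gap <- cornseed:::csn_residual_identity_gap_(tiny_net()$ptr, 64L, 3L)
  expect_lt(gap, 1e-5)
})

test_that("width scaling keeps the promised embedding/fusion dimensions", {
  lt <- describe_net(tiny_net())
  expect_equal(attr(lt, "embed_dim"), round(512 * 0.05))
  expect_equal(attr(lt, "fused_dim"), 2 * round(512 * 0.05))
  m25 <- fixture("net25", function()
    corn_seed_net(arch_spec(width_multiplier = 0.25), rng_seed = 2))
  expect_equal(attr(describe_net(m25), "embed_dim"), 128)
  # a forward pass on one chip runs on CPU in under a second
  chip <- array(0, c(224, 224, 4))
  t0 <- proc.time()
  p <- predict(m25, chip)
  expect_lt((proc.time() - t0)[3], 1)
  # finite, deterministic, normalized output on an all-zero chip
  expect_equal(p$prob_good + p$prob_bad, 1, tolerance = 1e-6)
  p2 <- predict(m25, chip)
  expect_identical(p$prob_good, p2$prob_good)
  expect_error(corn_seed_net(arch_spec(input_size = 112)), "224")
})

test_that("pretrained first-layer adaptation averages RGB into NIR", {
  k <- array(0, c(3, 3, 3, 4))
  k[, , 1, ] <- 1; k[, , 2, ] <- 2; k[, , 3, ] <- 3
  a <- adapt_pretrained_first_layer(k)
  expect_equal(dim(a), c(3, 3, 4, 4))
  expect_true(all(a[, , 4, ] == 2))
  expect_equal(a[, , 1:3, ], k)
  same <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  same[, , 2, ] <- same[, , 1, ]; same[, , 3, ] <- same[, , 1, ]
  expect_equal(adapt_pretrained_first_layer(same)[, , 4, ], same[, , 1, ])
  expect_error(adapt_pretrained_first_layer(array(0, c(3, 3, 4, 4))), "3")
  # kernels can be installed into a branch
  m <- tiny_net()
  cur <- cornseed:::csn_first_conv_weights_(m$ptr, "vgg")
  k4 <- array(seq_len(3 * 3 * 4 * ncol(cur)) / 1000, c(3, 3, 4, ncol(cur)))
  set_first_conv(m, "vgg", k4)
  now <- cornseed:::csn_first_conv_weights_(m$ptr, "vgg")
  expect_equal(now[, 1], as.vector(k4[, , , 1]), tolerance = 1e-6)
})

test_that("the reduced VGG head has far fewer parameters than the original", {
  # audited at full width via the layer table's parameter arithmetic
  m <- fixture("net_full", function()
    corn_seed_net(arch_spec(width_multiplier = 1), rng_seed = 1))
  lt <- describe_net(m)
  head_params <- sum(lt$params[lt$branch == "vgg" & lt$stage == "head"])
  original_fc_head <- 25088 * 4096 + 4096 + 4096 * 4096 + 4096
  expect_lt(head_params, original_fc_head)
  expect_equal(attr(lt, "fused_dim"), 1024)
})

test_that("plateau scheduling halves the rate after stalled epochs", {
  # constant test loss: halve after each `patience` run
  lrs <- plateau_schedule(rep(1, 8), lr0 = 0.001, patience = 3)
  expect_equal(lrs, 0.001 * c(1, 1, 1, 1, 0.5, 0.5, 0.5, 0.25))
  # steadily improving loss: never halves
  expect_equal(plateau_schedule(seq(1, 0.1, length.out = 6), 0.001),
               rep(0.001, 6))
})

test_that("training is deterministic, learns, and records its history", {
  chips <- chips_small()
  sp <- split_dataset(chips, 0.25, rng_seed = 1)
  cfg <- training_config(epochs = 2, batch_size = 16, rng_seed = 3)
  m1 <- corn_seed_net(arch_spec(width_multiplier = 0.05), rng_seed = 9)
  m1 <- csn_train(m1, sp$train, sp$test, cfg)
  m2 <- corn_seed_net(arch_spec(width_multiplier = 0.05), rng_seed = 9)
  m2 <- csn_train(m2, sp$train, sp$test, cfg)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_equal(nrow(m1$history), 2)
  expect_true(all(is.finite(m1$history$train_loss)))
  h <- tidy(m1)
  expect_named(h, c("epoch", "lr", "train_loss", "train_accuracy",
                    "test_loss", "test_accuracy"))
  g <- glance(m1)
  expect_equal(g$epochs_trained, 2)
  # batch prediction equals singleton prediction
  p_all <- predict(m1, sp$test)
  p_one <- predict(m1, sp$test$pixels[[3]])
  # single-precision arithmetic: batch and singleton paths agree to ~1e-5
  expect_equal(p_all$prob_good[3], p_one$prob_good, tolerance = 1e-4)
  expect_true(all(abs(p_all$prob_good + p_all$prob_bad - 1) < 1e-6))
  expect_equal(p_all$pred_label,
               ifelse(p_all$prob_good >= p_all$prob_bad, "good", "bad"))
  # checkpoints restore predictions exactly
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, path)
  p_back <- predict(load_model(path), sp$test)
  expect_equal(p_back$prob_good, p_all$prob_good, tolerance = 1e-7)
  expect_error(csn_train(m1, sp$train[sp$train$label == "good", ], sp$test, cfg),
               "every class")
})
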