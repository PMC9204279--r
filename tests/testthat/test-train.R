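test_that("learning-rate schedule is a staircase exponential decay", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_equal(lr_schedule(299, cfg), 2e-4)            # before first decay
  expect_equal(lr_schedule(300, cfg), 2e-4 * 0.96)     # 1.92e-4
  expect_equal(lr_schedule(650, cfg), 2e-4 * 0.96^2)
  steps <- 0:2000
  expect_true(all(diff(lr_schedule(steps, cfg)) <= 0)) # nonincreasing
  expect_error(train_config(decay_rate = 0), "decay_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("a short training run reduces the loss deterministically", {
  ph <- noise_free_phantoms(n = 4, size = 32, seed = 6)
  data <- list(images = ph$hu, masks = ph$masks,
               split = c("train", "train", "train", "validation"))
  tc <- train_config(batch_size = 2, epochs = 3, image_size = 32,
                     initial_lr = 5e-3, seed = 4,
                     model = model_config(num_levels = 2, base_channels = 4),
                     clahe = FALSE, augment = TRUE)
  fit1 <- msfa_train(data, tc)
  expect_s3_class(fit1, "msfa_unet")
  h <- fit1$history
  expect_equal(nrow(h), 3)
  expect_lt(h$train_loss[3], h$train_loss[1])
  # same config + seed reproduces the loss curve exactly
  fit2 <- msfa_train(data, tc)
  expect_identical(fit1$history, fit2$history)
  # images in HU: the stored preprocessing pipeline applies at predict time
  masks <- predict(fit1, ph$hu[[4]] * 0 + 40)         # flat background slice
  expect_equal(dim(masks[[1]]), c(32, 32))
  expect_true(all(masks[[1]] %in% c(0, 1)))
})

test_that("prediction thresholds probability maps consistently", {
  ph <- noise_free_phantoms(n = 2, size = 32, seed = 8)
  data <- list(images = ph$hu, masks = ph$masks,
               split = c("train", "validation"))
  tc <- train_config(batch_size = 1, epochs = 2, image_size = 32,
                     initial_lr = 5e-3, seed = 1,
                     model = model_config(num_levels = 2, base_channels = 4),
                     clahe = FALSE, augment = FALSE)
  fit <- msfa_train(data, tc)
  # raw phantom in HU goes in; both output types agree through the threshold
  probs <- predict(fit, ph$hu[[1]], type = "prob")
  masks <- predict(fit, ph$hu[[1]], type = "mask")
  expect_true(all(probs[[1]] > 0 & probs[[1]] < 1))
  expect_identical(masks[[1]], (probs[[1]] >= 0.5) * 1)
  m2 <- predict(fit, ph$hu[[1]], type = "mask", threshold = 0.99)
  expect_identical(m2[[1]], (probs[[1]] >= 0.99) * 1)
})

test_that("checkpoints round-trip weights, statistics and config", {
  net <- build_model(model_config(num_levels = 2, base_channels = 4), seed = 3)
  set.seed(1)
  x <- matrix(runif(32 * 32), 32, 32)
  p1 <- msfa_forward(net, x)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(net, ck)
  expect_true(file.exists(paste0(ck, ".json")))       # self-describing
  js <- jsonlite::read_json(paste0(ck, ".json"))
  expect_equal(js$num_levels, 2)
  net2 <- load_checkpoint(ck)
  expect_identical(msfa_forward(net2, x), p1)
})

test_that("evaluation reports aggregate exactly as mean and sd of cases", {
  set.seed(9)
  gts <- lapply(1:10, function(i) random_mask(24, 24))
  rep1 <- evaluate_masks(gts, gts)
  expect_equal(rep1$summary$mean[rep1$summary$metric == "dsc"], 1)
  expect_equal(rep1$summary$sd, rep(0, 5))
  expect_equal(rep1$summary$mean[rep1$summary$metric == "hd"], 0)
  # single-case report: sd 0 by convention, n = 1 recorded
  rep2 <- evaluate_masks(gts[1], gts[1])
  expect_equal(rep2$summary$sd, rep(0, 5))
  expect_equal(rep2$summary$n, rep(1, 5))
  # mean recomputable from the per-case CSV by independent summation
  preds <- lapply(gts, function(m) { m[1:4, ] <- 0; m })
  preds <- lapply(preds, function(m) { if (sum(m) == 0) m[12, 12] <- 1; m })
  rep3 <- evaluate_masks(preds, gts)
  path <- tempfile(fileext = ".csv")
  write_metric_report(rep3, path)
  per <- utils::read.csv(path)
  for (m in c("dsc", "jsc", "ppv", "se", "hd")) {
    x <- per[[m]][is.finite(per[[m]])]
    expect_equal(sum(x) / length(x),
                 rep3$summary$mean[rep3$summary$metric == m])
  }
  expect_error(evaluate_masks(preds[1:3], gts), "counts differ")
})
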