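cfg <- be_config("ABE")

tiny_control <- function(...) {
  args <- utils::modifyList(list(filters = 4L, epochs = 8L, batch_size = 16L,
                                 n_shuffles = 2L, patience = 4L), list(...))
  do.call(be_training_control, args)
}

test_that("input encoding: one-hot sequence plus broadcast factor channels", {
  site <- fixture_site()
  M <- encode_input(site)
  expect_equal(dim(M), c(40, 4))
  expect_equal(unname(rowSums(M)), rep(1, 40)) # exactly one base per position

  ann <- data.frame(site_id = site$site_id, H3K27ac = 0.7,
                    expression_flag = 1L)
  M2 <- encode_input(site, ann, c("H3K27ac", "expression"))
  expect_equal(dim(M2), c(40, 6))
  expect_equal(unname(M2[, "H3K27ac"]), rep(0.7, 40))
  expect_equal(unname(M2[, "expression"]), rep(1, 40)) # falls back to the flag

  expect_error(encode_input(site, ann, "CTCF"), "missing factor channel")

  # per-base methylation channel is positional, not broadcast
  pb <- data.frame(site_id = site$site_id, position = 5L, beta = 0.9,
                   methylated = 1L)
  M3 <- encode_input(site, ann, "methylation_per_base",
                     per_base_methylation = pb)
  expect_equal(sum(M3[, 5] != 0), 1) # only the covered base position
  expect_equal(unname(M3[15, 5]), 0.9) # protospacer position 5 = context row 15
})

test_that("masked loss ignores labels at non-target positions", {
  set.seed(3)
  n <- 8
  X <- array(stats::rnorm(n * 40 * 4), c(n, 40, 4))
  Y <- matrix(stats::runif(n * 20), n, 20)
  mask <- matrix(stats::rbinom(n * 20, 1, 0.5), n, 20)
  net <- cnn_init(4, tiny_control(), seed = 1)
  fw <- getFromNamespace("cnn_forward", "bequant")(net, X, cache = TRUE)
  ls1 <- getFromNamespace("cnn_loss", "bequant")(net, fw$yhat, Y, mask)
  g1 <- getFromNamespace("cnn_backward", "bequant")(net, fw, ls1$dyhat)
  Y2 <- Y
  Y2[mask == 0] <- stats::runif(sum(mask == 0)) # perturb only masked labels
  ls2 <- getFromNamespace("cnn_loss", "bequant")(net, fw$yhat, Y2, mask)
  g2 <- getFromNamespace("cnn_backward", "bequant")(net, fw, ls2$dyhat)
  expect_equal(ls1$loss, ls2$loss)
  expect_equal(g1$Wd, g2$Wd)
  expect_equal(g1$branches[[2]]$W, g2$branches[[2]]$W)
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(4)
  ctl <- be_training_control(kernel_widths = c(1, 3), filters = 2L)
  n <- 3
  X <- array(stats::rnorm(n * 40 * 4), c(n, 40, 4))
  Y <- matrix(stats::runif(n * 20), n, 20)
  mask <- matrix(1, n, 20)
  net <- cnn_init(4, ctl, seed = 2)
  forward <- getFromNamespace("cnn_forward", "bequant")
  lossf <- getFromNamespace("cnn_loss", "bequant")
  backward <- getFromNamespace("cnn_backward", "bequant")
  fw <- forward(net, X, cache = TRUE)
  ls <- lossf(net, fw$yhat, Y, mask)
  gr <- backward(net, fw, ls$dyhat)
  eps <- 1e-6
  loss_at <- function(nt) lossf(nt, forward(nt, X)$yhat, Y, mask)$loss
  # dense weight
  for (idx in list(c(1, 1), c(5, 7))) {
    np <- net; np$Wd[idx[1], idx[2]] <- np$Wd[idx[1], idx[2]] + eps
    nm <- net; nm$Wd[idx[1], idx[2]] <- nm$Wd[idx[1], idx[2]] - eps
    fd <- (loss_at(np) - loss_at(nm)) / (2 * eps)
    expect_equal(gr$Wd[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
  # convolution weight of the width-3 branch
  np <- net; np$branches[[2]]$W[2, 3, 1] <- np$branches[[2]]$W[2, 3, 1] + eps
  nm <- net; nm$branches[[2]]$W[2, 3, 1] <- nm$branches[[2]]$W[2, 3, 1] - eps
  fd <- (loss_at(np) - loss_at(nm)) / (2 * eps)
  expect_equal(gr$branches[[2]]$W[2, 3, 1], fd, tolerance = 1e-4)
  # bias
  np <- net; np$bd[4] <- np$bd[4] + eps
  nm <- net; nm$bd[4] <- nm$bd[4] - eps
  expect_equal(gr$bd[4], (loss_at(np) - loss_at(nm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("the network can overfit a small site set", {
  set.seed(11)
  sim <- simulate_dataset(50, "ABE", seed = 21)
  q <- quantify_dataset(sim$tables, sim$sites, sim$cfg)
  ds <- be_model_dataset(sim$sites, q$summaries, NULL, sim$cfg,
                         channels = character(0))
  ctl <- be_training_control(filters = 12L, epochs = 300L, batch_size = 50L,
                             learning_rate = 0.005)
  fit <- cnn_fit(ds$X, ds$Y, ds$mask, ctl, val_idx = NULL, seed = 5)
  pred <- predict_efficiency(fit$net, ds$X)
  msk <- ds$mask == 1
  expect_gt(stats::cor(pred[msk], ds$Y[msk]), 0.99)
  expect_true(all(pred > 0 & pred < 1)) # sigmoid bounds
})

test_that("training is deterministic and prediction batch-invariant", {
  sim <- simulate_dataset(40, "ABE", seed = 31)
  q <- quantify_dataset(sim$tables, sim$sites, sim$cfg)
  ds <- be_model_dataset(sim$sites, q$summaries, NULL, sim$cfg,
                         channels = character(0))
  cfg1 <- sim$cfg; cfg1$training <- tiny_control(); cfg1$seed <- 9L
  m1 <- train_efficiency_model(ds, cfg1)
  m2 <- train_efficiency_model(ds, cfg1)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$net, m2$net)
  cfg2 <- cfg1; cfg2$seed <- 10L
  m3 <- train_efficiency_model(ds, cfg2)
  expect_false(identical(m1$metrics$test_r, m3$metrics$test_r))

  # prediction of a site does not depend on batch composition
  p_all <- predict_efficiency(m1, ds)
  p_one <- predict_efficiency(m1$net, ds$X[3, , , drop = FALSE])
  expect_equal(unname(p_all[3, ]), as.numeric(p_one), tolerance = 1e-12)
})

test_that("factor channels separate sequence-only from endogenous models", {
  sim <- simulate_dataset(30, "ABE", seed = 41)
  q <- quantify_dataset(sim$tables, sim$sites, sim$cfg)
  ds_seq <- be_model_dataset(sim$sites, q$summaries, NULL, sim$cfg,
                             channels = character(0))
  ds_endo <- be_model_dataset(sim$sites, q$summaries, sim$annotation,
                              sim$cfg, channels = "H3K27ac")
  expect_equal(dim(ds_seq$X)[3], 4)
  expect_equal(dim(ds_endo$X)[3], 5)
  expect_equal(ds_endo$channels, "H3K27ac")
  # default ABE channel set is H3K27ac
  ds_def <- be_model_dataset(sim$sites, q$summaries, sim$annotation, sim$cfg)
  expect_equal(ds_def$channels, "H3K27ac")
  # the stratification key reflects factor presence
  expect_setequal(unique(ds_endo$strata), c("factor", "no_factor"))

  cfg1 <- sim$cfg; cfg1$training <- tiny_control()
  # small strata may collapse in the inner validation split; that fallback
  # warns by design
  m_endo <- suppressWarnings(train_efficiency_model(ds_endo, cfg1))
  expect_error(predict_efficiency(m_endo, ds_seq), "channel mismatch")
})

test_that("factor channels improve prediction when the factor drives efficiency", {
  # H3K27ac shifts the generating logit by up to +1; a sequence-only model
  # cannot explain that variance, so the factor-channel model must win the
  # paired 6-shuffle comparison
  sim <- simulate_dataset(300, "ABE", seed = 71)
  q <- quantify_dataset(sim$tables, sim$sites, sim$cfg)
  cfg1 <- sim$cfg
  cfg1$training <- be_training_control(epochs = 40L)
  ds_seq <- be_model_dataset(sim$sites, q$summaries, NULL, cfg1,
                             channels = character(0))
  ds_endo <- be_model_dataset(sim$sites, q$summaries, sim$annotation, cfg1,
                              channels = "H3K27ac")
  m_seq <- suppressWarnings(train_efficiency_model(ds_seq, cfg1))
  m_endo <- suppressWarnings(train_efficiency_model(ds_endo, cfg1))
  diffs <- m_endo$metrics$test_r - m_seq$metrics$test_r
  expect_gt(mean(diffs), 0)
  expect_gt(sum(diffs > 0), 3) # wins the majority of the 6 paired shuffles
})

test_that("efficiency model serializes and restores bit-exact predictions", {
  sim <- simulate_dataset(20, "ABE", seed = 51)
  q <- quantify_dataset(sim$tables, sim$sites, sim$cfg)
  ds <- be_model_dataset(sim$sites, q$summaries, NULL, sim$cfg,
                         channels = character(0))
  cfg1 <- sim$cfg; cfg1$training <- tiny_control(n_shuffles = 1L)
  mdl <- train_efficiency_model(ds, cfg1)
  f <- withr::local_tempfile(fileext = ".json")
  write_efficiency_model(mdl, f)
  back <- read_efficiency_model(f)
  expect_equal(predict_efficiency(back, ds), predict_efficiency(mdl, ds))
})

test_that("evaluation: correlations, grouping and the dependent-correlation Z", {
  set.seed(61)
  n <- 200
  obs <- matrix(stats::runif(n * 20), n, 20)
  mask <- matrix(1, n, 20)
  ev <- evaluate_predictions(obs, obs, mask)
  expect_equal(ev$pooled$r, 1)

  pred <- obs + matrix(stats::rnorm(n * 20, sd = 0.1), n, 20)
  ev2 <- evaluate_predictions(pred, obs, mask,
                              group = rep(c("g1", "g2"), each = n / 2))
  expect_equal(nrow(ev2$per_group), 2)
  expect_true(all(ev2$per_group$r > 0.8))
  expect_equal(nrow(ev2$per_position), 20)
  expect_true(all(ev2$per_position$conf_low < ev2$per_position$r))

  # identical predictions: Z exactly 0
  z0 <- compare_models(obs[, 1], pred[, 1], pred[, 1])
  expect_equal(z0$z, 0)

  # cross-check against the independently coded formula on a trivariate sample
  set.seed(62)
  S <- matrix(c(1, .6, .4, .6, 1, .5, .4, .5, 1), 3)
  L <- chol(S)
  Z3 <- matrix(stats::rnorm(3 * 500), 500, 3) %*% L
  zres <- compare_models(Z3[, 1], Z3[, 2], Z3[, 3])
  zora <- oracle_steiger(stats::cor(Z3[, 1], Z3[, 2]),
                         stats::cor(Z3[, 1], Z3[, 3]),
                         stats::cor(Z3[, 2], Z3[, 3]), 500)
  expect_equal(zres$z, zora, tolerance = 1e-10)

  expect_error(steiger_z(.5, .4, .3, 3), "n >= 4")
})
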