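test_that("feature-map side follows the floor(input / 2^stages) shape law", {
  for (input in c(32, 64, 224, 250)) {
    for (stages in c(3, 5)) {
      # independent trace: repeated halving with floor at every pool
      side <- input
      for (s in seq_len(stages)) side <- side %/% 2
      if (side < 1) {
        expect_error(backbone_spec("mini", input, stages), "collapses")
        next
      }
      m <- build_model(backbone_spec("mini", input, stages), seed = 1)
      pr <- predict_roi(m, array(stats::runif(input * input * 3),
                                 c(input, input, 3)))
      expect_identical(dim(pr$feature)[1:2], rep(as.integer(side), 2))
      expect_length(pr$deep, m$spec$channels_out)
    }
  }
})

test_that("the vgg19 preset maps 224 px input to a 7x7x512 feature tensor", {
  m <- build_model(backbone_spec("vgg19"), seed = 1)
  img <- array(stats::runif(224 * 224 * 3), c(224, 224, 3))
  pr <- predict_roi(m, img)
  expect_identical(dim(pr$feature), c(7L, 7L, 512L))
  expect_length(pr$deep, 512)
  expect_equal(pr$prediction$p_N + pr$prediction$p_F, 1, tolerance = 1e-9)
  expect_error(backbone_spec("vgg19", n_pool_stages = 3), "5 pooling stages")
  expect_error(build_model(backbone_spec("mini"), init = "pretrained_vgg19"),
               "vgg19 preset")
  expect_error(build_model(backbone_spec("vgg19"), init = "pretrained_vgg19"),
               "weights")
})

test_that("predictions are normalised Bernoulli distributions", {
  m <- build_model(backbone_spec("mini", 32, 3), seed = 2)
  imgs <- lapply(1:1000, function(i) {
    set.seed(i)
    array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  })
  pr <- predict(m, imgs)
  expect_true(all(abs(pr$p_N + pr$p_F - 1) < 1e-6))
  expect_true(all(pr$p_F >= 0 & pr$p_F <= 1))
  # a zeroed head is exactly indifferent
  m0 <- m
  m0$params$head$W[] <- 0
  m0$params$head$b[] <- 0
  p0 <- predict_roi(m0, imgs[[1]])$prediction
  expect_identical(unname(c(p0$p_N, p0$p_F)), c(0.5, 0.5))
  expect_error(predict_roi(m, array(0, c(32, 32, 4))), "RGB")
})

test_that("the GAP deep feature equals the brute-force spatial mean of F", {
  m <- build_model(desk_spec(), seed = 3)
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  pr <- predict_roi(m, img)
  oracle <- apply(pr$feature, 3, mean)
  expect_lt(max(abs(pr$deep - oracle)), 1e-10)
})

test_that("cross-entropy follows the 1/|C|-normalised form", {
  expect_identical(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2) / 2,
               tolerance = 1e-12)
  # loss decreases monotonically as the prediction approaches the label
  losses <- vapply(seq(0.5, 0.99, by = 0.07),
                   function(p) cross_entropy(c(1, 0), c(p, 1 - p)), 0)
  expect_true(all(diff(losses) < 0))
  expect_error(cross_entropy(c(1, 0), c(1.2, -0.2)), "\\[0, 1\\]")
  # matrix form averages over samples
  expect_equal(cross_entropy(rbind(c(1, 0), c(0, 1)),
                             rbind(c(1, 0), c(0.5, 0.5))),
               log(2) / 4, tolerance = 1e-12)
})

test_that("backpropagation matches central finite differences", {
  m <- build_model(backbone_spec("mini", 8, 2), seed = 2)
  imgs <- lapply(1:3, function(i) {
    set.seed(100 + i)
    array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  })
  y <- rbind(c(1, 0), c(0, 1), c(1, 0))
  fwd <- embscope:::net_forward(m, imgs, train = TRUE)
  gr <- embscope:::net_backward(m, fwd, y)
  loss_at <- function(params) {
    mt <- m
    mt$params <- params
    cross_entropy(y, embscope:::net_forward(mt, imgs)$probs)
  }
  eps <- 1e-6
  worst <- 0
  set.seed(9)
  for (l in seq_along(m$params$conv)) {
    for (nm in c("W", "b")) {
      p <- m$params$conv[[l]][[nm]]
      for (k in sample(length(p), min(5, length(p)))) {
        pp <- m$params
        pp$conv[[l]][[nm]][k] <- pp$conv[[l]][[nm]][k] + eps
        pm <- m$params
        pm$conv[[l]][[nm]][k] <- pm$conv[[l]][[nm]][k] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        worst <- max(worst, abs(num - gr$conv[[l]][[nm]][k]))
      }
    }
  }
  for (nm in c("W", "b")) {
    for (k in seq_along(m$params$head[[nm]])) {
      pp <- m$params
      pp$head[[nm]][k] <- pp$head[[nm]][k] + eps
      pm <- m$params
      pm$head[[nm]][k] <- pm$head[[nm]][k] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      worst <- max(worst, abs(num - gr$head[[nm]][k]))
    }
  }
  expect_lt(worst, 1e-7)
})

test_that("augmentation components behave as specified", {
  img <- array(stats::runif(250 * 250 * 3), c(250, 250, 3))
  set.seed(1)
  expect_identical(augment(img, crop = FALSE, hflip = FALSE, vflip = FALSE,
                           stain = FALSE), img)
  set.seed(1)
  out <- augment(img, crop = TRUE, hflip = FALSE, vflip = FALSE,
                 stain = FALSE)
  expect_identical(dim(out), c(224L, 224L, 3L))
  small <- array(0.5, c(100, 100, 3))
  expect_error(augment(small, crop = TRUE), "smaller than crop")
  # zero-magnitude stain jitter is the identity
  set.seed(2)
  same <- stain_augment(img, stain_aug_params(0, 0))
  expect_lt(max(abs(same - img)), 1 / 255)
  # nonzero jitter changes the image but stays in range
  set.seed(3)
  jit <- stain_augment(img, stain_aug_params(0.1, 0.1))
  expect_gt(max(abs(jit - img)), 1 / 255)
  expect_true(all(jit >= 0 & jit <= 1))
  # flips are draws from the current RNG stream: reproducible under a seed
  set.seed(4)
  a <- augment(img, crop = FALSE, stain = FALSE)
  set.seed(4)
  b <- augment(img, crop = FALSE, stain = FALSE)
  expect_identical(a, b)
})

test_that("prediction is invariant under horizontal flip of a symmetric image", {
  m <- build_model(desk_spec(), seed = 6)
  set.seed(10)
  half <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  sym <- (half + half[, 64:1, , drop = FALSE]) / 2
  flipped <- sym[, 64:1, , drop = FALSE]
  p1 <- predict_roi(m, sym)$prediction$p_F
  p2 <- predict_roi(m, flipped)$prediction$p_F
  expect_lt(abs(p1 - p2), 1e-5)
})

test_that("training bookkeeping is exact and leakage is rejected", {
  cfg <- desk_synth_config(2, seed = 41)
  small <- function(lab, cs) generate_case(lab, cfg, cs)
  mk_set <- function(cases, ids) {
    roi_set(unlist(lapply(cases, `[[`, "images"), recursive = FALSE),
            rep(vapply(cases, `[[`, "", "label"), each = 11),
            rep(ids, each = 11))
  }
  trn <- mk_set(list(small("failure", 1), small("non_failure", 2)),
                c("c1", "c2"))
  val <- mk_set(list(small("failure", 3), small("non_failure", 4)),
                c("c3", "c4"))
  fit <- train_cnn(build_model(desk_spec(), seed = 1), trn, val,
                   desk_train_config(epochs = 2, seed = 1))
  expect_identical(nrow(fit$history), 2L)
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  expect_error(train_cnn(build_model(desk_spec(), seed = 1), trn, trn,
                         desk_train_config(1, 1)), "share case")
  empty <- roi_set(list(), character(0), character(0))
  expect_error(train_cnn(build_model(desk_spec(), seed = 1), empty, val,
                         desk_train_config(1, 1)), "empty")
})

test_that("training at zero effect size cannot beat chance", {
  fx <- fx_trained(0)
  expect_gte(fx$val_auc, 0.35)
  expect_lte(fx$val_auc, 0.65)
})
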