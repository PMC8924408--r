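test_that("3-D convolution matches a naive R implementation", {
  set.seed(11)
  for (k in c(2L, 3L)) {
    x <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
    Wm <- matrix(rnorm(k^3 * 2 * 3), k^3 * 2, 3)
    b <- rnorm(3)
    got <- pulmoseq:::.conv3d_forward(x, Wm, b, rep(k, 3L))
    expect_equal(got, naive_conv3d(x, Wm, b, k), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("convolution and pooling backward passes match finite differences", {
  set.seed(12)
  k <- 3L
  x <- array(rnorm(5 * 4 * 4 * 2), c(5, 4, 4, 2))
  Wm <- matrix(rnorm(k^3 * 2 * 2), k^3 * 2, 2)
  b <- rnorm(2)
  G <- array(rnorm(5 * 4 * 4 * 2), c(5, 4, 4, 2))
  bk <- pulmoseq:::.conv3d_backward(x, Wm, G, rep(k, 3L))
  expect_equal(bk$dx,
               fd_grad(function(z) {
                 dim(z) <- dim(x)
                 sum(pulmoseq:::.conv3d_forward(z, Wm, b, rep(k, 3L)) * G)
               }, x),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.numeric(bk$dW),
               as.numeric(fd_grad(function(z) {
                 dim(z) <- dim(Wm)
                 sum(pulmoseq:::.conv3d_forward(x, z, b, rep(k, 3L)) * G)
               }, Wm)),
               tolerance = 1e-6)

  mp <- pulmoseq:::.maxpool3d_forward(x)
  Gp <- array(rnorm(length(mp$out)), dim(mp$out))
  dxp <- pulmoseq:::.maxpool3d_backward(Gp, mp$argmax, dim(x))
  expect_equal(dxp,
               fd_grad(function(z) {
                 dim(z) <- dim(x)
                 sum(pulmoseq:::.maxpool3d_forward(z)$out * Gp)
               }, x, h = 1e-5),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("branch forward meets the architecture contract at full width", {
  net1 <- build_branch(branch_config("archi1"), seed = 1)
  net2 <- build_branch(branch_config("archi2"), seed = 2)
  p30 <- array(runif(30 * 30 * 10), c(30, 30, 10))
  p40 <- array(runif(40 * 40 * 10), c(40, 40, 10))
  f1 <- branch_forward(net1, p30)
  f2 <- branch_forward(net2, p40)
  expect_length(as.numeric(f1$features), 256)
  expect_length(as.numeric(f2$features), 256)
  expect_length(as.numeric(f1$probs), 2)
  expect_equal(sum(f1$probs), 1, tolerance = 1e-12)
  expect_equal(sum(f2$probs), 1, tolerance = 1e-12)
  expect_length(fuse(as.numeric(f1$features), as.numeric(f2$features)), 512)
})

test_that("eval-mode forward is deterministic and zero propagates", {
  cfg <- branch_config("archi1", width_scale = 1 / 16, use_batchnorm = FALSE)
  net <- build_branch(cfg, seed = 3)
  p <- array(runif(30 * 30 * 10), c(30, 30, 10))
  expect_identical(branch_forward(net, p)$features,
                   branch_forward(net, p)$features)

  net0 <- build_branch(cfg, seed = 3, zero_init = TRUE)
  z <- array(0, c(30, 30, 10))
  expect_true(all(branch_forward(net0, z)$features == 0))
})

test_that("branch forward and build reject invalid inputs", {
  cfg <- branch_config("archi1", width_scale = 1 / 16)
  net <- build_branch(cfg, seed = 1)
  bad <- array(0, c(40, 40, 10))
  expect_error(branch_forward(net, bad), "does not match")

  tampered <- cfg
  tampered$kernels <- c(5L, 5L, 2L)   # archi2's kernels on archi1
  expect_error(build_branch(tampered), "kernels")
  expect_error(branch_config("archi1", dropout = 1), "dropout")
})

test_that("fuse enforces its length contract and ordering", {
  e1 <- c(1, rep(0, 255))
  z <- rep(0, 256)
  fused <- fuse(e1, z)
  expect_equal(which(fused != 0), 1L)
  expect_false(identical(fuse(e1, z + 2), fuse(z + 2, e1)))
  expect_error(fuse(rep(0, 255), z), "length")
})

test_that("focal loss matches independent scalar evaluation", {
  # gamma = 0, alpha = 0.5 reduces to half binary cross-entropy
  expect_equal(focal_loss(0.5, 1, alpha = 0.5, gamma = 0),
               -0.5 * log(0.5), tolerance = 1e-12)
  # term-by-term oracle for alpha=0.25, gamma=2, y=(1,0), p=(0.9,0.2)
  oracle <- -(0.25 * (1 - 0.9)^2 * log(0.9) +
                0.75 * 0.2^2 * log(1 - 0.2)) / 2
  expect_equal(focal_loss(c(0.9, 0.2), c(1, 0), alpha = 0.25, gamma = 2),
               oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.003479, tolerance = 1e-4)
  # perfect-prediction limit
  eps <- 1e-7
  expect_lt(focal_loss(c(1 - eps, eps), c(1, 0), alpha = 0.25, gamma = 2),
            1e-6)
  expect_error(focal_loss(c(0.5, 0.5), 1), "length")
})

test_that("focal loss with gamma 0 equals alpha-weighted cross-entropy", {
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(1:30, 1)
    p <- runif(m, 0.01, 0.99)
    y <- rbinom(m, 1, 0.5)
    a <- runif(1)
    ref <- -mean(a * y * log(p) + (1 - a) * (1 - y) * log(1 - p))
    expect_equal(focal_loss(p, y, alpha = a, gamma = 0), ref,
                 tolerance = 1e-12)
  }
})

test_that("focal loss is monotone in p and its gradient matches differences", {
  grid <- seq(0.02, 0.98, by = 0.02)
  l1 <- vapply(grid, function(p) focal_loss(p, 1), numeric(1))
  l0 <- vapply(grid, function(p) focal_loss(p, 0), numeric(1))
  expect_true(all(diff(l1) < 0))
  expect_true(all(diff(l0) > 0))

  set.seed(22)
  p <- runif(12, 0.05, 0.95)
  y <- rbinom(12, 1, 0.5)
  ga <- focal_loss_grad(p, y, alpha = 0.3, gamma = 1.7)
  gn <- fd_grad(function(z) focal_loss(z, y, alpha = 0.3, gamma = 1.7), p)
  expect_equal(ga, gn, tolerance = 1e-6)
})

test_that("a short training run on a separable toy problem reduces the loss", {
  set.seed(30)
  cfg <- branch_config("archi1", width_scale = 1 / 32, dropout = 0,
                       use_batchnorm = FALSE, maxnorm = Inf)
  net <- build_branch(cfg, seed = 5)
  mk <- function(on) {
    p <- array(0, c(30, 30, 10))
    if (on) p[13:18, 13:18, 4:7] <- 1
    p + array(runif(length(p), 0, 0.05), dim(p))
  }
  patches <- c(lapply(1:8, function(i) mk(TRUE)),
               lapply(1:8, function(i) mk(FALSE)))
  labels <- rep(c(1, 0), each = 8)
  eval_loss <- function(nn) {
    probs <- vapply(patches, function(pp) {
      branch_forward(nn, pp)$probs[2, 1]
    }, numeric(1))
    focal_loss(probs, labels)
  }
  before <- eval_loss(net)
  trained <- train_branch(net, patches, labels, epochs = 2, lr = 1e-3,
                          batch_size = 8, seed = 6)
  expect_lt(eval_loss(trained), before)
  expect_length(trained$history, 2)
})
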