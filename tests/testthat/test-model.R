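test_that("single-step attention collapses to the identity", {
  H <- matrix(c(0.3, -1.2, 0.5, 2), 1, 4)
  a <- ptwsa(H, P = matrix(0, 1, 4), diag(4), diag(4), diag(4), w_time = 1)
  expect_equal(a$weights, matrix(1, 1, 1))
  expect_equal(a$output, H)
})

test_that("PTW-SA with P = 0 and unit time weights equals textbook attention", {
  set.seed(12)
  t <- 5; d <- 8
  H <- matrix(rnorm(t * d), t, d)
  Wq <- matrix(rnorm(d * d, sd = 0.5), d, d)
  Wk <- matrix(rnorm(d * d, sd = 0.5), d, d)
  Wv <- matrix(rnorm(d * d, sd = 0.5), d, d)
  got <- ptwsa(H, P = matrix(0, t, d), Wq, Wk, Wv, w_time = rep(1, t))
  oracle <- brute_force_attention(H, Wq, Wk, Wv, scale = sqrt(d))
  expect_lt(max(abs(got$output - oracle$output)), 1e-6)
  expect_lt(max(abs(got$weights - oracle$weights)), 1e-6)
})

test_that("attention rows always sum to one", {
  set.seed(13)
  for (i in 1:5) {
    t <- sample(3:10, 1); d <- sample(2:8, 1)
    a <- ptwsa(matrix(rnorm(t * d), t, d), matrix(rnorm(t * d, sd = 0.1), t, d),
               matrix(rnorm(d * d), d, d), matrix(rnorm(d * d), d, d),
               matrix(rnorm(d * d), d, d), w_time = runif(t, 0.5, 2))
    expect_equal(rowSums(a$weights), rep(1, t), tolerance = 1e-6)
  }
})

test_that("raising one time weight concentrates attention on that key", {
  set.seed(14)
  t <- 6; d <- 4
  H <- matrix(rnorm(t * d), t, d)
  # under identity projections scores_ij = w_j <H'_i, H'_j>; a positive
  # gram matrix guarantees monotone concentration as w_j grows
  j <- 3
  Hpos <- matrix(abs(rnorm(t * d)) + 0.2, t, d)
  mass_pos <- vapply(c(1, 3, 9), function(f) {
    wt <- rep(1, t); wt[j] <- f
    a <- ptwsa(Hpos, matrix(0, t, d), diag(d), diag(d), diag(d), wt)
    mean(a$weights[, j])
  }, numeric(1))
  expect_true(all(diff(mass_pos) > 0))
})

test_that("attention scale modes differ but both normalize rows", {
  set.seed(15)
  t <- 4; d <- 9
  H <- matrix(rnorm(t * d), t, d)
  P <- matrix(rnorm(t * d, sd = 0.1), t, d)
  W <- matrix(rnorm(d * d), d, d)
  a1 <- ptwsa(H, P, W, W, W, rep(1, t), scale = "sqrt_d")
  a2 <- ptwsa(H, P, W, W, W, rep(1, t), scale = "d")
  expect_false(isTRUE(all.equal(a1$weights, a2$weights)))
  expect_equal(rowSums(a2$weights), rep(1, t), tolerance = 1e-6)
})

test_that("CBE output length equals input length across random configs", {
  set.seed(16)
  for (i in 1:5) {
    tl <- sample(8:24, 1)
    nl <- sample(1:2, 1)
    ch <- sample(2:6, nl, replace = TRUE)
    ks <- sample(c(1, 3, 5), nl, replace = TRUE)
    cfg <- claptnet_config(seq_len = tl, cbe_channels = ch,
                           cbe_kernel_sizes = ks, lstm_hidden = 4, dropout = 0)
    model <- claptnet_init(cfg)
    x <- matrix(rnorm(3 * tl), 3, tl)
    out <- cbe_forward(model, x, training = TRUE)
    expect_equal(dim(out), c(3L, tl, tail(ch, 1)))
    expect_true(all(is.finite(out)))
  }
  expect_error(claptnet_config(cbe_kernel_sizes = c(4L, 5L),
                               cbe_channels = c(4L, 4L)),
               "odd", class = "farrowcast_config_error")
})

test_that("identity-configured CBE approximates an ELU of its input", {
  cfg <- claptnet_config(seq_len = 10, cbe_channels = 1L, cbe_kernel_sizes = 1L,
                         lstm_hidden = 4, dropout = 0)
  model <- claptnet_init(cfg)
  model$params$conv[[1]]$W[1, 1, 1] <- 1
  model$params$conv[[1]]$b <- 0
  # eval mode with fresh buffers (mean 0, var 1) makes BN near-identity
  x <- matrix(seq(-2, 2.5, by = 0.5), 1, 10)
  out <- cbe_forward(model, x, training = FALSE)
  elu <- ifelse(x > 0, x, exp(x) - 1)
  expect_equal(as.numeric(out), as.numeric(elu), tolerance = 1e-3)
  # zero input maps to a constant sequence (ELU of the BN-shifted bias)
  z <- cbe_forward(model, matrix(0, 1, 10), training = FALSE)
  expect_equal(as.numeric(z), rep(as.numeric(z)[1], 10))
})

test_that("LDE is deterministic in eval mode and zero for zero weights", {
  cfg <- tiny_claptnet_config()
  model <- claptnet_init(cfg)
  feats <- array(rnorm(2 * cfg$seq_len * 4), c(2, cfg$seq_len, 4))
  h1 <- lde_forward(model, feats, training = FALSE)
  h2 <- lde_forward(model, feats, training = FALSE)
  expect_identical(h1, h2)

  zero_model <- model
  zero_model$params$lstm[[1]]$Wx[] <- 0
  zero_model$params$lstm[[1]]$Wh[] <- 0
  zero_model$params$lstm[[1]]$b[] <- 0
  expect_true(all(lde_forward(zero_model, feats) == 0))
})

test_that("prediction reacts to the most recent window values", {
  cfg <- tiny_claptnet_config(seed = 4)
  model <- claptnet_init(cfg)
  w <- rnorm(cfg$seq_len)
  base <- claptnet_forward(model, w)
  bumped_last <- w; bumped_last[cfg$seq_len] <- bumped_last[cfg$seq_len] + 1
  bumped_first <- w; bumped_first[1] <- bumped_first[1] + 1
  expect_false(isTRUE(all.equal(claptnet_forward(model, bumped_last), base)))
  expect_false(isTRUE(all.equal(claptnet_forward(model, bumped_first), base)))
})

test_that("forward passes are deterministic and batch-consistent", {
  cfg <- tiny_claptnet_config(seed = 9)
  model <- claptnet_init(cfg)
  w <- rnorm(cfg$seq_len)
  batch <- matrix(rep(w, 5), nrow = 5, byrow = TRUE)
  preds <- claptnet_forward(model, batch)
  expect_equal(preds, rep(preds[1], 5), tolerance = 1e-12)
  expect_identical(claptnet_forward(model, w), claptnet_forward(model, w))
  expect_error(claptnet_forward(model, rnorm(cfg$seq_len + 1)), "seq_len")
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- claptnet_config(seq_len = 6, cbe_channels = c(3L, 4L),
                         cbe_kernel_sizes = c(3L, 3L), lstm_hidden = 4,
                         lstm_layers = 2, dropout = 0, seed = 3)
  model <- claptnet_init(cfg)
  set.seed(42)
  x <- matrix(rnorm(3 * 6), 3, 6)
  y <- rnorm(3)
  fwd <- farrowcast:::claptnet_forward_pass
  bwd <- farrowcast:::claptnet_backward_pass
  flat_f <- farrowcast:::flatten_params
  assign_f <- farrowcast:::assign_flat

  loss_of <- function(params) {
    fw <- fwd(x, params, model$buffers, cfg, training = TRUE)
    mean((fw$yhat - y)^2)
  }
  fw <- fwd(x, model$params, model$buffers, cfg, training = TRUE)
  grads <- bwd(2 * (fw$yhat - y) / 3, model$params, cfg, fw$cache)
  gf <- flat_f(grads)
  pf <- flat_f(model$params)
  expect_identical(names(gf), names(pf))

  set.seed(7)
  eps <- 1e-5
  for (nm in names(pf)) {
    for (i in sample(length(pf[[nm]]), min(3, length(pf[[nm]])))) {
      pp <- pf; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- pf; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(assign_f(model$params, pp)) -
                loss_of(assign_f(model$params, pm))) / (2 * eps)
      rel <- abs(num - gf[[nm]][i]) / max(1e-6, abs(num) + abs(gf[[nm]][i]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("training runs, is seeded-reproducible, and reduces the loss", {
  set.seed(20)
  n <- 120
  t <- 12
  # learnable task: the label is the mean of the window plus noise
  X <- matrix(rnorm(n * t, mean = 10, sd = 3), n, t)
  windows <- tibble::tibble(
    sow_id = "s1", start_index = 1, end_index = t,
    label = rowMeans(X) * 10,
    window = lapply(seq_len(n), function(i) X[i, ])
  )
  cfg <- tiny_claptnet_config(epochs = 12L, seed = 5)
  m1 <- claptnet_fit(claptnet_init(cfg), windows)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])

  m2 <- claptnet_fit(claptnet_init(cfg), windows)
  expect_identical(m1$params, m2$params)

  # one epoch on ten samples runs with a finite loss
  small <- claptnet_fit(claptnet_init(tiny_claptnet_config(epochs = 1L)),
                        windows[1:10, ])
  expect_equal(nrow(small$history), 1L)
  expect_true(is.finite(small$history$train_loss))

  expect_error(claptnet_fit(claptnet_init(cfg), windows[0, ]), "empty")
})

test_that("checkpoints round-trip a trained model", {
  cfg <- tiny_claptnet_config(epochs = 2L)
  windows <- make_windows(simulate_cohort(tiny_sim_config(n_sows = 1)),
                          w = cfg$seq_len, step = 24)
  model <- claptnet_fit(claptnet_init(cfg), windows)
  path <- withr::local_tempfile(fileext = ".rds")
  save_claptnet(model, path)
  back <- load_claptnet(path)
  expect_equal(predict(back, windows)$prediction,
               predict(model, windows)$prediction)
})

test_that("tidy and glance summarize the fitted model", {
  model <- claptnet_init(tiny_claptnet_config())
  td <- tidy(model)
  expect_true(all(c("term", "block", "n_params", "l2_norm") %in% names(td)))
  expect_setequal(unique(td$block), c("conv", "lstm", "attn", "head"))
  expect_equal(sum(td$n_params), farrowcast:::claptnet_n_params(model))
  gl <- glance(model)
  expect_equal(gl$n_params, sum(td$n_params))
  expect_equal(gl$epochs_trained, 0L)
})
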