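test_that("self-attention reduces to hand softmax arithmetic", {
  # identity Q/K/V maps on a 2-feature hidden vector
  att <- list(W_q = diag(2), W_k = diag(2), W_v = diag(2),
              b_q = c(0, 0), b_k = c(0, 0), b_v = c(0, 0), alpha = 1)
  h <- matrix(c(0.3, -1.2, 2.0, 0.5), 2, 2, byrow = TRUE)
  out <- selfAttention(h, att)
  for (b in 1:2) {
    hb <- h[b, ]
    S <- outer(hb, hb)                      # q_i * k_j
    A <- exp(S) / rowSums(exp(S))
    expect_equal(unname(out[b, ]), unname(as.numeric(A %*% hb)),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(A)), c(1, 1))
  }
})

test_that("residual attention degenerates and scales as algebra says", {
  set.seed(21)
  H <- 6
  att <- list(W_q = matrix(rnorm(H * H, 0, 0.3), H, H),
              W_k = matrix(rnorm(H * H, 0, 0.3), H, H),
              W_v = matrix(rnorm(H * H, 0, 0.3), H, H),
              b_q = rnorm(H), b_k = rnorm(H), b_v = rnorm(H), alpha = 1)
  h <- matrix(rnorm(4 * H), 4, H)
  # w_v = 0, alpha = 1 -> identity
  attV0 <- att; attV0$W_v[] <- 0; attV0$b_v[] <- 0
  expect_equal(residualAttention(h, attV0), h, tolerance = 1e-12)
  # alpha = 0 -> pure attention output
  att0 <- att; att0$alpha <- 0
  expect_equal(residualAttention(h, att0), selfAttention(h, att))
  # linearity in alpha: out(2) - out(0) = 2h
  att2 <- att; att2$alpha <- 2
  expect_equal(residualAttention(h, att2) - residualAttention(h, att0),
               2 * h, tolerance = 1e-12)
})

test_that("encoder forward matches hand arithmetic and its contracts", {
  set.seed(22)
  m <- savaeModel(5, 4, 2, useAttention = FALSE)
  x <- matrix(runif(3 * 5), 3, 5)
  e <- encode(x, m)
  # hand forward, no attention
  for (b in 1:3) {
    hid <- pmax(m@encoder$W_h %*% x[b, ] + m@encoder$b_h, 0)
    expect_equal(unname(e$mu[b, ]),
                 unname(as.numeric(m@encoder$W_mu %*% hid + m@encoder$b_mu)),
                 tolerance = 1e-12)
  }
  expect_true(all(exp(e$logVar) > 0))
  # zero parameters -> mu 0, variance 1
  z <- savaecox:::.setGenParams(m, savaecox:::.zeroLike(
    savaecox:::.getGenParams(m)))
  ez <- encode(x, z)
  expect_equal(ez$mu, matrix(0, 3, 2))
  expect_equal(exp(ez$logVar), matrix(1, 3, 2))
  # NaN parameters rejected
  bad <- m; bad@encoder$W_h[1, 1] <- NaN
  expect_error(encode(x, bad), "non-finite")
})

test_that("no-attention variant equals attention with zeroed Q/K/V", {
  set.seed(23)
  m <- savaeModel(6, 4, 2, useAttention = TRUE)
  m@attention$W_q[] <- 0; m@attention$W_k[] <- 0; m@attention$W_v[] <- 0
  m@attention$b_q[] <- 0; m@attention$b_k[] <- 0; m@attention$b_v[] <- 0
  m@attention$alpha <- 1
  off <- m; off@useAttention <- FALSE
  x <- matrix(runif(5 * 6), 5, 6)
  expect_equal(encode(x, m), encode(x, off), tolerance = 1e-12)
})

test_that("reparameterization has the stated moments and edge cases", {
  mu <- matrix(c(1, -2), 1, 2)
  lv <- matrix(c(0.5, -1), 1, 2)
  expect_equal(reparameterize(mu, lv, matrix(0, 1, 2)), mu)
  # sigma = 0 -> z = mu for any zeta
  expect_equal(reparameterize(mu, matrix(-Inf, 1, 2), matrix(5, 1, 2)), mu)
  # paper-printed composition selectable
  z <- matrix(1, 1, 2)
  expect_equal(reparameterize(mu, lv, z, form = "paper"),
               mu * 1 + exp(lv / 2))
  # Monte-Carlo moments within 4 SE at 1e5 draws
  set.seed(24)
  n <- 1e5
  zeta <- matrix(rnorm(n), n, 1)
  zz <- reparameterize(matrix(0.7, n, 1), matrix(log(2.3), n, 1), zeta)
  seMean <- sqrt(2.3 / n)
  expect_lt(abs(mean(zz) - 0.7), 4 * seMean)
  seVar <- 2.3 * sqrt(2 / (n - 1))
  expect_lt(abs(var(zz) - 2.3), 4 * seVar)
})

test_that("decoder is a single affine map", {
  set.seed(25)
  m <- savaeModel(7, 4, 3)
  z1 <- matrix(rnorm(2 * 3), 2, 3)
  z2 <- matrix(rnorm(2 * 3), 2, 3)
  b <- matrix(m@decoder$b, 2, 7, byrow = TRUE)
  expect_equal(decode(matrix(0, 2, 3), m), b)
  expect_equal(decode(z1 + z2, m), decode(z1, m) + decode(z2, m) - b,
               tolerance = 1e-12)
  expect_equal(ncol(decode(z1, m)), 7L)
})

test_that("critic scores one unbounded real per sample", {
  set.seed(26)
  cr <- savaeCritic(16, nLayers = 3)
  widths <- vapply(cr@layers, function(l) nrow(l$W), integer(1))
  expect_equal(widths, c(8L, 4L, 2L))
  x <- matrix(runif(9 * 16), 9, 16)
  expect_length(discriminate(x, cr), 9L)
  z <- savaecox:::.setCriticParams(cr, savaecox:::.zeroLike(
    savaecox:::.getCriticParams(cr)))
  expect_equal(discriminate(x, z), rep(0, 9))
  expect_error(savaeCritic(4, nLayers = 4), "too small")
})

test_that("generator composition is pure and matches componentwise calls", {
  set.seed(27)
  m <- savaeModel(6, 4, 2)
  x <- matrix(runif(4 * 6), 4, 6)
  zeta <- matrix(rnorm(4 * 2), 4, 2)
  f1 <- forwardGenerator(x, m, zeta)
  f2 <- forwardGenerator(x, m, zeta)
  expect_identical(f1, f2)
  e <- encode(x, m)
  z <- reparameterize(e$mu, e$logVar, zeta)
  expect_equal(f1$xRec, decode(z, m))
  f0 <- forwardGenerator(x, m, matrix(0, 4, 2))
  expect_equal(f0$xRec, decode(e$mu, m))
})

test_that("hazard is the linear latent-mean score", {
  set.seed(28)
  m <- savaeModel(6, 4, 3)
  x <- matrix(runif(5 * 6), 5, 6)
  expect_equal(hazardScore(x, m), rep(0, 5))  # zero head
  m@coxHead <- c(0.5, -1, 2)
  e <- encode(x, m)
  expect_equal(hazardScore(x, m),
               as.numeric(e$mu %*% c(0.5, -1, 2)), tolerance = 1e-12)
  # monotone in a positively weighted latent coordinate
  m2 <- m; m2@coxHead <- c(1, 0, 0)
  mus <- e$mu[order(e$mu[, 1]), ]
  expect_true(all(diff(mus %*% m2@coxHead) >= 0))
})

test_that("checkpoints round-trip bit-exactly", {
  set.seed(29)
  m <- savaeModel(5, 4, 2)
  f <- tempfile(fileext = ".ckpt")
  saveCheckpoint(m, f)
  expect_identical(loadCheckpoint(f), m)
})
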