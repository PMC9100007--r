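# Manually constructed critics with known input gradients: a single
# always-active layer (large positive bias keeps the pre-activation in
# the linear region over bounded inputs) composed with a unit output.
linearCritic <- function(w) {
  new("SavaeCritic",
      layers = list(list(W = matrix(w, 1, length(w)), b = 100)),
      wOut = 1, bOut = 0, leak = 0.2)
}

test_that("critic loss is the negated Wasserstein objective", {
  expect_equal(criticLoss(c(1, 1), c(1, 1), penalty = 0), 0)
  expect_equal(criticLoss(c(2, 0), c(0, 0), penalty = 0), -1)
  expect_equal(criticLoss(c(2, 0), c(0, 0), penalty = 0.5, lambdaP = 10), 4)
  # strictly increasing in lambdaP when penalty > 0
  expect_gt(criticLoss(1, 0, penalty = 0.3, lambdaP = 20),
            criticLoss(1, 0, penalty = 0.3, lambdaP = 10))
  expect_error(criticLoss(numeric(0), numeric(0)), "empty")
  expect_error(criticLoss(1:3, 1:2), "equal size")
})

test_that("gradient penalty matches analytic critics", {
  set.seed(31)
  # unit-gradient linear critic -> exactly 0
  w <- rnorm(6); w <- w / sqrt(sum(w^2))
  cr <- linearCritic(w)
  xr <- matrix(runif(8 * 6), 8, 6)
  xf <- matrix(runif(8 * 6), 8, 6)
  expect_equal(as.numeric(gradientPenalty(cr, xr, xf)), 0)
  # D(x) = 2x in one dimension -> (2 - 1)^2 = 1
  cr2 <- linearCritic(2)
  expect_equal(as.numeric(gradientPenalty(
    cr2, matrix(runif(5)), matrix(runif(5)))), 1)
  # nonnegative for arbitrary critics
  cr3 <- savaeCritic(6, nLayers = 2)
  expect_gte(as.numeric(gradientPenalty(cr3, xr, xf)), 0)
})

test_that("penalty parameter gradient matches finite differences", {
  set.seed(32)
  cr <- savaeCritic(8, nLayers = 2)
  xHat <- matrix(runif(6 * 8), 6, 8)
  gb <- savaecox:::.gradientPenaltyBackward(cr, xHat)
  p <- savaecox:::.getCriticParams(cr)
  flat <- savaecox:::.flattenParams(p)
  gflat <- savaecox:::.flattenParams(gb$grads)
  penAt <- function(v) {
    cc <- savaecox:::.setCriticParams(
      cr, savaecox:::.unflattenParams(v, p)$value)
    savaecox:::.gradientPenaltyBackward(cc, xHat)$penalty
  }
  h <- 1e-6
  idx <- sort(sample(length(flat), 40))
  num <- vapply(idx, function(k) {
    u <- flat; u[k] <- u[k] + h
    d <- flat; d[k] <- d[k] - h
    (penAt(u) - penAt(d)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - gflat[idx])), 1e-5)
})

test_that("KL divergence evaluates its closed forms", {
  expect_equal(klDivergence(matrix(0), matrix(0)), 0)
  expect_equal(klDivergence(matrix(1), matrix(0)), 1)
  expect_equal(klDivergence(matrix(0), matrix(1)), exp(1) - 2)
  expect_equal(klDivergence(matrix(1), matrix(0), half = TRUE), 0.5)
  # summed over latent dims, averaged over batch
  mu <- rbind(c(1, 0), c(0, 0))
  lv <- matrix(0, 2, 2)
  expect_equal(klDivergence(mu, lv), 0.5)
  # minimum at (mu = 0, var = 1): strictly larger on a grid around it
  grid <- expand.grid(mu = seq(-1, 1, 0.25), lv = seq(-1, 1, 0.25))
  vals <- mapply(function(m, l) klDivergence(matrix(m), matrix(l)),
                 grid$mu, grid$lv)
  expect_true(all(vals[!(grid$mu == 0 & grid$lv == 0)] > 0))
  expect_equal(min(vals), 0)
})

test_that("L1 loss is the mean absolute difference", {
  a <- matrix(runif(12), 3, 4)
  expect_equal(l1Loss(a, a), 0)
  expect_equal(l1Loss(a + 1, a), 1)
  b <- matrix(runif(12), 3, 4)
  expect_equal(l1Loss(a, b), l1Loss(b, a))
})

test_that("generator loss composes linearly in its weights", {
  expect_equal(generatorLoss(0, 0, 0), 0)
  d <- c(1, 3)
  expect_equal(generatorLoss(d, 5, 7, lossWeights(lambda1 = 0, lambda2 = 0)),
               -2)
  l1w <- function(l1, l2) generatorLoss(d, 5, 7,
    lossWeights(lambda1 = l1, lambda2 = l2))
  expect_equal(l1w(2, 3) - l1w(0, 3), 2 * 5)
  expect_equal(l1w(2, 3) - l1w(2, 0), 3 * 7)
  expect_error(lossWeights(lambda1 = -1), "nonnegative")
})

test_that("cox loss equals the brute-force Breslow likelihood", {
  expect_warning(v <- coxNegLogLik(c(1, 2), c(3, 4), c(0, 0)), "no observed")
  expect_equal(as.numeric(v), 0)
  expect_equal(coxNegLogLik(c(0, 0), c(1, 2), c(1, 1)), log(2) / 2)
  set.seed(33)
  for (rep in 1:40) {
    inst <- randomSurvInstance(sample(3:50, 1))
    expect_equal(coxNegLogLik(inst$risk, inst$time, inst$event),
                 bruteCoxNll(inst$risk, inst$time, inst$event),
                 tolerance = 1e-10)
    # location invariance
    expect_equal(coxNegLogLik(inst$risk + 7.3, inst$time, inst$event),
                 coxNegLogLik(inst$risk, inst$time, inst$event),
                 tolerance = 1e-9)
  }
})

test_that("cox loss agrees with the Newton oracle at its optimum", {
  set.seed(34)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3)
  eta <- x %*% c(1, -0.5, 0.3)
  tt <- rexp(n, 0.01 * exp(eta))
  ev <- rbinom(n, 1, 0.8)
  if (sum(ev) == 0) ev[1] <- 1
  sv <- survivalTable(paste0("s", 1:n), tt, ev)
  fit <- fitCoxNewton(x, sv)
  risk <- as.numeric(x %*% fit$beta)
  expect_equal(coxNegLogLik(risk, tt, ev),
               -fit$loglik / sum(ev), tolerance = 1e-8)
  # optimum is no worse than the generating truth
  riskTrue <- as.numeric(eta)
  expect_lte(coxNegLogLik(risk, tt, ev),
             coxNegLogLik(riskTrue, tt, ev) + 1e-10)
})

test_that("analytic cox gradient matches central differences", {
  set.seed(35)
  devs <- vapply(1:50, function(i) {
    inst <- randomSurvInstance(sample(3:20, 1))
    coxGradientCheck(inst$risk, inst$time, inst$event)
  }, numeric(1))
  expect_lt(max(devs), 1e-5)
  # zero events -> zero gradient
  expect_equal(coxLossGradient(c(1, 2), c(1, 2), c(0, 0)), c(0, 0))
  # n = 2, single event at the earlier time: closed-form softmax gradient
  r <- c(0.4, -1.1)
  g <- coxLossGradient(r, c(1, 2), c(1, 0))
  p <- exp(r) / sum(exp(r))
  expect_equal(g, c(p[1] - 1, p[2]), tolerance = 1e-12)
})

test_that("printed (no-exp) cox form is selectable", {
  r <- c(2, 1); tt <- c(1, 2); ev <- c(1, 1)
  expect_equal(coxNegLogLik(r, tt, ev, form = "printed"),
               -((2 - log(3)) + (1 - log(1))) / 2)
})
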