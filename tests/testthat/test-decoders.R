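test_that("the linear decoder solves separable and Gaussian toy problems", {
  set.seed(31)
  # two separable clouds
  x <- rbind(matrix(rnorm(100, 5), 50, 2), matrix(rnorm(100, -5), 50, 2))
  y <- rep(1:2, each = 50)
  dec <- train_linear_decoder(x, y, K = 2)
  xt <- rbind(matrix(rnorm(100, 5), 50, 2), matrix(rnorm(100, -5), 50, 2))
  expect_equal(mean(decode_linear(dec, xt)$labels == y), 1)

  # 1-D Gaussians, unit variance, means +-1: Bayes rate pnorm(1) ~ 0.841
  n <- 4000
  x1 <- matrix(c(rnorm(n, -1), rnorm(n, 1)), ncol = 1)
  y1 <- rep(1:2, each = n)
  dec1 <- train_linear_decoder(x1, y1, K = 2)
  xt1 <- matrix(c(rnorm(n, -1), rnorm(n, 1)), ncol = 1)
  fc <- mean(decode_linear(dec1, xt1)$labels == y1)
  se <- sqrt(pnorm(1) * (1 - pnorm(1)) / (2 * n))
  expect_lt(abs(fc - pnorm(1)), 3 * se + 0.005)
})

test_that("the BB optimiser reaches the same optimum as an independent solver", {
  skip_if_not_installed("nnet")
  set.seed(32)
  x <- matrix(rnorm(600), 200, 3)
  y <- 1 + (x[, 1] + 0.5 * x[, 2] + rnorm(200) > 0) + (x[, 3] > 1)
  y <- pmin(y, 3)
  dec <- train_linear_decoder(x, y, K = 3, max_iter = 3000, tol = 1e-14)
  fit <- nnet::multinom(factor(y) ~ x, trace = FALSE, maxit = 1000,
                        reltol = 1e-14)
  p_ref <- fitted(fit)
  p_bb <- decode_linear(dec, x)$prob
  expect_lt(max(abs(p_bb - p_ref)), 1e-3)
  # objective agreement within 1e-6 relative tolerance
  nll <- function(p) -mean(log(p[cbind(1:200, y)]))
  expect_lt(abs(nll(p_bb) - nll(p_ref)) / nll(p_ref), 1e-6)
})

test_that("softmax read-out normalises, ties break low, duplicates agree", {
  set.seed(33)
  x <- matrix(rnorm(40), 10, 4)
  dec <- train_linear_decoder(rbind(x, x + 5), rep(1:2, each = 10), K = 2)
  dec0 <- dec; dec0$weights[] <- 0
  out <- decode_linear(dec0, x)
  expect_true(all(abs(out$prob - 0.5) < 1e-12))
  expect_true(all(out$labels == 1L))
  out2 <- decode_linear(dec, rbind(x[1, ], x[1, ]))
  expect_equal(out2$prob[1, ], out2$prob[2, ])
  expect_true(all(abs(rowSums(decode_linear(dec, x)$prob) - 1) < 1e-12))
  expect_error(decode_linear(dec, x[, 1:2]), "feature")
})

test_that("optimal posterior matches the brute-force oracle on a toy model", {
  set.seed(34)
  pop <- make_population(N = 2, uDC = -60, uAC = 12)
  nm <- noise_model(sigma = 3)
  stim <- gratings(orientation = rep(c(45, 135), each = 2),
                   phase = rep(c(90, 270), 2), spatial_period = 3,
                   contrast = 0.5)
  cls <- rep(1:2, each = 2)
  gm <- generative_model(pop, nm, stim, cls)
  for (th in c(-75, -60, -57, -52)) {
    nl <- frnl(th, exponent = 1)
    u <- sample_membrane_potentials(gm$means[rep(1:4, 3), ], nm)
    r <- apply_frnl(u, nl)
    post <- optimal_posterior(r, gm, nl = nl)
    ref <- posterior_oracle(r, gm$means, cls, 3, nl)
    expect_equal(post, ref, tolerance = 1e-6)
    expect_equal(rowSums(post), rep(1, nrow(r)), tolerance = 1e-12)
  }
})

test_that("optimal posterior handles degenerate inputs as specified", {
  set.seed(35)
  pop <- make_population(N = 3)
  nm <- noise_model(sigma = 3)
  stim <- gratings(orientation = c(30, 150), phase = 180)
  gm <- generative_model(pop, nm, stim, 1:2)
  expect_error(optimal_posterior(matrix(1, 1, 3), gm, nl = frnl(-55, exponent = 0.9)),
               "exponent")
  # no neurons: the prior comes back
  gm0 <- generative_model(make_population(N = 1), nm, stim, 1:2)
  gm0$means <- gm0$means[, 0, drop = FALSE]
  expect_equal(optimal_posterior(matrix(0, 2, 0), gm0, nl = frnl(-55)),
               matrix(0.5, 2, 2))
  # all-zero rates with class-constant zero probability: uniform posterior
  gm_c <- gm
  gm_c$means <- matrix(-60, 2, 3)
  post <- optimal_posterior(matrix(0, 1, 3), gm_c, nl = frnl(-55))
  expect_equal(post[1, ], c(0.5, 0.5), tolerance = 1e-12)
  # deep subthreshold likelihoods renormalise instead of yielding NaN
  post2 <- optimal_posterior(matrix(c(500, 0, 0), 1, 3), gm, nl = frnl(-55))
  expect_false(any(is.nan(post2)))
  expect_equal(sum(post2), 1, tolerance = 1e-12)
})

test_that("ILC posterior interpolates between the optimal posterior and uniform", {
  set.seed(36)
  pop <- make_population(N = 2)
  nm <- noise_model(sigma = 3)
  stim <- gratings(orientation = rep(c(30, 60, 120, 150), each = 2),
                   phase = rep(c(0, 180), 4))
  cls <- rep(c(1, 1, 2, 2), each = 2)
  gm <- generative_model(pop, nm, stim, cls)
  nl <- frnl(-58)
  r <- apply_frnl(sample_membrane_potentials(gm$means, nm), nl)

  expect_equal(ilc_posterior(r, gm, sd_theta = 1e-4, nl = nl),
               optimal_posterior(r, gm, nl = nl), tolerance = 1e-6)
  flat <- ilc_posterior(r, gm, sd_theta = 1e5, nl = nl)
  expect_true(all(abs(flat - 0.5) < 1e-6))

  # intermediate width against direct summation over the orientation grid
  sd <- 20
  lev <- sort(unique(stim$orientation))
  gm_f <- gm; gm_f$class <- match(stim$orientation, lev); gm_f$K <- length(lev)
  q <- optimal_posterior(r, gm_f, nl = nl)
  mix <- matrix(0, nrow(r), length(lev))
  for (j in seq_along(lev)) {
    for (i in seq_along(lev)) {
      d <- lev[i] - lev[j]
      mix[, j] <- mix[, j] + q[, i] *
        sum(dnorm(d + 180 * (-2:2), 0, sd))
    }
  }
  agg <- cbind(rowSums(mix[, lev < 90]), rowSums(mix[, lev >= 90]))
  agg <- agg / rowSums(agg)
  expect_equal(ilc_posterior(r, gm, sd_theta = sd, nl = nl), agg,
               tolerance = 1e-10)
})

test_that("performance measures satisfy their identities", {
  K <- 10
  onehot <- diag(K)
  perf <- performance(onehot, 1:K, K = K)
  expect_equal(perf$fc, 1)
  expect_equal(perf$pfc, 1)
  expect_equal(perf$mi_bits, log2(K))

  unif <- matrix(1 / K, 20, K)
  perf_u <- performance(unif, rep(1:K, 2), K = K)
  expect_equal(perf_u$fc, 1 / K)   # argmax ties to class 1; chance on average
  expect_equal(perf_u$pfc, 1 / K)
  expect_equal(perf_u$mi_bits, 0)
  expect_equal(perf_u$chance, 0.1)

  # log(PFC) is exactly the Monte-Carlo average of log posterior mass
  set.seed(37)
  p <- matrix(rexp(50), 10, 5); p <- p / rowSums(p)
  lab <- sample(1:5, 10, replace = TRUE)
  perf_p <- performance(p, lab, K = 5)
  expect_equal(log(perf_p$pfc), mean(log(p[cbind(1:10, lab)])),
               tolerance = 1e-14)
  expect_equal(perf_p$mi_bits, log2(5) + mean(log2(p[cbind(1:10, lab)])),
               tolerance = 1e-14)

  # floored posteriors are flagged, never NaN
  pz <- matrix(c(1, 0, 0, 1), 2, 2) / 1
  perf_z <- performance(pz, c(2, 1), K = 2)
  expect_equal(perf_z$floored, 2L)
  expect_false(is.nan(perf_z$pfc))
})

test_that("the sparseness-scaled prediction has the stated fixed points", {
  expect_equal(predicted_linear_fc(0.9, 0, 0.1), 0.1)
  expect_equal(predicted_linear_fc(0.1, 0.7, 0.1), 0.1)
  expect_equal(predicted_linear_fc(0.6, 0.5, 0.1), 0.35)
})

test_that("decoding is invariant to neuron order", {
  set.seed(38)
  pop <- tiny_pop(N = 12)
  nm <- noise_model(sigma = 3)
  bank <- build_bank(pop, bank_spec(K = 3, Mtheta = 2, Mphi = 8, Mrep = 3,
                                    Mrep_test = 3), nm)
  nl <- frnl(-58)
  rtr <- apply_frnl(bank$train$u, nl); rte <- apply_frnl(bank$test$u, nl)
  perm <- sample(ncol(rtr))
  set.seed(1); d1 <- train_linear_decoder(rtr, bank$train$labels, K = 3)
  set.seed(1); d2 <- train_linear_decoder(rtr[, perm], bank$train$labels, K = 3)
  f1 <- mean(decode_linear(d1, rte)$labels == bank$test$labels)
  f2 <- mean(decode_linear(d2, rte[, perm])$labels == bank$test$labels)
  expect_equal(f1, f2)

  gm <- generative_model(pop, nm, bank$stimuli, bank$stimuli$label, nl = nl)
  gmp <- gm; gmp$means <- gm$means[, perm]
  expect_equal(optimal_posterior(rte[, perm], gmp), optimal_posterior(rte, gm),
               tolerance = 1e-10)
})
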