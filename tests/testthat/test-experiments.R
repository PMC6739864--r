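# Reduced-size versions of the parameter scans, robustness regimes, nuisance
# decoding and the heterogeneous-population experiment.

test_that("jointly scaling signal and noise leaves the normalised optimum fixed", {
  z <- seq(-0.25, 0.75, by = 0.25)
  run <- function(uAC, sigma) {
    set.seed(61)
    pop <- make_population(N = 40, uAC = uAC)
    nm <- noise_model(sigma = sigma)
    bank <- build_bank(pop, bank_spec(K = 5, Mtheta = 2, Mphi = 12, Mrep = 3,
                                      Mrep_test = 4), nm)
    threshold_sweep(pop, nm, bank, thresholds = -60 + z * uAC,
                    which = "linear")$normalised_optimum
  }
  expect_equal(run(12, 3), run(24, 6))
})

test_that("varying sigma or uAC at equal noise-to-signal gives one optimum", {
  set.seed(62)
  tab_s <- parameter_scan("sigma", values = 3, N = 40, K = 5,
                          Mtheta = 2, Mphi = 12, Mrep = 3, Mrep_test = 4,
                          thresholds = seq(-66, -51, by = 3))
  set.seed(62)
  tab_a <- parameter_scan("uAC", values = 12, N = 40, K = 5, sigma = 3,
                          Mtheta = 2, Mphi = 12, Mrep = 3, Mrep_test = 4,
                          thresholds = seq(-66, -51, by = 3))
  expect_equal(tab_s$noise_to_signal, tab_a$noise_to_signal)
  expect_lt(abs(tab_s$normalised_optimum - tab_a$normalised_optimum),
            0.25 + 1e-9)   # one grid step
})

test_that("peak performance rises with N and falls with K", {
  set.seed(63)
  tab_n <- parameter_scan("N", values = c(15, 120), K = 5,
                          Mtheta = 2, Mphi = 12, Mrep = 3, Mrep_test = 6,
                          thresholds = seq(-63, -51, by = 3))
  expect_gt(tab_n$peak_fc[2], tab_n$peak_fc[1])
  set.seed(63)
  tab_k <- parameter_scan("K", values = c(4, 12), N = 60,
                          Mtheta = 2, Mphi = 12, Mrep = 3, Mrep_test = 6,
                          thresholds = seq(-63, -51, by = 3))
  expect_gt(tab_k$peak_fc[1], tab_k$peak_fc[2])
})

test_that("robust regimes have the stated structure", {
  set.seed(64)
  z <- seq(-0.5, 1, by = 0.25)
  ru <- robust_regime(0.25, criterion = "ru", kappas = c(1, 2), z_grid = z,
                      N = 30, K = 5, Mtheta = 2, Mphi = 10, Mrep = 2,
                      Mrep_test = 3)
  expect_true(is.finite(ru$table$lo) && is.finite(ru$table$hi))
  expect_lte(ru$table$lo, ru$table$hi)

  set.seed(64)
  im <- robust_regime(0.25, criterion = "infomax", kappas = c(1, 2),
                      z_grid = z, N = 30, K = 5, Mtheta = 2, Mphi = 10,
                      Mrep = 2, Mrep_test = 3, n_eval_optimal = 200)
  expect_identical(im$table$lo, -Inf)

  # criterion at 100%: the per-kappa argmax intersection, possibly empty
  set.seed(64)
  hard <- robust_regime(0.25, criterion = "ru", level = 1, kappas = c(1, 2),
                        z_grid = z, N = 30, K = 5, Mtheta = 2, Mphi = 10,
                        Mrep = 2, Mrep_test = 3)
  width <- hard$table$hi - hard$table$lo
  expect_true(is.na(width) || width <= 0.5 + 1e-9)

  expect_error(robust_regime(0.25, kappas = c(0.5, 1)), "kappas")

  # membership interpolation
  reg <- structure(list(criterion = "ru", level = 0.9, kappas = 1,
                        table = data.frame(ratio = c(0.2, 0.4),
                                           lo = c(0, 0.2), hi = c(1, 1.2))),
                   class = "robust_regime")
  expect_true(in_regime(reg, 0.3, 0.5))
  expect_false(in_regime(reg, 0.3, 0.05))
  expect_true(in_regime(reg, 0.6, 1.2))   # constant beyond computed range
})

test_that("nuisance-feature decoding uses equal-mass classes and beats chance", {
  set.seed(65)
  qper <- function(p) qlnorm(p, 0.95, 0.55)
  pop <- make_population(N = 60, lambda = qper(runif(60)))
  sw <- decode_nuisance("spatial_period", pop, noise_model(sigma = 3),
                        K = 2, Mwithin = 4, Mori = 8, Mphi = 8,
                        Mrep = 3, Mrep_test = 6,
                        thresholds = seq(-63, -51, by = 3))
  expect_equal(nrow(sw$table), 5)
  peak <- max(sw$table$fc_linear)
  expect_gt(peak, 0.5 + 3 * sqrt(0.25 / (2 * 4 * 8 * 8 * 6)))
  # period class boundary at the lognormal median
  expect_equal(equal_mass_classes(qper, 2)$edges, exp(0.95))
})

test_that("heterogeneous populations peak near locally optimal thresholds", {
  set.seed(66)
  hx <- heterogeneous_experiment(kappas = c(1, 1.5), sigmas = c(2, 4),
                                 n_per_combo = 10, radii = c(1, 3, 6, 12, 200),
                                 n_draws = 2, K = 5, hom_N = 30,
                                 z_grid = seq(-0.25, 0.75, by = 0.25),
                                 Mtheta = 2, Mphi = 10, Mrep = 2,
                                 Mrep_test = 4)
  expect_equal(hx$samples$fc[hx$samples$distance == 0], hx$reference_fc)
  # non-positive curvature over the decaying range
  sub <- hx$samples[hx$samples$distance <= 12, ]
  quad <- coef(lm(fc ~ distance + I(distance^2), sub))
  expect_lte(quad[["I(distance^2)"]], 1e-6)
  # perturbations far beyond uAC collapse decoding towards chance
  far <- mean(hx$samples$fc[hx$samples$distance == 200])
  expect_lt(far, hx$reference_fc - 0.1)
  expect_lt(far, 0.2 + 0.1)
})

test_that("optimal thresholds generalise across stimulus statistics", {
  set.seed(67)
  pop <- make_population(N = 50)
  nm <- noise_model(sigma = 3)
  spec_ref <- bank_spec(K = 4, Mtheta = 2, Mphi = 10, Mrep = 3,
                        Mrep_test = 6, spatial_period = "variable")
  spec_shift <- bank_spec(K = 4, Mtheta = 2, Mphi = 10, Mrep = 3,
                          Mrep_test = 6, spatial_period = "variable",
                          period_meanlog = 1.25)
  bank_ref <- build_bank(pop, spec_ref, nm)
  bank_shift <- build_bank(pop, spec_shift, nm)
  ths <- seq(-63, -51, by = 3)
  fc_cross <- fc_ref <- numeric(length(ths))
  for (i in seq_along(ths)) {
    nl <- frnl(ths[i])
    dec <- train_linear_decoder(apply_frnl(bank_ref$train$u, nl),
                                bank_ref$train$labels, K = 4)
    fc_ref[i] <- mean(decode_linear(dec, apply_frnl(bank_ref$test$u, nl))$labels ==
                        bank_ref$test$labels)
    fc_cross[i] <- mean(decode_linear(dec, apply_frnl(bank_shift$test$u, nl))$labels ==
                          bank_shift$test$labels)
  }
  # shifted-statistics performance at the reference-optimal threshold is
  # within 2 SE of the best over thresholds of the shifted evaluation
  n_test <- nrow(bank_shift$test$u)
  best <- max(fc_cross)
  at_ref_opt <- fc_cross[which.max(fc_ref)]
  expect_gte(at_ref_opt, best - 2 * sqrt(best * (1 - best) / n_test) - 1e-9)
})

test_that("retina and LGN responses stay entangled under phase nuisance", {
  for (kind in c("retina", "lgn")) {
    set.seed(68)
    pop <- make_population(N = 60, kind = kind)
    nm <- noise_model(sigma = 3)
    bank <- build_bank(pop, bank_spec(K = 5, Mtheta = 2, Mphi = 12, Mrep = 3,
                                      Mrep_test = 8), nm)
    sw <- threshold_sweep(pop, nm, bank, thresholds = seq(-69, -48, by = 3),
                          which = "linear")
    n_test <- nrow(bank$test$u)
    expect_true(all(sw$table$fc_linear <= 0.2 + 2 * sqrt(0.2 * 0.8 / n_test)))

    # without nuisance the same population supports decoding
    set.seed(68)
    bank_f <- build_bank(pop, bank_spec(K = 5, Mtheta = 2, Mphi = 2,
                                        Mrep = 10, Mrep_test = 10,
                                        phase = "fixed"), nm)
    dec <- train_linear_decoder(bank_f$train$u, bank_f$train$labels, K = 5)
    fc <- mean(decode_linear(dec, bank_f$test$u)$labels == bank_f$test$labels)
    expect_gt(fc, 0.5)
  }
})

test_that("the hypercolumn variant keeps an interior optimum", {
  set.seed(69)
  pop <- make_population(N = 50, R = 1.5)
  nm <- noise_model(sigma = 3)
  bank <- build_bank(pop, bank_spec(K = 5, Mtheta = 2, Mphi = 12, Mrep = 3,
                                    Mrep_test = 6), nm)
  sw <- threshold_sweep(pop, nm, bank, thresholds = seq(-72, -45, by = 3),
                        which = "linear")
  expect_gt(max(sw$table$fc_linear),
            sw$table$fc_linear[1] + 0.05)           # interior peak
  expect_gt(max(sw$table$fc_linear), 0.2 + 0.1)     # well above chance
  expect_true(sw$normalised_optimum > -0.5 && sw$normalised_optimum < 1)
})
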