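test_that("Kozak similarity is the KL divergence to the PWM", {
  ctx <- "AAAAAAATGCCC"
  uni <- matrix(0.25, 9, 4)
  expect_equal(kozak_similarity(ctx, uni), 9 * log(4))
  # a column with probability 1 at the observed base contributes 0
  pwm <- uni
  pwm[1, ] <- c(1, 0, 0, 0)  # position -6, observed A
  expect_equal(kozak_similarity(ctx, pwm), 8 * log(4))
  # prob 0.25 at observed base contributes ln 4
  pwm2 <- uni
  pwm2[1, ] <- c(0.25, 0.5, 0.125, 0.125)
  expect_equal(kozak_similarity(ctx, pwm2), 9 * log(4))
  # zero probability -> Inf
  pwm3 <- uni
  pwm3[1, ] <- c(0, 0.5, 0.25, 0.25)
  expect_equal(kozak_similarity(ctx, pwm3), Inf)
})

test_that("the sigmoid Kozak feature follows its closed form", {
  expect_equal(kozak_feature("AAAAAAATGCCC", rep(0, 36)), 0.5)
  # x.g = ln 3 -> f = 1/(1 + 3) = 0.25
  x <- rep(0, 36)
  x[1] <- log(3)  # position -6, base A; context has A there
  expect_equal(kozak_feature("AAAAAAATGCCC", x), 0.25)
  # large negative x.g -> f -> 1
  x[1] <- -50
  expect_equal(kozak_feature("AAAAAAATGCCC", x), 1)
  # ambiguous base errors
  expect_error(kozak_feature("AANAAAATGCCC", rep(0, 36)), "ambiguous")
  # no ATG errors
  expect_error(kozak_feature("AAAAAACTGCCC", rep(0, 36)), "ATG")
})

test_that("PWM construction shifts, normalises, and is shift-invariant", {
  x <- rep(0, 36)
  x[1:4] <- c(-1, 0, 1, 2)
  pwm <- motif_to_pwm(x)
  expect_equal(unname(pwm[1, ]), c(0, 1/6, 1/3, 1/2))
  # equal weights -> uniform row; all rows sum to 1
  expect_equal(unname(pwm[2, ]), rep(0.25, 4))
  expect_equal(unname(rowSums(pwm)), rep(1, 9))
  # invariant to adding a constant to all 4 weights of a position
  x2 <- x
  x2[1:4] <- x2[1:4] + 7.3
  expect_equal(motif_to_pwm(x2), pwm)
})

test_that("elastic-net coordinate descent matches independent solvers", {
  withr::with_seed(31, {
    n <- 10; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% c(1, -2, 0) + rnorm(n, 0, 0.5)
  })
  y <- as.numeric(y)
  for (l1 in c(0.1, 1)) {
    for (l2 in c(0.1, 1)) {
      cd <- riboflow:::elastic_net_cd(X, y, l1, l2)
      # independent oracle: numeric minimisation of the stated objective
      f <- function(par) {
        b0 <- par[1]; w <- par[-1]
        sum((y - b0 - X %*% w)^2) + l1 * sum(abs(w)) + l2 * sum(w^2)
      }
      opt <- optim(rep(0, p + 1), f, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14))
      expect_lte(f(c(cd$intercept, cd$w)), opt$value + 1e-5)
      expect_equal(cd$w, opt$par[-1], tolerance = 1e-3)
    }
  }
  # cross-check against glmnet's independent coordinate descent.
  # glmnet solves (1/2n) RSS + lambda (alpha |w|_1 + (1-alpha)/2 |w|_2^2)
  # after standardising y internally, which rescales the ridge (but not the
  # lasso) term by the population sd of y; calibrated on pure-lasso and
  # pure-ridge problems: lambda*alpha = l1/(2n), lambda*(1-alpha) = l2*sy/n.
  skip_if_not_installed("glmnet")
  n <- nrow(X)
  sy <- sd(y) * sqrt((n - 1) / n)
  for (l1 in c(0.1, 0.5)) {
    for (l2 in c(0.1, 1)) {
      cd <- riboflow:::elastic_net_cd(X, y, l1, l2)
      la <- l1 / (2 * n); lb <- l2 * sy / n
      g <- glmnet::glmnet(X, y, alpha = la / (la + lb), lambda = la + lb,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-16)
      expect_equal(cd$w, as.numeric(g$beta), tolerance = 1e-5)
    }
  }
})

test_that("TE regression recovers a planted motif and beats a wrong one", {
  sim <- simulate_te_dataset(n_genes = 700, seed = 5)
  fit <- fit_te_regression(sim$features, sim$te, sim$contexts,
                           n_splits = 3, seed = 2)
  # determinism
  fit2 <- fit_te_regression(sim$features, sim$te, sim$contexts,
                            n_splits = 3, seed = 2)
  expect_identical(fit$x, fit2$x)
  expect_identical(fit$splits, fit2$splits)

  # planted dominant bases recovered at >= 7/9 positions
  planted_dom <- apply(motif_to_pwm(sim$truth$planted_x), 1, which.max)
  learned_dom <- apply(fit$pwm, 1, which.max)
  expect_gte(sum(learned_dom == planted_dom), 7)

  # learned motif beats a wrong fixed motif; truth is at least as good
  wrong <- evaluate_fixed_motif(fit, consensus_weights("GGGGGGATGGGG", 2))
  expect_lt(fit$test_error, wrong$test_error)
  truth_fixed <- evaluate_fixed_motif(fit, sim$truth$planted_x)
  expect_lt(truth_fixed$test_error, wrong$test_error)

  # fixing the motif at the learned (split-averaged) x reproduces the
  # learned error closely; exact equality is not expected because each
  # split learns its own motif while the average is a single denoised one
  self_fixed <- evaluate_fixed_motif(fit, fit$x)
  expect_equal(self_fixed$test_error, fit$test_error, tolerance = 0.2)
  expect_lt(self_fixed$test_error, wrong$test_error)

  # null model error is near the variance of standardised TE
  expect_equal(fit$null_error, 1, tolerance = 0.15)

  # tidiers
  expect_true("kozak" %in% tidy(fit)$term)
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("extreme L1 penalty shrinks weights to zero and error to null", {
  sim <- simulate_te_dataset(n_genes = 300, effect_size = 0.5, seed = 6)
  fit <- fit_te_regression(sim$features, sim$te, sim$contexts,
                           lambda_grid = 1e6, n_splits = 8, seed = 3)
  expect_equal(unname(fit$w), rep(0, length(fit$w)))
  expect_equal(fit$test_error, 1, tolerance = 0.25)
})

test_that("MEME export writes a parseable motif", {
  pwm <- motif_to_pwm(consensus_weights("AATAAAATGTCC"))
  p <- file.path(withr::local_tempdir(), "kozak.meme")
  write_meme_pwm(pwm, p)
  lines <- readLines(p)
  expect_true(any(grepl("^MOTIF", lines)))
  mat <- read.table(text = lines[(which(grepl("letter-probability", lines)) + 1):length(lines)])
  expect_equal(unname(as.matrix(mat)), unname(pwm), tolerance = 1e-6)
})
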