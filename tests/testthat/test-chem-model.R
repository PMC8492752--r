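test_that("variable assembly applies the strict >1% OTU threshold", {
  # OTU_hi peaks above 1%, OTU_edge peaks at exactly 1.0%: excluded
  counts <- cbind(OTU_hi = c(20, 200), OTU_edge = c(10, 10),
                  OTU_rest = c(970, 790))
  rownames(counts) <- c("s1", "s2")
  chem <- data.frame(sample = c("s1", "s2"), depth_cm = c(4, 8),
                     TOC_pct = c(8, 9), d13C_TOC = c(-28, -28.2),
                     CH4_uM = c(10, 40), DIC_uM = c(500, 900),
                     S_pct = c(0.4, 0.5), TOC_TS = c(20, 18))
  vm <- assemble_variables(counts, chem, guilds = NULL, mag_map = NULL)
  keep <- colnames(vm$X)[vm$provenance == "otu_gt1pct"]
  expect_true("OTU_hi" %in% keep)
  expect_false("OTU_edge" %in% keep)

  # an empty biotic configuration leaves the six abiotic columns
  vm0 <- assemble_variables(counts, chem, guilds = NULL, mag_map = NULL,
                            otu_threshold_pct = Inf)
  expect_identical(colnames(vm0$X),
                   c("depth", "TOC", "d13C_TOC", "DIC", "S", "TOC_TS"))

  bad_chem <- chem
  bad_chem$sample <- c("s1", "zz")
  expect_error(assemble_variables(counts, bad_chem, guilds = NULL),
               "zz")
})

test_that("duplicate explanatory columns are collapsed with a warning", {
  cfg <- small_config(seed = 3)
  otu <- generate_otu_table(cfg)
  chem <- generate_core_chemistry(cfg)
  expect_warning(vm <- assemble_variables(otu, chem), "duplicate")
  expect_false(anyDuplicated(t(vm$X)) > 0)
  expect_identical(length(vm$provenance), ncol(vm$X))
  expect_identical(vm$samples, chem$sample)
})

test_that("PLSR nails a single-predictor response and its VIP geometry", {
  set.seed(1)
  # orthogonal centered columns: one NIPALS component isolates the signal
  X <- qr.Q(qr(cbind(1, matrix(rnorm(20 * 4), 20, 4))))[, 2:5]
  colnames(X) <- paste0("v", 1:4)
  y <- 3 * X[, 2] + 1
  fit <- fit_plsr(X, y, ncomp = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_identical(names(which.max(fit$vip)), "v2")
  # in a correlated design the auto-selected fit still reaches r2 = 1
  Xc <- matrix(rnorm(40), ncol = 4, dimnames = list(NULL, paste0("w", 1:4)))
  fc <- fit_plsr(Xc, 2 * Xc[, 1] - Xc[, 4])
  expect_equal(fc$r2, 1, tolerance = 1e-6)

  # orthonormal centered design, one informative column: VIP_j = sqrt(p)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(8 * 4), 8, 4))))[, 2:5]
  colnames(Q) <- paste0("q", 1:4)
  yq <- Q[, 3]
  fq <- fit_plsr(Q, yq, ncomp = 1, scale = FALSE)
  expect_equal(unname(fq$vip["q3"]), 2, tolerance = 1e-8)
  expect_equal(unname(fq$vip[c("q1", "q2", "q4")]), rep(0, 3),
               tolerance = 1e-8)
})

test_that("VIP normalization sum(VIP^2) = p holds for arbitrary fits", {
  for (s in 1:5) {
    set.seed(s)
    n <- 20
    p <- sample(3:12, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- rnorm(n) + X %*% rnorm(p, sd = 0.5)
    fit <- fit_plsr(X, y, ncomp = sample(1:3, 1))
    expect_equal(sum(fit$vip^2), length(fit$variables), tolerance = 1e-9)
    # identical copies of one column share VIP 1 each
  }
  Xc <- matrix(rnorm(15), ncol = 1)[, rep(1, 3)]
  colnames(Xc) <- paste0("c", 1:3)
  yc <- Xc[, 1] + rnorm(15, sd = 0.1)
  fc <- fit_plsr(Xc, yc, ncomp = 1)
  expect_equal(unname(fc$vip), rep(1, 3), tolerance = 1e-9)
})

test_that("full-rank PLSR reproduces ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(60), ncol = 3,
              dimnames = list(NULL, paste0("x", 1:3)))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(20, sd = 0.3)
  fit <- fit_plsr(X, y, ncomp = 3)
  ols <- lm(y ~ X)
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[-1]), unname(coef(ols)[-1]),
               tolerance = 1e-8)
})

test_that("PLSR is invariant to positive column rescaling when autoscaled", {
  set.seed(4)
  X <- matrix(rnorm(80), ncol = 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1] - X[, 3] + rnorm(20, sd = 0.2)
  f1 <- fit_plsr(X, y, ncomp = 2)
  X2 <- X
  X2[, 3] <- X2[, 3] * 1000
  f2 <- fit_plsr(X2, y, ncomp = 2)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-10)
  expect_equal(f2$vip, f1$vip, tolerance = 1e-10)
})

test_that("PLSR agrees with an independent NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(25 * 6), 25, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  y <- drop(X %*% c(2, 0, 1, 0, 0, -1)) + rnorm(25, sd = 0.5)
  fit <- fit_plsr(X, y, ncomp = 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  pred <- predict(mo, X)$predict[, 1, 3]
  expect_equal(fit$fitted, unname(pred), tolerance = 1e-6)
})

test_that("zero-variance predictors are dropped with a warning", {
  set.seed(7)
  X <- cbind(flat = rep(2, 12), ok = rnorm(12))
  y <- X[, "ok"] + rnorm(12, sd = 0.1)
  expect_warning(fit <- fit_plsr(X, y, ncomp = 1), "flat")
  expect_identical(fit$variables, "ok")
  expect_error(fit_plsr(X[1:4, ], y[1:4]), "5 samples")
})

test_that("MLR reports exact fits, the adjusted-r2 formula, and collinearity", {
  x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "x"))
  y <- drop(2 * x + 1)
  fit <- fit_mlr(x, y)
  expect_equal(fit$r2, 1)
  expect_equal(fit$adj_r2, 1)

  # n = 21, p = 6, r2 = 0.672 -> adjusted 1 - 0.328 * 20 / 14
  expect_equal(1 - (1 - 0.672) * 20 / 14, 0.5314286, tolerance = 1e-6)
  set.seed(8)
  n <- 21
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  yy <- X[, 1] + rnorm(n)
  m <- fit_mlr(X, yy)
  expect_equal(m$adj_r2, 1 - (1 - m$r2) * (n - 1) / (n - 6 - 1),
               tolerance = 1e-12)
  expect_lte(m$adj_r2, m$r2)

  Xc <- cbind(X, dup = X[, 1])
  expect_error(fit_mlr(Xc, yy), "dup")
  expect_error(fit_mlr(X[1:6, ], yy[1:6]), "n > p")
})

test_that("pure-noise designs average near zero adjusted r2", {
  set.seed(9)
  adj <- replicate(300, {
    X <- matrix(rnorm(21 * 6), 21, 6, dimnames = list(NULL, paste0("x", 1:6)))
    fit_mlr(X, rnorm(21))$adj_r2
  })
  expect_lt(abs(mean(adj)), 0.05)
})

test_that("suite comparison is stable and resists noise-column inflation", {
  cfg <- small_config(seed = 5)
  otu <- generate_otu_table(cfg)
  chem <- generate_core_chemistry(cfg)
  vm <- suppressWarnings(assemble_variables(otu, chem))
  cmp <- suppressWarnings(compare_models(
    vm, suites = list(abiotic = "abiotic", again = "abiotic")))
  expect_equal(cmp$plsr_r2[1], cmp$plsr_r2[2], tolerance = 1e-12)
  expect_equal(cmp$mlr_adj_r2[1], cmp$mlr_adj_r2[2], tolerance = 1e-12)

  # appending pure-noise columns must not lift the cross-validated fit
  set.seed(10)
  ab <- vm$X[, vm$provenance == "abiotic"]
  noise <- matrix(rnorm(nrow(ab) * 30), nrow(ab), 30,
                  dimnames = list(NULL, paste0("junk", 1:30)))
  f_ab <- fit_plsr(ab, vm$y)
  f_no <- fit_plsr(cbind(ab, noise), vm$y)
  expect_lt(f_no$q2 - f_ab$q2, 0.1)

  expect_warning(
    cmp2 <- suppressMessages(compare_models(
      vm, suites = list(abiotic = "abiotic", empty = "no_such_tag"))),
    "empty")
  expect_identical(nrow(cmp2), 1L)
})
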