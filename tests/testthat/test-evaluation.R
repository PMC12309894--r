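test_that("log-linear tensor fit recovers a noiseless tensor exactly", {
  dirs <- fixture_dirs()
  D <- diag(c(1.7e-3, 0.2e-3, 0.2e-3))
  # rotate so the tensor is not axis-aligned
  set.seed(33)
  Rm <- fixture_rotation()
  Dr <- Rm %*% D %*% t(Rm)
  S0 <- 100
  sig <- S0 * exp(-1000 * rowSums((dirs %*% Dr) * dirs))
  shell <- fixture_shell(sig, dirs, grid = c(2, 2, 2), b0 = S0)
  tens <- fit_dti(shell)
  got <- tens$D[1, 1, 1, ]
  want <- c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3])
  expect_equal(got, want, tolerance = 1e-8)
  expect_equal(sort(tens$evals[1, 1, 1, ], decreasing = TRUE),
               c(1.7e-3, 0.2e-3, 0.2e-3), tolerance = 1e-8)

  # isotropic signal -> equal eigenvalues; flat signal -> zero tensor
  iso <- fixture_shell(rep(S0 * exp(-1000 * 0.9e-3), 60), dirs, b0 = S0)
  evi <- fit_dti(iso)$evals[1, 1, 1, ]
  expect_equal(evi, rep(0.9e-3, 3), tolerance = 1e-8)
  flat <- fit_dti(fixture_shell(rep(S0, 60), dirs, b0 = S0))
  expect_equal(max(abs(flat$D)), 0, tolerance = 1e-12)
})

test_that("FA and MD match their closed forms", {
  mk_tensor <- function(ev) {
    structure(list(D = array(0, c(1, 1, 1, 6)),
                   evals = array(ev, c(1, 1, 1, 3)),
                   mask = array(TRUE, c(1, 1, 1)), n_negative_evals = 0),
              class = "tensor_image")
  }
  # independent evaluation of the FA formula
  fa_ref <- function(ev) {
    md <- mean(ev)
    sqrt(3 / 2) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
  }
  ev <- c(1.7e-3, 0.2e-3, 0.2e-3)
  r <- fa_md(mk_tensor(ev))
  expect_equal(r$md[1, 1, 1], 0.7e-3)
  expect_equal(r$fa[1, 1, 1], fa_ref(ev), tolerance = 1e-12)
  expect_equal(round(r$fa[1, 1, 1], 3), 0.870)
  expect_equal(fa_md(mk_tensor(c(1, 1, 1) * 1e-3))$fa[1, 1, 1], 0)
  expect_equal(fa_md(mk_tensor(c(1, 0, 0)))$fa[1, 1, 1], 1)
  expect_equal(fa_md(mk_tensor(c(0, 0, 0)))$fa[1, 1, 1], 0) # defined as 0
})

test_that("adjusted group test reduces to the classical t-test and is calibrated", {
  set.seed(55)
  grid <- c(6, 6, 6)
  n <- 8
  metrics <- lapply(1:(2 * n), function(i) array(rnorm(prod(grid), 0.5, 0.05), grid))
  tab <- data.frame(subject_id = sprintf("s%02d", 1:(2 * n)),
                    site = rep(c("A", "B"), each = n),
                    age = rnorm(2 * n, 50, 10))
  gt <- adjusted_group_test(metrics, tab, c("A", "B"))
  # oracle: equal-variance two-sample t-test per voxel
  v <- c(3, 4, 2)
  y <- sapply(metrics, function(m) m[v[1], v[2], v[3]])
  tt <- t.test(y[1:n], y[(n + 1):(2 * n)], var.equal = TRUE)
  expect_equal(abs(gt$t[v[1], v[2], v[3]]), abs(tt$statistic),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(gt$p[v[1], v[2], v[3]], tt$p.value, tolerance = 1e-10)
  # null calibration: significant fraction near alpha
  expect_lt(abs(gt$fraction - 0.05), 0.04)

  # a strong injected offset is detected almost everywhere
  metrics2 <- metrics
  for (i in (n + 1):(2 * n)) metrics2[[i]] <- metrics2[[i]] + 0.2
  gt2 <- adjusted_group_test(metrics2, tab, c("A", "B"), covariates = "age")
  expect_gt(gt2$fraction, 0.95)

  # identical maps for every subject -> all voxels excluded
  same <- lapply(1:(2 * n), function(i) array(1, grid))
  gt3 <- adjusted_group_test(same, tab, c("A", "B"))
  expect_equal(gt3$n_excluded, prod(grid))
  expect_true(is.na(gt3$fraction))
})

test_that("covariate adjustment removes a confounded age effect", {
  set.seed(66)
  grid <- c(5, 5, 5)
  n <- 10
  age <- c(rnorm(n, 35, 5), rnorm(n, 60, 5)) # confounded with site
  metrics <- lapply(1:(2 * n), function(i)
    array(0.8 - 0.004 * (age[i] - 47) + rnorm(prod(grid), 0, 0.01), grid))
  tab <- data.frame(subject_id = sprintf("s%02d", 1:(2 * n)),
                    site = rep(c("A", "B"), each = n), age = age)
  raw <- adjusted_group_test(metrics, tab, c("A", "B"))
  adj <- adjusted_group_test(metrics, tab, c("A", "B"), covariates = "age")
  expect_gt(raw$fraction, 0.5) # age gap masquerades as a site effect
  expect_lt(adj$fraction, 0.2) # adjustment removes it
})

test_that("scaling recovery error summarizes relative errors", {
  grid <- c(2, 2, 1)
  theta <- list(L0 = array(2, grid))
  est <- structure(list(theta = list(L0 = array(2.2, grid)),
                        valid = array(TRUE, grid), orders = 0),
                   class = "scaling_maps")
  err <- scaling_recovery_error(est, theta)
  expect_equal(err$median, 0.1, tolerance = 1e-12)
  est$theta$L0 <- theta$L0
  expect_equal(scaling_recovery_error(est, theta)$median, 0)
  expect_error(scaling_recovery_error(est, list(L2 = theta$L0)), "order")
})

test_that("age-metric correlation matches cor.test and flags degeneracy", {
  set.seed(77)
  grid <- c(3, 3, 3)
  age <- rnorm(12, 50, 10)
  metrics <- lapply(age, function(a) array(1 - 0.01 * a, grid))
  tab <- data.frame(subject_id = as.character(1:12), site = "A", age = age)
  r <- age_metric_correlation(metrics, tab)
  expect_equal(r$r, -1, tolerance = 1e-10)
  noisy <- lapply(age, function(a) array(1 - 0.01 * a + rnorm(1, 0, 0.05), grid))
  r2 <- age_metric_correlation(noisy, tab)
  ct <- cor.test(age, sapply(noisy, function(m) mean(m)))
  expect_equal(r2$r, unname(ct$estimate), tolerance = 1e-12)
  same <- lapply(age, function(a) array(1, grid))
  expect_true(is.na(age_metric_correlation(same, tab)$r))
})
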