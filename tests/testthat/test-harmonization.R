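test_that("training learns the injected site effect exactly without noise", {
  cfg <- fixture_cohort(n = 3, noise = "none", seed = 31)
  coh <- simulate_cohort(cfg)
  m <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                           method = "means", spec = sh_basis_spec(4, 0))
  err <- scaling_recovery_error(m$scaling$Tgt, coh$truth$theta$Tgt)
  expect_true(all(err$median < 1e-6))
  expect_equal(m$targets, "Tgt")
})

test_that("GLM and means scaling agree exactly with a dummies-only design", {
  cfg <- fixture_cohort(n = 4, noise = "gaussian", seed = 41)
  coh <- simulate_cohort(cfg)
  mm <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                            method = "means", spec = sh_basis_spec(4, 0))
  mg <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                            method = "glm", covariates = character(),
                            spec = sh_basis_spec(4, 0))
  for (l in names(mm$scaling$Tgt$theta)) {
    a <- mg$scaling$Tgt$theta[[l]]
    b <- mm$scaling$Tgt$theta[[l]]
    sel <- mm$scaling$Tgt$valid
    expect_lt(max(abs(a[sel] - b[sel]) / pmax(abs(b[sel]), 1e-300)), 1e-10)
  }
})

test_that("one-step multi-site model equals pairwise two-site models", {
  sites <- list(site_spec("Ref", 3, 50, 8, 0.5),
                site_spec("T1", 3, 50, 8, 0.5),
                site_spec("T2", 3, 50, 8, 0.5))
  cfg <- fixture_cohort(sites = sites, noise = "gaussian", seed = 51)
  coh <- simulate_cohort(cfg)
  m3 <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                            method = "glm", spec = sh_basis_spec(4, 0))
  expect_setequal(m3$targets, c("T1", "T2"))
  for (tgt in c("T1", "T2")) {
    keep <- coh$covariates$site %in% c("Ref", tgt)
    m2 <- train_harmonization(coh$subjects[keep],
                              covariate_table(as.data.frame(coh$covariates)[keep, ]),
                              "Ref", method = "means",
                              spec = sh_basis_spec(4, 0))
    for (l in names(m2$scaling[[tgt]]$theta)) {
      sel <- m2$scaling[[tgt]]$valid & m3$scaling[[tgt]]$valid
      expect_lt(max(abs(m3$scaling[[tgt]]$theta[[l]][sel] -
                          m2$scaling[[tgt]]$theta[[l]][sel])), 1e-10)
    }
  }
})

test_that("scaling estimates are scale-equivariant in the target signal", {
  # multiplying all target-site signals by k multiplies energies by k^2,
  # so theta = L_ref / L_tgt shrinks by k^2
  cfg <- fixture_cohort(n = 3, noise = "none", seed = 61)
  coh <- simulate_cohort(cfg)
  k <- 1.7
  scaled_subjects <- mapply(function(s, site) {
    if (site == "Tgt") s$data <- s$data * k
    s
  }, coh$subjects, coh$covariates$site, SIMPLIFY = FALSE)
  m1 <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                            method = "means", spec = sh_basis_spec(4, 0))
  m2 <- train_harmonization(scaled_subjects, coh$covariates, "Ref",
                            method = "means", spec = sh_basis_spec(4, 0))
  sel <- m1$scaling$Tgt$valid & m2$scaling$Tgt$valid &
    m1$scaling$Tgt$theta$L0 < 9 / k^2 # keep away from the clip bound
  expect_lt(max(abs(m2$scaling$Tgt$theta$L0[sel] -
                      m1$scaling$Tgt$theta$L0[sel] / k^2)), 1e-8)
})

test_that("training is deterministic and method='means' warns on covariates", {
  cfg <- fixture_cohort(n = 3, noise = "gaussian", seed = 71)
  coh <- simulate_cohort(cfg)
  m1 <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                            method = "glm", covariates = c("age", "sex"),
                            spec = sh_basis_spec(4, 0))
  m2 <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                            method = "glm", covariates = c("age", "sex"),
                            spec = sh_basis_spec(4, 0))
  expect_identical(m1$scaling, m2$scaling)
  expect_warning(train_harmonization(coh$subjects, coh$covariates, "Ref",
                                     method = "means",
                                     covariates = c("age"),
                                     spec = sh_basis_spec(4, 0)),
                 "ignores covariates")
})

test_that("harmonize_subject passes reference through and rescales targets", {
  cfg <- fixture_cohort(n = 3, noise = "none", seed = 81)
  coh <- simulate_cohort(cfg)
  m <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                           method = "means", spec = sh_basis_spec(4, 0))
  ref_idx <- which(coh$covariates$site == "Ref")[1]
  out_ref <- harmonize_subject(coh$subjects[[ref_idx]], m, "Ref")
  expect_identical(out_ref$data, coh$subjects[[ref_idx]]$data)

  tgt_idx <- which(coh$covariates$site == "Tgt")[1]
  harm <- harmonize_subject(coh$subjects[[tgt_idx]], m, "Tgt")
  # b0 volume untouched
  expect_equal(harm$data[, , , 1], coh$subjects[[tgt_idx]]$data[, , , 1])
  # harmonized target features should match the reference subject's
  # features where the scaling is valid (noiseless, identical biology)
  f_h <- compute_rish(fit_sh(select_shell(harm, 1000), sh_basis_spec(4, 0)))
  f_r <- compute_rish(fit_sh(select_shell(coh$subjects[[ref_idx]], 1000),
                             sh_basis_spec(4, 0)))
  sel <- m$scaling$Tgt$valid
  for (k in 1:3) {
    a <- f_h$features[, , , k][sel]
    b <- f_r$features[, , , k][sel]
    expect_lt(stats::median(abs(a - b) / pmax(b, 1e-12)), 1e-6)
  }
  expect_error(harmonize_subject(coh$subjects[[tgt_idx]], m, "Nowhere"),
               "not a target")
})

test_that("an identity model reduces to the SH projection of the input", {
  cfg <- fixture_cohort(n = 3, noise = "none", seed = 91)
  coh <- simulate_cohort(cfg)
  m <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                           method = "means", spec = sh_basis_spec(4, 0))
  for (l in names(m$scaling$Tgt$theta)) m$scaling$Tgt$theta[[l]][] <- 1
  sub <- coh$subjects[[which(coh$covariates$site == "Tgt")[1]]]
  harm <- harmonize_subject(sub, m, "Tgt")
  shell <- select_shell(sub, 1000)
  proj <- sh_reconstruct(fit_sh(shell, sh_basis_spec(4, 0)), shell$directions)
  expect_equal(harm$data[, , , -1], unclass(proj), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("model save/load roundtrips within float32 and guards misuse", {
  tmp <- withr::local_tempdir()
  cfg <- fixture_cohort(n = 3, noise = "gaussian", seed = 101)
  coh <- simulate_cohort(cfg)
  m <- train_harmonization(coh$subjects, coh$covariates, "Ref",
                           method = "glm", covariates = c("age", "sex"),
                           spec = sh_basis_spec(4, 0))
  save_model(m, tmp)
  back <- load_model(tmp)
  expect_equal(back$reference, m$reference)
  expect_equal(back$targets, m$targets)
  expect_equal(back$orders, m$orders)
  expect_equal(back$centering, m$centering, tolerance = 1e-12)
  for (l in names(m$scaling$Tgt$theta)) {
    a <- back$scaling$Tgt$theta[[l]]; b <- m$scaling$Tgt$theta[[l]]
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-6)), 1e-6) # float32
  }
  expect_identical(back$scaling$Tgt$valid, m$scaling$Tgt$valid)
  # grid mismatch surfaces at apply time
  small <- simulate_cohort(fixture_cohort(n = 2, noise = "none", seed = 1,
                                          grid = c(6, 6, 6)))
  expect_error(harmonize_subject(small$subjects[[3]], back, "Tgt"),
               "grid mismatch")
  expect_error(load_model(file.path(tmp, "nope")), "metadata.json")
})

test_that("optional scaling-map smoothing is mass-preserving and opt-in", {
  grid <- c(8, 8, 8)
  set.seed(12)
  theta <- list(L0 = array(runif(prod(grid), 0.8, 1.2), grid))
  sc <- structure(list(theta = theta, valid = array(TRUE, grid), orders = 0),
                  class = "scaling_maps")
  sm <- smooth_scaling_maps(sc, fwhm = 4, voxel_size = 2)
  # smoothing shrinks spatial variance but roughly preserves the mean
  expect_lt(sd(sm$theta$L0), sd(theta$L0))
  expect_equal(mean(sm$theta$L0), mean(theta$L0), tolerance = 0.01)
  # fwhm = 0 is a no-op; invalid voxels stay at 1
  expect_identical(smooth_scaling_maps(sc, 0)$theta$L0, theta$L0)
  sc$valid[1, 1, 1] <- FALSE
  sc$theta$L0[1, 1, 1] <- 1
  sm2 <- smooth_scaling_maps(sc, fwhm = 4)
  expect_equal(sm2$theta$L0[1, 1, 1], 1)
})
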