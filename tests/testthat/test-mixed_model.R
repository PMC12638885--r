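test_that("REML equals the EMS closed forms at an interior optimum", {
  sim <- generate_met(synth_config(n_gen = 10, n_env = 4, n_rep = 3, seed = 41))
  ems <- ems_variance_components(sim$data, "T1")
  fit <- fit_mixed_model(sim$data, "T1")
  expect_false(ems$truncated)
  expect_equal(fit$components$sigma2_g, ems$sigma2_g, tolerance = 1e-6)
  expect_equal(fit$components$sigma2_gei, ems$sigma2_gei, tolerance = 1e-6)
  expect_equal(fit$components$sigma2_e, ems$sigma2_e, tolerance = 1e-6)
})

test_that("REML, BLUPs and LRT statistics agree with lme4 on balanced data", {
  sim <- generate_met(synth_config(n_gen = 8, n_env = 4, n_rep = 3, seed = 42))
  d <- sim$data
  fit <- fit_mixed_model(d, "T1")
  df <- as.data.frame(d$data)
  m <- lme4::lmer(T1 ~ ENV + ENV:REP + (1 | GEN) + (1 | GEN:ENV),
                  data = df, REML = TRUE,
                  control = lme4::lmerControl(optCtrl = list(xtol_abs = 1e-10,
                                                             ftol_abs = 1e-10)))
  vc <- as.data.frame(lme4::VarCorr(m))
  vc <- setNames(vc$vcov, vc$grp)
  expect_equal(fit$components$sigma2_g, vc[["GEN"]], tolerance = 1e-4)
  expect_equal(fit$components$sigma2_gei, vc[["GEN:ENV"]], tolerance = 1e-4)
  expect_equal(fit$components$sigma2_e, vc[["Residual"]], tolerance = 1e-4)

  # genotype BLUPs: shrinkage identity vs mixed-model-equation solutions
  rg <- lme4::ranef(m)$GEN
  expect_equal(fit$genotype_blups$blup,
               rg[match(fit$genotype_blups$GEN, rownames(rg)), 1],
               tolerance = 1e-4)

  # interaction BLUPs: the double-centred matrix equals lme4's GEN:ENV
  # ranef after removing its genotype-constant row component
  rge <- lme4::ranef(m)$`GEN:ENV`
  key <- do.call(rbind, strsplit(rownames(rge), ":"))
  M <- matrix(NA_real_, 8, 4,
              dimnames = list(sort(unique(df$GEN)), sort(unique(df$ENV))))
  M[cbind(key[, 1], key[, 2])] <- rge[[1]]
  ge <- ge_interaction_blups(fit)
  expect_equal(sweep(M, 1, rowMeans(M)), ge[rownames(M), colnames(M)],
               tolerance = 1e-3)

  # LRT statistics against lme4 refits
  lrt <- lrt_random_terms(d, "T1")
  m_no_g <- lme4::lmer(T1 ~ ENV + ENV:REP + (1 | GEN:ENV), data = df, REML = TRUE)
  m_no_ge <- lme4::lmer(T1 ~ ENV + ENV:REP + (1 | GEN), data = df, REML = TRUE)
  expect_equal(lrt$statistic[lrt$term == "GEN"],
               2 * (as.numeric(logLik(m)) - as.numeric(logLik(m_no_g))),
               tolerance = 1e-4)
  expect_equal(lrt$statistic[lrt$term == "GEN:ENV"],
               2 * (as.numeric(logLik(m)) - as.numeric(logLik(m_no_ge))),
               tolerance = 1e-4)
})

test_that("negative EMS solutions truncate to zero with a flag", {
  # no genotype signal, strong interaction: MS_G < MS_GEI is likely
  found <- FALSE
  for (s in 1:20) {
    sim <- generate_met(synth_config(n_gen = 4, n_env = 3, n_rep = 2,
                                     sigma2_g = 0, sigma2_gei = 50,
                                     sigma2_e = 5, gei_rank = 2, seed = s))
    vc <- ems_variance_components(sim$data, "T1")
    if (vc$truncated) {
      found <- TRUE
      expect_equal(vc$sigma2_g, 0)
      break
    }
  }
  expect_true(found)
})

test_that("boundary REML: zero genotype variance gives a near-zero LRT statistic", {
  sim <- generate_met(synth_config(n_gen = 12, n_env = 4, n_rep = 3,
                                   sigma2_g = 0, sigma2_gei = 20,
                                   sigma2_e = 40, seed = 55))
  fit <- fit_mixed_model(sim$data, "T1")
  lrt <- lrt_random_terms(sim$data, "T1")
  g_stat <- lrt$statistic[lrt$term == "GEN"]
  if (fit$components$sigma2_g == 0) {
    expect_lt(g_stat, 1e-6)
  } else {
    expect_lt(g_stat, stats::qchisq(0.99, 1))
  }
})

test_that("BLUPs shrink raw deviations and respect the h2 limits", {
  sim <- generate_met(synth_config(n_gen = 8, n_env = 3, n_rep = 2, seed = 61))
  fit <- fit_mixed_model(sim$data, "T1")
  raw_dev <- tapply(sim$data$data$T1, factor(sim$data$data$GEN,
                                             unique(sim$data$data$GEN)),
                    mean) - mean(sim$data$data$T1)
  expect_true(all(abs(fit$genotype_blups$blup) <= abs(raw_dev) + 1e-10))
  expect_equal(sum(fit$genotype_blups$blup), 0, tolerance = 1e-8)

  # h2 -> 1 limit: predicted means equal raw means
  vc1 <- variance_components(10, 0, 0, n_env = 3, n_rep = 2)
  expect_equal(genetic_parameters(vc1)$h2_mean, 1)
  # h2 -> 0 limit
  vc0 <- variance_components(0, 5, 5, n_env = 3, n_rep = 2)
  expect_equal(genetic_parameters(vc0)$h2_mean, 0)
})

test_that("interaction BLUP matrix is double-centred and vanishes without GEI", {
  sim <- generate_met(synth_config(n_gen = 6, n_env = 4, n_rep = 3, seed = 71))
  fit <- fit_mixed_model(sim$data, "T1")
  ge <- ge_interaction_blups(fit)
  expect_lt(max(abs(rowSums(ge))), 1e-8)
  expect_lt(max(abs(colSums(ge))), 1e-8)

  sim0 <- generate_met(synth_config(n_gen = 6, n_env = 4, n_rep = 6,
                                    sigma2_gei = 0, gei_rank = 0,
                                    sigma2_g = 100, sigma2_e = 1, seed = 72))
  fit0 <- fit_mixed_model(sim0$data, "T1")
  if (fit0$components$sigma2_gei == 0) {
    expect_equal(max(abs(ge_interaction_blups(fit0))), 0)
  }
})

test_that("genetic parameters reproduce the published worked examples", {
  vc_tab <- horse_gram_table("variance_components")
  expected <- list(
    YD = c(H2 = 0.863, As = 0.993, rge = 0.412, r2gei = 0.056),
    NC = c(H2 = 0.771, As = 0.981, rge = 0.758, r2gei = 0.173),
    DM = c(H2 = 0.068, As = 0.785, rge = 0.127, r2gei = 0.118)
  )
  for (tr in names(expected)) {
    row <- vc_tab[vc_tab$TRAIT == tr, ]
    gp <- genetic_parameters(variance_components(
      row$SIGMA2_G, row$SIGMA2_GEI, row$SIGMA2_E,
      n_env = row$N_ENV, n_rep = row$N_REP))
    # printed values carry 3 decimals; allow one ulp of the last printed
    # digit since the components themselves are printed rounded
    expect_lt(abs(gp$H2_broad - expected[[tr]]["H2"]), 0.0015)
    expect_lt(abs(gp$accuracy_As - expected[[tr]]["As"]), 0.0015)
    expect_lt(abs(gp$r_ge - expected[[tr]]["rge"]), 0.0015)
    expect_lt(abs(gp$r2_gei - expected[[tr]]["r2gei"]), 0.0015)
    expect_equal(gp$accuracy_As^2, gp$h2_mean, tolerance = 1e-12)
    expect_true(all(unlist(gp) >= 0 & unlist(gp) <= 1))
  }
  expect_error(genetic_parameters(variance_components(0, 0, 0, 6, 6)), "zero")
})

test_that("h2_mean decreases strictly as error variance grows", {
  h2 <- vapply(c(1, 10, 100, 1000), function(s2e) {
    genetic_parameters(variance_components(50, 10, s2e, 6, 6))$h2_mean
  }, numeric(1))
  expect_true(all(diff(h2) < 0))
})

test_that("LRT has power at trial-scale genotype variance", {
  hits <- vapply(1:12, function(s) {
    sim <- generate_met(trial_design_config(seed = 300 + s))
    lrt <- lrt_random_terms(sim$data, "T1")
    lrt$p_value[lrt$term == "GEN"] < 0.01
  }, logical(1))
  expect_true(all(hits))
})
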