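make_waasby_table <- function(G = 20, traits = 5, seed = 101) {
  set.seed(seed)
  m <- matrix(runif(G * traits, 0, 100), G, traits,
              dimnames = list(paste0("G", seq_len(G)),
                              paste0("T", seq_len(traits))))
  m
}

test_that("the WAASBY table aligns genotypes across traits", {
  sim <- generate_met(synth_config(n_gen = 8, n_env = 4, n_rep = 2,
                                   n_traits = 3, seed = 111))
  sc <- lapply(sim$data$traits, function(tr) stability_scores(sim$data, tr))
  tab <- build_waasby_table(sc)
  expect_equal(dim(tab), c(8L, 3L))
  expect_true(all(tab >= 0 & tab <= 100))
  expect_equal(tab[sc[[2]]$GEN, 2], setNames(sc[[2]]$waasby, sc[[2]]$GEN))

  bad <- sc
  bad[[2]] <- bad[[2]][-1, ]
  expect_error(build_waasby_table(bad), "mismatch")
})

test_that("two uncorrelated trait blocks load on two separate factors", {
  # constructed covariance oracle: traits 1-3 share one latent factor,
  # traits 4-5 another; blocks independent
  set.seed(121)
  G <- 120
  f1 <- rnorm(G); f2 <- rnorm(G)
  tab <- cbind(
    A1 = f1 + rnorm(G, sd = 0.4), A2 = f1 + rnorm(G, sd = 0.4),
    A3 = f1 + rnorm(G, sd = 0.4),
    B1 = f2 + rnorm(G, sd = 0.4), B2 = f2 + rnorm(G, sd = 0.4)
  )
  rownames(tab) <- paste0("G", 1:G)
  fm <- fit_factor_model(tab)
  expect_equal(fm$n_factors, 2L)
  L <- abs(fm$loadings)
  a_factor <- which.max(colSums(L[1:3, , drop = FALSE]))
  b_factor <- which.max(colSums(L[4:5, , drop = FALSE]))
  expect_false(a_factor == b_factor)
  expect_true(all(L[1:3, a_factor] > 0.7))
  expect_true(all(L[4:5, b_factor] > 0.7))
})

test_that("varimax rotation is orthogonal and preserves communalities", {
  tab <- make_waasby_table(G = 25, traits = 6, seed = 131)
  fm <- fit_factor_model(tab, n_factors = 3)
  R <- fm$rotation
  expect_equal(crossprod(R), diag(ncol(R)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # communalities from unrotated retained loadings
  eig <- eigen(cor(tab), symmetric = TRUE)
  L0 <- eig$vectors[, 1:3] %*% diag(sqrt(eig$values[1:3]))
  expect_equal(unname(fm$communalities), rowSums(L0^2), tolerance = 1e-8)
  expect_equal(sum(fm$eigenvalues), ncol(tab), tolerance = 1e-10)
})

test_that("a genotype at the ideotype has MTSI 0 and rank 1", {
  tab <- make_waasby_table(G = 15, traits = 4, seed = 141)
  tab[3, ] <- 100  # exactly the ideotype
  fm <- fit_factor_model(tab, n_factors = 2)
  res <- mtsi_scores(fm)
  expect_equal(res$mtsi[res$GEN == "G3"], 0, tolerance = 1e-8)
  expect_equal(res$rank[res$GEN == "G3"], 1L)
  shares <- factor_contributions(fm, res)
  expect_true(shares$undefined[shares$GEN == "G3"])
  expect_equal(rowSums(as.matrix(shares[, c("FA1", "FA2")])), rep(1, 15),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("MTSI equals the hand distance for fixed factor scores", {
  # 2-factor toy: genotype at (1, 1), ideotype at (0, 0) -> sqrt(2)
  fake <- structure(
    list(scores = matrix(c(1, 1), 1, 2, dimnames = list("G1", c("FA1", "FA2"))),
         ideotype_scores = c(FA1 = 0, FA2 = 0),
         loadings = matrix(0, 2, 2, dimnames = list(NULL, c("FA1", "FA2")))),
    class = "factor_model")
  res <- mtsi_scores(fake)
  expect_equal(res$mtsi, sqrt(2))

  # direct-formula oracle on a random table
  tab <- make_waasby_table(G = 12, traits = 5, seed = 151)
  fm <- fit_factor_model(tab, n_factors = 2)
  res2 <- mtsi_scores(fm)
  Z <- scale(tab)
  L <- fm$loadings
  Rinv <- solve(cor(tab))
  F <- Z %*% Rinv %*% L
  Fi <- as.numeric(((100 - colMeans(tab)) / apply(tab, 2, sd)) %*% Rinv %*% L)
  oracle <- sqrt(rowSums(sweep(F, 2, Fi)^2))
  expect_equal(res2$mtsi, unname(oracle), tolerance = 1e-10)
})

test_that("MTSI is invariant to factor sign flips", {
  tab <- make_waasby_table(G = 18, traits = 5, seed = 161)
  fm <- fit_factor_model(tab, n_factors = 2)
  flipped <- fm
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$scores[, 1] <- -flipped$scores[, 1]
  flipped$ideotype_scores[1] <- -flipped$ideotype_scores[1]
  expect_equal(mtsi_scores(flipped)$mtsi, mtsi_scores(fm)$mtsi,
               tolerance = 1e-10)
})

test_that("selection takes floor(intensity * G) genotypes from the low end", {
  tab <- make_waasby_table(G = 30, traits = 5, seed = 171)
  res <- mtsi_scores(fit_factor_model(tab, n_factors = 2))
  sel <- select_genotypes(res, 0.15)
  expect_length(sel, 4L)
  expect_equal(sort(res$mtsi[res$GEN %in% sel]), sort(res$mtsi)[1:4])
  expect_length(select_genotypes(res, 1), 30L)
  small <- res[1:10, ]
  class(small) <- class(res)
  expect_error(select_genotypes(small, 0.05), "no genotypes")
})

test_that("selection response reproduces the published differentials and the gain identity", {
  resp <- horse_gram_table("selection_response")
  vc_tab <- horse_gram_table("variance_components")
  for (k in seq_len(nrow(resp))) {
    sd_pct <- selection_differential(resp$XS[k], resp$XO[k])
    # Xo/Xs are printed rounded, so recomputed SD% can differ in the last digit
    expect_lt(abs(sd_pct - resp$SD_PCT[k]), 0.1)
    row <- vc_tab[vc_tab$TRAIT == resp$TRAIT[k], ]
    h2m <- genetic_parameters(variance_components(
      row$SIGMA2_G, row$SIGMA2_GEI, row$SIGMA2_E, row$N_ENV, row$N_REP))$h2_mean
    expect_lt(abs(resp$SD_PCT[k] * h2m - resp$SG_PCT[k]), 0.05)
  }
})

test_that("selection_response computes Xo, Xs and SG from a means table", {
  means <- tibble::tibble(GEN = paste0("G", 1:4),
                          A = c(1, 2, 3, 4), B = c(10, 10, 20, 20))
  out <- selection_response(means, selected = c("G3", "G4"),
                            h2_mean = c(A = 0.5, B = 1))
  expect_equal(out$Xo, c(2.5, 15))
  expect_equal(out$Xs, c(3.5, 20))
  expect_equal(out$sd_pct, c(40, 100 / 3), tolerance = 1e-10)
  expect_equal(out$sg_pct, c(20, 100 / 3), tolerance = 1e-10)
  expect_error(selection_response(means, "G9", c(A = 1, B = 1)), "G9")
  expect_error(selection_response(means, "G1", c(A = 1)), "B")
})

test_that("factor contributions isolate the deviating factor", {
  fake <- structure(
    list(scores = matrix(c(2, 0), 1, 2, dimnames = list("G1", c("FA1", "FA2"))),
         ideotype_scores = c(FA1 = 0, FA2 = 0),
         loadings = matrix(0, 2, 2, dimnames = list(NULL, c("FA1", "FA2")))),
    class = "factor_model")
  res <- mtsi_scores(fake)
  sh <- factor_contributions(fake, res)
  expect_equal(as.numeric(sh[1, c("FA1", "FA2")]), c(1, 0))
})
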