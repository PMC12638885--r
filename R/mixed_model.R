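#' Variance components from expected mean squares
#'
#' Closed-form (method-of-moments) estimates for the balanced MET with
#' genotype and genotype-by-environment random:
#' `s2_e = MS_error`, `s2_gei = (MS_GEI - MS_error) / R`,
#' `s2_g = (MS_G - MS_GEI) / (E * R)`. Negative solutions are truncated to
#' zero and flagged. On balanced data with an interior optimum these equal
#' the REML estimates exactly.
#'
#' @param data A balanced [met_data] object.
#' @param trait Trait name.
#' @return A list of class `variance_components` with elements `sigma2_g`,
#'   `sigma2_gei`, `sigma2_e`, `n_env`, `n_rep`, `truncated` (logical).
#' @export
ems_variance_components <- function(data, trait) {
  an <- joint_anova(data, trait)
  ms <- stats::setNames(an$ms, an$source)
  E <- attr(an, "design")["n_env"]; R <- attr(an, "design")["n_rep"]
  s2e <- ms[["Residual"]]
  s2gei <- (ms[["GEN:ENV"]] - s2e) / R
  s2g <- (ms[["GEN"]] - ms[["GEN:ENV"]]) / (E * R)
  truncated <- s2gei < 0 || s2g < 0
  variance_components(max(s2g, 0), max(s2gei, 0), max(s2e, 0),
                      n_env = E, n_rep = R, truncated = truncated)
}

#' Bundle variance components with their design constants
#'
#' @param sigma2_g,sigma2_gei,sigma2_e Genotypic, interaction and error
#'   variances (>= 0).
#' @param n_env,n_rep Number of environments and replicates per environment.
#' @param truncated Whether any component was truncated at zero.
#' @return A list of class `variance_components`.
#' @export
variance_components <- function(sigma2_g, sigma2_gei, sigma2_e,
                                n_env, n_rep, truncated = FALSE) {
  if (any(c(sigma2_g, sigma2_gei, sigma2_e) < 0)) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  structure(
    list(sigma2_g = unname(sigma2_g), sigma2_gei = unname(sigma2_gei),
         sigma2_e = unname(sigma2_e),
         n_env = as.integer(n_env), n_rep = as.integer(n_rep),
         truncated = truncated),
    class = "variance_components"
  )
}

# Stratum sums of squares / dfs needed by the balanced REML likelihood,
# after projecting out the fixed effects (intercept, environment,
# replicate-within-environment).
reml_strata <- function(data, trait) {
  an <- joint_anova(data, trait)
  list(
    ss = stats::setNames(an$ss, an$source)[c("GEN", "GEN:ENV", "Residual")],
    df = stats::setNames(an$df, an$source)[c("GEN", "GEN:ENV", "Residual")],
    design = attr(an, "design"),
    anova = an
  )
}

# Restricted log-likelihood of the balanced MET mixed model, written in
# terms of the three random strata. lambda_G = s2e + R*s2gei + E*R*s2g,
# lambda_I = s2e + R*s2gei, lambda_e = s2e; fixed-effect directions cancel
# between log|V| and log|X'V^-1 X| on balanced data.
reml_loglik_balanced <- function(s2g, s2gei, s2e, strata) {
  E <- unname(strata$design["n_env"]); R <- unname(strata$design["n_rep"])
  lam <- c(s2e + R * s2gei + E * R * s2g,
           s2e + R * s2gei,
           s2e)
  if (any(lam <= 0)) return(-Inf)
  n_eff <- sum(strata$df)
  -0.5 * (sum(strata$df * log(lam)) + sum(strata$ss / lam) +
            n_eff * log(2 * pi))
}

# Maximize the restricted likelihood over a subset of active components.
# Interior solutions are available in closed form (stratum mean squares);
# when a closed-form component is negative the optimum lies on the
# boundary, and a bounded quasi-Newton search on log-variances (EMS start,
# floored) finds it before sub-epsilon variances are truncated to zero.
reml_fit_balanced <- function(strata, include_g = TRUE, include_gei = TRUE) {
  E <- unname(strata$design["n_env"]); R <- unname(strata$design["n_rep"])
  ms <- strata$ss / strata$df
  scale <- max(ms[["Residual"]], mean(ms), .Machine$double.eps)

  closed <- function() {
    if (include_g && include_gei) {
      s2e <- ms[["Residual"]]
      s2gei <- (ms[["GEN:ENV"]] - s2e) / R
      s2g <- (ms[["GEN"]] - ms[["GEN:ENV"]]) / (E * R)
    } else if (!include_g && include_gei) {
      # genotype stratum shares lambda_I with the interaction stratum
      s2e <- ms[["Residual"]]
      lam_i <- (strata$ss[["GEN"]] + strata$ss[["GEN:ENV"]]) /
        (strata$df[["GEN"]] + strata$df[["GEN:ENV"]])
      s2gei <- (lam_i - s2e) / R
      s2g <- 0
    } else if (include_g && !include_gei) {
      s2e <- (strata$ss[["GEN:ENV"]] + strata$ss[["Residual"]]) /
        (strata$df[["GEN:ENV"]] + strata$df[["Residual"]])
      s2g <- (ms[["GEN"]] - s2e) / (E * R)
      s2gei <- 0
    } else {
      s2e <- sum(strata$ss) / sum(strata$df)
      s2g <- 0; s2gei <- 0
    }
    c(s2g = s2g, s2gei = s2gei, s2e = s2e)
  }

  est <- closed()
  active <- c(g = include_g, gei = include_gei)
  if (all(est[c(active, TRUE)] >= 0)) {
    par <- est
  } else {
    # boundary case: bounded quasi-Newton on log-variances, EMS start
    start <- log(pmax(est, 1e-8 * scale))
    idx <- c(include_g, include_gei, TRUE)
    obj <- function(lp) {
      full <- c(-Inf, -Inf, log(scale))
      full[idx] <- lp
      v <- exp(full)
      -reml_loglik_balanced(v[1], v[2], v[3], strata)
    }
    opt <- stats::optim(start[idx], obj, method = "L-BFGS-B",
                        lower = log(1e-12 * scale), upper = log(1e12 * scale),
                        control = list(factr = 1e3, maxit = 500))
    full <- c(0, 0, 0)
    full[idx] <- exp(opt$par)
    par <- c(s2g = full[1], s2gei = full[2], s2e = full[3])
    par[par < 1e-8 * scale] <- 0
  }
  par <- pmax(par, 0)
  if (!include_g) par["s2g"] <- 0
  if (!include_gei) par["s2gei"] <- 0
  list(
    sigma2 = par,
    loglik = reml_loglik_balanced(par["s2g"], par["s2gei"],
                                  max(par["s2e"], .Machine$double.eps), strata)
  )
}

#' Fit the balanced MET mixed model by REML
#'
#' Linear mixed model with environment and replicate-within-environment
#' fixed and genotype and genotype-by-environment random, estimated by
#' restricted maximum likelihood. On the balanced design the restricted
#' likelihood factorises over three orthogonal strata (genotype,
#' interaction, residual), so an interior optimum is available in closed
#' form and coincides with the expected-mean-squares estimates; boundary
#' optima are found by bounded quasi-Newton on log-variances.
#'
#' @param data A balanced [met_data] object.
#' @param trait Trait name.
#' @return A list of class `met_mixed_fit`: `components`
#'   ([variance_components]), `loglik` (REML), `mu` (grand mean),
#'   `env_effects`, `rep_effects` (fixed-effect estimates),
#'   `genotype_blups` (tibble: `GEN`, `blup`, `predicted_mean`,
#'   `above_average`), `ge_blups` (G x E matrix), `h2_mean`, `anova`.
#' @export
fit_mixed_model <- function(data, trait) {
  stopifnot(inherits(data, "met_data"))
  strata <- reml_strata(data, trait)
  fit <- reml_fit_balanced(strata)
  E <- unname(strata$design["n_env"]); R <- unname(strata$design["n_rep"])
  vc <- variance_components(fit$sigma2["s2g"], fit$sigma2["s2gei"],
                            fit$sigma2["s2e"], n_env = E, n_rep = R)

  df <- data$data
  y <- df[[trait]]
  gens <- unique(df$GEN); envs <- unique(df$ENV)
  mu <- mean(y)
  gen_means <- tapply(y, factor(df$GEN, gens), mean)
  env_means <- tapply(y, factor(df$ENV, envs), mean)
  rep_means <- tapply(y, list(factor(df$ENV, envs), df$REP), mean)

  gp <- genetic_parameters(vc)
  h2m <- gp$h2_mean
  blup <- h2m * (gen_means - mu)
  gen_tbl <- tibble::tibble(
    GEN = gens,
    blup = as.numeric(blup),
    predicted_mean = mu + as.numeric(blup),
    above_average = as.numeric(blup) > 0
  )

  cell <- tapply(y, list(factor(df$GEN, gens), factor(df$ENV, envs)), mean)
  d <- sweep(sweep(cell, 1, rowMeans(cell)), 2, colMeans(cell)) + mu
  shrink <- if (vc$sigma2_gei + vc$sigma2_e / R > 0) {
    vc$sigma2_gei / (vc$sigma2_gei + vc$sigma2_e / R)
  } else 0
  ge <- shrink * d
  dimnames(ge) <- list(gens, envs)

  structure(
    list(components = vc, loglik = fit$loglik, mu = mu,
         env_effects = env_means - mu,
         rep_effects = sweep(rep_means, 1, rowMeans(rep_means)),
         genotype_blups = gen_tbl,
         ge_blups = ge,
         h2_mean = h2m,
         anova = strata$anova,
         trait = trait),
    class = "met_mixed_fit"
  )
}

#' @export
print.met_mixed_fit <- function(x, ...) {
  vc <- x$components
  cat(sprintf("<met_mixed_fit> trait %s: s2_g = %.4g, s2_gei = %.4g, s2_e = %.4g (h2_mean = %.3f)\n",
              x$trait, vc$sigma2_g, vc$sigma2_gei, vc$sigma2_e, x$h2_mean))
  invisible(x)
}

#' Genotype BLUPs and predicted means
#'
#' The balanced-design BLUP of a genotype effect is the shrunken deviation
#' `g_i = h2_mean * (ybar_i - ybar..)` with
#' `h2_mean = s2_g / (s2_g + s2_gei / E + s2_e / (E * R))` (the heritability
#' of genotype means); the predicted mean is `mu + g_i`. Genotypes with a
#' positive BLUP are flagged as above the predicted average.
#'
#' @param fit A `met_mixed_fit` from [fit_mixed_model()].
#' @return Tibble with columns `GEN`, `blup`, `predicted_mean`,
#'   `above_average`.
#' @export
genotype_blups <- function(fit) {
  stopifnot(inherits(fit, "met_mixed_fit"))
  fit$genotype_blups
}

#' Interaction BLUP matrix
#'
#' The BLUP of each genotype-by-environment effect on the balanced design:
#' the double-centred cell residual `d_ij` shrunken by
#' `s2_gei / (s2_gei + s2_e / R)`. The matrix is double-centred (row and
#' column sums zero) and is the input to the WAASB stability index.
#'
#' @param fit A `met_mixed_fit`.
#' @return G x E numeric matrix.
#' @export
ge_interaction_blups <- function(fit) {
  stopifnot(inherits(fit, "met_mixed_fit"))
  fit$ge_blups
}

#' Genetic-parameter summaries from variance components
#'
#' The standard mixed-model summaries for a balanced MET:
#' broad-sense heritability `H2 = s2_g / (s2_g + s2_gei + s2_e)`;
#' the GEI coefficient of determination
#' `R2_gei = s2_gei / (s2_g + s2_gei + s2_e)`;
#' the genotype-environment correlation `r_ge = s2_gei / (s2_gei + s2_e)`;
#' the heritability of genotype means
#' `h2_mean = s2_g / (s2_g + s2_gei / E + s2_e / (E * R))`; and the
#' selection accuracy `As = sqrt(h2_mean)`.
#'
#' @param vc A [variance_components] object.
#' @return One-row tibble with columns `r2_gei`, `accuracy_As`, `r_ge`,
#'   `H2_broad`, `h2_mean`, all in `[0, 1]`.
#' @export
genetic_parameters <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  tot <- vc$sigma2_g + vc$sigma2_gei + vc$sigma2_e
  if (tot <= 0) stop("all variance components are zero", call. = FALSE)
  E <- vc$n_env; R <- vc$n_rep
  denom_mean <- vc$sigma2_g + vc$sigma2_gei / E + vc$sigma2_e / (E * R)
  h2m <- if (denom_mean > 0) vc$sigma2_g / denom_mean else 0
  rge_den <- vc$sigma2_gei + vc$sigma2_e
  tibble::tibble(
    r2_gei = vc$sigma2_gei / tot,
    accuracy_As = sqrt(h2m),
    r_ge = if (rge_den > 0) vc$sigma2_gei / rge_den else 0,
    H2_broad = vc$sigma2_g / tot,
    h2_mean = h2m
  )
}

#' Likelihood-ratio tests for the random terms
#'
#' Refits the model without the genotype term and without the interaction
#' term, and compares restricted log-likelihoods:
#' `statistic = -2 * (loglik_reduced - loglik_full)`, referred to a
#' chi-squared distribution with one degree of freedom. Both fits share the
#' same fixed effects, so their restricted likelihoods are comparable. The
#' plain chi-squared reference is conservative for a variance component
#' tested on the boundary.
#'
#' @param data A balanced [met_data] object.
#' @param trait Trait name.
#' @return Tibble with columns `term`, `loglik_full`, `loglik_reduced`,
#'   `statistic`, `p_value`.
#' @export
lrt_random_terms <- function(data, trait) {
  strata <- reml_strata(data, trait)
  full <- reml_fit_balanced(strata)
  no_g <- reml_fit_balanced(strata, include_g = FALSE)
  no_gei <- reml_fit_balanced(strata, include_gei = FALSE)
  stat <- pmax(0, -2 * (c(no_g$loglik, no_gei$loglik) - full$loglik))
  tibble::tibble(
    term = c("GEN", "GEN:ENV"),
    loglik_full = full$loglik,
    loglik_reduced = c(no_g$loglik, no_gei$loglik),
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)
  )
}
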