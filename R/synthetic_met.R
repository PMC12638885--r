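#' Configuration for the synthetic MET generator
#'
#' Defines a balanced RCBD multi-environment trial with additive genotype and
#' environment effects, a low-rank (AMMI-structured) genotype-by-environment
#' interaction, blocks nested in environments, and Gaussian plot error.
#'
#' Defaults emulate the horse gram mutant trial that motivates the package:
#' 30 genotypes x 6 environments x 6 replicates at the yield-scale variance
#' components (sigma2_g = 25425, sigma2_gei = 1663, sigma2_e = 2374, grand
#' mean 938 kg/ha); environment and block variances and the interaction rank
#' are the package's own realistic choices (see the methods vignette).
#'
#' @param n_gen,n_env,n_rep Design constants (G, E, R), all >= 2.
#' @param mu Grand mean.
#' @param sigma2_g,sigma2_gei,sigma2_e Genotypic, interaction and plot-error
#'   variance components (>= 0).
#' @param sigma2_env,sigma2_block Environment main-effect and block-within-
#'   environment variances (>= 0).
#' @param gei_rank Rank of the simulated interaction matrix, in
#'   `[0, min(G, E) - 1]`.
#' @param n_traits Number of traits to simulate.
#' @param trait_cor Correlation matrix (n_traits x n_traits) of genotype
#'   effects across traits; identity by default.
#' @param trait_names Optional trait column names (default `T1..Tn`).
#' @param seed Integer seed; drives named sub-streams (genotype, environment,
#'   interaction, block, error) so draws are reproducible component-wise.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_gen = 30, n_env = 6, n_rep = 6,
                         mu = 938,
                         sigma2_g = 25425, sigma2_gei = 1663, sigma2_e = 2374,
                         sigma2_env = 260, sigma2_block = 50,
                         gei_rank = 2,
                         n_traits = 1, trait_cor = NULL,
                         trait_names = NULL,
                         seed = 1L) {
  if (any(c(n_gen, n_env, n_rep) < 2)) {
    stop("need at least 2 genotypes, environments and replicates", call. = FALSE)
  }
  vars <- c(sigma2_g = sigma2_g, sigma2_gei = sigma2_gei, sigma2_e = sigma2_e,
            sigma2_env = sigma2_env, sigma2_block = sigma2_block)
  if (any(vars < 0)) {
    stop("variance components must be >= 0 (offending: ",
         paste(names(vars)[vars < 0], collapse = ", "), ")", call. = FALSE)
  }
  if (gei_rank < 0 || gei_rank > min(n_gen, n_env) - 1) {
    stop("gei_rank must lie in [0, min(G, E) - 1]", call. = FALSE)
  }
  if (is.null(trait_cor)) trait_cor <- diag(n_traits)
  trait_cor <- as.matrix(trait_cor)
  if (!isTRUE(all.equal(dim(trait_cor), c(n_traits, n_traits))) ||
      !isTRUE(all.equal(trait_cor, t(trait_cor), tolerance = 1e-8)) ||
      !isTRUE(all.equal(diag(trait_cor), rep(1, n_traits),
                        check.attributes = FALSE))) {
    stop("trait_cor must be a symmetric n_traits x n_traits matrix with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("trait_cor must be positive definite", call. = FALSE)
  }
  if (is.null(trait_names)) trait_names <- paste0("T", seq_len(n_traits))
  stopifnot(length(trait_names) == n_traits)
  structure(
    list(n_gen = as.integer(n_gen), n_env = as.integer(n_env),
         n_rep = as.integer(n_rep), mu = mu,
         sigma2_g = sigma2_g, sigma2_gei = sigma2_gei, sigma2_e = sigma2_e,
         sigma2_env = sigma2_env, sigma2_block = sigma2_block,
         gei_rank = as.integer(gei_rank),
         n_traits = as.integer(n_traits), trait_cor = trait_cor,
         trait_names = trait_names, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Named sub-seeds derived from the master seed: one per stochastic component,
# so changing (say) only the error draw does not shift the genotype draw.
derive_subseeds <- function(seed, n_traits) {
  set.seed(seed)
  base <- sample.int(.Machine$integer.max - 1L, 2L + 3L * n_traits)
  list(
    genotype = base[1L],
    environment_block = base[2L],
    # per-trait streams for interaction, block, error
    interaction = base[2L + seq_len(n_traits)],
    block = base[2L + n_traits + seq_len(n_traits)],
    error = base[2L + 2L * n_traits + seq_len(n_traits)]
  )
}

# Rank-r double-centred interaction matrix with sum of squares
# (G-1)(E-1)*sigma2, so the EMS estimator of sigma2_gei is unbiased for the
# configured value.
simulate_interaction <- function(G, E, rank, sigma2, seed) {
  if (rank == 0 || sigma2 == 0) {
    return(matrix(0, G, E))
  }
  set.seed(seed)
  A <- matrix(stats::rnorm(G * rank), G, rank)
  B <- matrix(stats::rnorm(E * rank), E, rank)
  s <- sort(abs(stats::rnorm(rank)) + 0.5, decreasing = TRUE)
  # orthonormal columns orthogonal to the ones vector -> double-centred
  A <- qr.Q(qr(cbind(1, scale(A, scale = FALSE))))[, 1 + seq_len(rank), drop = FALSE]
  B <- qr.Q(qr(cbind(1, scale(B, scale = FALSE))))[, 1 + seq_len(rank), drop = FALSE]
  M <- A %*% diag(s, nrow = rank) %*% t(B)
  M * sqrt((G - 1) * (E - 1) * sigma2 / sum(M^2))
}

#' Generate a balanced synthetic MET dataset with known ground truth
#'
#' Simulates plot values
#' `y_ijr = mu + g_i + e_j + (ge)_ij + b_r(j) + eps_ijr` with
#' `g ~ N(0, sigma2_g)`, `e ~ N(0, sigma2_env)`, blocks nested in
#' environments `~ N(0, sigma2_block)` and `eps ~ N(0, sigma2_e)`. The
#' interaction matrix is built from `gei_rank` random orthonormal score
#' pairs, double-centred by construction, and scaled so the EMS estimator of
#' `sigma2_gei` is unbiased for the configured value. With `n_traits > 1`
#' the genotype effects are drawn with cross-trait correlation `trait_cor`;
#' all other components are independent across traits.
#'
#' @param config A [synth_config].
#' @return A list with elements `data` (a [met_data]) and `truth` (a
#'   `met_truth` ledger holding the config, realized effect vectors, the
#'   interaction matrix per trait and the derived sub-seeds).
#' @export
generate_met <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  G <- config$n_gen; E <- config$n_env; R <- config$n_rep
  TT <- config$n_traits
  seeds <- derive_subseeds(config$seed, TT)

  gens <- paste0("G", seq_len(G))
  envs <- paste0("E", seq_len(E))
  reps <- paste0("R", seq_len(R))

  set.seed(seeds$genotype)
  Z <- matrix(stats::rnorm(G * TT), G, TT)
  g_eff <- sqrt(config$sigma2_g) * (Z %*% chol(config$trait_cor))
  dimnames(g_eff) <- list(gens, config$trait_names)

  set.seed(seeds$environment_block)
  e_eff <- matrix(stats::rnorm(E * TT, sd = sqrt(config$sigma2_env)), E, TT,
                  dimnames = list(envs, config$trait_names))

  grid <- tidyr::expand_grid(ENV = envs, REP = reps, GEN = gens)
  i <- match(grid$GEN, gens); j <- match(grid$ENV, envs)
  r <- match(grid$REP, reps)

  interaction <- vector("list", TT)
  names(interaction) <- config$trait_names
  block_eff <- vector("list", TT)
  names(block_eff) <- config$trait_names

  for (t in seq_len(TT)) {
    interaction[[t]] <- simulate_interaction(G, E, config$gei_rank,
                                             config$sigma2_gei,
                                             seeds$interaction[t])
    dimnames(interaction[[t]]) <- list(gens, envs)
    set.seed(seeds$block[t])
    blk <- matrix(stats::rnorm(E * R, sd = sqrt(config$sigma2_block)), E, R,
                  dimnames = list(envs, reps))
    block_eff[[t]] <- blk
    set.seed(seeds$error[t])
    eps <- stats::rnorm(nrow(grid), sd = sqrt(config$sigma2_e))
    grid[[config$trait_names[t]]] <-
      config$mu + g_eff[i, t] + e_eff[j, t] +
      interaction[[t]][cbind(i, j)] + blk[cbind(j, r)] + eps
  }

  data <- met_data(grid[, c("ENV", "GEN", "REP", config$trait_names)],
                   traits = config$trait_names)
  truth <- structure(
    list(config = config, subseeds = seeds,
         genotype_effects = g_eff, environment_effects = e_eff,
         interaction = interaction, block_effects = block_eff),
    class = "met_truth"
  )
  list(data = data, truth = truth)
}

#' @rdname generate_met
#' @export
generate_multitrait_met <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_traits < 2) {
    stop("generate_multitrait_met needs n_traits >= 2; use generate_met",
         call. = FALSE)
  }
  generate_met(config)
}

#' Write a truth ledger to JSON
#'
#' @param truth A `met_truth` object from [generate_met()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_truth_json <- function(truth, file) {
  stopifnot(inherits(truth, "met_truth"))
  out <- list(
    config = truth$config[setdiff(names(truth$config), "trait_cor")],
    trait_cor = unclass(truth$config$trait_cor),
    subseeds = truth$subseeds,
    genotype_effects = truth$genotype_effects,
    environment_effects = truth$environment_effects,
    interaction = truth$interaction,
    block_effects = truth$block_effects
  )
  jsonlite::write_json(out, file, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(file)
}
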