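#' Joint ANOVA for a balanced MET
#'
#' Two-way genotype x environment ANOVA with replicates (blocks) nested in
#' environments, the first stage of an AMMI analysis. Genotype and
#' interaction mean squares are tested against the pooled residual;
#' environment is tested against the replicate-within-environment mean
#' square, the correct error stratum for an RCBD repeated over
#' environments. `pct_ss` expresses the E, G and GEI sums of squares as a
#' percentage of their three-way total.
#'
#' @param data A balanced [met_data] object.
#' @param trait Trait name.
#' @return Tibble of class `joint_anova` with columns `source`, `df`, `ss`,
#'   `ms`, `f`, `p`, `pct_ss`.
#' @export
joint_anova <- function(data, trait) {
  stopifnot(inherits(data, "met_data"))
  if (!trait %in% data$traits) stop("unknown trait '", trait, "'", call. = FALSE)
  stop_if_unbalanced(data)
  df <- data$data
  y <- df[[trait]]
  G <- unname(data$design["n_gen"]); E <- unname(data$design["n_env"])
  R <- unname(data$design["n_rep"])
  grand <- mean(y)

  gen_means <- tapply(y, df$GEN, mean)
  env_means <- tapply(y, df$ENV, mean)
  rep_means <- tapply(y, list(df$ENV, df$REP), mean)   # E x R
  cell_means <- tapply(y, list(df$GEN, df$ENV), mean)  # G x E

  ss_e <- G * R * sum((env_means - grand)^2)
  ss_r <- G * sum((sweep(rep_means, 1, rowMeans(rep_means)))^2)
  ss_g <- E * R * sum((gen_means - grand)^2)
  d <- sweep(sweep(cell_means, 1, rowMeans(cell_means)), 2, colMeans(cell_means)) + grand
  ss_gei <- R * sum(d^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_e - ss_r - ss_g - ss_gei

  dfs <- c(E - 1, E * (R - 1), G - 1, (G - 1) * (E - 1), E * (G - 1) * (R - 1))
  sss <- c(ss_e, ss_r, ss_g, ss_gei, ss_res)
  mss <- sss / dfs
  fs <- c(mss[1] / mss[2], NA, mss[3] / mss[5], mss[4] / mss[5], NA)
  ps <- stats::pf(fs, dfs, dfs[c(2, NA, 5, 5, NA)], lower.tail = FALSE)
  three_way <- ss_e + ss_g + ss_gei
  pct <- c(ss_e, NA, ss_g, ss_gei, NA) / three_way * 100

  out <- tibble::tibble(
    source = c("ENV", "REP(ENV)", "GEN", "GEN:ENV", "Residual"),
    df = as.integer(dfs), ss = sss, ms = mss, f = fs, p = ps, pct_ss = pct
  )
  class(out) <- c("joint_anova", class(out))
  attr(out, "trait") <- trait
  attr(out, "design") <- data$design
  out
}

#' AMMI decomposition of the interaction matrix
#'
#' Singular value decomposition of the double-centred matrix of cell means,
#' `d_ij = ybar_ij - ybar_i. - ybar_.j + ybar_..`, giving the multiplicative
#' part of the AMMI model `ybar_ij = ybar_i. + ybar_.j - ybar_.. +
#' sum_k lambda_k alpha_ik gamma_jk`. Scores are also reported in the
#' symmetric scaling `alpha_ik sqrt(lambda_k)` / `gamma_jk sqrt(lambda_k)`
#' conventional for biplots and for the weighted-average-of-absolute-scores
#' indices.
#'
#' @param means G x E matrix of cell means (e.g. from [ge_means()]).
#' @param n_rep Number of replicates behind each cell mean; used to put axis
#'   sums of squares on the plot basis (`SS_k = R * lambda_k^2`).
#' @return List of class `ammi` with elements `lambda` (singular values,
#'   length `K = min(G, E) - 1`), `alpha` (G x K), `gamma` (E x K),
#'   `ep` (proportion of interaction SS per axis), `scores_gen`,
#'   `scores_env` (symmetric scaling), `interaction` (the centred matrix),
#'   `n_rep`.
#' @export
ammi_decompose <- function(means, n_rep = 1) {
  means <- as.matrix(means)
  G <- nrow(means); E <- ncol(means)
  if (G < 2 || E < 2) stop("need at least 2 genotypes and 2 environments", call. = FALSE)
  if (any(!is.finite(means))) stop("cell-mean matrix has missing values", call. = FALSE)
  grand <- mean(means)
  d <- sweep(sweep(means, 1, rowMeans(means)), 2, colMeans(means)) + grand
  K <- min(G, E) - 1
  sv <- svd(d, nu = K, nv = K)
  lambda <- sv$d[seq_len(K)]
  lambda[lambda < 0] <- 0
  ss_axes <- lambda^2
  ep <- if (sum(ss_axes) > 0) ss_axes / sum(ss_axes) else rep(0, K)
  rl <- sqrt(lambda)
  structure(
    list(lambda = lambda,
         alpha = structure(sv$u, dimnames = list(rownames(means), paste0("PC", seq_len(K)))),
         gamma = structure(sv$v, dimnames = list(colnames(means), paste0("PC", seq_len(K)))),
         ep = ep,
         scores_gen = sweep(sv$u, 2, rl, "*"),
         scores_env = sweep(sv$v, 2, rl, "*"),
         interaction = d,
         n_rep = n_rep),
    class = "ammi"
  )
}

#' Significance of AMMI interaction axes (Gollob test)
#'
#' Tests each interaction principal component axis with Gollob degrees of
#' freedom `df_k = G + E - 1 - 2k`, axis sum of squares `R * lambda_k^2`,
#' and an F ratio against the pooled residual mean square from the joint
#' ANOVA.
#'
#' @param dec An `ammi` object.
#' @param residual_ms Pooled residual mean square (from [joint_anova()]).
#' @param residual_df Its degrees of freedom.
#' @param n_rep Replicates per cell mean (defaults to `dec$n_rep`).
#' @return Tibble with columns `axis`, `df`, `ss`, `ms`, `f`, `p`,
#'   `prop_ss`, `signif` (`**` p < 0.01, `*` p < 0.05).
#' @export
ipca_significance <- function(dec, residual_ms, residual_df, n_rep = dec$n_rep) {
  stopifnot(inherits(dec, "ammi"))
  if (!is.finite(residual_ms) || residual_ms <= 0) {
    stop("residual mean square must be positive", call. = FALSE)
  }
  G <- nrow(dec$alpha); E <- nrow(dec$gamma)
  K <- length(dec$lambda)
  k <- seq_len(K)
  dfk <- G + E - 1 - 2 * k
  ss <- n_rep * dec$lambda^2
  ms <- ss / dfk
  f <- ms / residual_ms
  p <- stats::pf(f, dfk, residual_df, lower.tail = FALSE)
  tibble::tibble(
    axis = paste0("PC", k), df = as.integer(dfk), ss = ss, ms = ms,
    f = f, p = p, prop_ss = dec$ep,
    signif = ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  )
}

#' Export AMMI scores in long form
#'
#' One row per entity and axis (`type` GEN or ENV), symmetric-scaled scores,
#' suitable for external biplotting.
#'
#' @param dec An `ammi` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ammi_scores_csv <- function(dec, file) {
  stopifnot(inherits(dec, "ammi"))
  K <- length(dec$lambda)
  gen <- tibble::tibble(
    entity = rep(rownames(dec$alpha), K),
    type = "GEN",
    axis = rep(paste0("PC", seq_len(K)), each = nrow(dec$alpha)),
    score = as.vector(dec$scores_gen)
  )
  env <- tibble::tibble(
    entity = rep(rownames(dec$gamma), K),
    type = "ENV",
    axis = rep(paste0("PC", seq_len(K)), each = nrow(dec$gamma)),
    score = as.vector(dec$scores_env)
  )
  readr::write_csv(dplyr::bind_rows(gen, env), file, progress = FALSE)
  invisible(file)
}
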