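#' WAASB: weighted average of absolute scores from the interaction BLUPs
#'
#' Singular value decomposition of the (double-centred) interaction BLUP
#' matrix; each genotype's score on axis k is the symmetric-scaled
#' `alpha_ik * sqrt(lambda_k)`, and
#' `WAASB_i = sum_k |score_ik| * EP_k / sum_k EP_k` where
#' `EP_k = lambda_k^2 / sum(lambda^2)` is the proportion of interaction
#' variation on axis k. All `K = min(G, E) - 1` axes enter by default.
#' Lower WAASB means more stable.
#'
#' @param ge_blups G x E matrix (e.g. from [ge_interaction_blups()]).
#' @param n_axes Number of axes to use (default all K).
#' @return Named numeric vector of per-genotype WAASB scores (>= 0).
#' @export
waasb_scores <- function(ge_blups, n_axes = NULL) {
  m <- as.matrix(ge_blups)
  if (length(m) == 0) stop("empty interaction matrix", call. = FALSE)
  dec <- ammi_decompose(m)
  K <- length(dec$lambda)
  if (is.null(n_axes)) n_axes <- K
  n_axes <- min(n_axes, K)
  if (sum(dec$ep) == 0) {
    return(stats::setNames(rep(0, nrow(m)), rownames(m)))
  }
  sc <- abs(dec$scores_gen[, seq_len(n_axes), drop = FALSE])
  ep <- dec$ep[seq_len(n_axes)]
  w <- as.numeric(sc %*% ep) / sum(ep)
  stats::setNames(w, rownames(m))
}

#' Rescale a vector linearly to \[0, 100\]
#'
#' Affine map of a vector onto `[0, 100]`. With `direction =
#' "larger-better"` the maximum maps to 100; with `"smaller-better"` the
#' minimum maps to 100 (used for stability scores, where smaller is
#' better).
#'
#' @param values Numeric vector with `max > min`.
#' @param direction `"larger-better"` or `"smaller-better"`.
#' @return Numeric vector in `[0, 100]`.
#' @export
rescale_linear <- function(values, direction = c("larger-better", "smaller-better")) {
  direction <- match.arg(direction)
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot rescale a constant vector", call. = FALSE)
  out <- (values - rng[1]) / diff(rng) * 100
  if (direction == "smaller-better") out <- 100 - out
  out
}

#' WAASBY: weighted blend of rescaled performance and stability
#'
#' `WAASBY_i = (rY_i * theta_y + rW_i * theta_s) / (theta_y + theta_s)`,
#' where `rY` is the trait mean rescaled to `[0, 100]` (larger better) and
#' `rW` the WAASB score rescaled to `[0, 100]` (smaller WAASB better). The
#' default weights 65/35 prioritise mean performance over stability.
#'
#' @param r_y,r_w Rescaled performance and stability vectors (equal length).
#' @param theta_y,theta_s Non-negative weights, not both zero.
#' @return Numeric vector of WAASBY values.
#' @export
waasby_index <- function(r_y, r_w, theta_y = 65, theta_s = 35) {
  if (length(r_y) != length(r_w)) stop("rY and rW lengths differ", call. = FALSE)
  if (theta_y < 0 || theta_s < 0 || theta_y + theta_s == 0) {
    stop("weights must be >= 0 and not both zero", call. = FALSE)
  }
  (r_y * theta_y + r_w * theta_s) / (theta_y + theta_s)
}

#' Classify genotypes into mean-vs-WAASB quadrants
#'
#' Splits the mean-performance axis at the grand mean of the trait and the
#' stability axis at the mean WAASB score. Quadrant I: low mean, high WAASB
#' (unstable, poor); II: high mean, high WAASB (good but unstable); III:
#' low mean, low WAASB (stable but poor); IV: high mean, low WAASB (the
#' breeder's target: well adapted and high performing). Points exactly on a
#' split line are assigned to the high-mean / low-WAASB side.
#'
#' @param means Per-genotype trait means.
#' @param waasb Per-genotype WAASB scores (same length/order).
#' @return Character vector of labels `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_quadrants <- function(means, waasb) {
  if (length(means) != length(waasb)) stop("length mismatch", call. = FALSE)
  high_mean <- means >= mean(means)
  high_waasb <- waasb > mean(waasb)
  ifelse(high_waasb,
         ifelse(high_mean, "II", "I"),
         ifelse(high_mean, "IV", "III"))
}

#' Per-trait stability scores (WAASB, WAASBY, quadrants)
#'
#' Convenience wrapper running the full per-trait stability stage: mixed
#' model fit, interaction BLUPs, WAASB, `[0, 100]` rescaling of means and
#' WAASB, the WAASBY blend and quadrant classification.
#'
#' @param data A balanced [met_data] object.
#' @param trait Trait name.
#' @param theta_y,theta_s WAASBY weights (default 65/35).
#' @param fit Optionally, a pre-computed `met_mixed_fit` for this trait.
#' @return Tibble of class `stability_scores` with columns `GEN`, `trait`,
#'   `mean`, `waasb`, `r_y`, `r_w`, `waasby`, `quadrant`.
#' @export
stability_scores <- function(data, trait, theta_y = 65, theta_s = 35, fit = NULL) {
  if (is.null(fit)) fit <- fit_mixed_model(data, trait)
  stopifnot(inherits(fit, "met_mixed_fit"))
  df <- data$data
  gens <- unique(df$GEN)
  means <- as.numeric(tapply(df[[trait]], factor(df$GEN, gens), mean))
  w <- waasb_scores(ge_interaction_blups(fit))
  w <- as.numeric(w[gens])
  out <- tibble::tibble(
    GEN = gens,
    trait = trait,
    mean = means,
    waasb = w,
    r_y = rescale_linear(means, "larger-better"),
    r_w = rescale_linear(w, "smaller-better"),
    quadrant = classify_quadrants(means, w)
  )
  out$waasby <- waasby_index(out$r_y, out$r_w, theta_y, theta_s)
  out <- out[, c("GEN", "trait", "mean", "waasb", "r_y", "r_w", "waasby", "quadrant")]
  class(out) <- c("stability_scores", class(out))
  out
}
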