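#' Assemble the genotype x trait WAASBY table
#'
#' Binds per-trait stability scores into the genotype x trait matrix of
#' WAASBY values that the multi-trait stability index is computed from.
#'
#' @param scores Named list of `stability_scores` tibbles (one per trait,
#'   from [stability_scores()]), all over the same genotype set.
#' @return Numeric matrix (genotypes x traits).
#' @export
build_waasby_table <- function(scores) {
  stopifnot(length(scores) >= 1)
  gens <- scores[[1]]$GEN
  traits <- vapply(scores, function(s) s$trait[1], character(1))
  mat <- matrix(NA_real_, length(gens), length(scores),
                dimnames = list(gens, traits))
  for (k in seq_along(scores)) {
    s <- scores[[k]]
    if (!setequal(s$GEN, gens) || nrow(s) != length(gens)) {
      off <- c(setdiff(gens, s$GEN), setdiff(s$GEN, gens))
      stop("genotype set mismatch for trait '", traits[k], "' (e.g. ",
           off[1], ")", call. = FALSE)
    }
    mat[, k] <- s$waasby[match(gens, s$GEN)]
  }
  mat
}

#' Factor model of a genotype x trait table
#'
#' Standardizes the columns (sample SD), eigen-decomposes their correlation
#' matrix, retains the factors with eigenvalue > 1 (Kaiser rule), rotates
#' the retained loadings by varimax, and computes factor scores by the
#' regression (Thomson) method `F = Z %*% solve(R) %*% L` on the rotated
#' loadings. The ideotype — every trait at the maximum rescaled value of
#' 100 — is standardized with the observed column means/SDs and scored
#' identically.
#'
#' @param table Genotype x trait numeric matrix (e.g. from
#'   [build_waasby_table()]).
#' @param n_factors Optional override of the Kaiser retention count.
#' @param ideotype_value Trait value defining the ideotype (default 100,
#'   the WAASBY maximum; all traits are treated as larger-better since the
#'   WAASBY rescaling already encodes each trait's sense).
#' @return A list of class `factor_model`: `correlation`, `eigenvalues`,
#'   `n_factors`, `loadings` (rotated, traits x f), `rotation`,
#'   `communalities`, `scores` (genotypes x f), `ideotype_scores`,
#'   `variance_explained` (per retained factor, % of total).
#' @export
fit_factor_model <- function(table, n_factors = NULL, ideotype_value = 100) {
  X <- as.matrix(table)
  if (ncol(X) < 3) stop("need at least 3 traits for a factor model", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("trait '", colnames(X)[which(sdv == 0)[1]], "' is constant", call. = FALSE)
  }
  Z <- scale(X, center = mu, scale = sdv)
  R <- stats::cor(X)
  if (rcond(R) < 1e-12) stop("correlation matrix is numerically singular", call. = FALSE)
  eig <- eigen(R, symmetric = TRUE)
  f <- if (is.null(n_factors)) sum(eig$values > 1) else as.integer(n_factors)
  if (f < 1) {
    stop("no eigenvalue exceeds 1; supply n_factors explicitly", call. = FALSE)
  }
  if (nrow(X) < f + 1) stop("need more genotypes than retained factors", call. = FALSE)
  L <- eig$vectors[, seq_len(f), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(f)]), nrow = f)
  if (f > 1) {
    rot <- stats::varimax(L)
    L_rot <- L %*% rot$rotmat
    rotmat <- rot$rotmat
  } else {
    L_rot <- L
    rotmat <- diag(1)
  }
  dimnames(L_rot) <- list(colnames(X), paste0("FA", seq_len(f)))
  Rinv <- solve(R)
  scores <- Z %*% Rinv %*% L_rot
  z_ideo <- (rep(ideotype_value, ncol(X)) - mu) / sdv
  ideo <- as.numeric(z_ideo %*% Rinv %*% L_rot)
  structure(
    list(correlation = R,
         eigenvalues = eig$values,
         n_factors = f,
         loadings = L_rot,
         rotation = rotmat,
         communalities = rowSums(L_rot^2),
         scores = scores,
         ideotype_scores = stats::setNames(ideo, colnames(L_rot)),
         variance_explained = eig$values[seq_len(f)] / ncol(X) * 100),
    class = "factor_model"
  )
}

#' Multi-trait stability index (MTSI)
#'
#' Euclidean distance, in rotated factor-score space, between each genotype
#' and the ideotype: `MTSI_i = sqrt(sum_f (F_if - F_f)^2)`. Lower values
#' indicate genotypes closer to the ideal of maximal WAASBY on every trait.
#'
#' @param model A `factor_model` from [fit_factor_model()].
#' @return Tibble of class `mtsi_result` with columns `GEN`, `mtsi`, `rank`
#'   (ascending, 1 = closest to the ideotype), carrying the model as
#'   attribute `model`.
#' @export
mtsi_scores <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  dev <- sweep(model$scores, 2, model$ideotype_scores)
  d <- sqrt(rowSums(dev^2))
  out <- tibble::tibble(
    GEN = rownames(model$scores),
    mtsi = as.numeric(d)
  )
  out$rank <- rank(out$mtsi, ties.method = "first")
  class(out) <- c("mtsi_result", class(out))
  attr(out, "model") <- model
  out
}

#' Select genotypes at a given intensity
#'
#' The `floor(intensity * G)` genotypes with the lowest MTSI; ties at the
#' cut are broken by label order with a warning.
#'
#' @param result An `mtsi_result` from [mtsi_scores()].
#' @param intensity Selection intensity in (0, 1], default 0.15.
#' @return Character vector of selected genotype labels, best first.
#' @export
select_genotypes <- function(result, intensity = 0.15) {
  stopifnot(inherits(result, "mtsi_result"))
  if (intensity <= 0 || intensity > 1) stop("intensity must be in (0, 1]", call. = FALSE)
  n_sel <- floor(intensity * nrow(result))
  if (n_sel < 1) {
    stop("selection intensity ", intensity, " selects no genotypes from ",
         nrow(result), call. = FALSE)
  }
  ord <- order(result$mtsi, result$GEN)
  cut_val <- result$mtsi[ord][n_sel]
  if (sum(result$mtsi == cut_val) > 1) {
    warning("tie at the selection cut broken by genotype label order")
  }
  result$GEN[ord][seq_len(n_sel)]
}

#' Selection differential and expected gain per trait
#'
#' For each trait: `Xo` is the mean over all genotypes, `Xs` the mean over
#' the selected set, `SD% = (Xs - Xo) / Xo * 100` and the expected genetic
#' gain `SG% = SD% * h2_mean` (heritability of genotype means).
#'
#' @param means Genotype x trait table of means (data frame with `GEN`
#'   column, e.g. from [genotype_means()], or a named-row matrix).
#' @param selected Character vector of selected genotype labels.
#' @param h2_mean Named numeric vector of per-trait heritabilities of means.
#' @return Tibble with columns `trait`, `Xo`, `Xs`, `sd_pct`, `sg_pct`,
#'   `h2_mean`, `sense`.
#' @export
selection_response <- function(means, selected, h2_mean) {
  if (length(selected) == 0) stop("selected set is empty", call. = FALSE)
  tbl <- tibble::as_tibble(means)
  if (!"GEN" %in% names(tbl)) {
    tbl <- tibble::add_column(tibble::as_tibble(as.data.frame(means)),
                              GEN = rownames(as.matrix(means)), .before = 1)
  }
  traits <- setdiff(names(tbl), "GEN")
  missing_h2 <- setdiff(traits, names(h2_mean))
  if (length(missing_h2) > 0) {
    stop("no h2_mean supplied for trait(s): ",
         paste(missing_h2, collapse = ", "), call. = FALSE)
  }
  missing_gen <- setdiff(selected, tbl$GEN)
  if (length(missing_gen) > 0) {
    stop("selected genotype(s) not in means table: ",
         paste(missing_gen, collapse = ", "), call. = FALSE)
  }
  sel <- tbl$GEN %in% selected
  out <- lapply(traits, function(tr) {
    xo <- mean(tbl[[tr]])
    xs <- mean(tbl[[tr]][sel])
    sd_pct <- selection_differential(xs, xo)
    tibble::tibble(trait = tr, Xo = xo, Xs = xs, sd_pct = sd_pct,
                   sg_pct = sd_pct * h2_mean[[tr]], h2_mean = h2_mean[[tr]],
                   sense = "increase")
  })
  dplyr::bind_rows(out)
}

#' Selection differential in percent
#'
#' `SD% = (Xs - Xo) / Xo * 100`: the percent superiority of the selected
#' genotypes' mean `Xs` over the population mean `Xo` before selection.
#'
#' @param xs Mean of the selected genotypes.
#' @param xo Population mean before selection (nonzero).
#' @return Numeric scalar (percent).
#' @export
selection_differential <- function(xs, xo) {
  if (any(xo == 0)) stop("population mean is zero", call. = FALSE)
  (xs - xo) / xo * 100
}

#' Per-factor contributions to each genotype's MTSI
#'
#' Each factor's share of the squared ideotype distance
#' `sum_f (F_if - F_f)^2`; shares sum to one per genotype. A genotype
#' exactly at the ideotype (MTSI 0) has undefined shares, reported as
#' uniform with `undefined = TRUE`.
#'
#' @param model A `factor_model`.
#' @param result The matching `mtsi_result`.
#' @param selected Optional subset of genotype labels to report (default
#'   all).
#' @return Tibble with columns `GEN`, one `FA*` column per factor,
#'   `undefined`.
#' @export
factor_contributions <- function(model, result, selected = NULL) {
  stopifnot(inherits(model, "factor_model"), inherits(result, "mtsi_result"))
  dev2 <- sweep(model$scores, 2, model$ideotype_scores)^2
  tot <- rowSums(dev2)
  undef <- tot == 0
  shares <- dev2 / ifelse(tot == 0, 1, tot)
  shares[undef, ] <- 1 / ncol(dev2)
  out <- tibble::as_tibble(shares)
  names(out) <- colnames(model$loadings)
  out <- tibble::add_column(out, GEN = rownames(model$scores), .before = 1)
  out$undefined <- undef
  if (!is.null(selected)) out <- out[out$GEN %in% selected, , drop = FALSE]
  out
}
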