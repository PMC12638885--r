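#' Yield relative to the environmental maximum (YREM)
#'
#' For each environment, divides every genotype's cell mean by the best cell
#' mean in that environment: `Y_ij = X_ij / MAX_j`. YREM removes the
#' environmental main effect, so the per-genotype average across
#' environments measures how much yield a genotype loses to crossover
#' genotype-by-environment interaction; `1 - YREM` is that crossover loss.
#' A genotype that wins every environment has average YREM 1 and loss 0.
#'
#' @param yields G x E matrix of genotype-by-environment cell means (e.g.
#'   from [ge_means()]); all values must be > 0.
#' @return A list of class `yrem_result`: `yrem` (G x E matrix in (0, 1]),
#'   `average` (named vector), `loss` (`1 - average`), `mean_yield` (row
#'   means of `yields`) and `rank` (dense ranks, 1 = best; see
#'   [rank_by_yrem()] for tie rules).
#' @export
yrem_scores <- function(yields) {
  yields <- as.matrix(yields)
  if (is.null(rownames(yields))) {
    rownames(yields) <- paste0("G", seq_len(nrow(yields)))
  }
  if (is.null(colnames(yields))) {
    colnames(yields) <- paste0("E", seq_len(ncol(yields)))
  }
  if (any(!is.finite(yields)) || any(yields <= 0)) {
    bad <- which(!(is.finite(yields) & yields > 0), arr.ind = TRUE)[1, ]
    stop("yields must be positive and finite (offending cell: row ",
         bad[1], ", column ", bad[2], ")", call. = FALSE)
  }
  col_max <- apply(yields, 2, max)
  yr <- sweep(yields, 2, col_max, "/")
  avg <- rowMeans(yr)
  res <- structure(
    list(yrem = yr, average = avg, loss = 1 - avg,
         mean_yield = rowMeans(yields)),
    class = "yrem_result"
  )
  ranked <- rank_by_yrem(res)
  res$rank <- stats::setNames(ranked$rank[match(names(avg), ranked$GEN)],
                              names(avg))
  res
}

#' Rank genotypes by average YREM
#'
#' Descending by average YREM; ties broken by mean yield (higher first),
#' then by genotype label order.
#'
#' @param res A `yrem_result` from [yrem_scores()].
#' @return Tibble with columns `GEN`, `average_yrem`, `loss`, `mean_yield`,
#'   `rank`, sorted best first.
#' @export
rank_by_yrem <- function(res) {
  stopifnot(inherits(res, "yrem_result"))
  gens <- names(res$average)
  ord <- order(-res$average, -res$mean_yield, seq_along(gens))
  tibble::tibble(
    GEN = gens[ord],
    average_yrem = res$average[ord],
    loss = res$loss[ord],
    mean_yield = res$mean_yield[ord],
    rank = seq_along(ord)
  )
}

#' Export YREM results as CSV
#'
#' One row per genotype: per-environment YREM, average, crossover loss and
#' rank.
#'
#' @param res A `yrem_result`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_yrem_csv <- function(res, file) {
  stopifnot(inherits(res, "yrem_result"))
  ranked <- rank_by_yrem(res)
  out <- tibble::as_tibble(res$yrem, rownames = "GEN")
  out$average_yrem <- res$average
  out$loss <- res$loss
  out$rank <- ranked$rank[match(out$GEN, ranked$GEN)]
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}
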