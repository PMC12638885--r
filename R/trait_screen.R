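#' Pearson correlations among trait genotype means
#'
#' Computes the pairwise Pearson correlation matrix of a genotype x trait
#' table of means (one row per genotype, one column per trait) together with
#' two-sided p-values from the t transform with n - 2 degrees of freedom.
#' Correlations are computed on genotype means across environments, the
#' standard screen used before multi-trait stability analysis.
#'
#' @param means Data frame or matrix of genotype means; an optional `GEN`
#'   column is carried as row identity and excluded from the correlations.
#' @return A list of class `trait_cor` with elements `traits`, `r`, `p`, `n`.
#' @export
trait_correlations <- function(means) {
  tbl <- tibble::as_tibble(means)
  if ("GEN" %in% names(tbl)) tbl <- tbl[setdiff(names(tbl), "GEN")]
  X <- as.matrix(tbl)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 3) stop("need at least 3 genotypes", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("trait '", colnames(X)[which(sds == 0)[1]], "' has zero variance",
         call. = FALSE)
  }
  r <- stats::cor(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(traits = colnames(X), r = r, p = p, n = n),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  cat(sprintf("<trait_cor> %d traits, n = %d genotypes\n", length(x$traits), x$n))
  stars <- ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", ""))
  m <- matrix(paste0(format(round(x$r, digits)), stars),
              nrow(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  invisible(x)
}

#' Select traits associated with a focal trait
#'
#' Keeps the traits whose correlation with the focal trait is positive and
#' significant at `alpha` (two-sided), plus the focal trait itself, plus any
#' forced keeps. A forced keep covers the common judgment call of retaining
#' an agronomically relevant trait (e.g. maturity) whose association with
#' yield is positive but not significant.
#'
#' @param cm A `trait_cor` object from [trait_correlations()].
#' @param focal Focal trait name (typically yield).
#' @param alpha Significance level, default 0.05.
#' @param keep Character vector of traits to retain regardless of the test.
#' @return Character vector of selected traits, in the table's trait order.
#' @export
select_yield_traits <- function(cm, focal, alpha = 0.05, keep = character()) {
  stopifnot(inherits(cm, "trait_cor"))
  if (!focal %in% cm$traits) {
    stop("focal trait '", focal, "' not in correlation matrix", call. = FALSE)
  }
  unknown <- setdiff(keep, cm$traits)
  if (length(unknown) > 0) {
    stop("unknown keep trait(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- cm$r[, focal]
  p <- cm$p[, focal]
  pass <- cm$traits[r > 0 & p < alpha]
  sel <- union(union(pass, keep), focal)
  cm$traits[cm$traits %in% sel]
}

#' Export a correlation matrix with significance flags
#'
#' Writes a CSV correlogram-style table: `r` values formatted with `*`
#' (p < 0.05) or `**` (p < 0.01).
#'
#' @param cm A `trait_cor` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_correlation_csv <- function(cm, file) {
  stopifnot(inherits(cm, "trait_cor"))
  stars <- ifelse(cm$p < 0.01, "**", ifelse(cm$p < 0.05, "*", ""))
  diag(stars) <- ""
  m <- matrix(paste0(formatC(cm$r, format = "f", digits = 3), stars),
              nrow(cm$r), dimnames = dimnames(cm$r))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, trait = cm$traits, .before = 1)
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}
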