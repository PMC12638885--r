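#' Construct a MET dataset from long-format plot records
#'
#' A `met_data` object is the single source of truth for all downstream
#' analyses: one row per plot (environment x genotype x replicate), one
#' numeric column per trait. The design constants (number of genotypes G,
#' environments E, replicates R) are inferred from the labels.
#'
#' @param records A data frame with columns `ENV`, `GEN`, `REP` and one
#'   numeric column per trait.
#' @param traits Character vector of trait column names, in the order they
#'   should be carried through the pipeline. Defaults to every column other
#'   than `ENV`/`GEN`/`REP`.
#'
#' @return An object of class `met_data`: a list with elements `data`
#'   (tibble of plot records), `traits`, and `design` (named integer vector
#'   `n_gen`, `n_env`, `n_rep`).
#'
#' @details Trait values must be finite. Balance (exactly one record per
#'   environment x genotype x replicate cell) is *reported* by
#'   [validate_design()]; the constructor only rejects duplicated records,
#'   so that incomplete data can still be inspected. All model-fitting
#'   functions require a balanced design.
#' @export
met_data <- function(records, traits = NULL) {
  records <- tibble::as_tibble(records)
  required <- c("ENV", "GEN", "REP")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(traits)) {
    traits <- setdiff(names(records), required)
  }
  missing_traits <- setdiff(traits, names(records))
  if (length(missing_traits) > 0) {
    stop("missing trait column(s): ", paste(missing_traits, collapse = ", "),
         call. = FALSE)
  }
  if (length(traits) == 0) {
    stop("no trait columns found", call. = FALSE)
  }
  for (tr in traits) {
    v <- records[[tr]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("trait '", tr, "' is not numeric (first offending row: ",
           if (length(bad)) bad[1] else NA, ")", call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop("trait '", tr, "' contains non-finite values (first offending row: ",
           which(!is.finite(v))[1], ")", call. = FALSE)
    }
  }
  records$ENV <- as.character(records$ENV)
  records$GEN <- as.character(records$GEN)
  records$REP <- as.character(records$REP)

  key <- paste(records$ENV, records$GEN, records$REP, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop("duplicate plot record(s), e.g. ENV=", d$ENV[1], " GEN=", d$GEN[1],
         " REP=", d$REP[1], call. = FALSE)
  }

  design <- c(
    n_gen = length(unique(records$GEN)),
    n_env = length(unique(records$ENV)),
    n_rep = length(unique(records$REP))
  )
  structure(
    list(
      data = records[, c(required, traits)],
      traits = traits,
      design = design
    ),
    class = "met_data"
  )
}

#' @export
print.met_data <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "<met_data> %d genotypes x %d environments x %d replicates (%d records)\n",
    d["n_gen"], d["n_env"], d["n_rep"], nrow(x$data)
  ))
  cat("traits:", paste(x$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format MET CSV
#'
#' Reads plot-level trial records from a CSV with header columns `ENV`,
#' `GEN`, `REP` followed by one numeric column per trait (UTF-8, `.` as the
#' decimal separator).
#'
#' @param file Path or connection passed to [readr::read_csv()].
#' @param traits Optional character vector restricting/ordering the trait
#'   columns; defaults to every non-design column.
#' @return A [met_data] object.
#' @export
read_met_csv <- function(file, traits = NULL) {
  raw <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  met_data(raw, traits = traits)
}

#' Write a MET dataset to CSV
#'
#' Emits the same dialect [read_met_csv()] reads, so a write/read round trip
#' reproduces the dataset.
#'
#' @param data A [met_data] object.
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_met_csv <- function(data, file) {
  stopifnot(inherits(data, "met_data"))
  readr::write_csv(data$data, file, progress = FALSE)
  invisible(file)
}

#' Check balance of a MET design
#'
#' Reports the inferred design, missing cells and duplicates. A design is
#' balanced when every (environment, genotype, replicate) combination occurs
#' exactly once. Downstream closed forms (EMS, balanced REML, shrinkage
#' BLUPs) require balance and refuse unbalanced data.
#'
#' @param data A [met_data] object.
#' @return A list of class `met_balance` with elements `balanced` (logical),
#'   `n_gen`, `n_env`, `n_rep`, `n_records`, `missing_cells` (tibble) and
#'   `duplicates` (tibble).
#' @export
validate_design <- function(data) {
  stopifnot(inherits(data, "met_data"))
  df <- data$data
  envs <- unique(df$ENV); gens <- unique(df$GEN); reps <- unique(df$REP)
  full <- tidyr::expand_grid(ENV = envs, GEN = gens, REP = reps)
  counts <- dplyr::count(df, .data$ENV, .data$GEN, .data$REP)
  joined <- dplyr::left_join(full, counts, by = c("ENV", "GEN", "REP"))
  joined$n[is.na(joined$n)] <- 0L
  missing_cells <- joined[joined$n == 0L, c("ENV", "GEN", "REP")]
  duplicates <- joined[joined$n > 1L, ]
  structure(
    list(
      balanced = nrow(missing_cells) == 0 && nrow(duplicates) == 0,
      n_gen = length(gens),
      n_env = length(envs),
      n_rep = length(reps),
      n_records = nrow(df),
      missing_cells = tibble::as_tibble(missing_cells),
      duplicates = tibble::as_tibble(duplicates)
    ),
    class = "met_balance"
  )
}

#' @export
print.met_balance <- function(x, ...) {
  cat(sprintf("<met_balance> %s: %d x %d x %d, %d records, %d missing, %d duplicated\n",
              if (x$balanced) "balanced" else "UNBALANCED",
              x$n_gen, x$n_env, x$n_rep, x$n_records,
              nrow(x$missing_cells), nrow(x$duplicates)))
  invisible(x)
}

stop_if_unbalanced <- function(data) {
  rep <- validate_design(data)
  if (!rep$balanced) {
    stop("design is not balanced (", nrow(rep$missing_cells), " missing, ",
         nrow(rep$duplicates), " duplicated cells); balanced closed forms do not apply",
         call. = FALSE)
  }
  invisible(rep)
}

#' Genotype-by-environment cell means for one trait
#'
#' Averages plot records over replicates, producing the G x E matrix of cell
#' means consumed by the AMMI decomposition and YREM.
#'
#' @param data A balanced [met_data] object.
#' @param trait Trait name.
#' @return Numeric matrix (genotypes as rows, environments as columns) with
#'   attribute `trait`.
#' @export
ge_means <- function(data, trait) {
  stopifnot(inherits(data, "met_data"))
  if (!trait %in% data$traits) {
    stop("unknown trait '", trait, "'", call. = FALSE)
  }
  stop_if_unbalanced(data)
  df <- data$data
  gens <- unique(df$GEN); envs <- unique(df$ENV)
  m <- tapply(df[[trait]], list(factor(df$GEN, gens), factor(df$ENV, envs)), mean)
  m <- matrix(as.numeric(m), nrow = length(gens), ncol = length(envs),
              dimnames = list(gens, envs))
  attr(m, "trait") <- trait
  m
}

#' Summary statistics of a vector of trait means
#'
#' Mean, minimum, maximum, sample standard deviation (n - 1 denominator) and
#' coefficient of variation (CV% = sd / mean x 100), the footer rows of a
#' genotype-mean table.
#'
#' @param values Numeric vector, length >= 2.
#' @return One-row tibble with columns `mean`, `minimum`, `maximum`, `sd`,
#'   `cv_percent`.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values))) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("mean is zero: CV is undefined", call. = FALSE)
  s <- stats::sd(values)
  tibble::tibble(
    mean = m,
    minimum = min(values),
    maximum = max(values),
    sd = s,
    cv_percent = s / m * 100
  )
}

#' Genotype means across environments for every trait
#'
#' @param data A balanced [met_data] object.
#' @return Tibble with column `GEN` and one column per trait holding the
#'   genotype means over all environments and replicates.
#' @export
genotype_means <- function(data) {
  stopifnot(inherits(data, "met_data"))
  df <- data$data
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$GEN),
    dplyr::across(dplyr::all_of(data$traits), mean),
    .groups = "drop"
  )
  out[match(unique(df$GEN), out$GEN), , drop = FALSE]
}
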