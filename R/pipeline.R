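#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. Either `input` (a path to
#' a long-format MET CSV) or `synth` (a [synth_config]) must be supplied.
#'
#' @param input Path to a MET CSV, or `NULL` to simulate.
#' @param synth A [synth_config], used when `input` is `NULL`.
#' @param traits Trait columns to read (default: all).
#' @param focal Focal trait for the correlation screen and YREM (default
#'   `"YD"` if present, else the first trait).
#' @param alpha Significance level of the trait screen (default 0.05).
#' @param keep Traits retained in the screen regardless of significance.
#' @param theta_y,theta_s WAASBY weights (default 65/35).
#' @param intensity Selection intensity (default 0.15).
#' @param out_dir Output directory for the stage CSVs and manifest.
#' @param seed Seed recorded in the manifest (the synthetic generator uses
#'   its own config seed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synth = NULL, traits = NULL,
                            focal = NULL, alpha = 0.05, keep = character(),
                            theta_y = 65, theta_s = 35,
                            intensity = 0.15, out_dir = tempfile("metstab_"),
                            seed = 1L) {
  if (is.null(input) && is.null(synth)) {
    stop("supply either an input CSV path or a synth_config", call. = FALSE)
  }
  if (theta_y < 0 || theta_s < 0 || theta_y + theta_s <= 0) {
    stop("WAASBY weights must be >= 0 with a positive sum", call. = FALSE)
  }
  if (intensity <= 0 || intensity > 1) stop("intensity must be in (0, 1]", call. = FALSE)
  structure(
    list(input = input, synth = synth, traits = traits, focal = focal,
         alpha = alpha, keep = keep, theta_y = theta_y, theta_s = theta_s,
         intensity = intensity, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full MET stability pipeline
#'
#' Executes the analysis sequence — correlation screen, YREM on the focal
#' trait, joint ANOVA + AMMI, REML/BLUP with genetic parameters, WAASB /
#' WAASBY, and MTSI selection with selection differential and gain — and
#' writes one CSV per stage plus a JSON run manifest to `cfg$out_dir`.
#' Deterministic given the same configuration and seed.
#'
#' @param cfg A [pipeline_config].
#' @return A list of class `met_pipeline` with the in-memory stage results:
#'   `data`, `correlations`, `selected_traits`, `yrem`, `anova` (per
#'   trait), `ammi` (per trait), `fits` (per trait), `gvc` (tibble),
#'   `stability` (tibble), `mtsi`, `selected`, `response`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  data <- if (!is.null(cfg$input)) {
    read_met_csv(cfg$input, traits = cfg$traits)
  } else {
    generate_met(cfg$synth)$data
  }
  stop_if_unbalanced(data)
  write_met_csv(data, file.path(cfg$out_dir, "met_data.csv"))

  focal <- cfg$focal
  if (is.null(focal)) focal <- if ("YD" %in% data$traits) "YD" else data$traits[1]

  gmeans <- genotype_means(data)

  # correlation screen (needs >= 3 traits to be meaningful)
  if (length(data$traits) >= 3) {
    cm <- trait_correlations(gmeans)
    selected_traits <- select_yield_traits(cm, focal, alpha = cfg$alpha,
                                           keep = cfg$keep)
    write_correlation_csv(cm, file.path(cfg$out_dir, "correlations.csv"))
  } else {
    cm <- NULL
    selected_traits <- data$traits
  }

  # YREM on the focal trait
  yr <- yrem_scores(ge_means(data, focal))
  write_yrem_csv(yr, file.path(cfg$out_dir, "yrem.csv"))

  anovas <- list(); ammis <- list(); fits <- list()
  gvc_rows <- list(); stab_rows <- list()
  for (tr in selected_traits) {
    an <- joint_anova(data, tr)
    anovas[[tr]] <- an
    dec <- ammi_decompose(ge_means(data, tr), n_rep = data$design["n_rep"])
    res_ms <- an$ms[an$source == "Residual"]
    res_df <- an$df[an$source == "Residual"]
    ammis[[tr]] <- list(decomposition = dec,
                        axes = ipca_significance(dec, res_ms, res_df))
    fit <- fit_mixed_model(data, tr)
    fits[[tr]] <- fit
    gvc_rows[[tr]] <- dplyr::bind_cols(
      tibble::tibble(trait = tr,
                     sigma2_g = fit$components$sigma2_g,
                     sigma2_gei = fit$components$sigma2_gei,
                     sigma2_e = fit$components$sigma2_e),
      genetic_parameters(fit$components),
      lrt_random_terms(data, tr) |>
        dplyr::select("term", "statistic") |>
        tidyr::pivot_wider(names_from = "term", values_from = "statistic",
                           names_prefix = "lrt_")
    )
    stab_rows[[tr]] <- stability_scores(data, tr, cfg$theta_y, cfg$theta_s,
                                        fit = fit)
  }
  anova_tbl <- dplyr::bind_rows(lapply(names(anovas), function(tr) {
    dplyr::mutate(tibble::as_tibble(anovas[[tr]]), trait = tr, .before = 1)
  }))
  readr::write_csv(anova_tbl, file.path(cfg$out_dir, "joint_anova.csv"),
                   progress = FALSE)
  gvc <- dplyr::bind_rows(gvc_rows)
  readr::write_csv(gvc, file.path(cfg$out_dir, "genetic_parameters.csv"),
                   progress = FALSE)
  stability <- dplyr::bind_rows(stab_rows)
  readr::write_csv(stability, file.path(cfg$out_dir, "stability.csv"),
                   progress = FALSE)

  # multi-trait selection
  waasby_tbl <- build_waasby_table(stab_rows)
  model <- fit_factor_model(waasby_tbl)
  mtsi <- mtsi_scores(model)
  selected <- select_genotypes(mtsi, cfg$intensity)
  h2 <- stats::setNames(gvc$h2_mean, gvc$trait)
  response <- selection_response(gmeans[, c("GEN", selected_traits)],
                                 selected, h2)
  readr::write_csv(mtsi, file.path(cfg$out_dir, "mtsi.csv"), progress = FALSE)
  readr::write_csv(response, file.path(cfg$out_dir, "selection_response.csv"),
                   progress = FALSE)
  eig_tbl <- tibble::tibble(
    component = paste0("PC", seq_along(model$eigenvalues)),
    eigenvalue = model$eigenvalues,
    variance_pct = model$eigenvalues / length(model$eigenvalues) * 100,
    cumulative_pct = cumsum(model$eigenvalues / length(model$eigenvalues) * 100)
  )
  readr::write_csv(eig_tbl, file.path(cfg$out_dir, "factor_eigenvalues.csv"),
                   progress = FALSE)

  manifest <- list(
    package = "metstab",
    version = as.character(utils::packageVersion("metstab")),
    seed = cfg$seed,
    input = if (is.null(cfg$input)) "synthetic" else cfg$input,
    synth = if (is.null(cfg$synth)) NULL else
      cfg$synth[setdiff(names(cfg$synth), "trait_cor")],
    focal = focal,
    alpha = cfg$alpha,
    keep = cfg$keep,
    theta_y = cfg$theta_y, theta_s = cfg$theta_s,
    intensity = cfg$intensity,
    selected_traits = selected_traits,
    selected_genotypes = selected,
    decisions = list(
      waasb_axes = "all K axes",
      quadrant_y_split = "mean of WAASB scores",
      factor_scores = "regression (Thomson) method on varimax-rotated loadings",
      lrt_reference = "chi-squared df 1 (conservative at the boundary)",
      selection_count = "floor(intensity * G)"
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(
    list(data = data, correlations = cm, selected_traits = selected_traits,
         yrem = yr, anova = anovas, ammi = ammis, fits = fits, gvc = gvc,
         stability = stability, mtsi = mtsi, selected = selected,
         response = response, out_dir = cfg$out_dir),
    class = "met_pipeline"
  )
}

#' @export
print.met_pipeline <- function(x, ...) {
  cat("<met_pipeline>\n")
  cat("  traits analysed:", paste(x$selected_traits, collapse = ", "), "\n")
  cat("  selected genotypes:", paste(x$selected, collapse = ", "), "\n")
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}
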