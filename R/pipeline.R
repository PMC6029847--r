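## End-to-end study orchestration: the cohort (tissue) analysis and the
## dose-ranging in vitro analysis, composed from the module functions,
## fully seeded, with tidy TSV reports and a JSON manifest.

#' Study configuration
#'
#' @param cohort A cohort data.frame, a path to a cohort TSV, or a
#'   [cohort_spec()] to synthesise (requires `seed`).
#' @param invitro A long data.frame (`donor`, `replicate`, `dose_um`,
#'   `youngs_modulus_kpa`), or `NULL` to synthesise (requires `seed`).
#' @param seed RNG seed; mandatory whenever anything is synthesised.
#' @param out_dir Output directory for report TSVs and the manifest, or
#'   `NULL` to skip writing.
#' @param correlation_vars Variables entering the correlation analysis.
#' @param control Control group / vehicle label.
#' @export
study_config <- function(cohort = cohort_spec(), invitro = NULL, seed = NULL,
                         out_dir = NULL,
                         correlation_vars = c("stiffness_kpa", "collagen_ug_mg",
                                              "immature_crosslinks",
                                              "mature_crosslinks"),
                         control = "control") {
  needs_seed <- inherits(cohort, "cohort_spec") || is.null(invitro)
  cm_check(!needs_seed || !is.null(seed), "cm_validation_error",
           "seed must be set whenever synthetic inputs are used")
  structure(list(cohort = cohort, invitro = invitro, seed = seed,
                 out_dir = out_dir, correlation_vars = correlation_vars,
                 control = control),
            class = "study_config")
}

test_result_row <- function(tr, variable = NA_character_) {
  data.frame(variable = variable, method = tr$method,
             comparison = if (all(is.na(tr$labels))) "omnibus"
             else paste(tr$labels, collapse = " vs "),
             statistic = tr$statistic, df = paste(signif(tr$df, 6), collapse = ";"),
             p = tr$p, p_adjusted = tr$p_adjusted,
             stringsAsFactors = FALSE)
}

write_report <- function(tables, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Run the cohort (tissue) analysis
#'
#' Composes the study's tissue-level analyses on a donor cohort: two-group
#' comparisons per variable (Welch's t on log stiffness and swelling,
#' Student's t on collagen concentration, Mann-Whitney on cross-link
#' densities and fibril diameters -- mirroring each variable's reported
#' test), and the missing-data (EM) multivariate correlation of
#' log stiffness, collagen and cross-link densities. The statistical unit
#' is the donor.
#'
#' @param config A [study_config()].
#' @return List `cohort`, `group_tests` (data.frame), `correlation`
#'   (a `correlation_result`), `manifest`; written as TSV + JSON when
#'   `config$out_dir` is set.
#' @export
run_cohort_analysis <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- config$cohort
  source_tag <- "user"
  if (inherits(cohort, "cohort_spec")) {
    cohort <- synth_cohort(cohort, synth_protocol(seed = config$seed))
    source_tag <- "synthetic"
  } else if (is.character(cohort)) {
    source_tag <- cohort
    cohort <- read_cohort(cohort)
  }
  cm_check(nrow(cohort) > 0, "cm_empty_cohort", "cohort has no donors")
  cm_check(all(c("group") %in% names(cohort)), "cm_validation_error",
           "cohort needs a 'group' column")
  groups <- unique(cohort$group)
  cm_check(length(groups) == 2 && config$control %in% groups,
           "cm_validation_error", "cohort must have two groups incl. the control")
  case <- setdiff(groups, config$control)

  plan <- list(stiffness_kpa = list(method = "welch_t", log = TRUE),
               collagen_ug_mg = list(method = "student_t", log = FALSE),
               immature_crosslinks = list(method = "mann_whitney", log = FALSE),
               mature_crosslinks = list(method = "mann_whitney", log = FALSE),
               diameter_nm = list(method = "mann_whitney", log = FALSE),
               swelling_ratio = list(method = "welch_t", log = TRUE))
  rows <- list()
  for (v in intersect(names(plan), names(cohort))) {
    xc <- cohort[[v]][cohort$group == config$control]
    xk <- cohort[[v]][cohort$group == case]
    xc <- xc[!is.na(xc)]; xk <- xk[!is.na(xk)]
    if (length(xc) < 2 || length(xk) < 2) next
    tr <- pairwise_tests(xk, xc, method = plan[[v]]$method,
                         log_transform = plan[[v]]$log,
                         labels = c(case, config$control))
    rows[[v]] <- test_result_row(tr, variable = v)
  }
  group_tests <- do.call(rbind, rows)

  corr_vars <- intersect(config$correlation_vars, names(cohort))
  correlation <- correlation_matrix(cohort, method = "em_mvn",
                                    vars = corr_vars, log_transform = TRUE)

  corr_long <- data.frame(
    var1 = rep(correlation$variables, times = length(correlation$variables)),
    var2 = rep(correlation$variables, each = length(correlation$variables)),
    r = as.vector(correlation$r), p = as.vector(correlation$p),
    n_eff = as.vector(correlation$n_eff))
  corr_long <- corr_long[corr_long$var1 < corr_long$var2, ]

  manifest <- list(analysis = "cohort", seed = config$seed,
                   source = source_tag,
                   package_version = as.character(utils::packageVersion("collagenmech")),
                   n_donors = nrow(cohort),
                   groups = as.list(table(cohort$group)),
                   correlation_method = "em_mvn on log10 scale",
                   statistical_unit = "donor")
  out <- list(cohort = cohort, group_tests = group_tests,
              correlation = correlation, manifest = manifest)
  if (!is.null(config$out_dir))
    write_report(list(cohort = cohort, group_tests = group_tests,
                      correlation_long = corr_long),
                 manifest, config$out_dir)
  out
}

#' Run the dose-ranging in vitro analysis
#'
#' Composes the inhibitor study: enzyme-inhibition IC50 fits (LOXL2/LOXL3
#' defaults), and the spheroid-stiffness dose response analysed as a
#' randomized-block (repeated-measures) ANOVA on log10 Young's modulus with
#' Dunnett comparisons against vehicle, donors as blocks (replicates
#' averaged per donor x dose first).
#'
#' @param config A [study_config()]; `config$invitro` supplies the stiffness
#'   table or `NULL` to synthesise with [synth_invitro_study()].
#' @param ic50_true Named vector of true IC50s (uM) for the synthetic
#'   inhibition curves.
#' @param dr_noise_sd Activity noise (%) for the synthetic inhibition curves.
#' @return List `stiffness` (per donor x dose means), `dunnett` (omnibus +
#'   comparisons), `ic50_fits` (data.frame), `manifest`.
#' @export
run_invitro_analysis <- function(config, ic50_true = c(LOXL2 = 0.005, LOXL3 = 0.016),
                                 dr_noise_sd = 2) {
  stopifnot(inherits(config, "study_config"))
  iv <- config$invitro
  source_tag <- "user"
  if (is.null(iv)) {
    iv <- synth_invitro_study(synth_protocol(seed = config$seed))
    source_tag <- "synthetic"
  }
  cm_check(all(c("donor", "dose_um", "youngs_modulus_kpa") %in% names(iv)),
           "cm_validation_error",
           "invitro table needs donor, dose_um, youngs_modulus_kpa")
  vehicle <- 0
  if (!any(iv$dose_um == vehicle))
    cm_stop("cm_missing_control",
            sprintf("vehicle group (dose_um == %g) missing", vehicle))

  ## average replicates within donor x dose -> complete randomized blocks
  agg <- stats::aggregate(youngs_modulus_kpa ~ donor + dose_um, data = iv, FUN = mean)
  dose_lab <- factor(sprintf("%g", agg$dose_um),
                     levels = sprintf("%g", sort(unique(agg$dose_um))))
  dun <- multigroup_tests(agg$youngs_modulus_kpa, dose_lab,
                          design = "rm_anova_dunnett", control = "0",
                          blocks = agg$donor, log_transform = TRUE)

  fits <- lapply(names(ic50_true), function(enz) {
    i <- match(enz, names(ic50_true))
    dr <- synth_dose_response(ic50 = ic50_true[[enz]],
                              protocol = synth_protocol(
                                seed = (config$seed %||% 0L) + i,
                                noise_sd = dr_noise_sd))
    fit <- fit_dose_response(dr$dose_um, dr$activity_pct)
    data.frame(enzyme = enz, ic50_um = fit$ic50, hill = fit$hill,
               top = fit$top, bottom = fit$bottom,
               converged = fit$converged)
  })
  ic50_fits <- do.call(rbind, fits)

  comp_rows <- do.call(rbind, c(list(test_result_row(dun$omnibus, "youngs_modulus_kpa")),
                                lapply(dun$comparisons, test_result_row,
                                       variable = "youngs_modulus_kpa")))
  manifest <- list(analysis = "invitro", seed = config$seed, source = source_tag,
                   package_version = as.character(utils::packageVersion("collagenmech")),
                   design = "rm_anova_dunnett on log10 E, donor blocks",
                   n_donors = length(unique(iv$donor)),
                   doses_um = sort(unique(iv$dose_um)))
  out <- list(stiffness = agg, dunnett = dun, dunnett_table = comp_rows,
              ic50_fits = ic50_fits, manifest = manifest)
  if (!is.null(config$out_dir))
    write_report(list(stiffness = agg, dunnett = comp_rows,
                      ic50_fits = ic50_fits),
                 manifest, config$out_dir)
  out
}
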