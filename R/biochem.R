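## Biochemical normalisation: hydroxyproline -> collagen conversion,
## cross-link densities and ratios, sequential-extraction solubility
## fractions and delta-delta-Ct relative gene expression.

## Conversion constants: 300 hydroxyproline residues and 300 kDa per
## collagen triple helix; free hydroxyproline M = 131.13 g/mol (assay
## standard), exposed as an argument.
.HYP_PER_HELIX <- 300
.COLLAGEN_MW <- 300000   # g/mol

#' Collagen content from hydroxyproline mass
#'
#' Molar collagen is the molar hydroxyproline divided by 300 residues per
#' triple helix; collagen mass uses 300 kDa per helix. The conversion is
#' linear: 1 ug hydroxyproline corresponds to ~7.63 ug collagen.
#'
#' @param hyp_ug Hydroxyproline mass in ug (>= 0, vectorised).
#' @param m_hyp Hydroxyproline molar mass, g/mol.
#' @return data.frame with `hyp_ug`, `collagen_mol`, `collagen_ug`.
#' @export
collagen_from_hydroxyproline <- function(hyp_ug, m_hyp = 131.13) {
  cm_check(all(hyp_ug >= 0), "cm_validation_error",
           "hydroxyproline mass must be >= 0")
  mol_hyp <- hyp_ug * 1e-6 / m_hyp
  mol_col <- mol_hyp / .HYP_PER_HELIX
  data.frame(hyp_ug = hyp_ug, collagen_mol = mol_col,
             collagen_ug = mol_col * .COLLAGEN_MW * 1e6)
}

#' Cross-link densities and ratios
#'
#' Normalises the four quantified cross-links to molar collagen and forms
#' the study's summary quantities: total immature divalent (DHLNL + HLNL),
#' total mature trivalent (PYD + DPD), the immature/mature ratio and the
#' DHLNL/HLNL ratio. Ratios with a zero denominator are returned as `NA`
#' and flagged.
#'
#' @param dhlnl,hlnl,pyd,dpd Cross-link amounts, mol (>= 0).
#' @param collagen_mol Molar collagen of the same sample (> 0).
#' @return List of per-mol-collagen `densities`, `immature_total`,
#'   `mature_total`, `immature_mature_ratio`, `dhlnl_hlnl_ratio` and
#'   `undefined_ratios` (character vector of flagged ratio names).
#' @export
crosslink_densities <- function(dhlnl, hlnl, pyd, dpd, collagen_mol) {
  cm_check(all(c(dhlnl, hlnl, pyd, dpd) >= 0), "cm_validation_error",
           "cross-link amounts must be >= 0")
  cm_check(is_scalar_number(collagen_mol) && collagen_mol > 0,
           "cm_validation_error", "collagen_mol must be > 0")
  dens <- c(DHLNL = dhlnl, HLNL = hlnl, PYD = pyd, DPD = dpd) / collagen_mol
  imm <- dens[["DHLNL"]] + dens[["HLNL"]]
  mat <- dens[["PYD"]] + dens[["DPD"]]
  undef <- character(0)
  imm_mat <- if (mat > 0) imm / mat else {
    undef <- c(undef, "immature_mature_ratio"); NA_real_
  }
  dh_hl <- if (dens[["HLNL"]] > 0) dens[["DHLNL"]] / dens[["HLNL"]] else {
    undef <- c(undef, "dhlnl_hlnl_ratio"); NA_real_
  }
  list(densities = dens, immature_total = imm, mature_total = mat,
       immature_mature_ratio = imm_mat, dhlnl_hlnl_ratio = dh_hl,
       undefined_ratios = undef)
}

#' Collagen solubility fractions
#'
#' Percent of total hydroxyproline recovered in each sequential-extraction
#' fraction (neutral salt/TBS, acetic acid, pepsin, insoluble residue);
#' fractions sum to 100 by construction.
#'
#' @param hyp_by_fraction Named non-negative numeric vector, at least one
#'   entry positive.
#' @return Named vector of percentages.
#' @export
solubility_fractions <- function(hyp_by_fraction) {
  cm_check(all(hyp_by_fraction >= 0), "cm_validation_error",
           "fraction amounts must be >= 0")
  total <- sum(hyp_by_fraction)
  cm_check(total > 0, "cm_validation_error", "total hydroxyproline is zero")
  100 * hyp_by_fraction / total
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_gene - mean(Ct_housekeeping)`; `ddCt` subtracts the
#' baseline dCt (the mean dCt of the baseline group, or a named baseline
#' sample); relative expression is `2^(-ddCt)`. Group summaries are
#' geometric means of expression, matching the study's reporting.
#'
#' @param ct Long-format data.frame with columns `gene`, `sample`, `ct` and
#'   optionally `group`.
#' @param housekeeping Character vector of housekeeping gene names; every
#'   sample must carry a finite Ct for each.
#' @param baseline Baseline group label (default `"control"`) or, if
#'   `baseline_is_sample = TRUE`, a single baseline sample name.
#' @param baseline_is_sample Interpret `baseline` as a sample name.
#' @return List `expression` (gene, sample, group, dct, ddct, rel_expr) and
#'   `group_geomeans` (gene, group, geomean).
#' @export
ddct_expression <- function(ct, housekeeping, baseline = "control",
                            baseline_is_sample = FALSE) {
  cm_check(all(c("gene", "sample", "ct") %in% names(ct)), "cm_validation_error",
           "ct table needs columns gene, sample, ct")
  cm_check(length(housekeeping) >= 1, "cm_validation_error",
           "housekeeping gene set is empty")
  samples <- unique(ct$sample)
  hk_mean <- vapply(samples, function(s) {
    v <- ct$ct[ct$sample == s & ct$gene %in% housekeeping]
    if (length(v) < length(housekeeping) || anyNA(v) || any(!is.finite(v)))
      cm_stop("cm_missing_housekeeping",
              sprintf("sample '%s' lacks a housekeeping Ct", s))
    mean(v)
  }, numeric(1))
  names(hk_mean) <- samples

  ex <- ct[!(ct$gene %in% housekeeping), c("gene", "sample", "ct",
                                           intersect("group", names(ct)))]
  ex$dct <- ex$ct - hk_mean[ex$sample]

  base_dct <- vapply(unique(ex$gene), function(g) {
    rows <- if (baseline_is_sample) ex$gene == g & ex$sample == baseline
    else ex$gene == g & ex$group == baseline
    cm_check(any(rows), "cm_validation_error",
             sprintf("gene '%s': no baseline observations ('%s')", g, baseline))
    mean(ex$dct[rows])
  }, numeric(1))
  ex$ddct <- ex$dct - base_dct[ex$gene]
  ex$rel_expr <- 2^(-ex$ddct)

  gm <- if ("group" %in% names(ex)) {
    agg <- stats::aggregate(rel_expr ~ gene + group, data = ex,
                            FUN = function(v) exp(mean(log(v))))
    names(agg)[3] <- "geomean"
    agg
  } else NULL
  list(expression = ex, group_geomeans = gm)
}
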