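# Chou-Talalay combination-index and dose-reduction-index analysis for
# fixed-ratio two-drug combinations.

.check_ratio <- function(ratio) {
  ratio <- as.numeric(ratio)
  if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("'ratio' must be two positive fractions", call. = FALSE)
  if (abs(sum(ratio) - 1) > 1e-8)
    stop("'ratio' components must sum to 1", call. = FALSE)
  ratio
}

#' Fit a fixed-ratio combination dose-response curve
#'
#' Median-effect fit of a two-drug combination series in which the dose
#' variable is the total dose and the two drugs are mixed at a fixed ratio
#' (fraction of total dose per drug). The ratio is carried on the returned
#' fit for downstream CI/DRI computation.
#'
#' @param total_dose total combination doses in uM.
#' @param viability vehicle-normalized viability fractions.
#' @param ratio numeric length-2, positive, summing to 1.
#' @param clip fa clipping bound, as in [fit_median_effect()].
#' @return a `"median_effect"` fit with an extra `ratio` element.
#' @export
fit_fixed_ratio_combo <- function(total_dose, viability, ratio, clip = 1e-4) {
  ratio <- .check_ratio(ratio)
  fit <- fit_median_effect(total_dose, viability, clip = clip)
  fit$ratio <- ratio
  fit
}

#' Fixed dose ratio from a ranking entry
#'
#' The validation dose ratio for a pair defaults to the pair's optimal
#' concentration ratio from the combination ranking, normalized to sum 1.
#'
#' @param ranking a `"combination_ranking"` with concentrations filled in.
#' @param pair character vector of length 2 naming the pair.
#' @return numeric length-2 ratio (fraction of total dose per drug), named
#'   by drug.
#' @export
ratio_from_ranking <- function(ranking, pair) {
  key <- .pair_key(pair[1L], pair[2L])
  idx <- match(key, .pair_key(ranking$drug_a, ranking$drug_b))
  if (is.na(idx)) stop("pair not found in ranking", call. = FALSE)
  conc <- c(ranking$conc_a_uM[idx], ranking$conc_b_uM[idx])
  names(conc) <- c(ranking$drug_a[idx], ranking$drug_b[idx])
  if (anyNA(conc) || sum(conc) <= 0)
    stop("ranking entry has no usable concentrations for this pair", call. = FALSE)
  conc / sum(conc)
}

.ci_core <- function(curve_a, curve_b, combo_curve, ratio, fa_grid) {
  ratio <- .check_ratio(ratio)
  fa_grid <- as.numeric(fa_grid)
  if (any(!is.finite(fa_grid)) || any(fa_grid <= 0) || any(fa_grid >= 1))
    stop("'fa_grid' values must lie strictly in (0, 1)", call. = FALSE)
  x <- 100 * fa_grid
  d_tot <- inhibitory_concentration(combo_curve, x)
  d_a <- d_tot * ratio[1L]
  d_b <- d_tot * ratio[2L]
  dx_a <- inhibitory_concentration(curve_a, x)
  dx_b <- inhibitory_concentration(curve_b, x)
  dri_a <- dx_a / d_a
  dri_b <- dx_b / d_b
  ci <- 1 / dri_a + 1 / dri_b
  data.frame(fa = fa_grid, ci = ci, dri_a = dri_a, dri_b = dri_b)
}

#' Combination index profile (Chou-Talalay)
#'
#' For each fraction affected fa, the total combination dose achieving fa is
#' read from the fixed-ratio combination curve and split into component
#' doses by the ratio; the isoeffective single-agent doses come from each
#' single-agent median-effect curve. The mutually exclusive form is used:
#' CI = D_A / Dx_A + D_B / Dx_B (no product term). CI < 1 indicates
#' synergy, CI = 1 additivity, CI > 1 antagonism. The per-drug dose
#' reduction indices DRI_i = Dx_i / D_i are returned alongside, so
#' CI = 1/DRI_A + 1/DRI_B holds identically.
#'
#' @param curve_a,curve_b single-agent `"median_effect"` fits.
#' @param combo_curve fixed-ratio combination fit on total dose
#'   ([fit_fixed_ratio_combo()]).
#' @param ratio fraction of total dose per drug (length 2, sums to 1);
#'   defaults to the ratio stored on `combo_curve`.
#' @param fa_grid fractions affected, strictly in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return an object of class `"ci_profile"`: a data frame with columns
#'   `fa`, `ci`, `dri_a`, `dri_b`; the ratio and curves are attached as
#'   attributes.
#' @export
#' @examples
#' cv <- list(Dm = 1, m = 1)
#' prof <- combination_index(cv, cv, cv, ratio = c(0.5, 0.5))
#' all.equal(prof$ci, rep(1, nrow(prof)))  # sham combination is additive
combination_index <- function(curve_a, curve_b, combo_curve, ratio = combo_curve$ratio,
                              fa_grid = seq(0.05, 0.95, by = 0.05)) {
  if (is.null(ratio)) stop("no 'ratio' supplied or stored on the combination curve", call. = FALSE)
  out <- .ci_core(curve_a, curve_b, combo_curve, ratio, fa_grid)
  structure(out, class = c("ci_profile", "data.frame"),
            ratio = .check_ratio(ratio),
            curves = list(a = curve_a, b = curve_b, combo = combo_curve))
}

#' Dose reduction index profile
#'
#' DRI_i(fa) = Dx_i / D_i: the fold reduction in drug i's dose permitted by
#' the combination at equal effect. DRI > 1 is a favorable reduction.
#'
#' @inheritParams combination_index
#' @return data frame with columns `fa`, `dri_a`, `dri_b`.
#' @export
dose_reduction_index <- function(curve_a, curve_b, combo_curve, ratio = combo_curve$ratio,
                                 fa_grid = seq(0.05, 0.95, by = 0.05)) {
  if (is.null(ratio)) stop("no 'ratio' supplied or stored on the combination curve", call. = FALSE)
  .ci_core(curve_a, curve_b, combo_curve, ratio, fa_grid)[, c("fa", "dri_a", "dri_b")]
}

#' @export
print.ci_profile <- function(x, ...) {
  r <- attr(x, "ratio")
  cat(sprintf("Combination index profile (ratio %.3g : %.3g)\n", r[1L], r[2L]))
  mid <- x[which.min(abs(x$fa - 0.5)), ]
  cat(sprintf("  CI at fa = %.2g: %.4g (DRI %.4g / %.4g)\n",
              mid$fa, mid$ci, mid$dri_a, mid$dri_b))
  cat(sprintf("  CI range over fa grid: [%.4g, %.4g]\n", min(x$ci), max(x$ci)))
  invisible(x)
}

#' @export
plot.ci_profile <- function(x, ...) {
  graphics::plot(x$fa, x$ci, type = "b", xlab = "fraction affected (Fa)",
                 ylab = "combination index", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Cohort summary of combination-index profiles
#'
#' Per-fa median, minimum and maximum CI across a cohort of lines (the
#' median-and-range display conventionally used for Fa-CI plots).
#'
#' @param profiles non-empty list of `"ci_profile"` objects on a common fa
#'   grid.
#' @return data frame with columns `fa`, `median_ci`, `min_ci`, `max_ci`.
#' @export
summarize_ci_across_lines <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  fa <- profiles[[1L]]$fa
  for (p in profiles)
    if (!isTRUE(all.equal(p$fa, fa)))
      stop("profiles must share a common fa grid", call. = FALSE)
  M <- vapply(profiles, `[[`, numeric(length(fa)), "ci")
  M <- matrix(M, nrow = length(fa))
  data.frame(fa = fa,
             median_ci = apply(M, 1L, stats::median),
             min_ci = apply(M, 1L, min),
             max_ci = apply(M, 1L, max))
}
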