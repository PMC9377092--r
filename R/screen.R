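# Screening-arm and ancillary statistics: median-viability drug ranking
# with hit calling, tumor volume and growth rate, and the basal
# pathway-score vs sensitivity correlation.

#' Rank screened drugs by median viability and call hits
#'
#' Per-drug median viability across lines (midpoint convention for even
#' counts), ranked ascending; hits are drugs whose median falls below the
#' threshold, i.e. drugs that reduce median cell viability by more than
#' 50 percent at the default threshold of 0.5.
#'
#' @param viability_matrix numeric matrix, drugs x lines, with drug row
#'   names.
#' @param hit_threshold hit-calling cutoff on median viability (default
#'   0.5).
#' @return an object of class `"screen_result"`: list with `ranking` (data
#'   frame `drug`, `median_viability`, `rank`, `hit`) and `hits` (character
#'   vector).
#' @export
screen_rank <- function(viability_matrix, hit_threshold = 0.5) {
  M <- as.matrix(viability_matrix)
  if (!nrow(M) || !ncol(M)) stop("empty viability matrix", call. = FALSE)
  if (any(!is.finite(M))) stop("viabilities must be finite", call. = FALSE)
  if (is.null(rownames(M))) rownames(M) <- paste0("drug", seq_len(nrow(M)))
  med <- apply(M, 1L, stats::median)
  ord <- order(med, rownames(M))
  ranking <- data.frame(drug = rownames(M)[ord],
                        median_viability = unname(med[ord]),
                        rank = seq_len(nrow(M)),
                        hit = unname(med[ord]) < hit_threshold,
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, hits = ranking$drug[ranking$hit],
                 hit_threshold = hit_threshold, n_lines = ncol(M)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, n = 10L, ...) {
  cat("Drug screen over", x$n_lines, "lines;",
      length(x$hits), "hit(s) with median viability <", x$hit_threshold, "\n")
  print(utils::head(x$ranking, n), row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Tumor volume from caliper diameters
#'
#' V = pi/6 * A^2 * B, with A the smallest and B the largest superficial
#' diameter (mm). Homogeneous of degree 3: scaling both diameters by c
#' scales the volume by c^3.
#'
#' @param A smallest superficial diameter (mm); 0 < A <= B.
#' @param B largest superficial diameter (mm).
#' @return volume(s) in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 20)  # 1000 * pi / 3
tumor_volume <- function(A, B) {
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(A <= 0) || any(B <= 0))
    stop("diameters must be positive", call. = FALSE)
  if (any(A > B))
    stop("'A' must be the smallest diameter (A <= B)", call. = FALSE)
  pi / 6 * A^2 * B
}

#' Tumor growth rate from a volume time series
#'
#' Ordinary least-squares slope of volume (or log volume) against day.
#' The linear-scale slope is the default, matching volume-vs-time growth
#' summaries on a linear axis; with `log = TRUE` the slope is the
#' exponential growth constant per day.
#'
#' @param day time points (days); at least 3.
#' @param volume tumor volumes (mm^3); positive when `log = TRUE`.
#' @param log fit log(volume) instead of volume.
#' @return list with `slope`, `se`, `conf_int` (95 percent), `log_scale`
#'   and the underlying `lm` fit.
#' @export
growth_rate <- function(day, volume, log = FALSE) {
  if (length(day) != length(volume))
    stop("'day' and 'volume' must have equal length", call. = FALSE)
  if (length(day) < 3L) stop("need at least 3 time points", call. = FALSE)
  y <- if (log) {
    if (any(volume <= 0)) stop("volumes must be positive on the log scale", call. = FALSE)
    base::log(volume)
  } else volume
  fit <- stats::lm(y ~ day)
  slope <- unname(stats::coef(fit)["day"])
  # slope SE computed directly (summary.lm warns on exact fits)
  n <- length(day)
  sxx <- sum((day - mean(day))^2)
  se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2L) / sxx)
  tq <- stats::qt(0.975, n - 2L)
  list(slope = slope, se = se,
       conf_int = c(slope - tq * se, slope + tq * se),
       log_scale = log, fit = fit)
}

#' Correlate basal pathway score with combination sensitivity
#'
#' Pearson product-moment correlation between a per-line pathway expression
#' score (sum of normalized p-JNK/JNK and c-Jun components) and the
#' combination IC50 of the anchor drug. Line exclusions are explicit user
#' input, never automatic outlier removal.
#'
#' @param pjnk_over_jnk per-line p-JNK/JNK component (reference-normalized).
#' @param cjun per-line c-Jun component (reference-normalized).
#' @param ic50 per-line combination IC50 (uM).
#' @param lines line identifiers (needed when excluding lines).
#' @param exclude optional character vector of lines to leave out.
#' @param summed_normalization if `TRUE` the score is (p-JNK/JNK + c-Jun)
#'   divided by the sum of the reference components rather than
#'   per-component normalized input; default `FALSE` (inputs are already
#'   per-component normalized).
#' @param reference_sum reference-line component sum, used only with
#'   `summed_normalization = TRUE`.
#' @return list with `r`, `p_value`, `n`, `excluded` and the per-line
#'   `scores` actually used.
#' @export
pathway_sensitivity_correlation <- function(pjnk_over_jnk, cjun, ic50,
                                            lines = NULL, exclude = NULL,
                                            summed_normalization = FALSE,
                                            reference_sum = 1) {
  n0 <- length(ic50)
  if (length(pjnk_over_jnk) != n0 || length(cjun) != n0)
    stop("component and IC50 vectors must have equal length", call. = FALSE)
  if (is.null(lines)) lines <- paste0("line", seq_len(n0))
  score <- if (summed_normalization)
    (pjnk_over_jnk + cjun) / reference_sum
  else
    pjnk_over_jnk + cjun
  keep <- !(lines %in% exclude)
  if (sum(keep) < 3L)
    stop("need at least 3 paired observations after exclusions", call. = FALSE)
  s <- score[keep]; v <- ic50[keep]
  if (stats::sd(s) == 0 || stats::sd(v) == 0)
    stop("zero variance in pathway score or IC50", call. = FALSE)
  ct <- stats::cor.test(s, v, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep),
       excluded = lines[!keep],
       scores = stats::setNames(s, lines[keep]))
}
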