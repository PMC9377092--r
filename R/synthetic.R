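# Ground-truth viability simulator: Hill single-drug kill curves combined by
# Bliss independence, with planted pairwise interactions, emulating a tumor
# organoid cohort plus a less-sensitive non-tumorigenic reference line.

#' Ground-truth pharmacology model of one cell line
#'
#' Single-drug survival follows a Hill curve s_i = 1 / (1 + (D_i/Dm_i)^m_i).
#' Drugs combine by Bliss independence (product of survivals) times an
#' interaction multiplier exp(-sum_{i<j} gamma_ij (1-s_i)(1-s_j)): positive
#' gamma produces excess-over-Bliss killing that vanishes whenever either
#' drug is absent, so zero-dose anchored designs behave sensibly.
#'
#' @param cell_line line identifier.
#' @param Dm named vector of median-effect doses (uM), one per drug; > 0.
#' @param m Hill slopes, same length; > 0.
#' @param gamma symmetric interaction matrix with zero diagonal (default all
#'   zero).
#' @param noise_sd additive Gaussian measurement noise on viability.
#' @return an object of class `"ground_truth_model"`.
#' @export
ground_truth_model <- function(cell_line, Dm, m, gamma = NULL, noise_sd = 0.05) {
  k <- length(Dm)
  if (length(m) != k) stop("'Dm' and 'm' must have equal length", call. = FALSE)
  if (any(!is.finite(Dm)) || any(Dm <= 0)) stop("'Dm' must be positive", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0)) stop("'m' must be positive", call. = FALSE)
  if (is.null(names(Dm))) names(Dm) <- paste0("drug", seq_len(k))
  names(m) <- names(Dm)
  if (is.null(gamma)) gamma <- matrix(0, k, k)
  gamma <- as.matrix(gamma)
  if (!all(dim(gamma) == k) || max(abs(gamma - t(gamma))) > 1e-12 ||
      any(diag(gamma) != 0))
    stop("'gamma' must be a symmetric k x k matrix with zero diagonal", call. = FALSE)
  dimnames(gamma) <- list(names(Dm), names(Dm))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(cell_line = cell_line, Dm = Dm, m = m, gamma = gamma,
                 noise_sd = noise_sd, drugs = names(Dm)),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat("Ground-truth model for", x$cell_line, "-", length(x$Dm), "drugs\n")
  cat("  Dm (uM):", paste(signif(x$Dm, 3), collapse = ", "), "\n")
  nz <- which(upper.tri(x$gamma) & x$gamma != 0, arr.ind = TRUE)
  if (nrow(nz))
    cat("  interactions:",
        paste(sprintf("%s:%s = %g", x$drugs[nz[, 1L]], x$drugs[nz[, 2L]],
                      x$gamma[nz]), collapse = ", "), "\n")
  invisible(x)
}

#' Expected viability under the ground-truth model
#'
#' Deterministic (noise-free) viability at given doses: Bliss product of
#' Hill survivals times the pairwise interaction multiplier, clipped to
#' [0, 1]. Monotone non-increasing in every dose when all gamma >= 0.
#'
#' @param model a [ground_truth_model()].
#' @param doses numeric vector of per-drug doses (uM), or a matrix with one
#'   column per drug for many dose points at once.
#' @return expected viability fraction(s).
#' @export
#' @examples
#' gt <- ground_truth_model("line1", Dm = c(a = 1, b = 2), m = c(1, 1),
#'                          gamma = matrix(c(0, 1, 1, 0), 2))
#' simulate_viability(gt, c(1, 2))  # 0.25 * exp(-0.25)
simulate_viability <- function(model, doses) {
  k <- length(model$Dm)
  D <- if (is.matrix(doses)) doses else matrix(doses, nrow = 1L)
  if (ncol(D) != k) stop("'doses' must give one dose per drug", call. = FALSE)
  if (any(!is.finite(D)) || any(D < 0)) stop("doses must be finite and >= 0", call. = FALSE)
  E <- sweep(sweep(D, 2L, model$Dm, "/"), 2L, model$m, "^")
  S <- 1 / (1 + E)
  v0 <- exp(rowSums(log(S)))
  F1 <- 1 - S
  inter <- 0.5 * rowSums((F1 %*% model$gamma) * F1)
  v <- pmin(pmax(v0 * exp(-inter), 0), 1)
  if (is.matrix(doses)) v else v[1L]
}

#' Simulate plate records for a mapped design
#'
#' Per run and replicate, viability = expected viability + N(0, noise_sd),
#' truncated at 0. Reproducible under a seed.
#'
#' @param model a [ground_truth_model()].
#' @param plate_map output of [map_design_to_concentrations()] (columns:
#'   `run_id`, optional `block`, per-drug concentrations in uM).
#' @param replicates replicates per run (default 3).
#' @param seed optional RNG seed.
#' @param noise_sd noise level; defaults to the model's.
#' @return data frame with columns `run_id`, `cell_line`, `replicate`,
#'   `viability`.
#' @export
simulate_oacd_experiment <- function(model, plate_map, replicates = 3L,
                                     seed = NULL, noise_sd = model$noise_sd) {
  drug_cols <- intersect(model$drugs, names(plate_map))
  if (length(drug_cols) != length(model$drugs))
    stop("plate map is missing concentration columns for some drugs", call. = FALSE)
  D <- as.matrix(plate_map[, model$drugs, drop = FALSE])
  v_true <- simulate_viability(model, D)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(D)
  out <- data.frame(
    run_id = rep(plate_map$run_id, each = replicates),
    cell_line = model$cell_line,
    replicate = rep(seq_len(replicates), times = n),
    viability = pmax(rep(v_true, each = replicates) +
                       stats::rnorm(n * replicates, 0, noise_sd), 0),
    stringsAsFactors = FALSE)
  out
}

#' Simulate outputs from a known quadratic surface
#'
#' Evaluates a second-order polynomial at the design's coded levels and adds
#' Gaussian noise; the regression-recovery oracle for
#' [fit_quadratic_surface()].
#'
#' @param coefficients named coefficient vector in
#'   [quadratic_model_matrix()] column order, or a `"qpop_surface"` object.
#' @param design an [oacd_design()] or coded matrix.
#' @param noise_sd Gaussian noise level (default 0).
#' @param seed optional RNG seed.
#' @return numeric vector of per-run outputs.
#' @export
simulate_quadratic_truth <- function(coefficients, design, noise_sd = 0, seed = NULL) {
  X <- .as_coded_matrix(design)
  if (inherits(coefficients, "qpop_surface")) {
    colnames(X) <- coefficients$drugs
    coefficients <- coefficients$coefficients
  }
  mm <- quadratic_model_matrix(X)
  if (length(coefficients) != ncol(mm))
    stop("coefficient vector does not match the design dimension", call. = FALSE)
  y <- drop(mm %*% coefficients)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  y
}

#' Simulate a dose-response series
#'
#' Single-agent or fixed-ratio combination (total-dose) series from the
#' ground-truth model plus truncated Gaussian noise.
#'
#' @param model a [ground_truth_model()].
#' @param drug drug name for a single-agent series (ignored when `pair` is
#'   given).
#' @param pair optional character vector of two drug names for a fixed-ratio
#'   combination series.
#' @param ratio fraction of total dose per drug (length 2, sums to 1);
#'   required with `pair`.
#' @param doses dose ladder (total dose for combinations); defaults to
#'   [dose_ladder()], log-spaced 0.0001 to 100 uM.
#' @param replicates replicates per dose.
#' @param seed optional RNG seed.
#' @param noise_sd noise level; defaults to the model's.
#' @return data frame with columns `cell_line`, `drug`, `dose_uM`,
#'   `replicate`, `viability`, `ratio_a` (NA for single-agent rows).
#' @export
simulate_dose_response_series <- function(model, drug = NULL, pair = NULL,
                                          ratio = NULL, doses = dose_ladder(),
                                          replicates = 3L, seed = NULL,
                                          noise_sd = model$noise_sd) {
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  k <- length(model$Dm)
  D <- matrix(0, length(doses), k, dimnames = list(NULL, model$drugs))
  if (!is.null(pair)) {
    ratio <- .check_ratio(ratio)
    ij <- match(pair, model$drugs)
    if (anyNA(ij) || length(ij) != 2L) stop("unknown drug in 'pair'", call. = FALSE)
    D[, ij[1L]] <- doses * ratio[1L]
    D[, ij[2L]] <- doses * ratio[2L]
    label <- paste(pair, collapse = " + ")
    ratio_a <- ratio[1L]
  } else {
    j <- match(drug, model$drugs)
    if (is.na(j)) stop("unknown 'drug'", call. = FALSE)
    D[, j] <- doses
    label <- drug
    ratio_a <- NA_real_
  }
  v_true <- simulate_viability(model, D)
  if (!is.null(seed)) set.seed(seed)
  n <- length(doses)
  data.frame(cell_line = model$cell_line, drug = label,
             dose_uM = rep(doses, each = replicates),
             replicate = rep(seq_len(replicates), times = n),
             viability = pmax(rep(v_true, each = replicates) +
                                stats::rnorm(n * replicates, 0, noise_sd), 0),
             ratio_a = ratio_a, stringsAsFactors = FALSE)
}

# Panel-typical pharmacology for the canonical nine-drug set: potent
# proteasome/CDK inhibitors in the tens-of-nM range, kinase inhibitors and
# chemotherapy agents in the low-uM range.
.default_panel <- function(k) {
  if (k == 9L) {
    list(drugs = c("ixazomib", "dinaciclib", "carfilzomib", "sorafenib",
                   "regorafenib", "lenvatinib", "cabozantinib", "oxaliplatin",
                   "fluorouracil"),
         Dm = c(0.05, 0.01, 0.02, 3, 4, 5, 6, 2, 5),
         m = c(1.5, 1.2, 1.5, 1.2, 1.2, 1.0, 1.0, 1.0, 0.9))
  } else {
    list(drugs = paste0("drug", seq_len(k)),
         Dm = 10^seq(-2, 0.7, length.out = k),
         m = rep(1.2, k))
  }
}

#' Generate a synthetic organoid cohort with a planted synergistic pair
#'
#' Builds `n_tumor_lines` tumor ground-truth models plus one
#' non-tumorigenic reference line. Per-line (Dm, m) are jittered
#' log-normally around panel-typical values with coefficient of variation
#' `heterogeneity_cv` (mean-preserving). The planted pair receives
#' interaction strength `gamma_strength` in every tumor line and 0 in the
#' reference line; the reference line is uniformly less sensitive (all Dm
#' scaled up by `normal_shift`), emulating the tumor-selectivity premise of
#' the therapeutic output.
#'
#' @param n_tumor_lines number of tumor lines (default 18).
#' @param k_drugs number of drugs (default 9; the canonical named panel).
#' @param planted_pair two drug names (or indices) to receive the planted
#'   synergy; default ixazomib + dinaciclib for the 9-drug panel.
#' @param gamma_strength planted interaction strength (default 2).
#' @param heterogeneity_cv lognormal CV of per-line (Dm, m) jitter
#'   (default 0.1).
#' @param noise_sd measurement noise on viability (default 0.05).
#' @param normal_shift fold increase of the reference line's Dm (default 4).
#' @param background_gamma_sd if positive, non-planted tumor-line pairs draw
#'   small interactions from N(0, sd); default 0 (independent).
#' @param seed RNG seed (default 1).
#' @return an object of class `"cohort"`: list with `tumor` (list of
#'   models), `normal` (reference model), `drugs`, `base` (panel Dm and m),
#'   `planted_pair` and the generator settings.
#' @export
make_cohort <- function(n_tumor_lines = 18L, k_drugs = 9L, planted_pair = NULL,
                        gamma_strength = 2, heterogeneity_cv = 0.1,
                        noise_sd = 0.05, normal_shift = 4,
                        background_gamma_sd = 0, seed = 1L) {
  if (heterogeneity_cv < 0) stop("'heterogeneity_cv' must be >= 0", call. = FALSE)
  panel <- .default_panel(as.integer(k_drugs))
  k <- length(panel$drugs)
  if (is.null(planted_pair))
    planted_pair <- panel$drugs[1:2]
  if (is.numeric(planted_pair)) planted_pair <- panel$drugs[planted_pair]
  ij <- match(planted_pair, panel$drugs)
  if (anyNA(ij) || length(ij) != 2L || ij[1L] == ij[2L])
    stop("'planted_pair' must name two distinct panel drugs", call. = FALSE)
  set.seed(seed)
  s <- sqrt(log(1 + heterogeneity_cv^2))
  tumor <- vector("list", n_tumor_lines)
  for (i in seq_len(n_tumor_lines)) {
    Dm_i <- panel$Dm * stats::rlnorm(k, -s^2 / 2, s)
    m_i <- panel$m * stats::rlnorm(k, -s^2 / 2, s)
    gamma <- matrix(0, k, k)
    if (background_gamma_sd > 0) {
      g <- stats::rnorm(k * (k - 1) / 2, 0, background_gamma_sd)
      gamma[upper.tri(gamma)] <- g
      gamma <- gamma + t(gamma)
    }
    gamma[ij[1L], ij[2L]] <- gamma_strength
    gamma[ij[2L], ij[1L]] <- gamma_strength
    tumor[[i]] <- ground_truth_model(
      cell_line = sprintf("PDXO%02d", i),
      Dm = stats::setNames(Dm_i, panel$drugs), m = m_i,
      gamma = gamma, noise_sd = noise_sd)
  }
  normal <- ground_truth_model(
    cell_line = "THLE-2",
    Dm = stats::setNames(panel$Dm * normal_shift, panel$drugs), m = panel$m,
    gamma = NULL, noise_sd = noise_sd)
  structure(list(tumor = tumor, normal = normal, drugs = panel$drugs,
                 base = list(Dm = stats::setNames(panel$Dm, panel$drugs),
                             m = stats::setNames(panel$m, panel$drugs)),
                 planted_pair = panel$drugs[ij],
                 gamma_strength = gamma_strength,
                 heterogeneity_cv = heterogeneity_cv, noise_sd = noise_sd,
                 normal_shift = normal_shift, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$tumor), "tumor lines +",
      x$normal$cell_line, "\n")
  cat("  drugs:", paste(x$drugs, collapse = ", "), "\n")
  cat("  planted pair:", paste(x$planted_pair, collapse = " + "),
      sprintf("(gamma = %g)", x$gamma_strength), "\n")
  cat(sprintf("  heterogeneity CV = %g, noise sd = %g, seed = %d\n",
              x$heterogeneity_cv, x$noise_sd, x$seed))
  invisible(x)
}

#' Dose specifications anchored at panel-level ICx
#'
#' Coded levels -1/0/+1 map to IC0/IC10/IC20 computed from the cohort's
#' panel-typical (base) median-effect parameters, mirroring dosing anchored
#' to dose-response curves determined across the panel of lines.
#'
#' @param cohort a [make_cohort()] object.
#' @param levels_pct percent-inhibition anchors for levels (-1, 0, +1);
#'   default `c(0, 10, 20)`.
#' @return list of [dose_spec()] objects, one per drug.
#' @export
cohort_dose_specs <- function(cohort, levels_pct = c(0, 10, 20)) {
  lapply(cohort$drugs, function(d) {
    cv <- list(Dm = cohort$base$Dm[[d]], m = cohort$base$m[[d]])
    dose_spec(d, inhibitory_concentration(cv, levels_pct))
  })
}

#' Run the full design-fit-rank pipeline on a synthetic cohort
#'
#' Simulates the composite-design experiment for every tumor line and the
#' shared reference line, averages replicates per run, forms the
#' therapeutic output delta = v_normal - v_tumor, fits the quadratic
#' surface per line and ranks all two-drug combinations, then aggregates
#' the cohort frequency table.
#'
#' @param cohort a [make_cohort()] object.
#' @param design an [oacd_design()]; defaults to the composite design for
#'   the cohort's drugs.
#' @param replicates plate replicates per run (default 3).
#' @param seed RNG seed for the simulated plates.
#' @param top_n frequency-table cutoff (default 25).
#' @param objective ranking objective (default `"delta"`).
#' @return list with `rankings` (per line), `surfaces` (per line),
#'   `frequency` (cohort [rank_frequency()] table), `design` and `specs`.
#' @export
run_qpop_cohort <- function(cohort, design = NULL, replicates = 3L, seed = 1L,
                            top_n = 25L, objective = "delta") {
  if (is.null(design))
    design <- oacd_design(length(cohort$drugs), drugs = cohort$drugs)
  specs <- cohort_dose_specs(cohort)
  plate_map <- map_design_to_concentrations(design, specs)
  normal_rec <- simulate_oacd_experiment(cohort$normal, plate_map,
                                         replicates = replicates, seed = seed)
  v_normal <- average_replicates(normal_rec$run_id, normal_rec$viability)
  surfaces <- vector("list", length(cohort$tumor))
  rankings <- vector("list", length(cohort$tumor))
  for (i in seq_along(cohort$tumor)) {
    rec <- simulate_oacd_experiment(cohort$tumor[[i]], plate_map,
                                    replicates = replicates, seed = seed + i)
    v_tumor <- average_replicates(rec$run_id, rec$viability)
    delta <- therapeutic_output(v_normal, v_tumor)
    surfaces[[i]] <- fit_quadratic_surface(design, delta)
    rankings[[i]] <- score_two_drug_combinations(
      surfaces[[i]], specs = specs, objective = objective,
      cell_line = cohort$tumor[[i]]$cell_line)
  }
  names(surfaces) <- names(rankings) <-
    vapply(cohort$tumor, `[[`, character(1L), "cell_line")
  list(rankings = rankings, surfaces = surfaces,
       frequency = rank_frequency(rankings, top_n = top_n),
       design = design, specs = specs)
}
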