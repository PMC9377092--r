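# Second-order response-surface regression on the therapeutic output and
# exhaustive two-drug ranking: the core of the quadratic phenotypic
# optimization workflow.

#' Therapeutic output: normal-line minus tumor-line viability
#'
#' Delta = viability(normal reference line) - viability(tumor organoid line)
#' at the same drug doses. Larger delta means more tumor-selective killing;
#' negative values mean the combination harms the normal line more.
#'
#' @param v_thle2 normalized viability of the non-tumorigenic reference line.
#' @param v_pdxo normalized viability of the tumor organoid line.
#' @return numeric vector of deltas.
#' @export
therapeutic_output <- function(v_thle2, v_pdxo) {
  if (length(v_thle2) != length(v_pdxo))
    stop("viability vectors must have equal length", call. = FALSE)
  if (any(!is.finite(v_thle2)) || any(!is.finite(v_pdxo)))
    stop("viabilities must be finite", call. = FALSE)
  v_thle2 - v_pdxo
}

# Internal OLS on a prebuilt model matrix with regression diagnostics.
.ols_quadratic <- function(mm, y) {
  n <- nrow(mm)
  p <- ncol(mm) - 1L
  fit <- stats::lm.fit(mm, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  fitted <- drop(mm %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_resid <- n - p - 1L
  if (tss <= .Machine$double.eps * n * max(1, mean(y)^2)) {
    r2 <- 0; adj_r2 <- 0; f_stat <- NA_real_; f_p <- NA_real_
  } else {
    r2 <- 1 - rss / tss
    adj_r2 <- 1 - (1 - r2) * (n - 1) / df_resid
    f_stat <- ((tss - rss) / p) / (rss / df_resid)
    f_p <- stats::pf(f_stat, p, df_resid, lower.tail = FALSE)
  }
  sigma2 <- rss / df_resid
  xtx_inv <- chol2inv(chol(crossprod(mm)))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  list(beta = beta, fitted = fitted, residuals = res, rss = rss, tss = tss,
       r2 = r2, adj_r2 = adj_r2, f_stat = f_stat, f_pvalue = f_p,
       df_resid = df_resid, se = se)
}

#' Fit the second-order quadratic response surface
#'
#' Ordinary least squares of the per-run therapeutic output on the full
#' second-order polynomial in coded dose levels: intercept, k linear terms
#' (beta_i), k pure-quadratic terms (beta_ii) and k(k-1)/2 pairwise
#' interaction terms (beta_ij). The overall regression F-test is computed
#' from the regression and residual sums of squares, and predictive power is
#' summarized by the adjusted R-squared.
#'
#' With `eliminate = TRUE`, terms are removed by backward elimination: the
#' least significant non-intercept term with p-value above `alpha` is
#' dropped and the surface refit, until all remaining terms are significant.
#' Removed terms keep coefficient 0 and are listed in `removed_terms`.
#'
#' @param design an [oacd_design()] object or coded matrix (runs x drugs).
#' @param outputs numeric vector of per-run therapeutic outputs (one value
#'   per run; average replicates first, e.g. via [average_replicates()]).
#' @param eliminate logical; apply backward term elimination (default off).
#' @param alpha significance level for elimination.
#' @return an object of class `"qpop_surface"` with coefficient blocks
#'   `beta0`, `beta_lin`, `beta_quad`, `beta_int`, diagnostics `adj_r2`,
#'   `f_stat`, `f_pvalue`, `residual_ss`, `df_resid`, and a coefficient
#'   table (`coef_table`).
#' @export
#' @examples
#' d <- oacd_design(3)
#' y <- 0.1 + 0.2 * d$runs[, 1] - 0.1 * d$runs[, 2]^2 +
#'   0.5 * d$runs[, 1] * d$runs[, 3]
#' s <- fit_quadratic_surface(d, y)
#' s$adj_r2
fit_quadratic_surface <- function(design, outputs, eliminate = FALSE,
                                  alpha = 0.05) {
  X <- .as_coded_matrix(design)
  k <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("drug", seq_len(k))
  outputs <- as.numeric(outputs)
  if (length(outputs) != nrow(X))
    stop("'outputs' must have one value per design run", call. = FALSE)
  if (any(!is.finite(outputs)))
    stop("outputs must be finite", call. = FALSE)
  mm <- quadratic_model_matrix(X)
  if (nrow(mm) < ncol(mm))
    stop("insufficient runs: ", nrow(mm), " runs for ", ncol(mm),
         " second-order coefficients", call. = FALSE)
  if (qr(mm)$rank < ncol(mm))
    stop("design model matrix is rank deficient; the quadratic surface is not identifiable",
         call. = FALSE)

  terms_all <- colnames(mm)
  active <- terms_all
  removed <- character(0)
  repeat {
    sol <- .ols_quadratic(mm[, active, drop = FALSE], outputs)
    if (!eliminate) break
    tv <- sol$beta / sol$se
    pv <- 2 * stats::pt(abs(tv), sol$df_resid, lower.tail = FALSE)
    cand <- setdiff(active, "(Intercept)")
    if (!length(cand)) break
    pc <- pv[match(cand, active)]
    worst <- which.max(pc)
    if (is.na(pc[worst]) || pc[worst] <= alpha) break
    removed <- c(removed, cand[worst])
    active <- setdiff(active, cand[worst])
  }

  beta <- stats::setNames(numeric(length(terms_all)), terms_all)
  beta[active] <- sol$beta
  se <- stats::setNames(rep(NA_real_, length(terms_all)), terms_all)
  se[active] <- sol$se
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), sol$df_resid, lower.tail = FALSE)
  coef_table <- data.frame(term = terms_all, estimate = unname(beta),
                           se = unname(se), t = unname(tval), p = unname(pval),
                           stringsAsFactors = FALSE)

  nm <- colnames(X)
  pr <- utils::combn(k, 2L)
  int_names <- paste0(nm[pr[1L, ]], ":", nm[pr[2L, ]])
  structure(list(
    drugs = nm, k = k,
    coefficients = beta,
    beta0 = unname(beta[1L]),
    beta_lin = stats::setNames(unname(beta[nm]), nm),
    beta_quad = stats::setNames(unname(beta[paste0(nm, "^2")]), nm),
    beta_int = stats::setNames(unname(beta[int_names]), int_names),
    pair_index = pr,
    adj_r2 = sol$adj_r2, r2 = sol$r2,
    f_stat = sol$f_stat, f_pvalue = sol$f_pvalue,
    residual_ss = sol$rss, df_resid = sol$df_resid,
    fitted_values = sol$fitted, residuals = sol$residuals,
    coef_table = coef_table, removed_terms = removed,
    n_runs = nrow(X)),
    class = "qpop_surface")
}

#' Average replicate viabilities per run
#'
#' @param run_id run identifiers (one per record).
#' @param viability viability values.
#' @return named numeric vector of per-run means, ordered by first
#'   appearance of each run id.
#' @export
average_replicates <- function(run_id, viability) {
  if (length(run_id) != length(viability))
    stop("'run_id' and 'viability' must have equal length", call. = FALSE)
  ord <- unique(run_id)
  out <- tapply(viability, factor(run_id, levels = ord), mean)
  stats::setNames(as.numeric(out), as.character(ord))
}

#' @export
print.qpop_surface <- function(x, ...) {
  cat("Quadratic response surface (", x$k, " drugs, ", x$n_runs, " runs)\n", sep = "")
  cat(sprintf("  adjusted R2 = %.4f; F = %s on %d and %d df (p = %s)\n",
              x$adj_r2,
              if (is.na(x$f_stat)) "NA" else sprintf("%.3f", x$f_stat),
              length(x$coefficients) - 1L, x$df_resid,
              if (is.na(x$f_pvalue)) "NA" else format.pval(x$f_pvalue)))
  if (length(x$removed_terms))
    cat("  terms removed by backward elimination:",
        paste(x$removed_terms, collapse = ", "), "\n")
  top <- utils::head(x$beta_int[order(-abs(x$beta_int))], 3L)
  cat("  largest interactions:",
      paste(sprintf("%s = %.3g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.qpop_surface <- function(object, ...) {
  structure(list(surface = object), class = "summary.qpop_surface")
}

#' @export
print.summary.qpop_surface <- function(x, ...) {
  print(x$surface)
  cat("\nCoefficients:\n")
  tab <- x$surface$coef_table
  tab$estimate <- signif(tab$estimate, 4L)
  tab$se <- signif(tab$se, 3L)
  tab$t <- signif(tab$t, 3L)
  tab$p <- signif(tab$p, 3L)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.qpop_surface <- function(object, ...) object$coefficients

#' @export
residuals.qpop_surface <- function(object, ...) object$residuals

#' @export
fitted.qpop_surface <- function(object, ...) object$fitted_values

#' Evaluate the fitted surface at coded dose levels
#'
#' @param object a `"qpop_surface"` fit.
#' @param newdata matrix or data frame of coded levels (rows are points,
#'   one column per drug).
#' @param ... unused.
#' @return predicted therapeutic output at each point.
#' @export
predict.qpop_surface <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$k)
    stop("'newdata' must have ", object$k, " columns", call. = FALSE)
  colnames(X) <- object$drugs
  drop(quadratic_model_matrix(X) %*% object$coefficients)
}

#' Response-surface map for one drug pair
#'
#' Evaluates the fitted surface over a regular grid on [-1, 1]^2 for the
#' chosen pair, all other drugs held at level -1 (absent). The resulting
#' grid table is the data behind a parabolic response-surface map.
#'
#' @param surface a `"qpop_surface"` fit.
#' @param pair character or integer vector of length 2 naming the pair.
#' @param grid_points_per_axis grid resolution per axis (default 21).
#' @return data frame with columns `level_a`, `level_b`, `output`
#'   (`grid_points_per_axis^2` rows).
#' @export
export_response_surface <- function(surface, pair, grid_points_per_axis = 21L) {
  ij <- .pair_to_index(surface, pair)
  g <- seq(-1, 1, length.out = grid_points_per_axis)
  grid <- expand.grid(level_a = g, level_b = g)
  X <- matrix(-1, nrow(grid), surface$k)
  X[, ij[1L]] <- grid$level_a
  X[, ij[2L]] <- grid$level_b
  grid$output <- predict(surface, X)
  attr(grid, "pair") <- surface$drugs[ij]
  grid
}

#' @export
plot.qpop_surface <- function(x, pair = NULL, grid_points_per_axis = 41L, ...) {
  if (is.null(pair))
    pair <- names(x$beta_int)[which.max(abs(x$beta_int))]
  if (is.character(pair) && length(pair) == 1L)
    pair <- strsplit(pair, ":", fixed = TRUE)[[1L]]
  grid <- export_response_surface(x, pair, grid_points_per_axis)
  g <- sort(unique(grid$level_a))
  z <- matrix(grid$output, length(g), length(g))
  drugs <- attr(grid, "pair")
  graphics::filled.contour(g, g, z, xlab = paste(drugs[1L], "(coded level)"),
                           ylab = paste(drugs[2L], "(coded level)"),
                           main = "Projected therapeutic output", ...)
  invisible(x)
}

.pair_to_index <- function(surface, pair) {
  if (length(pair) != 2L) stop("'pair' must name two drugs", call. = FALSE)
  if (is.character(pair)) {
    ij <- match(pair, surface$drugs)
    if (anyNA(ij)) stop("unknown drug in 'pair'", call. = FALSE)
  } else ij <- as.integer(pair)
  if (any(ij < 1L | ij > surface$k) || ij[1L] == ij[2L])
    stop("invalid drug pair", call. = FALSE)
  sort(ij)
}

#' Rank all two-drug combinations on a fitted surface
#'
#' For each unordered drug pair, all other drugs are fixed at level -1
#' (absent) and the surface is evaluated at the four realizable coded dose
#' points \{0, +1\} x \{0, +1\}. The pair's score is the best projected
#' output under the objective, recorded together with the arg-max levels
#' and, when dose specifications are supplied, the matching concentrations.
#' Ties are broken lexicographically by drug-name pair so rankings are
#' deterministic.
#'
#' Objectives: `"delta"` maximizes the therapeutic output fitted by the
#' surface; `"pdxo_kill"` and `"thle2_kill"` are for surfaces fitted
#' directly to a viability readout and minimize the projected viability.
#'
#' @param surface a `"qpop_surface"` fit.
#' @param specs optional list of [dose_spec()] objects (one per drug) used
#'   to report concentrations.
#' @param objective ranking objective; see Details.
#' @param cell_line optional identifier carried into the ranking.
#' @return an object of class `"combination_ranking"`: a data frame with
#'   columns `rank`, `drug_a`, `drug_b`, `level_a`, `level_b`, `conc_a_uM`,
#'   `conc_b_uM`, `projected_output`.
#' @export
score_two_drug_combinations <- function(surface, specs = NULL,
                                        objective = c("delta", "thle2_kill", "pdxo_kill"),
                                        cell_line = NA_character_) {
  objective <- match.arg(objective)
  maximize <- objective == "delta"
  k <- surface$k
  if (!is.null(specs)) {
    if (length(specs) != k)
      stop("need one dose spec per drug", call. = FALSE)
    spec_names <- vapply(specs, `[[`, character(1L), "drug")
    if (!setequal(spec_names, surface$drugs))
      stop("dose specs do not match the surface's drugs", call. = FALSE)
    specs <- specs[match(surface$drugs, spec_names)]
  }
  pr <- utils::combn(k, 2L)
  P <- ncol(pr)
  cand <- as.matrix(expand.grid(a = c(0, 1), b = c(0, 1)))
  rows <- vector("list", P)
  for (p in seq_len(P)) {
    i <- pr[1L, p]; j <- pr[2L, p]
    X <- matrix(-1, nrow(cand), k)
    X[, i] <- cand[, "a"]
    X[, j] <- cand[, "b"]
    val <- predict(surface, X)
    best <- if (maximize) which.max(val) else which.min(val)
    la <- cand[best, "a"]; lb <- cand[best, "b"]
    rows[[p]] <- data.frame(
      drug_a = surface$drugs[i], drug_b = surface$drugs[j],
      level_a = la, level_b = lb,
      conc_a_uM = if (is.null(specs)) NA_real_ else unname(specs[[i]]$conc[as.character(la)]),
      conc_b_uM = if (is.null(specs)) NA_real_ else unname(specs[[j]]$conc[as.character(lb)]),
      projected_output = val[best],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  sgn <- if (maximize) -1 else 1
  ord <- order(sgn * out$projected_output, out$drug_a, out$drug_b)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(P), out)
  rownames(out) <- NULL
  structure(out, class = c("combination_ranking", "data.frame"),
            objective = objective, cell_line = cell_line)
}

#' @export
print.combination_ranking <- function(x, n = 10L, ...) {
  cl <- attr(x, "cell_line")
  cat("Two-drug combination ranking (objective: ", attr(x, "objective"),
      if (!is.na(cl)) paste0("; line: ", cl), ")\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4L)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more pairs\n", sep = "")
  invisible(x)
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = " + ")
}

#' Cohort frequency of top-ranked drugs and pairs
#'
#' Counts, across a cohort of per-line rankings, how often each drug pair
#' (and each member drug) appears within the top `top_n` ranks of a line.
#'
#' @param rankings list of [score_two_drug_combinations()] results over the
#'   same drug set.
#' @param top_n rank cutoff (default 25).
#' @return an object of class `"frequency_table"`: list with `pair_counts`
#'   and `drug_counts` data frames (sorted by descending count, ties by
#'   name), plus `top_n` and `n_lines`.
#' @export
rank_frequency <- function(rankings, top_n = 25L) {
  if (!length(rankings)) stop("no rankings supplied", call. = FALSE)
  universe <- sort(.pair_key(rankings[[1L]]$drug_a, rankings[[1L]]$drug_b))
  drugs <- sort(unique(c(rankings[[1L]]$drug_a, rankings[[1L]]$drug_b)))
  for (r in rankings) {
    if (!identical(sort(.pair_key(r$drug_a, r$drug_b)), universe))
      stop("rankings are not over the same drug set", call. = FALSE)
  }
  if (top_n > length(universe))
    stop("'top_n' exceeds the number of drug pairs", call. = FALSE)
  pair_counts <- stats::setNames(integer(length(universe)), universe)
  drug_counts <- stats::setNames(integer(length(drugs)), drugs)
  for (r in rankings) {
    top <- r[r$rank <= top_n, , drop = FALSE]
    keys <- .pair_key(top$drug_a, top$drug_b)
    pair_counts[keys] <- pair_counts[keys] + 1L
    tb <- table(c(top$drug_a, top$drug_b))
    drug_counts[names(tb)] <- drug_counts[names(tb)] + as.integer(tb)
  }
  pc <- data.frame(pair = names(pair_counts), count = as.integer(pair_counts),
                   stringsAsFactors = FALSE)
  pc <- pc[order(-pc$count, pc$pair), , drop = FALSE]
  rownames(pc) <- NULL
  dc <- data.frame(drug = names(drug_counts), count = as.integer(drug_counts),
                   stringsAsFactors = FALSE)
  dc <- dc[order(-dc$count, dc$drug), , drop = FALSE]
  rownames(dc) <- NULL
  structure(list(top_n = as.integer(top_n), n_lines = length(rankings),
                 pair_counts = pc, drug_counts = dc),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, n = 10L, ...) {
  cat("Top-", x$top_n, " frequency over ", x$n_lines, " lines\n", sep = "")
  cat("Pairs:\n")
  print(utils::head(x$pair_counts, n), row.names = FALSE)
  cat("Drugs:\n")
  print(utils::head(x$drug_counts, n), row.names = FALSE)
  invisible(x)
}

#' Hierarchical clustering of cohort rank profiles
#'
#' Agglomerative clustering (average linkage) of per-line pair-ranking
#' vectors, with distance 1 - Spearman correlation. Lines with identical
#' rank profiles merge at height 0; exactly reversed profiles are at the
#' maximal distance 2.
#'
#' @param rank_matrix numeric matrix, lines x pairs, of ranks (row names
#'   identify lines).
#' @return an object of class `"hclust"`.
#' @export
cluster_rank_profiles <- function(rank_matrix) {
  M <- as.matrix(rank_matrix)
  if (nrow(M) < 2L) stop("need at least 2 lines to cluster", call. = FALSE)
  if (is.null(rownames(M))) rownames(M) <- paste0("line", seq_len(nrow(M)))
  sds <- apply(M, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant rank vector for line(s): ",
         paste(rownames(M)[sds == 0], collapse = ", "), call. = FALSE)
  rho <- stats::cor(t(M), method = "spearman")
  d <- stats::as.dist(1 - rho)
  stats::hclust(d, method = "average")
}

#' Rank matrix from a list of rankings
#'
#' @param rankings list of `"combination_ranking"` objects over the same
#'   pairs; names (or cell-line attributes) label the rows.
#' @return integer matrix, lines x pairs, of ranks.
#' @export
rank_matrix <- function(rankings) {
  keys <- sort(.pair_key(rankings[[1L]]$drug_a, rankings[[1L]]$drug_b))
  M <- t(vapply(rankings, function(r) {
    rk <- stats::setNames(r$rank, .pair_key(r$drug_a, r$drug_b))
    as.integer(rk[keys])
  }, integer(length(keys))))
  colnames(M) <- keys
  labs <- names(rankings)
  if (is.null(labs))
    labs <- vapply(rankings, function(r) {
      cl <- attr(r, "cell_line")
      if (is.na(cl)) NA_character_ else cl
    }, character(1L))
  if (!anyNA(labs)) rownames(M) <- labs
  M
}

#' Polygonogram edge list
#'
#' One edge per unordered drug pair, weighted by the pair's fitted
#' interaction coefficient beta_ij; if a ranking is supplied the pair's
#' projected score and rank are joined. The edge list is the data behind a
#' polygonogram display of pairwise interaction effects.
#'
#' @param surface a `"qpop_surface"` fit.
#' @param ranking optional `"combination_ranking"` for the same surface.
#' @return data frame with columns `drug_a`, `drug_b`, `interaction` and,
#'   when a ranking is given, `projected_output` and `rank`.
#' @export
polygonogram_edges <- function(surface, ranking = NULL) {
  pr <- surface$pair_index
  out <- data.frame(drug_a = surface$drugs[pr[1L, ]],
                    drug_b = surface$drugs[pr[2L, ]],
                    interaction = unname(surface$beta_int),
                    stringsAsFactors = FALSE)
  if (!is.null(ranking)) {
    key <- .pair_key(out$drug_a, out$drug_b)
    rkey <- .pair_key(ranking$drug_a, ranking$drug_b)
    idx <- match(key, rkey)
    out$projected_output <- ranking$projected_output[idx]
    out$rank <- ranking$rank[idx]
  }
  out
}
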