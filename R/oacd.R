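# Orthogonal array composite designs (OACD) for combinatorial dosing.
#
# An OACD concatenates a three-level L27 orthogonal array (coded levels
# -1/0/+1) with a two-level regular fractional factorial (-1/+1), giving
# enough runs, at enough distinct levels, to estimate a full second-order
# polynomial in the drug doses with far fewer wells than a factorial grid.

# Coefficient vectors over GF(3) defining the 13 columns of the standard
# L27(3^13) strength-2 orthogonal array: all non-proportional nonzero linear
# functionals of the 3 base symbols.
.l27_coefs <- matrix(c(
  1, 0, 0,
  0, 1, 0,
  0, 0, 1,
  1, 1, 0,
  1, 2, 0,
  1, 0, 1,
  1, 0, 2,
  0, 1, 1,
  0, 1, 2,
  1, 1, 1,
  1, 1, 2,
  1, 2, 1,
  1, 2, 2), ncol = 3, byrow = TRUE)

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x %% 1 != 0)
    stop("'", name, "' must be a single integer", call. = FALSE)
  as.integer(x)
}

#' Three-level L27 orthogonal array
#'
#' Returns the first `n_factors` columns of the standard 27-run strength-2
#' orthogonal array L27(3^13), recoded to coded dose levels \{-1, 0, +1\}.
#' Every column carries each level exactly 9 times and every pair of columns
#' carries each of the 9 level pairs exactly 3 times. The recoding is chosen
#' so that the all-centre run (every drug at level 0) is one of the 27 rows.
#'
#' @param n_factors number of drugs (columns), between 1 and 13.
#' @return integer matrix of dimension 27 x `n_factors` with entries in
#'   \{-1, 0, 1\}.
#' @seealso [build_two_level_fraction()], [oacd_design()]
#' @export
#' @examples
#' M <- build_three_level_oa(9)
#' colSums(M == 0)  # each level appears 9 times per column
build_three_level_oa <- function(n_factors) {
  n_factors <- .check_count(n_factors, "n_factors")
  if (n_factors < 1L || n_factors > 13L)
    stop("L27 accommodates between 1 and 13 three-level factors, got ",
         n_factors, call. = FALSE)
  base <- as.matrix(expand.grid(a = 0:2, b = 0:2, c = 0:2))
  lev <- (base %*% t(.l27_coefs)) %% 3
  # GF(3) level 0 -> coded 0 keeps the all-zero row as the centre run
  recode <- c(0L, -1L, 1L)
  M <- matrix(recode[lev + 1L], nrow = 27L)
  M[, seq_len(n_factors), drop = FALSE]
}

# Minimum-aberration regular two-level fractions: number of base factors and
# generator words (as indices into the base factors) for k = 5..10.
# k <= 4 uses the full factorial.
.ff_table <- list(
  `5`  = list(nb = 4L, gens = list(c(1L, 2L, 3L, 4L))),                 # 2^(5-1)_V
  `6`  = list(nb = 5L, gens = list(1:5)),                               # 2^(6-1)_VI
  `7`  = list(nb = 6L, gens = list(1:6)),                               # 2^(7-1)_VII
  `8`  = list(nb = 6L, gens = list(c(1L, 2L, 3L, 4L),
                                   c(1L, 2L, 5L, 6L))),                 # 2^(8-2)_V
  `9`  = list(nb = 7L, gens = list(c(1L, 3L, 4L, 6L, 7L),
                                   c(2L, 3L, 5L, 6L, 7L))),             # 2^(9-2)_VI
  `10` = list(nb = 7L, gens = list(c(1L, 2L, 3L, 7L),
                                   c(2L, 3L, 4L, 5L),
                                   c(1L, 3L, 4L, 6L)))                  # 2^(10-3)_V
)

#' Two-level regular fractional factorial
#'
#' Builds a regular 2^(k-p) fraction at the highest resolution attainable at
#' the tabulated run size (minimum-aberration generators; full factorial for
#' k <= 4). For k = 9 the run size is 128, so that together with the L27
#' block the composite design has 155 runs.
#'
#' @param n_factors number of drugs, between 2 and 10.
#' @return integer matrix with entries in \{-1, +1\}; columns are balanced
#'   and pairwise orthogonal.
#' @export
#' @examples
#' F9 <- build_two_level_fraction(9)
#' nrow(F9)       # 128
#' colSums(F9)    # all zero
build_two_level_fraction <- function(n_factors) {
  n_factors <- .check_count(n_factors, "n_factors")
  if (n_factors < 2L)
    stop("a two-level fraction needs at least 2 factors", call. = FALSE)
  if (n_factors > 10L)
    stop("two-level fractions are tabulated for up to 10 factors, got ",
         n_factors, call. = FALSE)
  if (n_factors <= 4L) {
    M <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n_factors)))
  } else {
    tab <- .ff_table[[as.character(n_factors)]]
    B <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), tab$nb)))
    G <- vapply(tab$gens,
                function(idx) apply(B[, idx, drop = FALSE], 1L, prod),
                numeric(nrow(B)))
    M <- cbind(B, G)
  }
  dimnames(M) <- NULL
  storage.mode(M) <- "integer"
  M
}

# 32-bit FNV-1a over a character scalar, returned as 8 hex digits.
# Double arithmetic is kept exact by splitting the 32-bit state into
# 16-bit halves for the multiply.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  g <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * g) %% 65536) * 65536 + h0 * g) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Second-order model matrix
#'
#' Expands a coded design matrix into the model matrix of the full quadratic
#' polynomial: intercept, k linear terms, k pure-quadratic terms and
#' k(k-1)/2 pairwise interaction terms, in that order.
#'
#' @param X numeric matrix of coded levels (runs x drugs); column names, if
#'   present, label the terms.
#' @return numeric matrix with `1 + 2k + k(k-1)/2` columns.
#' @export
quadratic_model_matrix <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  quad <- X^2
  colnames(quad) <- paste0(nm, "^2")
  if (k >= 2L) {
    pr <- utils::combn(k, 2L)
    int <- X[, pr[1L, ], drop = FALSE] * X[, pr[2L, ], drop = FALSE]
    colnames(int) <- paste0(nm[pr[1L, ]], ":", nm[pr[2L, ]])
  } else {
    int <- matrix(numeric(0), nrow = nrow(X), ncol = 0L)
  }
  lin <- X
  colnames(lin) <- nm
  cbind(`(Intercept)` = rep(1, nrow(X)), lin, quad, int)
}

#' Compose an orthogonal array composite design
#'
#' Concatenates the three-level L27 block with the two-level fractional
#' factorial block. For 9 drugs this gives the canonical 155-run layout
#' (27 + 128) whose second-order model matrix has full column rank 55, so
#' the quadratic response-surface fit is uniquely determined.
#'
#' @param n_factors number of drugs, between 2 and 10.
#' @param drugs optional character vector of drug names (defaults to
#'   `drug1..drugk`).
#' @return an object of class `"oacd_design"`: a list with elements
#'   `n_factors`, `runs` (coded matrix with drug column names), `block`
#'   (per-row label, `"three_level"` or `"two_level"`), `run_id` and
#'   `design_hash` (stable content digest).
#' @export
#' @examples
#' d <- oacd_design(9)
#' nrow(d$runs)                               # 155
#' qr(quadratic_model_matrix(d$runs))$rank    # 55
oacd_design <- function(n_factors, drugs = NULL) {
  n_factors <- .check_count(n_factors, "n_factors")
  if (n_factors < 2L)
    stop("an OACD needs at least 2 drugs", call. = FALSE)
  oa <- build_three_level_oa(n_factors)
  ff <- build_two_level_fraction(n_factors)
  runs <- rbind(oa, ff)
  if (is.null(drugs)) drugs <- paste0("drug", seq_len(n_factors))
  if (length(drugs) != n_factors || anyDuplicated(drugs))
    stop("'drugs' must be ", n_factors, " unique names", call. = FALSE)
  colnames(runs) <- drugs
  block <- rep(c("three_level", "two_level"), c(nrow(oa), nrow(ff)))
  hash <- .fnv1a(paste(c(drugs, as.integer(runs)), collapse = ","))
  structure(list(n_factors = n_factors,
                 runs = runs,
                 block = block,
                 run_id = seq_len(nrow(runs)),
                 design_hash = hash),
            class = "oacd_design")
}

#' @rdname oacd_design
#' @export
compose_oacd <- oacd_design

#' @export
print.oacd_design <- function(x, ...) {
  cat("Orthogonal array composite design\n")
  cat("  drugs:", x$n_factors, paste0("(", paste(colnames(x$runs), collapse = ", "), ")"), "\n")
  cat("  runs :", nrow(x$runs), "=",
      sum(x$block == "three_level"), "three-level OA +",
      sum(x$block == "two_level"), "two-level fraction\n")
  cat("  second-order terms:", ncol(quadratic_model_matrix(x$runs)), "\n")
  cat("  hash :", x$design_hash, "\n")
  invisible(x)
}

.as_coded_matrix <- function(design) {
  if (inherits(design, "oacd_design")) design$runs else as.matrix(design)
}

#' Per-drug dose specification at coded levels
#'
#' Records the concentration (in uM) a drug takes at coded levels -1, 0 and
#' +1. In the dosing convention used here the levels are the IC0, IC10 and
#' IC20 of the drug, so level -1 is usually 0 uM (drug absent).
#'
#' @param drug drug name.
#' @param conc numeric vector of length 3, concentrations at levels
#'   (-1, 0, +1); must be non-negative and non-decreasing.
#' @return an object of class `"dose_spec"`.
#' @export
#' @examples
#' dose_spec("ixazomib", c(0, 0.012, 0.020))
dose_spec <- function(drug, conc) {
  if (!is.character(drug) || length(drug) != 1L || !nzchar(drug))
    stop("'drug' must be a non-empty name", call. = FALSE)
  conc <- as.numeric(conc)
  if (length(conc) != 3L || anyNA(conc) || any(!is.finite(conc)))
    stop("'conc' must give finite concentrations at levels -1, 0, +1", call. = FALSE)
  if (conc[1L] < 0)
    stop("concentration at level -1 must be >= 0", call. = FALSE)
  if (is.unsorted(conc))
    stop("concentrations must be non-decreasing in the coded level", call. = FALSE)
  names(conc) <- c("-1", "0", "1")
  structure(list(drug = drug, conc = conc), class = "dose_spec")
}

#' @export
print.dose_spec <- function(x, ...) {
  cat(sprintf("%s: %g / %g / %g uM at levels -1/0/+1\n",
              x$drug, x$conc[1L], x$conc[2L], x$conc[3L]))
  invisible(x)
}

#' Map a coded design to plate concentrations
#'
#' Replaces each coded entry of the design by the concentration the matching
#' dose specification assigns to that level; row order is preserved.
#'
#' @param design an [oacd_design()] object or coded matrix.
#' @param specs list of [dose_spec()] objects, one per design column, in
#'   column order or named consistently with the columns.
#' @return data frame with columns `run_id`, `block` (if available) and one
#'   concentration column (uM) per drug.
#' @export
map_design_to_concentrations <- function(design, specs) {
  X <- .as_coded_matrix(design)
  k <- ncol(X)
  if (!is.list(specs) || length(specs) != k)
    stop("need one dose spec per design column", call. = FALSE)
  ok <- vapply(specs, inherits, logical(1L), what = "dose_spec")
  if (!all(ok)) stop("'specs' must be a list of dose_spec objects", call. = FALSE)
  spec_names <- vapply(specs, `[[`, character(1L), "drug")
  if (anyDuplicated(spec_names)) stop("drug names in 'specs' must be unique", call. = FALSE)
  cn <- colnames(X)
  if (!is.null(cn)) {
    if (!setequal(cn, spec_names))
      stop("dose specs do not match the design's drugs", call. = FALSE)
    specs <- specs[match(cn, spec_names)]
    spec_names <- cn
  }
  conc <- vapply(seq_len(k), function(j) {
    lv <- as.character(X[, j])
    specs[[j]]$conc[lv]
  }, numeric(nrow(X)))
  if (anyNA(conc)) stop("design contains a coded level missing from a dose spec", call. = FALSE)
  colnames(conc) <- spec_names
  out <- data.frame(run_id = if (inherits(design, "oacd_design")) design$run_id else seq_len(nrow(X)),
                    check.names = FALSE)
  if (inherits(design, "oacd_design")) out$block <- design$block
  cbind(out, as.data.frame(conc, check.names = FALSE))
}

#' Write / read a design as CSV
#'
#' The CSV carries `run_id`, `block` and one coded-level column per drug.
#' `read_design_csv()` accepts a user-supplied layout (for instance a
#' transcription of a published run table) as an override for the
#' constructed design; invariants are re-checked on load.
#'
#' @param design an [oacd_design()] object.
#' @param path file path.
#' @return `read_design_csv()` returns an `"oacd_design"` object.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "oacd_design"))
  df <- data.frame(run_id = design$run_id, block = design$block,
                   design$runs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("run_id", "block") %in% names(df)))
    stop("design CSV must have 'run_id' and 'block' columns", call. = FALSE)
  drug_cols <- setdiff(names(df), c("run_id", "block"))
  X <- as.matrix(df[, drug_cols, drop = FALSE])
  if (!all(X %in% c(-1L, 0L, 1L)))
    stop("coded levels must be in {-1, 0, 1}", call. = FALSE)
  storage.mode(X) <- "integer"
  two <- df$block == "two_level"
  if (any(X[two, ] == 0L))
    stop("two-level block rows may only contain levels -1 and +1", call. = FALSE)
  hash <- .fnv1a(paste(c(drug_cols, as.integer(X)), collapse = ","))
  structure(list(n_factors = ncol(X), runs = X, block = df$block,
                 run_id = df$run_id, design_hash = hash),
            class = "oacd_design")
}

#' Write / read dose specifications as JSON
#'
#' One record per drug: `{"drug": name, "levels": {"-1": uM, "0": uM, "1": uM}}`.
#'
#' @param specs list of [dose_spec()] objects.
#' @param path file path.
#' @return `read_dose_specs()` returns a list of `"dose_spec"` objects.
#' @export
write_dose_specs <- function(specs, path) {
  recs <- lapply(specs, function(s)
    list(drug = s$drug, levels = as.list(s$conc)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_specs
#' @export
read_dose_specs <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    lv <- r$levels
    need <- c("-1", "0", "1")
    if (!all(need %in% names(lv)))
      stop("dose spec for '", r$drug, "' is missing a coded level", call. = FALSE)
    dose_spec(r$drug, unlist(lv[need]))
  })
}
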