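# Shared helpers: independent brute-force oracles and small generators.

# Random full second-order coefficient vector matching
# quadratic_model_matrix() column order for a k-drug design.
random_surface_coefs <- function(k, seed) {
  set.seed(seed)
  p <- 1L + 2L * k + k * (k - 1L) / 2L
  stats::rnorm(p, 0, 0.5)
}

# Direct polynomial evaluation at one coded point, written independently of
# quadratic_model_matrix(): beta0 + sum bi xi + sum bii xi^2 + sum bij xi xj.
eval_poly_naive <- function(coefs, x) {
  k <- length(x)
  coefs <- unname(coefs)
  val <- coefs[1L]
  val <- val + sum(coefs[1L + seq_len(k)] * x)
  val <- val + sum(coefs[1L + k + seq_len(k)] * x^2)
  idx <- 1L + 2L * k
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- idx + 1L
      val <- val + coefs[idx] * x[i] * x[j]
    }
  }
  val
}

# Exhaustive-enumeration pair-scoring oracle: best value of the polynomial
# over all 3^k coded points with at most the two pair drugs above level -1
# (pair levels restricted to {0, 1}).
brute_force_pair_scores <- function(coefs, k, drugs, maximize = TRUE) {
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), k)))
  vals <- apply(grid, 1L, function(x) eval_poly_naive(coefs, x))
  pr <- utils::combn(k, 2L)
  out <- data.frame(drug_a = drugs[pr[1L, ]], drug_b = drugs[pr[2L, ]],
                    score = NA_real_, stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pr))) {
    i <- pr[1L, p]; j <- pr[2L, p]
    keep <- apply(grid, 1L, function(x) {
      others <- x[-c(i, j)]
      all(others == -1) && x[i] %in% c(0, 1) && x[j] %in% c(0, 1)
    })
    v <- vals[keep]
    out$score[p] <- if (maximize) max(v) else min(v)
  }
  out
}

# Naive average-linkage agglomeration on a distance matrix: returns the
# sequence of merge heights, independent of stats::hclust.
naive_average_linkage_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- mean(D[clusters[[a]], clusters[[b]]])
        if (h < bh) { bh <- h; best <- c(a, b) }
      }
    }
    heights <- c(heights, bh)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Coefficient vector for a surface whose only structure is an
# absence-anchored pairwise synergy c * (xi + 1) * (xj + 1): the interaction
# vanishes whenever either drug is at level -1 (absent), as mechanistic
# interactions do. Expands to beta0 = beta_i = beta_j = beta_ij = c.
planted_pair_coefs <- function(k, i, j, strength, drugs = paste0("drug", seq_len(k))) {
  mm_names <- colnames(quadratic_model_matrix(
    matrix(0, 1, k, dimnames = list(NULL, drugs))))
  coefs <- stats::setNames(numeric(length(mm_names)), mm_names)
  coefs["(Intercept)"] <- strength
  coefs[drugs[i]] <- strength
  coefs[drugs[j]] <- strength
  coefs[paste0(drugs[min(i, j)], ":", drugs[max(i, j)])] <- strength
  coefs
}

# Loewe-additive fixed-ratio combination of two median-effect drugs sharing
# a common slope m: closed-form fa at total dose from dose-equivalence.
loewe_viability <- function(total_dose, ratio, Dm_a, Dm_b, m) {
  r <- (total_dose * ratio[1L] / Dm_a + total_dose * ratio[2L] / Dm_b)^m
  1 / (1 + r)
}
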