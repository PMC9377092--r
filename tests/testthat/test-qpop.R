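test_that("therapeutic output is the normal-minus-tumor viability difference", {
  expect_equal(therapeutic_output(1.0, 0.2), 0.8)
  expect_equal(therapeutic_output(0.5, 0.5), 0.0)
  expect_equal(therapeutic_output(0.2, 1.0), -0.8)
  expect_error(therapeutic_output(NA_real_, 0.5), "finite")
  expect_error(therapeutic_output(Inf, 0.5), "finite")
})

test_that("quadratic surface is recovered exactly from noise-free data", {
  d <- oacd_design(9)
  coefs <- random_surface_coefs(9, seed = 42)
  y <- simulate_quadratic_truth(coefs, d)
  fit <- fit_quadratic_surface(d, y)
  expect_lt(max(abs(fit$coefficients - coefs)), 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # coefficient blocks partition the full vector
  expect_equal(length(fit$beta_lin), 9L)
  expect_equal(length(fit$beta_quad), 9L)
  expect_equal(length(fit$beta_int), 36L)
  expect_equal(unname(c(fit$beta0, fit$beta_lin, fit$beta_quad, fit$beta_int)),
               unname(fit$coefficients))
})

test_that("degenerate and undersized inputs are handled per contract", {
  d <- oacd_design(4)
  fit <- fit_quadratic_surface(d, rep(0.3, nrow(d$runs)))
  expect_equal(unname(fit$beta0), 0.3, tolerance = 1e-12)
  expect_lt(max(abs(fit$coefficients[-1L])), 1e-12)
  expect_true(is.na(fit$f_stat))
  expect_equal(fit$adj_r2, 0)

  expect_error(fit_quadratic_surface(matrix(c(-1, 0, 1), 10, 9), rnorm(10)),
               "insufficient runs")
})

test_that("predict/residuals/coef methods are consistent with the fit", {
  d <- oacd_design(5)
  coefs <- random_surface_coefs(5, seed = 3)
  y <- simulate_quadratic_truth(coefs, d, noise_sd = 0.02, seed = 9)
  fit <- fit_quadratic_surface(d, y)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(y))
  expect_equal(unname(predict(fit, d$runs)), unname(fitted(fit)))
  # prediction at a point equals naive polynomial arithmetic
  x <- c(0.5, -1, 1, 0, -0.5)
  expect_equal(predict(fit, matrix(x, 1)), eval_poly_naive(fit$coefficients, x))
})

test_that("backward elimination drops only insignificant terms", {
  d <- oacd_design(4)
  # strong signal in two terms, everything else zero
  coefs <- rep(0, 15)
  coefs[1] <- 0.2; coefs[2] <- 1; coefs[12] <- 1.5  # intercept, x1, one interaction
  y <- simulate_quadratic_truth(coefs, d, noise_sd = 0.01, seed = 5)
  fit <- fit_quadratic_surface(d, y, eliminate = TRUE, alpha = 0.05)
  kept <- names(fit$coefficients)[fit$coefficients != 0]
  expect_true(all(c("drug1", names(fit$coefficients)[12]) %in% kept))
  expect_gt(length(fit$removed_terms), 0)
  expect_true(all(fit$coefficients[fit$removed_terms] == 0))
})

test_that("a planted pairwise synergy wins pair scoring at (1,1)", {
  d <- oacd_design(4, drugs = c("a", "b", "c", "e"))
  # absence-anchored synergy 0.5 * (x_b + 1)(x_c + 1): zero whenever either
  # partner is absent, maximal at the (IC20, IC20) corner
  coefs <- planted_pair_coefs(4, 2, 3, 0.5, drugs = c("a", "b", "c", "e"))
  y <- simulate_quadratic_truth(coefs, d)
  fit <- fit_quadratic_surface(d, y)
  rk <- score_two_drug_combinations(fit)
  expect_equal(c(rk$drug_a[1], rk$drug_b[1]), c("b", "c"))
  expect_equal(c(rk$level_a[1], rk$level_b[1]), c(1, 1))
  expect_equal(rk$projected_output[1], 0.5 * 4, tolerance = 1e-10)
  # every pair not containing both partners projects 0
  expect_equal(rk$projected_output[-1], rep(0, 5), tolerance = 1e-10)
  expect_equal(rk$rank, seq_len(6))

  # a bare interaction coefficient also contributes at the all-absent
  # baseline through the (-1)(-1) cross term, so a disjoint pair inherits
  # the same best score: the coded-space prediction is shared, not unique
  bare <- rep(0, 15)
  names(bare) <- names(coefs)
  bare["b:c"] <- 0.5
  fit2 <- fit_quadratic_surface(d, simulate_quadratic_truth(bare, d))
  rk2 <- score_two_drug_combinations(fit2)
  expect_equal(max(rk2$projected_output), 0.5, tolerance = 1e-10)
  bc <- rk2[rk2$drug_a == "b" & rk2$drug_b == "c", ]
  expect_equal(bc$projected_output, 0.5, tolerance = 1e-10)
  expect_equal(c(bc$level_a, bc$level_b), c(1, 1))
})

test_that("pair scoring matches the exhaustive-enumeration oracle", {
  for (k in 3:5) {
    d <- oacd_design(k)
    coefs <- random_surface_coefs(k, seed = 100 + k)
    y <- simulate_quadratic_truth(coefs, d)
    fit <- fit_quadratic_surface(d, y)
    rk <- score_two_drug_combinations(fit)
    oracle <- brute_force_pair_scores(fit$coefficients, k, fit$drugs)
    key <- paste(rk$drug_a, rk$drug_b)
    okey <- paste(oracle$drug_a, oracle$drug_b)
    expect_equal(rk$projected_output, oracle$score[match(key, okey)],
                 tolerance = 1e-10)
  }
})

test_that("ranking is equivariant under drug relabeling and output shifts", {
  d <- oacd_design(4, drugs = c("a", "b", "c", "e"))
  coefs <- random_surface_coefs(4, seed = 77)
  y <- simulate_quadratic_truth(coefs, d)
  fit <- fit_quadratic_surface(d, y)
  rk <- score_two_drug_combinations(fit)

  # permute drug labels: same scores attached to permuted names
  perm <- c(3, 1, 4, 2)
  Xp <- d$runs[, perm]
  fitp <- fit_quadratic_surface(Xp, y)
  rkp <- score_two_drug_combinations(fitp)
  key <- function(r) paste(pmin(r$drug_a, r$drug_b), pmax(r$drug_a, r$drug_b))
  expect_equal(sort(key(rk)), sort(key(rkp)))
  expect_equal(rkp$projected_output[match(key(rk), key(rkp))],
               rk$projected_output, tolerance = 1e-10)

  # adding a constant to the outputs shifts every score but no rank
  fit2 <- fit_quadratic_surface(d, y + 5)
  rk2 <- score_two_drug_combinations(fit2)
  expect_equal(key(rk2), key(rk))
  expect_equal(rk2$projected_output - rk$projected_output, rep(5, 6),
               tolerance = 1e-9)
})

test_that("kill objectives minimize projected viability", {
  d <- oacd_design(3, drugs = c("a", "b", "c"))
  coefs <- rep(0, 10)
  names(coefs) <- colnames(quadratic_model_matrix(d$runs))
  coefs["(Intercept)"] <- 1
  coefs["a:b"] <- -0.4  # this pair kills most at (1,1)
  y <- simulate_quadratic_truth(coefs, d)
  fit <- fit_quadratic_surface(d, y)
  rk <- score_two_drug_combinations(fit, objective = "pdxo_kill")
  expect_equal(c(rk$drug_a[1], rk$drug_b[1]), c("a", "b"))
  expect_equal(rk$projected_output[1], 0.6, tolerance = 1e-10)
})

test_that("frequency tables count pairs and drugs coherently", {
  d <- oacd_design(9)
  coefs <- random_surface_coefs(9, seed = 11)
  y <- simulate_quadratic_truth(coefs, d)
  fit <- fit_quadratic_surface(d, y)
  rk <- score_two_drug_combinations(fit)
  n_lines <- 4L
  ft <- rank_frequency(rep(list(rk), n_lines), top_n = 25)
  # identical rankings: every top-25 pair counted n_lines times
  expect_equal(sum(ft$pair_counts$count), 25L * n_lines)
  expect_true(all(ft$pair_counts$count %in% c(0L, n_lines)))
  # drug counts are the column sums of pair membership
  for (dr in ft$drug_counts$drug) {
    in_pair <- grepl(dr, ft$pair_counts$pair, fixed = TRUE)
    expect_equal(ft$drug_counts$count[ft$drug_counts$drug == dr],
                 sum(ft$pair_counts$count[in_pair]))
  }
  expect_error(rank_frequency(list(rk), top_n = 37), "exceeds")
})

test_that("a planted common pair dominates a small cohort frequency table", {
  drugs <- paste0("d", 1:6)
  d <- oacd_design(6, drugs = drugs)
  rankings <- lapply(1:3, function(i) {
    coefs <- random_surface_coefs(6, seed = 400 + i) * 0.1 +
      planted_pair_coefs(6, 2, 5, 2, drugs = drugs)  # shared strong pair
    fit <- fit_quadratic_surface(d, simulate_quadratic_truth(coefs, d))
    score_two_drug_combinations(fit)
  })
  ft <- rank_frequency(rankings, top_n = 3)
  expect_equal(ft$pair_counts$pair[1], "d2 + d5")
  expect_equal(ft$pair_counts$count[1], 3L)
})

test_that("rank-profile clustering matches a naive linkage oracle", {
  r1 <- c(1, 2, 3, 4, 5, 6)
  M <- rbind(a = r1, b = r1, c = rev(r1), e = c(2, 1, 3, 4, 6, 5))
  hc <- cluster_rank_profiles(M)
  # identical lines merge at height 0; reversed profiles sit at distance 2
  expect_equal(min(hc$height), 0)
  rho <- cor(t(M), method = "spearman")
  expect_equal(1 - rho["a", "c"], 2)
  # merge heights equal an independently coded naive average-linkage pass
  D <- 1 - rho
  expect_equal(sort(hc$height),
               sort(naive_average_linkage_heights(D)),
               tolerance = 1e-12)
  expect_error(cluster_rank_profiles(rbind(a = r1, b = rep(2, 6))), "b")
})

test_that("surface grids and polygonogram edges expose the fitted geometry", {
  d <- oacd_design(3, drugs = c("a", "b", "c"))
  coefs <- rep(0, 10)
  names(coefs) <- colnames(quadratic_model_matrix(d$runs))
  coefs["a:b"] <- 0.8
  fit <- fit_quadratic_surface(d, simulate_quadratic_truth(coefs, d))
  grid <- export_response_surface(fit, c("a", "b"), grid_points_per_axis = 21)
  expect_equal(nrow(grid), 441L)
  # corner evaluations equal direct polynomial arithmetic
  for (pt in list(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))) {
    row <- grid[grid$level_a == pt[1] & grid$level_b == pt[2], ]
    expect_equal(row$output,
                 eval_poly_naive(fit$coefficients, c(pt, -1)),
                 tolerance = 1e-10)
  }
  # positive interaction: saddle with the grid maximum attained at (1, 1)
  expect_equal(max(grid$output), 0.8, tolerance = 1e-10)
  expect_equal(grid$output[grid$level_a == 1 & grid$level_b == 1], 0.8,
               tolerance = 1e-10)
  expect_lt(grid$output[grid$level_a == 1 & grid$level_b == -1], 0)
  edges <- polygonogram_edges(fit, score_two_drug_combinations(fit))
  expect_equal(nrow(edges), 3L)
  expect_equal(edges$interaction[edges$drug_a == "a" & edges$drug_b == "b"],
               0.8, tolerance = 1e-10)
  expect_true(all(c("projected_output", "rank") %in% names(edges)))
})

test_that("replicate averaging preserves run order", {
  av <- average_replicates(c(2, 2, 1, 1), c(0.4, 0.6, 1, 0.8))
  expect_equal(unname(av), c(0.5, 0.9))
  expect_equal(names(av), c("2", "1"))
})
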