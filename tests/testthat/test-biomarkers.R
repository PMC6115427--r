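test_that("fit_linear reproduces closed-form OLS on a hand example", {
  y <- c(1, 2, 3, 4); x <- c(1, 2, 3, 5)
  X <- cbind(intercept = 1, x = x)
  fit <- fit_linear(y, X, "toy")
  beta_hat <- solve(t(X) %*% X) %*% t(X) %*% y       # normal equations
  expect_equal(unname(fit$coefficients), c(beta_hat))
  res <- y - X %*% beta_hat
  se <- sqrt(c(sum(res^2) / 2) * diag(solve(t(X) %*% X)))
  p_slope <- 2 * pt(-abs(beta_hat[2] / se[2]), df = 2)
  expect_equal(unname(fit$p_values["x"]), unname(p_slope))
  expect_equal(r_squared(fit), 1 - sum(res^2) / sum((y - mean(y))^2))
})

test_that("fit_linear handles perfect fits, degenerate designs and rank deficiency", {
  x <- 1:6
  fit <- suppressWarnings(fit_linear(2 * x, cbind(intercept = 1, x = x)))
  expect_equal(unname(fit$coefficients), c(0, 2))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  expect_equal(r_squared(fit), 1)
  # intercept-only: fits, no non-intercept p-values
  fit0 <- fit_linear(rnorm(8), cbind(intercept = rep(1, 8)))
  expect_length(fit0$p_values, 0)
  expect_equal(r_squared(fit0), 0)
  expect_error(fit_linear(1:6, cbind(intercept = 1, x = x, x2 = 2 * x)),
               "collinear.*x2")
  expect_error(fit_linear(1:6, cbind(x = x)), "intercept")
  fconst <- suppressWarnings(fit_linear(rep(2, 6),
                                        cbind(intercept = 1, x = x)))
  expect_warning(r2 <- r_squared(fconst), "constant")
  expect_equal(r2, 0)
})

test_that("R-squared never decreases when a column is added", {
  set.seed(31)
  for (i in 1:10) {
    n <- 20
    y <- rnorm(n)
    x1 <- rnorm(n); x2 <- rnorm(n)
    f1 <- fit_linear(y, cbind(i = 1, x1 = x1))
    f2 <- fit_linear(y, cbind(i = 1, x1 = x1, x2 = x2))
    expect_gte(r_squared(f2), r_squared(f1) - 1e-12)
  }
})

test_that("predictor comparison recovers the planted generative mode", {
  # tissue-generated dependencies -> tissue wins
  tis <- c(A = 8, B = 8, C = 8)
  br <- rbind(A = c(0.10, 0.60, 0.20), B = c(0.40, 0.10, 0.60),
              C = c(0.70, 0.30, 0.05))
  colnames(br) <- c("A199", "W539", "A121")
  cfg <- sim_config(tissues = tis, base_rates = br,
                    dependency_rules = list(),
                    emt = list(xl_coupling = 0, synergy = 0),
                    crispr = NULL, seed = 41)
  b <- simulate_screen(cfg)
  cmp <- compare_predictors(build_profiles(b$viability_panel),
                            b$tissue_labels, b$mutations,
                            phenotypes = c("A199", "W539", "A121"))
  expect_true(all(cmp$winner == "tissue"))
  # mutation-generated dependencies -> mutation wins
  br0 <- br; br0[] <- 0.1
  cfg2 <- sim_config(tissues = tis, base_rates = br0,
                     dependency_rules = list(),
                     mutation_rules = list(
                       list(gene = "TP53", condition = "W539", effect = 50),
                       list(gene = "KRAS", condition = "A121", effect = 50)),
                     emt = list(xl_coupling = 0, synergy = 0),
                     crispr = NULL, seed = 42)
  b2 <- simulate_screen(cfg2)
  cmp2 <- compare_predictors(build_profiles(b2$viability_panel),
                             b2$tissue_labels, b2$mutations,
                             phenotypes = c("W539", "A121"))
  expect_true(all(cmp2$winner == "mutation"))
})

test_that("expression association finds the planted driver with the right sign", {
  cfg <- sim_config(crispr = NULL, seed = 51)
  b <- simulate_screen(cfg)
  prof <- build_profiles(b$viability_panel)
  assoc <- expression_association(prof, b$expression,
                                  phenotypes = c("W539", "A121"))
  w <- assoc[assoc$phenotype == "W539", ]
  # planted rule: high NOXA (PMAIP1) -> BCL-XL dependence, positive slope
  expect_equal(w$gene[which.min(w$p_value)], "PMAIP1")
  expect_gt(w$slope[w$gene == "PMAIP1"], 0)
  expect_equal(w$inverse_p, 1 / w$p_value)
  # planted rule: low BCL2L1 -> MCL-1 dependence, negative slope
  a <- assoc[assoc$phenotype == "A121", ]
  expect_equal(a$gene[which.min(a$p_value)], "BCL2L1")
  expect_lt(a$slope[a$gene == "BCL2L1"], 0)
  # BH adjustment is monotone in p and never smaller
  adj <- expression_association(prof, b$expression,
                                phenotypes = "W539", adjust = "BH")
  expect_true(all(adj$p_adj >= adj$p_value - 1e-15))
})

test_that("permuting expression across lines kills the association signal", {
  cfg <- sim_config(crispr = NULL, seed = 52)
  b <- simulate_screen(cfg)
  prof <- build_profiles(b$viability_panel)
  set.seed(99)
  hits <- replicate(20, {
    ex <- b$expression[, sample(ncol(b$expression))]
    colnames(ex) <- colnames(b$expression)
    a <- expression_association(prof, ex, phenotypes = "W539")
    mean(a$p_value < 0.05)
  })
  # null rejection rate ~ 5%; generous binomial band over 20x15 tests
  expect_lt(mean(hits), 0.12)
})

test_that("find_threshold equals the brute-force oracle on small data", {
  set.seed(61)
  for (i in 1:60) {
    n <- sample(6:12, 1)
    # mix continuous values and ties
    expr <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) + 0
            else rnorm(n)
    scores <- if (i %% 2 == 0) rnorm(n, 50, 20)
              else 40 + 40 * (expr > median(expr)) + rnorm(n, 0, 5)
    mgs <- sample(2:3, 1)
    oracle <- brute_threshold(expr, scores, mgs)
    if (is.null(oracle)) {
      expect_error(find_threshold(expr, scores, mgs), "admissible")
      next
    }
    got <- find_threshold(expr, scores, mgs)
    expect_equal(got$threshold, oracle$threshold)
    expect_equal(got$p_value, oracle$p)
    expect_equal(got$direction, oracle$dir)
  }
})

test_that("step-function scores yield the exact separating threshold", {
  expr <- 1:10
  scores <- c(rep(0, 5), rep(80, 5))
  res <- find_threshold(expr, scores, min_group_size = 3)
  expect_equal(res$threshold, 5.5)
  expect_equal(res$direction, "above-sensitive")
  expect_equal(res$p_value, 0)  # perfect separation, zero within-group var
  expect_equal(res$n_below, 5); expect_equal(res$n_above, 5)
  # all-equal scores: every split ties at p = 1
  flat <- find_threshold(expr, rep(10, 10), min_group_size = 3)
  expect_equal(flat$p_value, 1)
  expect_error(find_threshold(rep(1, 10), rnorm(10)), "distinct")
  expect_error(find_threshold(1:4, rnorm(4), min_group_size = 3),
               "2\\*min_group_size")
})

test_that("welch variant matches stats::t.test per split", {
  set.seed(62)
  expr <- rnorm(14); scores <- rnorm(14, 50, 15)
  got <- find_threshold(expr, scores, min_group_size = 4, ttest = "welch")
  oracle <- brute_threshold(expr, scores, 4, welch = TRUE)
  expect_equal(got$threshold, oracle$threshold)
  expect_equal(got$p_value, oracle$p)
})

test_that("permutation-adjusted threshold p is calibrated under the null", {
  set.seed(71)
  n_seeds <- 500
  rej <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    expr <- rnorm(20); scores <- rnorm(20, 50, 10)
    res <- find_threshold(expr, scores, min_group_size = 3, n_perm = 99)
    rej[i] <- res$p_perm <= 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
  # while the raw minimum p is selection-biased (far more than 5% below 0.05)
  set.seed(72)
  raw <- replicate(200, find_threshold(rnorm(20), rnorm(20, 50, 10),
                                       min_group_size = 3)$p_value)
  expect_gt(mean(raw < 0.05), 0.10)
})

test_that("a fixed threshold validates on an independent cohort", {
  set.seed(81)
  thr <- 10
  make_cohort <- function(n) {
    expr <- rnorm(n, 10, 1.5)
    list(expr = setNames(expr, paste0("c", 1:n)),
         sens = setNames(-2 * (expr > thr) + rnorm(n, 0, 0.8),
                         paste0("c", 1:n)))
  }
  co <- make_cohort(100)
  v <- validate_threshold(thr, co$expr, co$sens)
  expect_lt(v$p_value, 0.05)
  expect_lt(v$mean_above, v$mean_below)  # planted: above-threshold sensitive
  expect_equal(v$n_below + v$n_above, 100)
  # threshold outside the expression range -> degenerate split -> error
  expect_error(validate_threshold(99, co$expr, co$sens), "fewer than 2")
  # null cohort: p roughly uniform (single draw, just not systematically tiny)
  co0 <- make_cohort(100)
  co0$sens[] <- rnorm(100)
  expect_gt(validate_threshold(thr, co0$expr, co0$sens)$p_value, 1e-4)
})

test_that("outlier deltas are zero at the tissue mean and guarded at 0/0", {
  expr <- matrix(3, 2, 4, dimnames = list(c("PMAIP1", "BCL2L1"),
                                          paste0("L", 1:4)))
  prof <- data.frame(cell_line = rep(paste0("L", 1:4), each = 1),
                     condition = "W539", score = c(20, 20, 0, 0),
                     n = 3, class = NA)
  tl <- data.frame(cell_line = paste0("L", 1:4),
                   tissue = c("A", "A", "B", "B"))
  out <- outlier_analysis(prof, expr, tl, phenotypes = "W539")
  expect_true(all(out$dep_delta == 0))
  expect_true(all(out$expr_delta == 0))  # 0/0 tissue-mean guard via equal values
})

test_that("a planted expression/dependency outlier is flagged concordant", {
  expr <- matrix(10, 1, 4, dimnames = list("PMAIP1", paste0("L", 1:4)))
  expr["PMAIP1", "L1"] <- 12  # +2 log2 over its tissue mates
  prof <- data.frame(cell_line = paste0("L", 1:4), condition = "W539",
                     score = c(60, 20, 20, 20), n = 3, class = NA)
  tl <- data.frame(cell_line = paste0("L", 1:4), tissue = "A")
  assoc <- data.frame(phenotype = "W539", gene = "PMAIP1", sign = 1)
  out <- outlier_analysis(prof, expr, tl, phenotypes = "W539",
                          associations = assoc)
  l1 <- out[out$cell_line == "L1", ]
  expect_gt(l1$dep_delta, 0)
  expect_gt(l1$expr_delta, 0)
  expect_true(l1$concordant)
  # singleton tissues are skipped with a message
  tl2 <- data.frame(cell_line = paste0("L", 1:4),
                    tissue = c("A", "A", "A", "B"))
  expect_message(out2 <- outlier_analysis(prof, expr, tl2,
                                          phenotypes = "W539"),
                 "singleton")
  expect_false("L4" %in% out2$cell_line)
})
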