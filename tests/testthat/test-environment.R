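# Environmental PCA, Box-Cox, and soil-variable discrimination.

test_that("environment PCA satisfies rank, sign and orthogonality properties", {
  p <- sim_params(n_pops = 4, site_type_labels = c("M", "M", "NM", "NM"),
                  cluster_assignment = c(1, 1, 2, 3), seed = 1)
  env <- generate_environment(p)
  vars <- c(soil_var_names(), climate_var_names())
  res <- env_pca(env, vars)
  # 4 observations -> at most 3 informative components
  expect_lte(sum(res$var_explained > 1e-8), 3)
  expect_true(all(res$var_explained >= 0))
  expect_lte(sum(res$var_explained), 100 + 1e-8)
  gram <- crossprod(res$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # duplicated observations coincide
  env2 <- rbind(env, env[1, ])
  res2 <- env_pca(env2, vars)
  expect_lt(max(abs(res2$scores[1, ] - res2$scores[5, ])), 1e-8)
  # zero-variance variable is refused by name
  env3 <- env; env3$pH <- 1
  expect_error(env_pca(env3, vars), "pH")
})

test_that("PCA is invariant to variable order and affine rescaling", {
  p <- sim_params(seed = 2)
  env <- generate_environment(p)
  vars <- soil_var_names()
  a <- env_pca(env, vars)
  b <- env_pca(env, rev(vars))
  expect_equal(abs(a$scores), abs(b$scores), tolerance = 1e-8)
  env2 <- env
  env2$Cd_tot <- 100 * env2$Cd_tot - 7
  c_ <- env_pca(env2, vars)
  expect_equal(abs(a$scores), abs(c_$scores), tolerance = 1e-8)
})

test_that("perfectly correlated variables load PC1 equally", {
  set.seed(3)
  d <- data.frame(x = rnorm(20))
  d$y <- 2 * d$x + 5
  res <- env_pca(d, c("x", "y"))
  expect_equal(abs(res$loadings["x", 1]), abs(res$loadings["y", 1]),
               tolerance = 1e-10)
  expect_equal(res$var_explained[1], 100, tolerance = 1e-8)
})

test_that("Box-Cox exponent maximizes the profile likelihood", {
  set.seed(4)
  # the transform obeys its definition at the returned exponent, and at
  # lambda = 1 it is exactly x - 1 (shape preserved)
  x <- rnorm(50, 10, 1)
  bc <- box_cox(x)
  expect_equal(bc$values,
               if (abs(bc$lambda) < 1e-12) log(x) else (x^bc$lambda - 1) / bc$lambda,
               tolerance = 1e-12)
  expect_equal(cor(bc$values, x), 1, tolerance = 0.01)
  # a squared normal wants lambda ~ 0.5
  y <- rnorm(300, 10, 2)^2
  expect_lt(abs(box_cox(y)$lambda - 0.5), 0.25)
  # lognormal samples want the log transform
  hits <- 0
  for (r in 1:20) {
    ln <- exp(rnorm(100))
    l <- box_cox(ln)$lambda
    if (l >= -0.2 && l <= 0.2) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
  expect_error(box_cox(c(1, -2, 3)), "positive")
  expect_error(box_cox(rep(2, 10)), "constant")
})

test_that("soil discrimination selects separated variables and runs checks", {
  # constructed: clear two-site-type separation, 2 sites each, 3 replicates
  tab <- data.frame(
    site = rep(c("M1", "M2", "N1", "N2"), each = 3),
    Site_type = rep(c(1, 1, 0, 0), each = 3),
    sep = c(10, 10.2, 9.8, 10.1, 9.9, 10.3, 1, 1.1, 0.9, 1.2, 0.8, 1.0),
    flat = rep(5, 12) + rep(c(0.01, -0.01, 0), 4))
  res <- test_soil_discrimination(tab, c("sep", "flat"))
  expect_true("sep" %in% res$selected)
  expect_false("flat" %in% res$selected)
  expect_true(all(res$tests$anova_p >= 0 & res$tests$anova_p <= 1))
  # direct F oracle for the separated variable
  f_oracle <- anova(lm(sep ~ factor(site), tab))$`F value`[1]
  sel <- res$tests[res$tests$variable == "sep", ]
  if (!sel$box_cox) expect_equal(sel$f_value, f_oracle, tolerance = 1e-10)
  expect_error(test_soil_discrimination(tab[c(1, 4, 7, 10), ], "sep"),
               "replicate")
})

test_that("identical site distributions are almost never selected", {
  set.seed(6)
  false_hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    tab <- data.frame(site = rep(c("M1", "M2", "N1", "N2"), each = 3),
                      Site_type = rep(c(1, 1, 0, 0), each = 3),
                      v = rnorm(12, 10, 1))
    res <- suppressWarnings(test_soil_discrimination(tab, "v"))
    if ("v" %in% res$selected) false_hits <- false_hits + 1
  }
  expect_lte(false_hits / n_rep, 0.01)
})

test_that("skewed variables trigger the Box-Cox branch", {
  set.seed(7)
  tab <- data.frame(site = rep(c("M1", "M2", "N1", "N2"), each = 6),
                    Site_type = rep(c(1, 1, 0, 0), each = 6),
                    skew = exp(rnorm(24, 0, 1)))
  res <- test_soil_discrimination(tab, "skew")
  expect_true(res$tests$box_cox[1])
  expect_false(is.na(res$tests$lambda[1]))
})

test_that("the generator's designated soil variables are all selected", {
  hits <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    p <- sim_params(seed = 800 + r)
    env <- generate_environment(p)
    reps <- generate_soil_replicates(env, seed = 900 + r)
    res <- test_soil_discrimination(reps, soil_var_names())
    if (all(designated_soil_vars() %in% res$selected)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
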