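# Site characterization: environmental PCA and selection of soil variables
# that discriminate metalliferous from non-metalliferous sites.

#' PCA over environmental variables
#'
#' Standard PCA of the (optionally standardized) environment matrix.
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, so results are reproducible across platforms.
#'
#' @param table environment data.frame (rows = observations).
#' @param variables character vector of numeric columns to use.
#' @param standardize divide each variable by its standard deviation
#'   (default `TRUE`).
#' @return object of class `env_pca`: `scores` (observation coordinates),
#'   `var_explained` (percent per component), `loadings`.
#' @export
env_pca <- function(table, variables, standardize = TRUE) {
  x <- as.matrix(table[, variables, drop = FALSE])
  if (nrow(x) < 2) stop_invalid("need at least 2 observations for PCA")
  if (anyNA(x)) stop_invalid("missing values in PCA input")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop_invalid("zero-variance variable(s): %s",
                 paste(variables[sds == 0], collapse = ","))
  p <- prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  structure(list(scores = p$x,
                 var_explained = 100 * p$sdev^2 / sum(p$sdev^2),
                 loadings = p$rotation),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf("env_pca: %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(ve), ve[1], if (length(ve) > 1) ve[2] else NA))
  invisible(x)
}

#' Box-Cox power transform with profile-likelihood exponent
#'
#' The exponent maximizes the Box-Cox profile log-likelihood over the grid
#' [-5, 5] in steps of 0.01; the transform is (x^l - 1)/l, or ln(x) at l = 0.
#'
#' @param values positive numeric vector.
#' @return list with `values` (transformed) and `lambda` (the exponent).
#' @export
box_cox <- function(values) {
  if (any(values <= 0))
    stop_invalid("Box-Cox requires positive values; shift the variable first")
  if (sd(values) == 0)
    stop_invalid("Box-Cox is undefined for constant input")
  grid <- seq(-5, 5, by = 0.01)
  prof <- MASS::boxcox(values ~ 1, lambda = grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  tr <- if (abs(lambda) < 1e-12) log(values) else (values^lambda - 1) / lambda
  list(values = tr, lambda = lambda)
}

#' Select soil variables that discriminate M from NM sites
#'
#' For each soil variable, fits a one-way ANOVA of the variable against site
#' on replicate topsoil measurements. If the residuals fail a Shapiro-Wilk
#' normality check or a Breusch-Pagan homoscedasticity check (P <
#' `alpha_assume`), the variable is Box-Cox transformed and the model refit.
#' A variable is selected when the (possibly refit) ANOVA has P <
#' `alpha_select` and every metalliferous site mean differs from every
#' non-metalliferous site mean in the same direction — i.e. the variable
#' separates the two site types consistently, not merely some pair of sites.
#'
#' @param table replicate-level data.frame with columns `site`, `Site_type`
#'   and the soil variables (e.g. from [generate_soil_replicates()]).
#' @param soil_variables character vector of soil columns to test.
#' @param alpha_assume significance level for the assumption checks
#'   (default 0.05).
#' @param alpha_select ANOVA significance level for selection
#'   (default 0.001).
#' @return list with `tests` (per-variable data.frame: Shapiro P,
#'   Breusch-Pagan P, Box-Cox flag and exponent, F, dfs, P, selected) and
#'   `selected` (character vector).
#' @export
test_soil_discrimination <- function(table, soil_variables,
                                     alpha_assume = 0.05,
                                     alpha_select = 0.001) {
  if (min(table(table$site)) < 2)
    stop_invalid("need at least 2 replicate measurements per site")
  site <- factor(table$site)
  m_sites <- unique(table$site[table$Site_type == 1])
  nm_sites <- unique(table$site[table$Site_type == 0])
  rows <- lapply(soil_variables, function(v) {
    y <- table[[v]]
    fit <- lm(y ~ site)
    sh_p <- shapiro.test(resid(fit))$p.value
    bp_p <- lmtest::bptest(fit)$p.value
    bc_flag <- (sh_p < alpha_assume) || (bp_p < alpha_assume)
    lambda <- NA_real_
    if (bc_flag) {
      bc <- box_cox(y)
      lambda <- bc$lambda
      fit <- lm(bc$values ~ site)
    }
    an <- anova(fit)
    f <- an$`F value`[1]
    p <- an$`Pr(>F)`[1]
    # consistent-direction condition on (transformed) site means
    mu <- tapply(fit$model[[1]], site, mean)
    diffs <- outer(mu[as.character(m_sites)], mu[as.character(nm_sites)], `-`)
    consistent <- all(diffs > 0) || all(diffs < 0)
    data.frame(variable = v, shapiro_p = sh_p, breusch_pagan_p = bp_p,
               box_cox = bc_flag, lambda = lambda,
               f_value = f, df1 = an$Df[1], df2 = an$Df[2], anova_p = p,
               selected = (p < alpha_select) && consistent,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  list(tests = tests, selected = tests$variable[tests$selected])
}
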