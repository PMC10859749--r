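# Small fixtures shared across test files; everything is built in code.

tiny_panel <- function(mafs = c(rs1 = 0.1, rs2 = 0.3)) {
  variant_panel(rsid = names(mafs), maf_combined = unname(mafs))
}

# A cohort with no genetic effects and independent covariates, for null
# simulations.
null_cohort <- function(n, seed = 1) {
  set.seed(seed)
  cov <- simulate_covariates(n = n)
  spec <- effect_spec(data.frame(rsid = character(), trait = character(),
                                 beta = numeric()))
  simulate_phenotypes(matrix(0L, n, 0), cov, spec)
}

# Brute-force OLS via the normal equations, independent of lm().
ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  XtX <- crossprod(X)
  bhat <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% bhat
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = drop(bhat), se = se,
       p = 2 * pt(abs(drop(bhat) / se), df, lower.tail = FALSE))
}
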