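# central-difference gradient for delta-method standard errors
.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hp <- h * max(abs(x[i]), 1)
    xp <- x; xp[i] <- xp[i] + hp
    xm <- x; xm[i] <- xm[i] - hp
    (f(xp) - f(xm)) / (2 * hp)
  }, numeric(1))
}

.delta_se <- function(f, theta, cov_theta) {
  if (is.null(cov_theta)) return(NA_real_)
  g <- .num_grad(f, theta)
  v <- as.numeric(t(g) %*% cov_theta %*% g)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Heritability from a univariate variance-component fit
#'
#' h2 = sigma2_animal / (sum of all fitted variance components, including
#' litter, pen and residual). The standard error comes from the delta
#' method on the inverse average-information matrix.
#'
#' @param fit result of [reml_univariate()].
#' @return list with `h2` and `se`.
#' @export
heritability <- function(fit) {
  th <- fit$theta
  if (!"animal" %in% names(th)) stop("fit has no animal component")
  tot <- sum(th)
  if (tot <= 0) stop("zero total variance")
  f <- function(x) x[which(names(th) == "animal")] / sum(x)
  list(h2 = unname(th["animal"] / tot),
       se = .delta_se(f, th, fit$cov_theta))
}

#' Genetic and phenotypic correlations from a bivariate fit
#'
#' r_g = cov_animal / sqrt(var_a1 var_a2); r_p uses the summed component
#' covariances and variances over every fitted structure. Delta-method
#' standard errors; a correlation whose variance sits at the floor is
#' reported missing.
#'
#' @param fit result of [reml_bivariate()].
#' @return list with `r_g`, `r_g_se`, `r_p`, `r_p_se`, and `h2` (per-trait
#'   heritabilities with SEs).
#' @export
correlations <- function(fit) {
  th <- fit$theta
  nm <- names(th)
  structs <- unique(sub("\\.(v1|c|v2)$", "", nm))
  at_floor <- function(s) any(th[paste0(s, c(".v1", ".v2"))] <= fit$floor * 1.01)
  rg_f <- function(x) {
    names(x) <- nm
    x["animal.c"] / sqrt(x["animal.v1"] * x["animal.v2"])
  }
  rp_f <- function(x) {
    names(x) <- nm
    cv <- sum(x[paste0(structs, ".c")])
    v1 <- sum(x[paste0(structs, ".v1")])
    v2 <- sum(x[paste0(structs, ".v2")])
    cv / sqrt(v1 * v2)
  }
  h2_f <- function(which_v) {
    function(x) {
      names(x) <- nm
      x[paste0("animal.", which_v)] / sum(x[paste0(structs, ".", which_v)])
    }
  }
  r_g <- if ("animal" %in% structs && !at_floor("animal"))
    unname(rg_f(th)) else NA_real_
  list(
    r_g = r_g,
    r_g_se = if (is.na(r_g)) NA_real_ else .delta_se(rg_f, th, fit$cov_theta),
    r_p = unname(rp_f(th)),
    r_p_se = .delta_se(rp_f, th, fit$cov_theta),
    h2 = list(
      trait1 = list(h2 = unname(h2_f("v1")(th)),
                    se = .delta_se(h2_f("v1"), th, fit$cov_theta)),
      trait2 = list(h2 = unname(h2_f("v2")(th)),
                    se = .delta_se(h2_f("v2"), th, fit$cov_theta))
    )
  )
}

#' Likelihood-ratio test between nested variance-component models
#'
#' LRT = 2 (LL_full - LL_reduced), clipped at zero. Because the extra
#' variance component sits on the boundary of its space under the null, the
#' p-value uses the 50:50 chi-square mixture (for one extra component:
#' 0.5 chi2_0 + 0.5 chi2_1, so p = 0.5 P(chi2_1 >= LRT), which equals 0.5
#' at LRT = 0). The naive chi-square p-value is also reported.
#'
#' @param reduced,full fits from [reml_univariate()] (full must extend
#'   reduced by >= 1 random term).
#' @return list with `statistic`, `df`, `p_mixture`, `p_naive`.
#' @export
likelihood_ratio_test <- function(reduced, full) {
  r_terms <- reduced$random %||% names(reduced$theta)
  f_terms <- full$random %||% names(full$theta)
  if (!all(r_terms %in% f_terms))
    stop("models are not nested: reduced has terms absent from full")
  df <- length(setdiff(f_terms, r_terms))
  if (df < 1) stop("models are not nested: no extra random term in full")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p_naive <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  # mixture 0.5 chi2_{df-1} + 0.5 chi2_df (chi2_0 is a point mass at 0)
  p_lower <- if (df - 1 == 0) as.numeric(stat <= 0) else
    stats::pchisq(stat, df = df - 1, lower.tail = FALSE)
  p_mix <- 0.5 * p_lower + 0.5 * p_naive
  list(statistic = stat, df = df, p_mixture = p_mix, p_naive = p_naive)
}

#' Fixed-effects linear model with sequential Wald F tests
#'
#' Ordinary least squares with incremental (type-I) F tests in the order
#' terms are declared — the screening model used to decide which design
#' factors to carry into the genetic analyses, and (with an enterotype
#' term) to estimate enterotype contrasts on production traits in trait
#' units.
#'
#' @param trait response column name.
#' @param data data.frame.
#' @param fixed character vector of model terms, in testing order.
#' @return list with `fit` (lm), `anova` (sequential F table),
#'   `solutions` (coefficients), and `contrasts` (named coefficient
#'   estimates for factor levels, e.g. the enterotype effect).
#' @export
fit_fixed_model <- function(trait, data, fixed) {
  form <- stats::reformulate(fixed, response = trait)
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit))))
    message("aliased coefficient(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  av <- stats::anova(fit)
  co <- stats::coef(fit)
  list(fit = fit, anova = av, solutions = co[!is.na(co)],
       contrasts = co[!is.na(co)][-1])
}

#' Per-family, per-age effect profile and cross-age correlations
#'
#' Fits sex + birth site as fixed effects and the age x family interaction
#' as a random effect (lme4), extracts the shrunken per-cell family
#' effects, centres them within age, and returns their pairwise Pearson
#' correlations across ages (pairwise-complete when a family is missing at
#' an age).
#'
#' @param data data.frame with columns `shannon` (or `response`), `sex`,
#'   `bs`, `family`, `age`.
#' @param response response column name.
#' @param fixed fixed-effect columns.
#' @return list with `effects` (family x age matrix, centred within age)
#'   and `correlations` (age x age Pearson matrix).
#' @export
family_effect_profile <- function(data, response = "shannon",
                                  fixed = c("sex", "bs")) {
  stopifnot(all(c("family", "age") %in% names(data)))
  if (length(unique(data$family)) < 2 || length(unique(data$age)) < 2)
    stop("need >= 2 families observed at >= 2 ages")
  data$fam_age_ <- interaction(data$age, data$family, drop = TRUE)
  form <- stats::as.formula(paste(response, "~",
                                  paste(fixed, collapse = " + "),
                                  "+ (1 | fam_age_)"))
  fit <- lme4::lmer(form, data = data, REML = TRUE)
  re <- lme4::ranef(fit)$fam_age_
  parts <- strsplit(rownames(re), ".", fixed = TRUE)
  cell <- data.frame(age = vapply(parts, `[`, "", 1),
                     family = vapply(parts, function(p)
                       paste(p[-1], collapse = "."), ""),
                     effect = re[["(Intercept)"]],
                     stringsAsFactors = FALSE)
  ages <- unique(as.character(data$age))
  fams <- unique(as.character(data$family))
  M <- matrix(NA_real_, length(fams), length(ages),
              dimnames = list(fams, ages))
  M[cbind(cell$family, cell$age)] <- cell$effect
  M <- sweep(M, 2, colMeans(M, na.rm = TRUE))
  list(effects = M,
       correlations = stats::cor(M, use = "pairwise.complete.obs"),
       fit = fit)
}
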