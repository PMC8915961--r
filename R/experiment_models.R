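#' Fit a mixed-effects Poisson model of tweets shared per round
#'
#' Models the count of covert (or total) tweets a participant shared per
#' round with fixed effects for outgroup size (categorical: the design
#' contrasts sizes 1/4/6/9), cost condition, and the demographic adjustment
#' covariates, plus Gaussian random intercepts. The default random-effects
#' structure (`re = "nested"`) nests the outgroup condition within
#' individuals: a participant intercept plus a participant x outgroup-size
#' intercept. The sensitivity structure (`re = "participant"`) keeps the
#' participant intercept only; with a single scalar random effect the
#' likelihood is evaluated by adaptive Gauss-Hermite quadrature
#' (`nAGQ` nodes, default 15), otherwise by the Laplace approximation
#' (`nAGQ = 1`, the only option lme4 offers for multiple terms).
#'
#' @param rounds Round records (see [generate_experiment_dataset()]).
#' @param participants Participant records with `audience_arm`,
#'   `political_group` and the demographic covariates.
#' @param response `"covert"` or `"total"`.
#' @param arm Optional audience arm to subset to (`"copartisan"` or
#'   `"cross_partisan"`).
#' @param covariates Adjustment covariates; those constant in the data are
#'   dropped automatically. `age` is standardized.
#' @param conditions Which experimental condition factors enter the fixed
#'   effects; drop `"outgroup"` (or `"cost"`) to fit the corresponding
#'   null model for a Bayes-factor comparison.
#' @param re Random-effects structure: `"nested"` (default) or
#'   `"participant"`.
#' @param nAGQ Quadrature nodes; default 15 when the structure permits
#'   quadrature, forced to 1 (Laplace) for the nested structure.
#' @return Object of class `"covertsig_glmm"`: list with the `lme4` fit,
#'   the model `data`, `loglik`, `BIC`, `k` (estimated parameters), `N`
#'   (observations), and metadata. Optimizer failure raises an error with
#'   the optimizer's diagnostics.
#' @export
fit_poisson_glmm <- function(rounds, participants,
                             response = c("covert", "total"),
                             arm = NULL,
                             covariates = c("age", "gender", "race",
                                            "education", "political_group"),
                             conditions = c("outgroup", "cost"),
                             re = c("nested", "participant"),
                             nAGQ = NULL) {
  response <- match.arg(response)
  re <- match.arg(re)
  dat <- merge(rounds, participants, by = "participant_id")
  if (!is.null(arm)) dat <- dat[dat$audience_arm == arm, , drop = FALSE]
  if (nrow(dat) == 0) stop("no rounds to fit", call. = FALSE)
  dat$y <- if (response == "covert") dat$n_covert_shared else dat$n_total
  dat$outgroup_f <- factor(dat$outgroup_size)
  dat$cost_f <- factor(dat$cost_condition)
  if ("age" %in% covariates && "age" %in% names(dat))
    dat$age <- as.numeric(scale(dat$age))
  covariates <- covariates[covariates %in% names(dat)]
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(dat[[v]])) > 1, logical(1))]
  fixed_terms <- c(if ("outgroup" %in% conditions &&
                         nlevels(dat$outgroup_f) > 1) "outgroup_f",
                   if ("cost" %in% conditions &&
                         nlevels(dat$cost_f) > 1) "cost_f",
                   covariates)
  if (length(fixed_terms) == 0) fixed_terms <- "1"
  re_terms <- switch(re,
                     participant = "(1 | participant_id)",
                     nested = paste("(1 | participant_id) +",
                                    "(1 | participant_id:outgroup_f)"))
  fml <- stats::as.formula(paste("y ~", paste(fixed_terms, collapse = " + "),
                                 "+", re_terms))
  if (is.null(nAGQ)) nAGQ <- if (re == "participant") 15L else 1L
  if (re == "nested" && nAGQ > 1) {
    message("nested random effects: quadrature unavailable, using Laplace")
    nAGQ <- 1L
  }
  if (stats::var(dat$y) == 0) {
    # a constant response makes the random effects unidentifiable; the
    # maximum-likelihood fit is the plain Poisson regression (intercept
    # log(k) for the intercept-only model)
    message("constant response: random effects dropped (variance 0)")
    fit <- stats::glm(stats::as.formula(
      paste("y ~", paste(fixed_terms, collapse = " + "))),
      family = stats::poisson(), data = dat)
    conv <- list()
  } else {
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = dat, family = stats::poisson(), nAGQ = nAGQ,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               optCtrl = list(maxfun = 1e5))),
      message = function(m) invokeRestart("muffleMessage")
    )
    conv <- fit@optinfo$conv
  }
  if (!is.null(conv$opt) && conv$opt != 0)
    stop("GLMM optimizer failed to converge: ",
         paste(unlist(conv), collapse = "; "), call. = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  N <- stats::nobs(fit)
  structure(list(fit = fit, data = dat, formula = fml,
                 response = response, arm = arm,
                 loglik = ll, k = k, N = N,
                 BIC = -2 * ll + k * log(N),
                 nAGQ = nAGQ, re = re,
                 messages = unlist(conv$lme4$messages)),
            class = "covertsig_glmm")
}

#' @export
print.covertsig_glmm <- function(x, ...) {
  cat(sprintf("Mixed-effects Poisson model of %s tweets shared (N = %d)\n",
              x$response, x$N))
  cat(sprintf("  random effects: %s; nAGQ = %d\n", x$re, x$nAGQ))
  cat(sprintf("  logLik = %.2f, k = %d, BIC = %.2f\n", x$loglik, x$k, x$BIC))
  print(model_fixef(x))
  invisible(x)
}

model_fixef <- function(model) {
  if (inherits(model$fit, "merMod")) lme4::fixef(model$fit)
  else stats::coef(model$fit)
}

model_vcov <- function(model) {
  as.matrix(stats::vcov(model$fit))
}

# fixed-effects design matrix for new data, with the fit's factor levels
fixed_model_matrix <- function(model, newdata) {
  tt <- stats::delete.response(stats::terms(lme4::nobars(model$formula)))
  xlev <- lapply(model$data[, all.vars(tt), drop = FALSE],
                 function(v) if (is.factor(v)) levels(v)
                             else if (is.character(v)) sort(unique(v)))
  xlev <- Filter(Negate(is.null), xlev)
  mf <- stats::model.frame(tt, newdata, xlev = xlev)
  X <- stats::model.matrix(tt, mf)
  X[, names(model_fixef(model)), drop = FALSE]
}

# total Gaussian random-intercept variance on the log scale
re_variance <- function(model) {
  if (!inherits(model$fit, "merMod")) return(0)
  vc <- lme4::VarCorr(model$fit)
  sum(vapply(vc, function(m) m[1, 1], numeric(1)))
}

#' Average predictive margins over a condition grid
#'
#' For every cell of the condition grid, sets each observation's condition
#' variables to the cell values, predicts the expected count, and averages
#' over the sample's covariate distribution. Under the log link the
#' marginal expectation (Gaussian random intercepts integrated out)
#' multiplies the fixed-effects prediction by `exp(sigma^2 / 2)`, where
#' `sigma^2` sums the random-intercept variances (`type = "marginal"`,
#' default); `type = "conditional"` sets the random effects to zero
#' instead. Standard errors use the delta method over the fixed-effects
#' covariance (the random-variance estimate is treated as fixed).
#'
#' @param model A [fit_poisson_glmm()] fit.
#' @param grid Data frame of condition cells (columns among `outgroup_size`
#'   and `cost_condition`); defaults to all combinations observed in the
#'   data. Cells absent from the training data trigger an extrapolation
#'   warning.
#' @param type `"marginal"` or `"conditional"`.
#' @param level Confidence level (default 0.95, normal critical values).
#' @return Data frame: the grid columns plus `margin`, `se`, `lower`,
#'   `upper`.
#' @export
average_predictive_margins <- function(model, grid = NULL,
                                       type = c("marginal", "conditional"),
                                       level = 0.95) {
  stopifnot(inherits(model, "covertsig_glmm"))
  type <- match.arg(type)
  dat <- model$data
  if (is.null(grid))
    grid <- expand.grid(outgroup_size = sort(unique(dat$outgroup_size)),
                        cost_condition = sort(unique(dat$cost_condition)))
  cond_cols <- intersect(names(grid), c("outgroup_size", "cost_condition"))
  if (length(cond_cols) == 0)
    stop("grid must contain `outgroup_size` and/or `cost_condition`",
         call. = FALSE)
  seen <- unique(dat[, cond_cols, drop = FALSE])
  beta <- model_fixef(model)
  V <- model_vcov(model)
  adj <- if (type == "marginal") exp(re_variance(model) / 2) else 1
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- grid
  out$margin <- NA_real_
  out$se <- NA_real_
  grads <- matrix(NA_real_, nrow(grid), length(beta))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, cond_cols, drop = FALSE]
    if (nrow(merge(cell, seen)) == 0)
      warning(sprintf("condition cell (%s) not observed in training data",
                      paste(unlist(cell), collapse = ", ")), call. = FALSE)
    nd <- dat
    for (cc in cond_cols) nd[[cc]] <- cell[[cc]]
    nd$outgroup_f <- factor(nd$outgroup_size,
                            levels = levels(dat$outgroup_f))
    nd$cost_f <- factor(nd$cost_condition, levels = levels(dat$cost_f))
    X <- fixed_model_matrix(model, nd)
    mu <- adj * exp(as.numeric(X %*% beta))
    out$margin[i] <- mean(mu)
    grads[i, ] <- colMeans(mu * X)
    out$se[i] <- sqrt(drop(t(grads[i, ]) %*% V %*% grads[i, ]))
  }
  out$lower <- out$margin - z * out$se
  out$upper <- out$margin + z * out$se
  attr(out, "gradients") <- grads
  attr(out, "type") <- type
  out
}

#' Average marginal effect between two condition cells
#'
#' The AME is the difference between the average predictive margins at two
#' condition assignments (e.g. outgroup size 9 versus 1), with a
#' delta-method standard error that accounts for the covariance between
#' the two margins.
#'
#' @param model A [fit_poisson_glmm()] fit.
#' @param cell_a,cell_b One-row data frames (or named lists) of condition
#'   values; the AME is `margin(cell_b) - margin(cell_a)`.
#' @inheritParams average_predictive_margins
#' @return List with `ame`, `se`, `conf_int`, `level`, and the two margins.
#' @export
average_marginal_effect <- function(model, cell_a, cell_b,
                                    type = c("marginal", "conditional"),
                                    level = 0.95) {
  type <- match.arg(type)
  grid <- rbind(as.data.frame(cell_a), as.data.frame(cell_b))
  m <- average_predictive_margins(model, grid, type = type, level = level)
  g <- attr(m, "gradients")
  dg <- g[2, ] - g[1, ]
  V <- model_vcov(model)
  se <- sqrt(drop(t(dg) %*% V %*% dg))
  ame <- m$margin[2] - m$margin[1]
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ame = ame, se = se, conf_int = c(ame - z * se, ame + z * se),
       level = level, margin_a = m$margin[1], margin_b = m$margin[2])
}

#' BIC-approximate Bayes factor for the null model
#'
#' Approximates the Bayes factor in favor of the null (restricted) model by
#' `BF01 = exp((BIC_alt - BIC_null) / 2)`. Values above 1 favor the null;
#' equal BICs give exactly 1. Both models must be fit to the same
#' observations.
#'
#' @param model_null,model_alt Two [fit_poisson_glmm()] fits of the same
#'   response on the same data.
#' @return The Bayes factor `BF01` (a number).
#' @export
bic_bayes_factor <- function(model_null, model_alt) {
  stopifnot(inherits(model_null, "covertsig_glmm"),
            inherits(model_alt, "covertsig_glmm"))
  if (model_null$N != model_alt$N)
    stop("models are fit to different numbers of observations",
         call. = FALSE)
  exp((model_alt$BIC - model_null$BIC) / 2)
}
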