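# Mixed-effects models of trial-level behaviour and per-point outcomes:
# (generalized) linear mixed models with a convergence fallback ladder,
# likelihood-ratio tests per predictor, odds-ratio conversion, and
# nested-model resolution of interactions.

# Strip random-effect bars from a mixed-model formula.
fixed_part <- function(formula) {
  lme4::nobars(formula)
}

# Simplify the random-effects structure one rung down the ladder:
# any random slopes -> intercept-only for the same grouping factors.
simplify_random <- function(formula) {
  bars <- lme4::findbars(formula)
  if (is.null(bars)) return(NULL)
  grps <- vapply(bars, function(b) deparse(b[[3]]), character(1))
  if (all(vapply(bars, function(b) identical(deparse(b[[2]]), "1"),
                 logical(1))))
    return(NULL)  # already intercept-only
  fx <- deparse(fixed_part(formula))
  re <- paste(sprintf("(1 | %s)", unique(grps)), collapse = " + ")
  stats::as.formula(paste(fx, "+", re))
}

#' Fit a linear or logistic mixed model with a fallback ladder
#'
#' Gaussian models are fitted by REML (refitted by ML for likelihood-ratio
#' tests), binomial models by Laplace approximation.  If the fit fails or
#' does not converge, the random-effects structure is simplified to
#' random intercepts; a fit that still fails is returned flagged rather
#' than raising.  Singular random-effect fits are flagged, not fatal.
#'
#' @param formula an `lme4`-style mixed-model formula.
#' @param data model data frame.
#' @param family `"gaussian"` or `"binomial"`.
#' @param reml use REML for gaussian fits (default TRUE).
#' @param lrt also compute per-predictor likelihood-ratio chi-square tests
#'   (ML refits respecting marginality).
#' @param nagq `nAGQ` for binomial fits (0 is fast and adequate for
#'   large-sample recovery).
#' @return a `fit_result`: list with `beta`, `se`, `loglik`, `converged`,
#'   `singular`, `formula`, `family`, `model`, and `lrt` (data frame) when
#'   requested.
#' @export
fit_mixed <- function(formula, data, family = c("gaussian", "binomial"),
                      reml = TRUE, lrt = FALSE, nagq = 1L) {
  family <- match.arg(family)
  y <- stats::model.frame(fixed_part(formula), data)[[1]]
  if (family == "binomial" && length(unique(y)) < 2L) {
    return(structure(list(beta = NULL, se = NULL, loglik = NA,
                          converged = FALSE, singular = NA,
                          message = "complete separation: outcome constant",
                          formula = formula, family = family, model = NULL),
                     class = "fit_result"))
  }
  do_fit <- function(fml) {
    tryCatch({
      mod <- if (family == "binomial")
        lme4::glmer(fml, data, family = stats::binomial(), nAGQ = nagq,
                    control = lme4::glmerControl(calc.derivs = FALSE))
      else
        lme4::lmer(fml, data, REML = reml,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      mod
    }, error = function(e) e)
  }
  mod <- do_fit(formula)
  used <- formula
  if (inherits(mod, "error")) {
    fml2 <- simplify_random(formula)
    if (!is.null(fml2)) {
      mod <- do_fit(fml2)
      used <- fml2
    }
  }
  if (inherits(mod, "error")) {
    return(structure(list(beta = NULL, se = NULL, loglik = NA,
                          converged = FALSE, singular = NA,
                          message = conditionMessage(mod),
                          formula = formula, family = family, model = NULL),
                     class = "fit_result"))
  }
  beta <- lme4::fixef(mod)
  se <- sqrt(diag(as.matrix(stats::vcov(mod))))
  res <- structure(list(beta = beta, se = se,
                        loglik = as.numeric(stats::logLik(mod)),
                        converged = TRUE,
                        singular = lme4::isSingular(mod),
                        formula = used, family = family, nagq = nagq,
                        model = mod),
                   class = "fit_result")
  if (lrt) res$lrt <- lrt_table(res)
  res
}

#' Per-predictor likelihood-ratio chi-square tests
#'
#' Each fixed-effect term is tested by refitting (ML) without it;
#' removing a main effect also removes interactions containing it, so each
#' comparison is between nested models.
#'
#' @param fit a `fit_result` from [fit_mixed()].
#' @return data frame with `term`, `chisq`, `df`, `p`.
#' @export
lrt_table <- function(fit) {
  stopifnot(inherits(fit, "fit_result"), fit$converged)
  mod <- fit$model
  if (fit$family == "gaussian" && lme4::isREML(mod))
    mod <- lme4::refitML(mod)
  ll_full <- stats::logLik(mod)
  labs <- attr(stats::terms(fixed_part(fit$formula)), "term.labels")
  frame <- mod@frame
  refit_reduced <- function(fml) {
    if (fit$family == "binomial")
      lme4::glmer(fml, frame, family = stats::binomial(),
                  nAGQ = fit$nagq %||% 1L,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    else
      lme4::lmer(fml, frame, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE))
  }
  out <- lapply(labs, function(term) {
    tvars <- all.vars(stats::reformulate(term))
    containing <- labs[vapply(labs, function(L)
      all(tvars %in% all.vars(stats::reformulate(L))), logical(1))]
    higher <- setdiff(containing, term)
    # type-II comparison: both models exclude interactions containing the
    # term; they differ only in the term itself
    base_fml <- if (length(higher))
      stats::update(stats::formula(mod), stats::as.formula(
        paste(". ~ .", paste("-", higher, collapse = " "))))
    else stats::formula(mod)
    full_i <- if (length(higher)) refit_reduced(base_fml) else mod
    red <- refit_reduced(stats::update(base_fml, stats::as.formula(
      paste(". ~ . -", term))))
    ll_f <- stats::logLik(full_i)
    ll_r <- stats::logLik(red)
    chisq <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
    df <- attr(ll_f, "df") - attr(ll_r, "df")
    data.frame(term = term, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Likelihood-ratio test between two nested fits
#'
#' REML fits are refitted by ML; the statistic is twice the log-likelihood
#' difference with degrees of freedom equal to the parameter difference.
#'
#' @param full,reduced `fit_result` objects (reduced nested in full).
#' @return list with `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"),
            full$converged, reduced$converged)
  get_ml <- function(f) {
    m <- f$model
    if (f$family == "gaussian" && lme4::isREML(m)) m <- lme4::refitML(m)
    stats::logLik(m)
  }
  ll_f <- get_ml(full)
  ll_r <- get_ml(reduced)
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0) stop("`reduced` must be nested in `full`")
  chisq <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Odds ratio from a log-odds coefficient
#'
#' @param beta coefficient(s) on the log-odds scale.
#' @return `exp(beta)`; conventionally reported to two decimals.
#' @export
odds_ratio <- function(beta) {
  stopifnot(all(is.finite(beta)))
  exp(beta)
}

#' Resolve a two-way interaction by nested models
#'
#' For each level of the `outer` factor, fits a model with the `inner`
#' predictor nested within `outer` (`outer / inner` coding) and reports the
#' inner effect's estimate, SE, t (Satterthwaite degrees of freedom for
#' gaussian outcomes; Wald z for binomial) and p, in both nesting
#' directions.
#'
#' @param data model data.
#' @param outcome outcome column name.
#' @param outer,inner names of the two (two-level) factors.
#' @param covariates optional additional fixed-effect column names.
#' @param random random-effects specification string
#'   (default `"(1 | subject)"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return data frame with one row per nesting direction x outer level.
#' @export
resolve_interaction <- function(data, outcome, outer, inner,
                                covariates = character(0),
                                random = "(1 | subject)",
                                family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  one_direction <- function(out_var, in_var) {
    d <- data
    d$.outer <- factor(d[[out_var]])
    if (length(levels(d$.outer)) != 2L)
      stop("`", out_var, "` must have exactly two levels")
    rhs <- paste(c(covariates, ".outer", paste0(".outer:", in_var), random),
                 collapse = " + ")
    fml <- stats::as.formula(paste(outcome, "~", rhs))
    res <- lapply(levels(d$.outer), function(lv) {
      cname <- paste0(".outer", lv, ":", in_var)
      if (family == "gaussian") {
        mod <- lmerTest::lmer(fml, d)
        cf <- stats::coef(summary(mod))
        if (!cname %in% rownames(cf)) return(NULL)
        r <- cf[cname, ]
        data.frame(outer = out_var, inner = in_var, level = lv,
                   beta = r[["Estimate"]], se = r[["Std. Error"]],
                   stat = r[["t value"]], df = r[["df"]],
                   p = r[["Pr(>|t|)"]])
      } else {
        mod <- lme4::glmer(fml, d, family = stats::binomial())
        cf <- stats::coef(summary(mod))
        if (!cname %in% rownames(cf)) return(NULL)
        r <- cf[cname, ]
        data.frame(outer = out_var, inner = in_var, level = lv,
                   beta = r[["Estimate"]], se = r[["Std. Error"]],
                   stat = r[["z value"]], df = NA_real_,
                   p = r[["Pr(>|z|)"]])
      }
    })
    do.call(rbind, res)
  }
  out <- rbind(one_direction(outer, inner), one_direction(inner, outer))
  rownames(out) <- NULL
  out
}
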