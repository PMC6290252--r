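#' Variance components of a multi-environment RCBD trial
#'
#' Fits the random-effects decomposition of a randomized-complete-block
#' trial replicated across environments: genotype, environment,
#' replication nested within environment, genotype-by-environment
#' interaction, and plot error. For balanced data the expected-mean-squares
#' method-of-moments estimators from the two-way ANOVA are used (these
#' coincide with REML on balanced data up to truncation at zero);
#' unbalanced data are routed to an iterative REML fit via
#' \code{lme4::lmer}. Negative method-of-moments estimates are truncated
#' to zero and reported.
#'
#' With a single environment the model reduces to genotype + replication
#' blocks and no interaction component is estimable (`var_ge = NA`).
#'
#' @param obs a `trait_obs` table (see [trait_obs()]).
#' @param method `"auto"` (moments when balanced, REML otherwise),
#'   `"moments"` (balanced data only) or `"reml"` (force the iterative
#'   fit).
#' @return An object of class `varcomp`: list with `var_g`, `var_ge`,
#'   `var_error`, `s`, `r`, `grand_mean`, `acc_means` (per accession,
#'   across environments), `env_means`, `mean_squares`, `method`,
#'   `truncated`.
#' @export
fit_variance_components <- function(obs, method = c("auto", "moments", "reml")) {
  stopifnot(inherits(obs, "data.frame"))
  method <- match.arg(method)
  acc <- factor(obs$accession)
  env <- factor(obs$environment)
  rep_ <- factor(obs$replication)
  s <- nlevels(env)
  r <- nlevels(rep_)
  if (s == 1 && r == 1)
    stop("genotypic and error variance are inseparable with one ",
         "environment and one replication")
  counts <- table(acc, env)
  balanced <- all(counts == r) &&
    all(table(acc, env, rep_) == 1)
  if (method == "moments" && !balanced)
    stop("method-of-moments estimators need a balanced design")
  if (method == "reml") balanced <- FALSE
  truncated <- character(0)
  if (balanced) {
    if (s == 1) {
      fit <- stats::aov(value ~ acc + rep_, data = obs)
      ms <- summary(fit)[[1]][, "Mean Sq"]
      names(ms) <- trimws(rownames(summary(fit)[[1]]))
      ms_g <- ms[["acc"]]; ms_e <- ms[["Residuals"]]
      var_g <- (ms_g - ms_e) / r
      var_ge <- NA_real_
      var_error <- ms_e
    } else {
      form <- if (r == 1) value ~ acc + env + acc:env
              else value ~ acc + env + env:rep_ + acc:env
      fit <- stats::aov(form, data = obs)
      tab <- summary(fit)[[1]]
      ms <- tab[, "Mean Sq"]
      names(ms) <- trimws(rownames(tab))
      ms_g <- ms[["acc"]]; ms_ge <- ms[["acc:env"]]
      ms_e <- if ("Residuals" %in% names(ms)) ms[["Residuals"]] else 0
      if (r == 1) {
        # no within-block replication: interaction MS is the error stratum
        var_g <- (ms_g - ms_ge) / s
        var_ge <- NA_real_
        var_error <- ms_ge
      } else {
        var_g <- (ms_g - ms_ge) / (s * r)
        var_ge <- (ms_ge - ms_e) / r
        var_error <- ms_e
      }
    }
    method <- "moments"
    mean_squares <- ms
  } else {
    dat <- data.frame(value = obs$value, acc = acc, env = env, rep_ = rep_)
    form <- if (s == 1)
      value ~ (1 | acc) + (1 | rep_)
    else
      value ~ (1 | acc) + (1 | env) + (1 | env:rep_) + (1 | acc:env)
    fit <- lme4::lmer(form, data = dat, REML = TRUE,
                      control = lme4::lmerControl(
                        optimizer = "bobyqa",
                        check.nobs.vs.nlev = "ignore",
                        check.nobs.vs.nRE = "ignore",
                        optCtrl = list(rhoend = 1e-12)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(g) {
      i <- match(g, vc$grp)
      if (is.na(i)) NA_real_ else vc$vcov[i]
    }
    var_g <- getv("acc")
    var_ge <- if (s == 1) NA_real_ else getv("acc:env")
    var_error <- vc$vcov[vc$grp == "Residual"]
    method <- "reml"
    mean_squares <- NULL
  }
  # snap floating-point dust to exact zero (constant or near-constant data)
  tiny <- 1e-10 * max(mean(obs$value^2), .Machine$double.eps)
  for (nm in c("var_g", "var_ge", "var_error")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) {
      assign(nm, 0)
      truncated <- c(truncated, nm)
    } else if (!is.na(v) && v < tiny) assign(nm, 0)
  }
  if (length(truncated))
    message("negative variance estimate(s) truncated to 0: ",
            paste(truncated, collapse = ", "))
  structure(list(var_g = var_g, var_ge = var_ge, var_error = var_error,
                 s = s, r = r,
                 grand_mean = mean(obs$value),
                 acc_means = tapply(obs$value, acc, mean),
                 env_means = tapply(obs$value, env, mean),
                 mean_squares = mean_squares,
                 method = method, truncated = truncated),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat(sprintf("variance components (%s, s = %d environments, r = %d replications)\n",
              x$method, x$s, x$r))
  cat(sprintf("  genotypic       var_g  = %.*g\n", digits, x$var_g))
  cat(sprintf("  genotype x env  var_ge = %.*g\n", digits, x$var_ge))
  cat(sprintf("  error           var    = %.*g\n", digits, x$var_error))
  h2 <- tryCatch(heritability(x), error = function(e) NA_real_)
  if (!is.na(h2)) cat(sprintf("  heritability h2 = %.*g\n", digits, h2))
  invisible(x)
}

#' Heritability on an entry-mean basis
#'
#' Single-environment: `h2 = var_g / (var_g + var_error / r)`.
#' Multi-environment:
#' `h2 = var_g / (var_g + var_ge / s + var_error / (s * r))`.
#' The result is clipped to `[0, 1]`.
#'
#' @param vc a `varcomp` object.
#' @param mode `"multi_env"` (default when `s > 1`) or `"single_env"`.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc, mode = if (vc$s > 1) "multi_env" else "single_env") {
  mode <- match.arg(mode, c("single_env", "multi_env"))
  vge <- if (is.na(vc$var_ge)) 0 else vc$var_ge
  if (vc$var_g == 0 && vge == 0 && vc$var_error == 0)
    stop("all variance components are zero; heritability undefined")
  denom <- if (mode == "single_env")
    vc$var_g + vc$var_error / vc$r
  else
    vc$var_g + vge / vc$s + vc$var_error / (vc$s * vc$r)
  min(max(vc$var_g / denom, 0), 1)
}

#' Genetic coefficient of variation
#'
#' `100 * sqrt(var_g) / grand mean`, in percent.
#'
#' @param vc a `varcomp` object.
#' @return GCV in percent.
#' @export
gcv <- function(vc) {
  if (vc$grand_mean == 0) stop("grand mean is zero; GCV undefined")
  100 * sqrt(vc$var_g) / vc$grand_mean
}
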