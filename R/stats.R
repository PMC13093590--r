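#' Two-sample comparison with pooled-SD effect size
#'
#' Welch's t-test (unequal variances) with Cohen's D computed from the pooled
#' standard deviation, `sd_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) /
#' (n1 + n2 - 2)`, the convention used when standardized mean differences are
#' reported alongside group summaries. Accepts either raw value vectors or
#' pre-computed summaries, so printed tables (n, mean, SD per group) can be
#' re-analyzed directly.
#'
#' @param x,y numeric vectors, or `NULL` when summaries are supplied.
#' @param summary1,summary2 optional lists/vectors with elements `n`, `mean`,
#'   `sd` for group 1 and group 2.
#' @return A one-row tibble: `n1`, `mean1`, `sd1`, `n2`, `mean2`, `sd2`, `t`,
#'   `df`, `p`, `cohens_d`. The sign of `cohens_d` is the sign of
#'   `mean1 - mean2`.
#' @export
two_sample_summary <- function(x = NULL, y = NULL,
                               summary1 = NULL, summary2 = NULL) {
  if (!is.null(x)) summary1 <- list(n = length(x), mean = mean(x), sd = stats::sd(x))
  if (!is.null(y)) summary2 <- list(n = length(y), mean = mean(y), sd = stats::sd(y))
  s1 <- as.list(summary1); s2 <- as.list(summary2)
  n1 <- s1$n; n2 <- s2$n
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  se2 <- s1$sd^2 / n1 + s2$sd^2 / n2
  t <- (s1$mean - s2$mean) / sqrt(se2)
  df <- se2^2 / ((s1$sd^2 / n1)^2 / (n1 - 1) + (s2$sd^2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  sp <- sqrt(((n1 - 1) * s1$sd^2 + (n2 - 1) * s2$sd^2) / (n1 + n2 - 2))
  d <- if (sp > 0) (s1$mean - s2$mean) / sp else 0
  if (s1$mean == s2$mean) { t <- 0; d <- 0; p <- 1 }
  tibble::tibble(n1 = n1, mean1 = s1$mean, sd1 = s1$sd,
                 n2 = n2, mean2 = s2$mean, sd2 = s2$sd,
                 t = t, df = df, p = p, cohens_d = d)
}

#' Paired (one-sample) t summary of matched differences
#'
#' `t = mean_diff / (sd_diff / sqrt(n))` with a two-sided p-value on n - 1
#' degrees of freedom. Accepts a vector of within-pair differences or a
#' printed summary (mean, sd, n).
#'
#' @param differences numeric vector of matched-pair differences, or `NULL`.
#' @param mean_diff,sd_diff,n summary inputs used when `differences` is
#'   `NULL`.
#' @return A one-row tibble: `n`, `mean_diff`, `sd_diff`, `t`, `df`, `p`.
#' @export
paired_summary <- function(differences = NULL, mean_diff = NULL,
                           sd_diff = NULL, n = NULL) {
  if (!is.null(differences)) {
    n <- length(differences)
    mean_diff <- mean(differences)
    sd_diff <- stats::sd(differences)
  }
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  t <- if (sd_diff > 0) mean_diff / (sd_diff / sqrt(n)) else 0
  p <- if (sd_diff > 0) 2 * stats::pt(-abs(t), n - 1) else as.numeric(mean_diff == 0)
  tibble::tibble(n = n, mean_diff = mean_diff, sd_diff = sd_diff,
                 t = t, df = n - 1, p = p)
}

#' Exhaustive AIC-ranked logistic model selection
#'
#' Fits a binomial GLM (logit link) for every subset of the candidate
#' predictors — 2^p models from the intercept-only to the saturated model —
#' and ranks them by AIC. `delta_aic` is relative to the best model; Akaike
#' weights are `exp(-delta/2)` normalized over converged models; models
#' within 2 AIC units of the best are flagged as equally supported. A fit
#' showing complete separation (non-convergence or exploding coefficients) is
#' refit with a tiny ridge penalty and flagged.
#'
#' @param data a data frame holding the response and predictors.
#' @param response name of the binary (0/1) response column.
#' @param predictors character vector of predictor column names (at most 20).
#' @return An object of class `model_table`: a tibble sorted by AIC with
#'   columns `model` (label), `predictors` (list-column), `k`, `logLik`,
#'   `aic`, `delta_aic`, `weight`, `supported`, `converged`, plus the fitted
#'   model objects in attribute `fits`.
#' @export
exhaustive_logistic <- function(data, response, predictors) {
  stopifnot(length(predictors) <= 20)
  data <- as.data.frame(data)
  yv <- data[[response]]
  if (!all(yv %in% c(0, 1))) stop("response must be 0/1", call. = FALSE)
  p <- length(predictors)
  subsets <- purrr::map(0:(2^p - 1), function(bits) {
    predictors[bitwAnd(bits, 2^(seq_len(p) - 1)) > 0]
  })
  fits <- purrr::map(subsets, function(vars) {
    rhs <- if (length(vars) == 0) "1" else paste(vars, collapse = " + ")
    f <- stats::as.formula(paste(response, "~", rhs))
    fit <- suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
    separated <- !fit$converged || any(abs(stats::coef(fit)) > 15 &
                                       c(FALSE, rep(TRUE, length(vars))))
    if (separated && length(vars) > 0) {
      fit <- ridge_logistic(data, response, vars)
      warning("separation detected; ridge-stabilized refit for model {",
              paste(vars, collapse = ", "), "}", call. = FALSE)
    }
    fit
  })
  tab <- tibble::tibble(
    model = purrr::map_chr(subsets, ~ if (length(.x) == 0) "(intercept)"
                                      else paste(.x, collapse = " + ")),
    predictors = subsets,
    k = purrr::map_int(subsets, ~ length(.x) + 1L),
    logLik = purrr::map_dbl(fits, ~ as.numeric(stats::logLik(.x))),
    converged = purrr::map_lgl(fits, ~ isTRUE(.x$converged))
  )
  tab$aic <- 2 * tab$k - 2 * tab$logLik
  ord <- order(tab$aic)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - tab$aic[1]
  w <- exp(-tab$delta_aic / 2)
  w[!tab$converged] <- 0
  tab$weight <- w / sum(w)
  tab$supported <- tab$delta_aic <= 2.0
  structure(tab, fits = fits, response = response,
            class = c("model_table", class(tab)))
}

# logistic fit with a small L2 penalty via data augmentation; used only to
# stabilize complete separation
ridge_logistic <- function(data, response, vars, lambda = 1e-3) {
  x <- as.matrix(data[vars])
  y <- data[[response]]
  # augment with 2 pseudo-observations per predictor at +/- sqrt(1/(2*lambda))
  scale <- sqrt(1 / (2 * lambda))
  aug_x <- rbind(x, diag(length(vars)) * scale, -diag(length(vars)) * scale)
  aug_y <- c(y, rep(0.5, 2 * length(vars)))
  aug_w <- c(rep(1, length(y)), rep(lambda, 2 * length(vars)))
  df <- as.data.frame(aug_x)
  names(df) <- vars
  df[[response]] <- aug_y
  f <- stats::as.formula(paste(response, "~", paste(vars, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = df, family = stats::binomial(),
                                     weights = aug_w))
  fit$ridge <- TRUE
  fit
}

#' @export
print.model_table <- function(x, n = 10, ...) {
  cat(sprintf("<model_table> %d models, response '%s'\n", nrow(x),
              attr(x, "response")))
  print(tibble::as_tibble(x)[seq_len(min(n, nrow(x))),
                             c("model", "k", "aic", "delta_aic", "weight")])
  invisible(x)
}

#' Predicted encounter probability from a logistic model
#'
#' `p = exp(a) / (1 + exp(a))` on the linear predictor `a`, evaluated
#' numerically stably. `model` can be a fitted `glm` or a named coefficient
#' vector (with an `(Intercept)` element), so printed model equations can be
#' applied directly.
#'
#' @param model a fitted binomial `glm`, or a named numeric coefficient
#'   vector.
#' @param covariates a data frame of predictor values.
#' @return Numeric vector of probabilities.
#' @export
predict_probability <- function(model, covariates) {
  covariates <- as.data.frame(covariates)
  if (inherits(model, "glm")) {
    coefs <- stats::coef(model)
  } else {
    coefs <- model
  }
  a <- rep(unname(coefs[["(Intercept)"]]), max(1, nrow(covariates)))
  for (nm in setdiff(names(coefs), "(Intercept)")) {
    a <- a + coefs[[nm]] * covariates[[nm]]
  }
  stats::plogis(a)
}

#' Classification agreement of predicted probabilities
#'
#' High-confidence bins: among points with predicted probability `>= hi`, the
#' fraction with label 1; among points with `<= lo`, the fraction with label
#' 0. Cohen's kappa is computed on the 2x2 table of the dichotomized
#' prediction (`p >= threshold`) against the label:
#' `kappa = (po - pe) / (1 - pe)`.
#'
#' @param probs predicted probabilities.
#' @param labels observed 0/1 labels.
#' @param hi,lo high/low probability bin limits (defaults 0.75, 0.25).
#' @param threshold dichotomization threshold for kappa (default 0.5).
#' @return A one-row tibble: `n_hi`, `pct_correct_hi`, `n_lo`,
#'   `pct_correct_lo`, `kappa`.
#' @export
classification_agreement <- function(probs, labels, hi = 0.75, lo = 0.25,
                                     threshold = 0.5) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  hi_bin <- probs >= hi
  lo_bin <- probs <= lo
  pred <- as.integer(probs >= threshold)
  tab <- table(factor(pred, levels = c(1, 0)), factor(labels, levels = c(1, 0)))
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  tibble::tibble(
    n_hi = sum(hi_bin),
    pct_correct_hi = if (any(hi_bin)) 100 * mean(labels[hi_bin] == 1) else NA_real_,
    n_lo = sum(lo_bin),
    pct_correct_lo = if (any(lo_bin)) 100 * mean(labels[lo_bin] == 0) else NA_real_,
    kappa = kappa
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the U statistic, a tie-corrected normal z
#' approximation, and exact enumeration of the permutation distribution for
#' small samples (`n1 + n2 <= 16`, at most 12870 rank splits; ties are
#' included in the enumeration). U is the number of (x, y) pairs with x > y,
#' counting ties as 1/2.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return A one-row tibble: `n1`, `n2`, `U`, `z`, `p`, `exact` (logical).
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  exact <- n <= 16
  if (exact) {
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9))),
      greater = mean(us >= U - 1e-9),
      less = mean(us <= U + 1e-9))
  } else {
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(-z),
      less = stats::pnorm(z))
    p <- min(1, p)
  }
  tibble::tibble(n1 = n1, n2 = n2, U = U, z = z, p = p, exact = exact)
}
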