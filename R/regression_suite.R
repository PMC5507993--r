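DEFAULT_PREDICTORS <- c("total_passes", "density", "clustering",
                        "centralization")

#' Odds ratios and confidence limits from logistic coefficients
#'
#' The odds-ratio transform \eqn{e^\beta} with two-sided normal-theory
#' confidence limits \eqn{e^{\beta \pm z \cdot SE}}: the multiplicative
#' change in success odds per unit increase of the predictor.
#'
#' @param beta Numeric vector of logistic regression coefficients.
#' @param se Standard errors (optional; `NA` limits when omitted).
#' @param conf_mult Normal quantile for the limits (default 1.96, 95%).
#' @return A tibble with columns `beta`, `odds_ratio`, `lower`, `upper`.
#' @export
odds_ratio <- function(beta, se = NULL, conf_mult = 1.96) {
  if (is.null(se)) se <- rep(NA_real_, length(beta))
  stopifnot(length(se) == length(beta))
  tibble::tibble(beta = beta, odds_ratio = exp(beta),
                 lower = exp(beta - conf_mult * se),
                 upper = exp(beta + conf_mult * se))
}

#' Belsley collinearity screen
#'
#' Condition indexes and variance-decomposition proportions of the design
#' matrix (intercept included, columns scaled to unit length, not
#' centered). Collinearity is diagnosed for a dimension when its condition
#' index exceeds 30 and more than one variable has a variance proportion
#' above 0.5 on that dimension. An exactly rank-deficient design yields an
#' infinite condition index and flags every variable loading on the
#' degenerate dimension.
#'
#' @param cases A data frame of regression cases.
#' @param predictors Character vector of predictor column names.
#' @param ci_threshold,vp_threshold The double criterion's thresholds
#'   (defaults 30 and 0.5).
#' @return A list with `condition_indexes` (one per dimension, ascending),
#'   `variance_proportions` (dimension x variable matrix; each variable's
#'   column sums to 1) and `flags` (list of `list(dimension, condition_index,
#'   variables)` for diagnosed dimensions).
#' @export
screen_collinearity <- function(cases, predictors = DEFAULT_PREDICTORS,
                                ci_threshold = 30, vp_threshold = 0.5) {
  X <- cbind(`(Intercept)` = 1, as.matrix(cases[predictors]))
  if (nrow(X) < ncol(X) + 1L)
    stop("need at least p + 2 cases for the collinearity screen",
         call. = FALSE)
  # Belsley scaling: each column to unit Euclidean length, no centering
  X <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
  sv <- svd(X)
  d <- sv$d
  tiny <- d <= max(d) * 1e-12
  ci <- ifelse(tiny, Inf, max(d) / d)

  # variance proportions: phi_jk = v_jk^2 / d_k^2, normalized over k per j
  dsafe <- ifelse(tiny, max(d) * 1e-12, d)
  phi <- sweep(sv$v^2, 2L, dsafe^2, "/")      # variable x dimension
  pi_mat <- t(sweep(phi, 1L, rowSums(phi), "/"))  # dimension x variable
  colnames(pi_mat) <- colnames(X)

  ord <- order(ci)
  ci <- ci[ord]
  pi_mat <- pi_mat[ord, , drop = FALSE]
  rownames(pi_mat) <- seq_along(ci)

  flags <- list()
  for (k in seq_along(ci)) {
    vars <- colnames(pi_mat)[pi_mat[k, ] > vp_threshold]
    if (ci[k] > ci_threshold && length(vars) >= 2L)
      flags[[length(flags) + 1L]] <-
        list(dimension = k, condition_index = ci[k], variables = vars)
  }
  list(condition_indexes = ci, variance_proportions = pi_mat, flags = flags)
}

#' Linearity-of-the-logit test (Box-Tidwell style)
#'
#' Fits a single logistic model containing all predictors plus, for each
#' predictor x, the interaction term x*ln(x), and reports each
#' interaction's Wald p-value. Linearity of the logit is tenable for a
#' predictor when its interaction is non-significant (p > 0.05). Because
#' the network metrics can be exactly 0, a predictor containing zeros is
#' shifted by +1 before the logarithm (x*ln(x) becomes
#' (x+1)*ln(x+1)); the shift used is reported. Negative predictor values
#' are an error: shift the predictor into the positive range first.
#'
#' @param cases A data frame with an `outcome` column (0/1).
#' @param predictors Character vector of predictor column names.
#' @return A list with `p_values` (named per predictor), `shifts` (the
#'   offset applied per predictor, 0 or 1) and `linear` (TRUE when all
#'   p > 0.05).
#' @export
test_logit_linearity <- function(cases, predictors = DEFAULT_PREDICTORS) {
  df <- as.data.frame(cases[c("outcome", predictors)])
  shifts <- numeric(length(predictors))
  names(shifts) <- predictors
  for (j in predictors) {
    x <- df[[j]]
    if (any(x < 0))
      stop("predictor '", j, "' has negative values; shift it into the ",
           "positive range before testing linearity of the logit",
           call. = FALSE)
    shifts[j] <- if (any(x == 0)) 1 else 0
    xs <- x + shifts[j]
    df[[paste0(j, "_xlnx")]] <- xs * log(xs)
  }
  terms <- c(predictors, paste0(predictors, "_xlnx"))
  fml <- stats::reformulate(terms, response = "outcome")
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100L))
  sm <- summary(fit)$coefficients
  inter <- paste0(predictors, "_xlnx")
  wald <- (sm[inter, "Estimate"] / sm[inter, "Std. Error"])^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  names(p) <- predictors
  list(p_values = p, shifts = shifts, linear = all(p > 0.05))
}

#' z-score outlier screen
#'
#' Standardizes each predictor column and flags cases with any
#' standardized value strictly exceeding the threshold in absolute value
#' (default 3.29). Constant columns contribute no outliers.
#'
#' @param cases A data frame of regression cases.
#' @param predictors Character vector of predictor column names.
#' @param threshold Absolute z-score threshold (strict inequality).
#' @return Integer row indices of flagged cases.
#' @export
screen_outliers <- function(cases, predictors = DEFAULT_PREDICTORS,
                            threshold = 3.29) {
  if (nrow(cases) < 2L) stop("need at least 2 cases", call. = FALSE)
  flagged <- rep(FALSE, nrow(cases))
  for (j in predictors) {
    x <- cases[[j]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) next
    flagged <- flagged | abs((x - mean(x)) / s) > threshold
  }
  which(flagged)
}

#' Drop successful-network cases with no passes
#'
#' SOP networks that registered no passes carry no structure to analyse
#' and are removed before modeling; zero-pass UOP cases are retained.
#'
#' @param cases A data frame of regression cases.
#' @return The filtered cases.
#' @export
drop_zero_pass_sop <- function(cases) {
  cases[!(cases$outcome == 1L & cases$total_passes == 0L), , drop = FALSE]
}

#' Rescale the network metrics from \[0, 1\] to \[0, 10\]
#'
#' Multiplies `density`, `clustering` and `centralization` by `factor`
#' (default 10) so that a one-unit change corresponds to 0.1 on the raw
#' scale, adjusting the logistic model's sensitivity; `total_passes` is
#' untouched. The returned case set is flagged and a second rescaling is
#' refused.
#'
#' @param cases A data frame of regression cases.
#' @param factor Multiplier (default 10).
#' @return The rescaled cases, with attribute `rescaled = TRUE`.
#' @export
rescale_metrics <- function(cases, factor = 10) {
  if (isTRUE(attr(cases, "rescaled")))
    stop("cases have already been rescaled; refusing to rescale twice",
         call. = FALSE)
  for (j in c("density", "clustering", "centralization"))
    cases[[j]] <- cases[[j]] * factor
  attr(cases, "rescaled") <- TRUE
  cases
}

#' Full pre-model screening pipeline
#'
#' Applies the preliminary procedures in order: collinearity diagnosis,
#' linearity-of-the-logit test, removal of zero-pass SOP cases, z-score
#' outlier removal, and rescaling of the metrics to a 0-10 scale.
#'
#' @param cases A data frame of regression cases.
#' @param predictors Character vector of predictor column names.
#' @param z_threshold Outlier threshold (default 3.29).
#' @param rescale_factor Metric rescale factor (default 10).
#' @return A list with `cases` (screened, rescaled) and `report` (a
#'   `screening_report` list: collinearity, logit linearity, outlier ids,
#'   zero-pass SOP ids, case counts before and after).
#' @export
screen_cases <- function(cases, predictors = DEFAULT_PREDICTORS,
                         z_threshold = 3.29, rescale_factor = 10) {
  n0 <- nrow(cases)
  collin <- screen_collinearity(cases, predictors)
  linearity <- test_logit_linearity(cases, predictors)
  zero_ids <- which(cases$outcome == 1L & cases$total_passes == 0L)
  kept <- drop_zero_pass_sop(cases)
  out_ids_local <- screen_outliers(kept, predictors, z_threshold)
  if (length(out_ids_local) > 0L)
    kept <- kept[-out_ids_local, , drop = FALSE]
  kept <- rescale_metrics(kept, rescale_factor)
  report <- structure(list(
    collinearity = collin,
    logit_linearity_p = linearity$p_values,
    logit_linear = linearity$linear,
    outlier_ids = out_ids_local,
    zero_pass_ids = zero_ids,
    n_initial = n0, n_kept = nrow(kept),
    n_uop = sum(kept$outcome == 0L), n_sop = sum(kept$outcome == 1L)),
    class = "screening_report")
  list(cases = kept, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report\n")
  cat(sprintf("  cases: %d initial, %d kept (%d UOP, %d SOP)\n",
              x$n_initial, x$n_kept, x$n_uop, x$n_sop))
  cat(sprintf("  max condition index: %.3f; %d dimension(s) flagged\n",
              max(x$collinearity$condition_indexes),
              length(x$collinearity$flags)))
  cat(sprintf("  linearity of the logit: %s (min p = %.3f)\n",
              if (x$logit_linear) "met" else "violated",
              min(x$logit_linearity_p)))
  cat(sprintf("  outliers removed: %d; zero-pass SOP removed: %d\n",
              length(x$outlier_ids), length(x$zero_pass_ids)))
  invisible(x)
}

#' Fit a binary logistic regression with full diagnostics
#'
#' Maximum-likelihood logistic regression (logit link, iteratively
#' reweighted least squares) of `outcome` on the given terms, reporting
#' per-term standard errors, Wald chi-square statistics
#' \eqn{(\beta/SE)^2} with p from \eqn{\chi^2_1}, odds ratios
#' \eqn{e^\beta} with 95% CIs \eqn{e^{\beta \pm 1.96\,SE}}, the maximized
#' and constant-only log-likelihoods, the model chi-square
#' \eqn{G = -2(LL_0 - LL_1)}, Nagelkerke's r-square, the Hosmer-Lemeshow
#' test and a classification table. Complete or quasi-complete separation
#' is detected from diverging standardized coefficients
#' (|beta x sd(x)| > 15) and reported with a warning; the fit is returned
#' flagged `separation = TRUE`.
#'
#' @param cases A data frame with an `outcome` column (0/1) and the term
#'   columns.
#' @param terms Character vector of predictor column names (use
#'   `character(0)` for the constant-only model).
#' @param cutoff Classification cutoff on the fitted probability.
#' @param hl_groups Number of Hosmer-Lemeshow risk groups.
#' @return An object of class `model_fit`.
#' @export
fit_logistic <- function(cases, terms, cutoff = 0.5, hl_groups = 10L) {
  df <- as.data.frame(cases)
  if (!all(df$outcome %in% c(0L, 1L)))
    stop("outcome must be coded 0/1", call. = FALSE)
  if (nrow(df) <= length(terms) + 1L)
    stop("need more cases than model terms", call. = FALSE)
  fml <- if (length(terms) == 0L) outcome ~ 1 else
    stats::reformulate(terms, response = "outcome")
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100L))
  sm <- summary(fit)$coefficients
  beta <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  wald <- (beta / se)^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  ll1 <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(outcome ~ 1, family = stats::binomial(), data = df)
  ll0 <- as.numeric(stats::logLik(fit0))
  n <- nrow(df)

  separation <- FALSE
  if (length(terms) > 0L) {
    sds <- vapply(terms, function(j) stats::sd(df[[j]]), numeric(1))
    std_beta <- abs(beta[terms]) * ifelse(sds > 0, sds, 1)
    if (any(std_beta > 15)) {
      separation <- TRUE
      warning("possible complete separation: standardized |beta| > 15 for ",
              paste(terms[std_beta > 15], collapse = ", "), call. = FALSE)
    }
  }

  out <- structure(list(
    terms = terms,
    coef = beta, se = se, wald = wald, p = p,
    odds_ratio = stats::setNames(odds_ratio(beta, se)$odds_ratio,
                                 names(beta)),
    ci95 = cbind(lower = exp(beta - 1.96 * se),
                 upper = exp(beta + 1.96 * se)),
    loglik = ll1, loglik_null = ll0, n = n,
    G = -2 * (ll0 - ll1), G_df = length(terms),
    G_p = stats::pchisq(-2 * (ll0 - ll1), df = max(length(terms), 1L),
                        lower.tail = FALSE),
    fitted = as.numeric(stats::fitted(fit)),
    y = df$outcome,
    converged = fit$converged,
    separation = separation,
    glm = fit), class = "model_fit")
  out$nagelkerke_r2 <- nagelkerke_r2(out)
  hl <- hosmer_lemeshow(out, groups = hl_groups)
  out$hl_chi2 <- hl$chi2; out$hl_df <- hl$df; out$hl_p <- hl$p
  out$classification <- classification_table(out, cutoff = cutoff)
  out
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Binary logistic regression (n = %d)\n", x$n))
  tab <- data.frame(
    `beta (S.E.)` = sprintf("%.3f (%.3f)", x$coef, x$se),
    Wald = round(x$wald, digits), p = round(x$p, digits),
    `Exp(beta)` = round(x$odds_ratio, digits),
    `CI lower` = round(x$ci95[, "lower"], digits),
    `CI upper` = round(x$ci95[, "upper"], digits),
    check.names = FALSE, row.names = names(x$coef))
  print(tab)
  cat(sprintf("G(%d) = %.3f, p = %.3f; Nagelkerke r2 = %.3f\n",
              x$G_df, x$G, x$G_p, x$nagelkerke_r2))
  cat(sprintf("Hosmer-Lemeshow chi2(%d) = %.3f, p = %.3f\n",
              x$hl_df, x$hl_chi2, x$hl_p))
  cl <- x$classification
  cat(sprintf("Classification: %.1f%% UOP, %.1f%% SOP, %.1f%% overall\n",
              cl$pct_uop, cl$pct_sop, cl$pct_overall))
  invisible(x)
}

#' Two-block hierarchical logistic regression
#'
#' Fits the first block (by default, total passes only), then the second
#' block adding the network metrics, so that the metrics' specific effect
#' is estimated after controlling for pass volume. Reports each block's
#' improvement G over the constant-only model and the second block's
#' improvement over the first (a likelihood-ratio chi-square on the number
#' of added terms).
#'
#' @param cases Screened, rescaled regression cases.
#' @param block1_terms,block2_terms Character vectors of predictor names.
#' @param cutoff,hl_groups Passed to [fit_logistic()].
#' @return An object of class `hierarchical_fit`: `block1` and `block2`
#'   ([fit_logistic()] fits) and `improvement` (`G`, `df`, `p` of block 2
#'   over block 1).
#' @export
hierarchical_fit <- function(cases, block1_terms = "total_passes",
                             block2_terms = c("density", "clustering",
                                              "centralization"),
                             cutoff = 0.5, hl_groups = 10L) {
  fit1 <- fit_logistic(cases, block1_terms, cutoff, hl_groups)
  fit2 <- fit_logistic(cases, c(block1_terms, block2_terms), cutoff,
                       hl_groups)
  G12 <- -2 * (fit1$loglik - fit2$loglik)
  structure(list(
    block1 = fit1, block2 = fit2,
    improvement = list(G = G12, df = length(block2_terms),
                       p = stats::pchisq(G12, df = length(block2_terms),
                                         lower.tail = FALSE))),
    class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat("== Block 1 ==\n"); print(x$block1)
  cat("\n== Block 2 ==\n"); print(x$block2)
  cat(sprintf("\nBlock 2 over block 1: G(%d) = %.3f, p = %.3f\n",
              x$improvement$df, x$improvement$G, x$improvement$p))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Cases are sorted by fitted probability and cut into `groups`
#' equal-count risk groups (quantile cutpoints of type 7; tied fitted
#' values are never split across groups, so degenerate fits yield fewer
#' groups). The statistic sums \eqn{(O-E)^2/E} over groups and both
#' outcomes, with `df = groups - 2`. Groups whose expected count is zero
#' for either outcome are merged with a neighbor, reducing the df, with a
#' warning.
#'
#' @param fit A `model_fit`, or a list with elements `fitted` and `y`.
#' @param groups Number of risk groups (default 10: deciles of risk).
#' @return A list with `chi2`, `df`, `p` and the per-group `table`
#'   (observed and expected counts).
#' @export
hosmer_lemeshow <- function(fit, groups = 10L) {
  p <- fit$fitted
  y <- fit$y
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                                   type = 7, names = FALSE))
  if (length(breaks) < 3L) {
    # fewer than two distinct groups: test undefined, chi2 = 0 on 0 df
    return(list(chi2 = 0, df = 0L, p = NA_real_,
                table = data.frame(n = length(y), o1 = sum(y),
                                   e1 = sum(p))))
  }
  bin <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  o1 <- tapply(y, bin, sum)
  e1 <- tapply(p, bin, sum)
  nn <- tapply(y, bin, length)

  # merge groups with a zero expected count for either outcome
  merged <- FALSE
  repeat {
    e0 <- nn - e1
    bad <- which(e1 == 0 | e0 == 0)
    if (length(bad) == 0L || length(nn) <= 1L) break
    i <- bad[1]
    j <- if (i == 1L) 2L else i - 1L
    o1[j] <- o1[j] + o1[i]; e1[j] <- e1[j] + e1[i]; nn[j] <- nn[j] + nn[i]
    o1 <- o1[-i]; e1 <- e1[-i]; nn <- nn[-i]
    merged <- TRUE
  }
  if (merged)
    warning("Hosmer-Lemeshow groups with zero expected count merged; ",
            "degrees of freedom reduced", call. = FALSE)
  e0 <- nn - e1
  o0 <- nn - o1
  chi2 <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- max(length(nn) - 2L, 1L)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       table = data.frame(n = as.integer(nn), o1 = as.integer(o1), e1 = e1))
}

#' Nagelkerke's r-square
#'
#' Cox-Snell \eqn{R^2_{CS} = 1 - \exp\{2(LL_0 - LL_1)/n\}} rescaled to a
#' unit maximum: \eqn{R^2_N = R^2_{CS} / (1 - \exp\{2 LL_0 / n\})}.
#'
#' @param fit A `model_fit`, or a list with `loglik`, `loglik_null`, `n`.
#' @return A value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  r2_cs <- 1 - exp(2 * (fit$loglik_null - fit$loglik) / fit$n)
  r2 <- r2_cs / (1 - exp(2 * fit$loglik_null / fit$n))
  min(max(r2, 0), 1)
}

#' Classification table at a probability cutoff
#'
#' Predicts success when the fitted probability is at least `cutoff` and
#' cross-tabulates predictions against observed outcomes, reporting the
#' percentage of unsuccessful (UOP, outcome 0) and successful (SOP,
#' outcome 1) cases classified correctly, and the overall percentage.
#'
#' @param fit A `model_fit`, or a list with elements `fitted` and `y`.
#' @param cutoff Probability cutoff (default 0.5).
#' @return A list with the 2x2 `table` (observed x predicted) and
#'   `pct_uop`, `pct_sop`, `pct_overall`.
#' @export
classification_table <- function(fit, cutoff = 0.5) {
  pred <- as.integer(fit$fitted >= cutoff)
  y <- fit$y
  tab <- table(observed = factor(y, levels = 0:1),
               predicted = factor(pred, levels = 0:1))
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  list(table = tab,
       pct_uop = if (n0 > 0L) 100 * tab["0", "0"] / n0 else NA_real_,
       pct_sop = if (n1 > 0L) 100 * tab["1", "1"] / n1 else NA_real_,
       pct_overall = 100 * (tab["0", "0"] + tab["1", "1"]) / length(y))
}

#' Render a full model report
#'
#' Bundles the screening report and the two-block fit into a
#' machine-readable structure, its JSON serialization, and a plain-text
#' table with the SPSS-style columns `beta (S.E.) | Wald | p | Exp(beta) |
#' 95% CI` for each block, followed by the block G statistics, Nagelkerke
#' r-square, Hosmer-Lemeshow test and classification percentages.
#'
#' @param screen A `screening_report` (from [screen_cases()]), or `NULL`.
#' @param fits A `hierarchical_fit`.
#' @param path Optional path; when given, the JSON is written there.
#' @return A list with `report` (nested list), `json` (character scalar)
#'   and `text` (character vector of rendered lines), invisibly writing
#'   `json` to `path` when requested.
#' @export
model_report <- function(screen, fits, path = NULL) {
  stopifnot(inherits(fits, "hierarchical_fit"))
  fit_block <- function(f) list(
    terms = names(f$coef), beta = unname(f$coef), se = unname(f$se),
    wald = unname(f$wald), p = unname(f$p),
    odds_ratio = unname(f$odds_ratio),
    ci95_lower = unname(f$ci95[, "lower"]),
    ci95_upper = unname(f$ci95[, "upper"]),
    loglik = f$loglik, loglik_null = f$loglik_null, n = f$n,
    G = f$G, G_df = f$G_df, G_p = f$G_p,
    nagelkerke_r2 = f$nagelkerke_r2,
    hl_chi2 = f$hl_chi2, hl_df = f$hl_df, hl_p = f$hl_p,
    classification = list(
      table = as.vector(f$classification$table),
      pct_uop = f$classification$pct_uop,
      pct_sop = f$classification$pct_sop,
      pct_overall = f$classification$pct_overall),
    separation = f$separation)
  report <- list(
    screening = if (is.null(screen)) NULL else list(
      condition_indexes = unname(screen$collinearity$condition_indexes),
      collinearity_flags = screen$collinearity$flags,
      logit_linearity_p = as.list(screen$logit_linearity_p),
      outliers_removed = length(screen$outlier_ids),
      zero_pass_sop_removed = length(screen$zero_pass_ids),
      n_initial = screen$n_initial, n_kept = screen$n_kept,
      n_uop = screen$n_uop, n_sop = screen$n_sop),
    block1 = fit_block(fits$block1),
    block2 = fit_block(fits$block2),
    improvement = fits$improvement)
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)

  render_block <- function(f, label) {
    rows <- sprintf("%-22s %8s %8.3f %6.3f %9.3f %8.3f %8.3f",
                    names(f$coef), sprintf("%.3f (%.3f)", f$coef, f$se),
                    f$wald, f$p, f$odds_ratio,
                    f$ci95[, "lower"], f$ci95[, "upper"])
    c(sprintf("-- %s --", label),
      sprintf("%-22s %8s %8s %6s %9s %8s %8s", "term", "b (SE)", "Wald",
              "p", "Exp(b)", "CI lo", "CI hi"),
      rows,
      sprintf("G(%d) = %.3f, p = %.3f | Nagelkerke r2 = %.3f",
              f$G_df, f$G, f$G_p, f$nagelkerke_r2),
      sprintf("Hosmer-Lemeshow chi2(%d) = %.3f, p = %.3f",
              f$hl_df, f$hl_chi2, f$hl_p),
      sprintf("Classified correctly: %.1f%% UOP, %.1f%% SOP, %.1f%% overall",
              f$classification$pct_uop, f$classification$pct_sop,
              f$classification$pct_overall))
  }
  text <- c(render_block(fits$block1, "Block 1"), "",
            render_block(fits$block2, "Block 2"),
            sprintf("Block 2 over block 1: G(%d) = %.3f, p = %.3f",
                    fits$improvement$df, fits$improvement$G,
                    fits$improvement$p))
  invisible(list(report = report, json = as.character(json), text = text))
}
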