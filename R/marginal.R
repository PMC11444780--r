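#' Back-transformed marginal means with 95% confidence intervals
#'
#' Computes the model-predicted mean response at each factor level (for a
#' categorical fit) or at given predictor values (for a continuous fit). The
#' linear predictor eta and its standard error come from the coefficient
#' covariance; the mean is `exp(eta)` with CI `exp(eta +/- 1.96 * se)`,
#' i.e. the interval is symmetric on the log scale (`mean/lower ==
#' upper/mean`). The normal 1.96 multiplier is used throughout.
#'
#' @param fit A single-predictor [gamma_glm()] fit.
#' @param at For a continuous fit, the predictor values at which to evaluate
#'   (default: the mean of the observed predictor). For a categorical fit,
#'   a subset of levels (default: all levels).
#' @return Data frame with columns `at`, `mean`, `lower`, `upper` (kg scale).
#' @export
marginal_means <- function(fit, at = NULL) {
  stopifnot(inherits(fit, "gamma_glm"))
  pred_name <- attr(fit$terms, "term.labels")
  if (length(pred_name) == 0L) {            # intercept-only model
    eta <- unname(fit$coefficients[1])
    se <- sqrt(fit$vcov[1, 1])
    return(data.frame(at = "(intercept)", mean = exp(eta),
                      lower = exp(eta - 1.96 * se),
                      upper = exp(eta + 1.96 * se)))
  }
  if (length(pred_name) != 1L)
    stop("marginal_means supports single-predictor fits", call. = FALSE)
  v <- fit$model[[pred_name]]
  if (is.factor(v)) {
    lev <- levels(v)
    if (is.null(at)) at <- lev
    if (!all(at %in% lev))
      stop("unknown category label(s): ",
           paste(setdiff(at, lev), collapse = ", "), call. = FALSE)
    nd <- stats::setNames(data.frame(factor(at, levels = lev)), pred_name)
  } else {
    if (is.null(at)) at <- mean(v)
    nd <- stats::setNames(data.frame(at), pred_name)
  }
  pr <- predict(fit, nd, type = "link", se.fit = TRUE)
  data.frame(at = at, mean = exp(pr$fit),
             lower = exp(pr$fit - 1.96 * pr$se.fit),
             upper = exp(pr$fit + 1.96 * pr$se.fit))
}

#' Pairwise Wald comparisons of category levels
#'
#' Wald z tests on all pairwise log-scale contrasts of a categorical Gamma
#' GLM, with optional Bonferroni adjustment (p multiplied by the number of
#' pairs, capped at 1), plus a compact letter display at level `alpha`.
#'
#' @param fit A [gamma_glm()] fit with a single factor predictor.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @param alpha Significance level for the letters.
#' @return An object of class `"pairwise_table"`: a list with `table` (one
#'   row per pair: `estimate` on the log scale, `se`, `z`, `p`, `p_adj`),
#'   `letters` (named per-level letter strings), `p_matrix` (symmetric
#'   adjusted p matrix), `alpha` and `adjust`.
#' @export
pairwise_comparisons <- function(fit, adjust = c("bonferroni", "none"),
                                 alpha = 0.05) {
  stopifnot(inherits(fit, "gamma_glm"))
  adjust <- match.arg(adjust)
  pred_name <- attr(fit$terms, "term.labels")
  if (length(pred_name) != 1L || !is.factor(fit$model[[pred_name]]))
    stop("pairwise comparisons require a categorical (factor) design",
         call. = FALSE)
  lev <- levels(fit$model[[pred_name]])
  k <- length(lev)
  if (k < 2L) stop("need at least 2 levels", call. = FALSE)
  tt <- stats::delete.response(fit$terms)
  nd <- stats::setNames(data.frame(factor(lev, levels = lev)), pred_name)
  L <- stats::model.matrix(tt, stats::model.frame(tt, nd, xlev = fit$xlevels))
  pairs <- utils::combn(k, 2)
  npair <- ncol(pairs)
  est <- se <- numeric(npair)
  for (m in seq_len(npair)) {
    cvec <- L[pairs[1, m], ] - L[pairs[2, m], ]
    est[m] <- sum(cvec * fit$coefficients)
    se[m] <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (adjust == "bonferroni") pmin(1, p * npair) else p
  pmat <- matrix(1, k, k, dimnames = list(lev, lev))
  for (m in seq_len(npair)) {
    pmat[pairs[1, m], pairs[2, m]] <- p_adj[m]
    pmat[pairs[2, m], pairs[1, m]] <- p_adj[m]
  }
  tab <- data.frame(contrast = paste(lev[pairs[1, ]], "-", lev[pairs[2, ]]),
                    estimate = est, se = se, z = z, p = p, p_adj = p_adj)
  structure(list(table = tab,
                 letters = cld_letters(lev, pmat, alpha),
                 p_matrix = pmat, alpha = alpha, adjust = adjust),
            class = "pairwise_table")
}

#' @export
print.pairwise_table <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise Wald comparisons (log scale), %s adjustment\n",
              x$adjust))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nLetters (alpha = %g): levels sharing a letter are not",
              x$alpha), "significantly different\n")
  print(x$letters)
  invisible(x)
}

#' Compact letter display by insert-and-absorb
#'
#' Assigns letters to levels so that two levels share at least one letter if
#' and only if their (adjusted) p-value exceeds `alpha`. Implements the
#' insert-and-absorb algorithm: start from one letter covering all levels,
#' split it on each significant pair, then absorb redundant letter columns.
#' Letters are assigned in level order starting at "a".
#'
#' @param labels Character vector of level names, in display order.
#' @param p_matrix Symmetric matrix of (adjusted) pairwise p-values with
#'   dimensions `length(labels)`; the diagonal is ignored.
#' @param alpha Significance level; `p <= alpha` separates a pair.
#' @return Named character vector of letter strings, one per level.
#' @examples
#' p <- matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3)
#' cld_letters(c("A", "B", "C"), p)  # "a", "ab", "b"
#' @export
cld_letters <- function(labels, p_matrix, alpha = 0.05) {
  k <- length(labels)
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) == k, ncol(p_matrix) == k)
  if (max(abs(p_matrix - t(p_matrix))) > 1e-12)
    stop("'p_matrix' must be symmetric", call. = FALSE)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (p_matrix[i, j] > alpha) next
    new_cols <- list()
    for (cl in cols) {
      if (i %in% cl && j %in% cl)
        new_cols <- c(new_cols, list(setdiff(cl, i)), list(setdiff(cl, j)))
      else new_cols <- c(new_cols, list(cl))
    }
    ## absorb: drop any column whose level set is contained in another's
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      if (!keep[a]) next
      for (b in seq_along(new_cols)) {
        if (a == b || !keep[b]) next
        if (all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  cols <- cols[lengths(cols) > 0]
  cols <- cols[order(vapply(cols, min, 1L))]
  out <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cols, function(cl) i %in% cl, TRUE))],
           collapse = ""), "")
  stats::setNames(out, labels)
}

#' McFadden pseudo-R-squared
#'
#' Likelihood-ratio measure of explained variation,
#' `1 - loglik(fit) / loglik(null_fit)`, where `null_fit` is the
#' intercept-only Gamma GLM on the same data. Each fit uses its own
#' profile-ML shape.
#'
#' @param fit A [gamma_glm()] fit.
#' @param null_fit The intercept-only [gamma_glm()] fit on the same data;
#'   computed automatically if omitted.
#' @return The pseudo-R-squared (scalar, at most 1).
#' @export
mcfadden <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "gamma_glm"))
  y <- stats::model.response(fit$model)
  if (is.null(null_fit)) {
    d0 <- data.frame(.y = y)
    null_fit <- gamma_glm(.y ~ 1, d0)
  }
  stopifnot(inherits(null_fit, "gamma_glm"))
  y0 <- stats::model.response(null_fit$model)
  if (length(y) != length(y0) || !isTRUE(all.equal(sort(y), sort(y0))))
    stop("'fit' and 'null_fit' must be fit to the same response data",
         call. = FALSE)
  1 - fit$loglik / null_fit$loglik
}
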