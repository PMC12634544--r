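#' Percent change of a treatment mean relative to a control mean
#'
#' Returns `100 * (treatment - control) / control`, the signed percentage by
#' which the treatment mean differs from the control mean — the convention
#' under which an EC drop from 131.33 to 82.00 uS/cm reads as -37.56%.
#'
#' @param control_mean positive control (reference) mean; vectorised.
#' @param treatment_mean treatment mean; vectorised.
#' @return Signed percent change(s). Display rounding is left to the caller;
#'   one decimal matches common reporting precision.
#' @export
#' @examples
#' percent_change(131.33, 82.00)   # -37.56
#' percent_change(60.34, 111.16)   # +84.2
percent_change <- function(control_mean, treatment_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0))
    abort("control_mean must be strictly positive")
  100 * (treatment_mean - control_mean) / control_mean
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition for a single grouping factor, with
#' the p-value from the F distribution. The degenerate case of zero pooled
#' within-group variance but distinct group means (perfect separation) is
#' reported as `F = Inf`, `p = 0` rather than an error.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @return An object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `mse` (pooled within-group variance)
#'   and `group_n`.
#' @export
one_way_anova <- function(values, groups) {
  if (length(values) != length(groups))
    abort("values and groups must have equal length")
  if (anyNA(values) || anyNA(groups)) abort("missing values not supported")
  groups <- factor(groups)
  n_i <- table(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (any(n_i < 2L))
    abort("every group needs at least 2 observations (smallest has %d)", min(n_i))
  if (stats::var(values) == 0)
    abort("zero total variance: the F statistic is undefined")
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df_b <- k - 1L
  df_w <- N - k
  mse <- ssw / df_w
  if (mse == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ssb / df_b) / mse
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(F = f, df_between = df_b, df_within = df_w, p = p,
                 group_means = means, mse = mse, group_n = as.vector(n_i),
                 groups = levels(groups)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(round(x$group_means, 4))
  invisible(x)
}

#' Fisher's LSD compact letter display
#'
#' Protected least-significant-difference comparisons: pairwise t tests using
#' the pooled ANOVA mean square error and its degrees of freedom are carried
#' out only when the omnibus ANOVA is significant at `alpha`; otherwise every
#' group shares the letter "a". Letters are assembled by the insert-and-absorb
#' algorithm on the pairwise significance graph, with groups ordered by
#' descending mean, so two groups share a letter iff their comparison is
#' non-significant.
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @param alpha significance level (default 0.05).
#' @return An object of class `letter_display`: list with `letters` (named by
#'   group, descending-mean order), `alpha`, `p_matrix` of pairwise p-values
#'   (NA when the omnibus test was not significant) and the underlying
#'   `anova` result.
#' @export
lsd_letters <- function(values, groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  an <- one_way_anova(values, groups)
  groups <- factor(groups)
  means <- an$group_means
  n_i <- stats::setNames(an$group_n, an$groups)
  ord <- names(sort(means, decreasing = TRUE))
  k <- length(ord)
  p_mat <- matrix(NA_real_, k, k, dimnames = list(ord, ord))
  if (an$p < alpha) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      a <- ord[i]; b <- ord[j]
      se <- sqrt(an$mse * (1 / n_i[[a]] + 1 / n_i[[b]]))
      if (se == 0) {
        p_mat[i, j] <- p_mat[j, i] <- if (means[[a]] == means[[b]]) 1 else 0
      } else {
        tstat <- (means[[a]] - means[[b]]) / se
        p_mat[i, j] <- p_mat[j, i] <-
          2 * stats::pt(-abs(tstat), an$df_within)
      }
    }
    nonsig <- p_mat >= alpha
    diag(nonsig) <- TRUE
    letters_vec <- assemble_letters(nonsig)
  } else {
    letters_vec <- stats::setNames(rep("a", k), ord)
  }
  structure(list(letters = letters_vec, alpha = alpha, p_matrix = p_mat,
                 anova = an),
            class = "letter_display")
}

## insert-and-absorb on a logical "shares a letter" matrix whose rows are in
## descending-mean order; returns the letter string per group
assemble_letters <- function(nonsig) {
  k <- nrow(nonsig)
  ord <- rownames(nonsig)
  # columns of `membership` are letter groups (maximal under absorption)
  membership <- matrix(TRUE, k, 1)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (nonsig[i, j]) next
    # i and j must not share any letter column: split columns containing both
    both <- which(membership[i, ] & membership[j, ])
    for (col in both) {
      a <- membership[, col]; a[j] <- FALSE
      b <- membership[, col]; b[i] <- FALSE
      membership <- cbind(membership[, -col, drop = FALSE], a, b)
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, ncol(membership))
    for (c1 in seq_len(ncol(membership))) for (c2 in seq_len(ncol(membership))) {
      if (c1 != c2 && keep[c1] && keep[c2] &&
          all(membership[, c1] <= membership[, c2]) &&
          any(membership[, c1] != membership[, c2]))
        keep[c1] <- FALSE
    }
    membership <- membership[, keep, drop = FALSE]
    membership <- unique(membership, MARGIN = 2)
  }
  # order letter columns by the first (highest-mean) group they contain
  first <- apply(membership, 2, function(col) which(col)[1])
  membership <- membership[, order(first), drop = FALSE]
  labels <- letters[seq_len(ncol(membership))]
  out <- vapply(seq_len(k), function(i)
    paste0(labels[membership[i, ]], collapse = ""), character(1))
  stats::setNames(out, ord)
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("LSD compact letter display (alpha = %g)\n", x$alpha))
  print(x$letters)
  invisible(x)
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise Pearson correlations over the requested columns with two-sided
#' t-test p-values and the conventional star annotation (* p < 0.05,
#' ** p < 0.01; raw thresholds, no multiplicity correction). Constant
#' variables yield `NA` correlations for their pairs and are flagged with a
#' warning rather than silently zeroed.
#'
#' @param table data.frame holding the variables.
#' @param variables character vector of column names (default: all numeric
#'   columns except `replicate`).
#' @return An object of class `correlation_matrix`: list with matrices `r`,
#'   `p`, `stars`, the sample size `n` and `flagged` (names of constant
#'   variables, if any).
#' @export
pearson_matrix <- function(table, variables = NULL) {
  if (is.null(variables)) {
    num <- vapply(table, is.numeric, logical(1))
    variables <- setdiff(names(table)[num], "replicate")
  }
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols))
    abort("columns not found: %s", paste(missing_cols, collapse = ", "))
  X <- as.matrix(table[, variables, drop = FALSE])
  if (!is.numeric(X)) abort("all requested variables must be numeric")
  if (anyNA(X)) abort("missing values not supported")
  n <- nrow(X)
  if (n < 3L) abort("need at least 3 complete observations")
  sds <- apply(X, 2, stats::sd)
  flagged <- variables[sds == 0]
  if (length(flagged))
    warning("constant variable(s), correlations undefined: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  r <- suppressWarnings(stats::cor(X))
  r[flagged, ] <- NA_real_
  r[, flagged] <- NA_real_
  diag(r) <- ifelse(variables %in% flagged, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  diag(p) <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n, flagged = flagged),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  disp <- matrix(paste0(format(round(x$r, digits)), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}
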