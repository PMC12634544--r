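## Partial least squares path modelling (PLS-PM), implemented from scratch:
## iterative outer-weight estimation (mode A, centroid/factorial/path inner
## schemes), OLS structural coefficients, R^2, AVE, goodness-of-fit and
## bootstrap validation of the path coefficients.

#' Specify a PLS path model
#'
#' A model is a set of latent variables, each measured reflectively (mode A)
#' by a block of observed indicator columns, plus an acyclic inner model
#' given as a strictly lower-triangular adjacency matrix in block order
#' (row = response, column = predictor).
#'
#' @param blocks named list: latent name -> character vector of indicator
#'   column names; indicator names must be unique across blocks.
#' @param paths square 0/1 matrix over the latents (row = response,
#'   column = predictor), strictly lower-triangular in the order of
#'   `blocks`. Alternatively a 2-column character matrix / data.frame of
#'   `from`, `to` edges.
#' @param scheme inner weighting scheme: `"path"` (default), `"centroid"`
#'   or `"factorial"`.
#' @return An object of class `plspm_spec`.
#' @export
#' @examples
#' spec <- plspm_spec(
#'   blocks = list(A = "x1", B = "x2"),
#'   paths = data.frame(from = "A", to = "B"))
plspm_spec <- function(blocks, paths, scheme = c("path", "centroid", "factorial")) {
  scheme <- match.arg(scheme)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    abort("blocks must be a named list")
  if (any(lengths(blocks) < 1L)) abort("every latent needs at least 1 indicator")
  inds <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(inds)) abort("indicator names must be unique across blocks")
  k <- length(blocks)
  lat <- names(blocks)
  if (is.data.frame(paths) || (is.matrix(paths) && is.character(paths))) {
    edges <- as.data.frame(paths, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      edges <- stats::setNames(edges[, 1:2], c("from", "to"))
    pm <- matrix(0, k, k, dimnames = list(lat, lat))
    for (e in seq_len(nrow(edges))) {
      i <- match(edges$to[e], lat)
      j <- match(edges$from[e], lat)
      if (is.na(i) || is.na(j))
        abort("unknown latent in path %s -> %s", edges$from[e], edges$to[e])
      pm[i, j] <- 1
    }
  } else {
    pm <- as.matrix(paths)
    dimnames(pm) <- list(lat, lat)
  }
  if (!all(pm %in% c(0, 1))) abort("paths matrix must be binary")
  if (any(pm[upper.tri(pm, diag = TRUE)] != 0))
    abort("inner model must be acyclic: paths must run from earlier to later blocks")
  if (all(pm == 0)) abort("inner model has no paths")
  structure(list(blocks = blocks, paths = pm, scheme = scheme, latents = lat),
            class = "plspm_spec")
}

#' Fit a PLS path model
#'
#' Indicators are standardized; outer weights start equal and are iterated:
#' (i) each latent score is the standardized weighted sum of its block,
#' (ii) an inner proxy is formed per the scheme — centroid: signs of the
#' correlations with adjacent latents; factorial: the correlations
#' themselves; path: regression weights on predecessors and correlations
#' with successors — and (iii) mode-A weights are updated as the
#' correlations between each indicator and its block's inner proxy. On
#' convergence (max absolute outer-weight change below `tol`) the path
#' coefficients are ordinary least squares regressions of each endogenous
#' latent score on its predecessors' scores; loadings are the correlations
#' between indicators and their own latent. The global sign indeterminacy of
#' each latent is fixed by requiring its largest-|loading| indicator to load
#' positively.
#'
#' @param data data.frame containing every indicator column (numeric,
#'   non-constant). Rows with any missing indicator are dropped listwise.
#' @param spec a [plspm_spec()].
#' @param tol convergence tolerance on the maximum absolute outer-weight
#'   change (default 1e-6).
#' @param max_iter maximum outer iterations (default 300).
#' @return An object of class `plspm_fit` with outer weights, `loadings`,
#'   `communalities`, standardized latent `scores`, `path_coefficients`
#'   (matrix) and `paths` (edge data.frame with estimates), `r_squared` per
#'   endogenous latent, `ave` per block, `gof`, `iterations` and
#'   `tolerance_reached`.
#' @seealso [gof()], [ave()], [bootstrap_paths()]
#' @export
fit_plspm <- function(data, spec, tol = 1e-6, max_iter = 300) {
  stopifnot(inherits(spec, "plspm_spec"))
  inds <- unlist(spec$blocks, use.names = FALSE)
  missing_cols <- setdiff(inds, names(data))
  if (length(missing_cols))
    abort("indicator column(s) missing: %s", paste(missing_cols, collapse = ", "))
  X <- as.matrix(data[, inds, drop = FALSE])
  if (!is.numeric(X)) abort("all indicators must be numeric")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  k <- length(spec$blocks)
  pm <- spec$paths
  max_pred <- max(rowSums(pm))
  if (n <= max_pred + 1)
    abort("too few rows (%d) for %d predictors", n, max_pred)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    abort("constant indicator(s): %s", paste(inds[sds == 0], collapse = ", "))
  X <- scale(X)
  block_idx <- lapply(spec$blocks, function(b) match(b, inds))
  lat <- spec$latents

  w <- lapply(block_idx, function(ix) rep(1, length(ix)))
  score_of <- function(w) {
    Y <- sapply(seq_len(k), function(h) {
      y <- X[, block_idx[[h]], drop = FALSE] %*% w[[h]]
      y / stats::sd(y)
    })
    colnames(Y) <- lat
    Y
  }
  link <- pm + t(pm)
  iter <- 0L
  delta <- Inf
  repeat {
    iter <- iter + 1L
    Y <- score_of(w)
    R <- stats::cor(Y)
    E <- matrix(0, k, k)   # inner weights: column h holds weights forming Z_h
    for (h in seq_len(k)) {
      nb <- which(link[h, ] == 1)
      if (spec$scheme == "centroid") {
        E[nb, h] <- sign(R[nb, h])
      } else if (spec$scheme == "factorial") {
        E[nb, h] <- R[nb, h]
      } else {
        pred <- which(pm[h, ] == 1)
        succ <- which(pm[, h] == 1)
        if (length(pred))
          E[pred, h] <- solve(R[pred, pred, drop = FALSE], R[pred, h])
        if (length(succ))
          E[succ, h] <- R[succ, h]
      }
    }
    Z <- Y %*% E
    w_new <- lapply(seq_len(k), function(h) {
      z <- Z[, h]
      wh <- drop(stats::cor(X[, block_idx[[h]], drop = FALSE], z))
      wh
    })
    # compare on the unit-variance normalization so the scale is well-defined
    norm_w <- function(w) lapply(seq_len(k), function(h) {
      y <- X[, block_idx[[h]], drop = FALSE] %*% w[[h]]
      w[[h]] / stats::sd(y)
    })
    delta <- max(mapply(function(a, b) max(abs(a - b)),
                        norm_w(w_new), norm_w(w)))
    w <- w_new
    if (delta < tol || iter >= max_iter) break
  }
  if (delta >= tol)
    abort("PLS-PM did not converge in %d iterations (last delta %.3g)",
          max_iter, delta)

  Y <- score_of(w)
  loadings <- stats::setNames(numeric(length(inds)), inds)
  weights <- stats::setNames(numeric(length(inds)), inds)
  for (h in seq_len(k)) {
    ix <- block_idx[[h]]
    lo <- drop(stats::cor(X[, ix, drop = FALSE], Y[, h]))
    # sign alignment: largest-|loading| indicator loads positively
    if (lo[which.max(abs(lo))] < 0) {
      Y[, h] <- -Y[, h]
      lo <- -lo
      w[[h]] <- -w[[h]]
    }
    loadings[ix] <- lo
    yh <- X[, ix, drop = FALSE] %*% w[[h]]
    weights[ix] <- w[[h]] / stats::sd(yh)
  }

  beta <- matrix(0, k, k, dimnames = list(lat, lat))
  r2 <- stats::setNames(rep(NA_real_, k), lat)
  for (h in seq_len(k)) {
    pred <- which(pm[h, ] == 1)
    if (!length(pred)) next
    fit <- stats::lm.fit(cbind(1, Y[, pred, drop = FALSE]), Y[, h])
    beta[h, pred] <- fit$coefficients[-1]
    r2[h] <- 1 - sum(fit$residuals^2) / sum((Y[, h] - mean(Y[, h]))^2)
  }
  edges <- which(pm == 1, arr.ind = TRUE)
  paths_df <- data.frame(from = lat[edges[, 2]], to = lat[edges[, 1]],
                         estimate = beta[edges], stringsAsFactors = FALSE)
  paths_df <- paths_df[order(match(paths_df$to, lat), match(paths_df$from, lat)), ]
  rownames(paths_df) <- NULL

  communality <- loadings^2
  ave_block <- vapply(seq_len(k), function(h)
    mean(communality[block_idx[[h]]]), numeric(1))
  names(ave_block) <- lat
  r2_endo <- r2[!is.na(r2)]
  fit_obj <- structure(list(
    spec = spec,
    n = n,
    outer_weights = weights,
    loadings = loadings,
    communalities = communality,
    scores = Y,
    path_coefficients = beta,
    paths = paths_df,
    r_squared = r2_endo,
    ave = ave_block,
    iterations = iter,
    tolerance_reached = delta), class = "plspm_fit")
  fit_obj$gof <- gof(fit_obj)
  fit_obj
}

#' Goodness-of-fit of a PLS path model
#'
#' `GoF = sqrt(mean communality x mean R^2)`, the geometric mean of the
#' average indicator communality (over all indicators; single-indicator
#' blocks contribute 1) and the average R^2 over endogenous latents.
#' Values above 0.6 are conventionally read as excellent fit for
#' soil-microbe systems.
#'
#' @param fit a `plspm_fit`.
#' @return The GoF index in `[0, 1]`.
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "plspm_fit"))
  if (!length(fit$r_squared)) abort("model has no endogenous latent")
  sqrt(mean(fit$communalities) * mean(fit$r_squared))
}

#' Classify a goodness-of-fit value
#'
#' Applies the conventional cutoff for soil-microbe path models: GoF above
#' 0.6 is `"excellent"`, otherwise `"modest"`.
#'
#' @param g a GoF value (from [gof()]) or a `plspm_fit`.
#' @return `"excellent"` or `"modest"`.
#' @export
classify_gof <- function(g) {
  if (inherits(g, "plspm_fit")) g <- g$gof
  if (!is.finite(g)) abort("GoF must be finite")
  if (g > 0.6) "excellent" else "modest"
}

#' Average variance extracted per block
#'
#' `AVE = mean of squared loadings` within each indicator block; invariant
#' to indicator sign flips, equal to 1 for single-indicator blocks.
#'
#' @param fit a `plspm_fit`.
#' @return Named numeric vector, one value per latent.
#' @export
ave <- function(fit) {
  stopifnot(inherits(fit, "plspm_fit"))
  fit$ave
}

#' Bootstrap validation of path coefficients
#'
#' Resamples rows with replacement, refits the model on each resample (the
#' largest-|loading| sign rule keeps orientations comparable across
#' resamples) and summarises each inner path with its bootstrap mean,
#' standard error, percentile 95% confidence interval and a two-sided
#' normal-approximation p-value for the original estimate.
#'
#' @param data,spec,tol,max_iter as in [fit_plspm()].
#' @param n_boot number of bootstrap resamples (at least 100; default 1000).
#' @param seed integer seed.
#' @return An object of class `plspm_boot`: data.frame `paths` with columns
#'   `from`, `to`, `estimate`, `boot_mean`, `boot_se`, `ci_lower`,
#'   `ci_upper`, `p`, plus `n_boot`, `n_failed` and `seed`.
#' @export
bootstrap_paths <- function(data, spec, n_boot = 1000, seed = 1,
                            tol = 1e-6, max_iter = 300) {
  if (n_boot < 100) abort("n_boot must be at least 100")
  full <- fit_plspm(data, spec, tol = tol, max_iter = max_iter)
  inds <- unlist(spec$blocks, use.names = FALSE)
  X <- data[stats::complete.cases(data[, inds, drop = FALSE]), , drop = FALSE]
  n <- nrow(X)
  set.seed(substream_seed(seed, "plspm_bootstrap"))
  draws <- matrix(NA_real_, n_boot, nrow(full$paths))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_plspm(X[idx, , drop = FALSE], spec,
                             tol = tol, max_iter = max_iter),
                   error = function(e) NULL)
    if (is.null(fb)) failed <- failed + 1L else draws[b, ] <- fb$paths$estimate
  }
  if (failed > 0.1 * n_boot)
    abort("%d of %d bootstrap refits failed (> 10%%)", failed, n_boot)
  ok <- stats::complete.cases(draws)
  est <- full$paths$estimate
  bm <- colMeans(draws[ok, , drop = FALSE])
  bse <- apply(draws[ok, , drop = FALSE], 2, stats::sd)
  ci <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  p <- 2 * stats::pnorm(-abs(est / bse))
  out <- cbind(full$paths,
               data.frame(boot_mean = bm, boot_se = bse,
                          ci_lower = ci[1, ], ci_upper = ci[2, ], p = p))
  rownames(out) <- NULL
  structure(list(paths = out, n_boot = n_boot, n_failed = failed,
                 seed = seed, fit = full),
            class = "plspm_boot")
}

#' @export
print.plspm_boot <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap path validation (%d resamples, %d failed)\n",
              x$n_boot, x$n_failed))
  print(cbind(x$paths[, c("from", "to")],
              round(x$paths[, c("estimate", "boot_mean", "boot_se",
                                "ci_lower", "ci_upper", "p")], digits)))
  invisible(x)
}

#' @export
print.plspm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("PLS path model: %d latents, %d indicators, n = %d\n",
              length(x$spec$blocks), length(x$loadings), x$n))
  cat(sprintf("Converged in %d iterations (delta %.2g); GoF = %.3f\n",
              x$iterations, x$tolerance_reached, x$gof))
  cat("\nPath coefficients:\n")
  print(cbind(x$paths[, c("from", "to")],
              estimate = round(x$paths$estimate, digits)))
  invisible(x)
}

#' @export
summary.plspm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.plspm_fit")
}

#' @export
print.summary.plspm_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f)
  cat("\nR-squared (endogenous latents):\n")
  print(round(f$r_squared, digits))
  cat("\nAVE per block:\n")
  print(round(f$ave, digits))
  cat("\nLoadings:\n")
  print(round(f$loadings, digits))
  invisible(x)
}

#' @export
coef.plspm_fit <- function(object, ...) {
  stats::setNames(object$paths$estimate,
                  paste(object$paths$from, "->", object$paths$to))
}

#' Read a PLS path model specification from YAML
#'
#' The file lists latents (name + indicators), directed paths (`from`,
#' `to`) and optionally the inner `scheme`. The bundled
#' `model_sr_os2.yaml` encodes the six-latent rotation model with its
#' biological (rotation -> soil properties -> microbial community -> enzyme
#' ratios) and physicochemical (rotation -> micronutrients -> enzyme
#' activity -> enzyme ratios) pathways.
#'
#' @param path YAML file path.
#' @return A [plspm_spec()].
#' @export
#' @examples
#' f <- system.file("extdata", "model_sr_os2.yaml", package = "rotastoich")
#' read_plspm_model(f)
read_plspm_model <- function(path) {
  y <- yaml::read_yaml(path)
  blocks <- stats::setNames(
    lapply(y$latents, function(l) unlist(l$indicators)),
    vapply(y$latents, `[[`, character(1), "name"))
  edges <- do.call(rbind, lapply(y$paths, function(p)
    data.frame(from = p$from, to = p$to, stringsAsFactors = FALSE)))
  scheme <- if (!is.null(y$scheme)) y$scheme else "path"
  plspm_spec(blocks, edges, scheme = scheme)
}
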