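#' Generating parameters for the bundled soil and enzyme variables
#'
#' Returns the per-treatment means and standard deviations (long format:
#' variable, unit, treatment, mean, sd) used by [generate_soil_table()] as its
#' default generating parameters. The table covers six physicochemical
#' variables (pH, EC, SOC, TN, AP, AK) and five extracellular enzyme
#' activities (BG, NAG, LAP, ALP, PPO) across the four rotation stages
#' B1 (untreated control), B2 (substrate amendment), B3 (first crop) and
#' B4 (second no-till crop).
#'
#' @return A data.frame with columns `variable`, `unit`, `treatment`,
#'   `mean`, `sd`.
#' @export
soil_param_table <- function() {
  path <- system.file("extdata", "soil_table_params.tsv",
                      package = "rotastoich", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles the parameters of the three generators — treatment-structured soil
#' tables, compositional count matrices and latent-variable datasets — into a
#' single validated object. Each generator draws from its own seed substream
#' (see [substream_seed()]), so the streams do not interact.
#'
#' @param seed integer global seed; every generator derives its own substream
#'   from it.
#' @param n_treatments number of treatments, labelled `B1..Bk` in order.
#' @param n_replicates replicate plots per treatment (must be at least 2).
#' @param variable_specs data.frame with columns `variable`, `treatment`,
#'   `mean`, `sd` giving the generating parameters for each soil/enzyme
#'   variable under each treatment. Defaults to [soil_param_table()].
#' @param count_spec list describing the compositional count generator:
#'   `n_taxa` (>= 4), `read_depth` (> 0; default 60000 reads per sample),
#'   `log_mean` (length-`n_taxa` log-scale basis means), `log_cov`
#'   (`n_taxa` x `n_taxa` symmetric positive semi-definite log-scale basis
#'   covariance), `fold_changes` (optional named list: treatment label ->
#'   named numeric vector of multiplicative fold changes applied to the basis
#'   abundance of selected taxa), `n_samples_per_treatment` (default
#'   `n_replicates`).
#' @param variable_correlation optional correlation matrix (dimnames = a
#'   subset of the variable names) injected between soil variables within a
#'   replicate via a Gaussian copula on the generating normals; by default
#'   variables are drawn independently, since only per-variable means and
#'   SDs are specified.
#' @param latent_spec list describing the latent-variable generator:
#'   `blocks` (named list: latent name -> character vector of indicator
#'   names), `path_matrix` (square numeric matrix over the latents, row =
#'   response, column = predictor, strictly lower-triangular in block order),
#'   `loadings` (scalar in (0, 1] or named per-indicator vector),
#'   `noise_sd` (per-latent structural noise SDs; `NULL` chooses them so each
#'   latent has unit theoretical variance), `n_samples`.
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' soil <- generate_soil_table(cfg)
#' head(soil)
synthetic_config <- function(seed,
                             n_treatments = 4L,
                             n_replicates = 3L,
                             variable_specs = soil_param_table(),
                             variable_correlation = NULL,
                             count_spec = NULL,
                             latent_spec = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  n_treatments <- as.integer(n_treatments)
  n_replicates <- as.integer(n_replicates)
  if (n_treatments < 2L) abort("need at least 2 treatments")
  if (n_replicates < 2L) abort("n_replicates must be at least 2")
  treatments <- paste0("B", seq_len(n_treatments))

  if (!is.null(variable_specs)) {
    need <- c("variable", "treatment", "mean", "sd")
    if (!all(need %in% names(variable_specs)))
      abort("variable_specs must have columns %s", paste(need, collapse = ", "))
    if (any(variable_specs$sd < 0))
      abort("negative SD in variable_specs")
    key <- paste(variable_specs$variable, variable_specs$treatment)
    if (anyDuplicated(key))
      abort("duplicate variable/treatment rows in variable_specs")
    for (v in unique(variable_specs$variable)) {
      have <- variable_specs$treatment[variable_specs$variable == v]
      if (!all(treatments %in% have))
        abort("variable '%s' lacks parameters for some treatments", v)
    }
  }

  if (!is.null(variable_correlation)) {
    check_symmetric(variable_correlation, "variable_correlation")
    if (is.null(rownames(variable_correlation)))
      abort("variable_correlation needs variable names as dimnames")
    if (!all(rownames(variable_correlation) %in% variable_specs$variable))
      abort("variable_correlation names must be configured variables")
    ev <- eigen(variable_correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) abort("variable_correlation is not positive semi-definite")
  }

  count_spec <- validate_count_spec(count_spec, n_replicates, treatments)
  latent_spec <- validate_latent_spec(latent_spec)

  structure(list(seed = as.integer(seed) %% 2147483647L,
                 n_treatments = n_treatments,
                 n_replicates = n_replicates,
                 treatments = treatments,
                 variable_specs = variable_specs,
                 variable_correlation = variable_correlation,
                 count_spec = count_spec,
                 latent_spec = latent_spec),
            class = "synthetic_config")
}

validate_count_spec <- function(spec, n_replicates, treatments) {
  if (is.null(spec)) {
    n_taxa <- 30L
    spec <- list(n_taxa = n_taxa,
                 read_depth = 60000L,
                 # rank-abundance gradient on the log scale
                 log_mean = seq(3, 0, length.out = n_taxa),
                 log_cov = diag(n_taxa),
                 fold_changes = NULL,
                 n_samples_per_treatment = n_replicates)
  }
  spec$n_taxa <- as.integer(spec$n_taxa)
  if (spec$n_taxa < 4L)
    abort("count_spec$n_taxa must be at least 4 (required by basis-correlation inference)")
  if (is.null(spec$read_depth)) spec$read_depth <- 60000L
  if (spec$read_depth <= 0) abort("read_depth must be positive")
  if (is.null(spec$log_mean)) spec$log_mean <- rep(0, spec$n_taxa)
  if (length(spec$log_mean) != spec$n_taxa)
    abort("log_mean must have length n_taxa")
  if (is.null(spec$log_cov)) spec$log_cov <- diag(spec$n_taxa)
  check_symmetric(spec$log_cov, "count_spec$log_cov")
  if (nrow(spec$log_cov) != spec$n_taxa)
    abort("log_cov must be n_taxa x n_taxa")
  ev <- eigen(spec$log_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    abort("count_spec$log_cov is not positive semi-definite")
  if (is.null(spec$n_samples_per_treatment))
    spec$n_samples_per_treatment <- n_replicates
  if (!is.null(spec$fold_changes)) {
    if (!all(names(spec$fold_changes) %in% treatments))
      abort("fold_changes names must be treatment labels")
    for (fc in spec$fold_changes)
      if (any(fc <= 0)) abort("fold changes must be positive")
  }
  spec
}

validate_latent_spec <- function(spec) {
  if (is.null(spec)) {
    spec <- list(
      blocks = list(LV1 = c("x1", "x2", "x3"),
                    LV2 = c("x4", "x5", "x6"),
                    LV3 = c("x7", "x8", "x9")),
      path_matrix = matrix(c(0, 0, 0,
                             0.8, 0, 0,
                             0, 0.6, 0), 3, 3, byrow = TRUE),
      loadings = 0.9,
      noise_sd = NULL,
      n_samples = 100L)
  }
  if (is.null(names(spec$blocks)) || any(!nzchar(names(spec$blocks))))
    abort("latent_spec$blocks must be a named list")
  inds <- unlist(spec$blocks, use.names = FALSE)
  if (anyDuplicated(inds)) abort("indicator names must be unique across blocks")
  k <- length(spec$blocks)
  pm <- spec$path_matrix
  if (!is.matrix(pm) || nrow(pm) != k || ncol(pm) != k)
    abort("path_matrix must be %d x %d (row = response, column = predictor)", k, k)
  if (any(pm[upper.tri(pm, diag = TRUE)] != 0))
    abort("path_matrix must be strictly lower-triangular: the inner model must be acyclic")
  lo <- spec$loadings
  if (length(lo) == 1L && is.null(names(lo))) {
    lo <- stats::setNames(rep(lo, length(inds)), inds)
  } else if (!all(inds %in% names(lo))) {
    abort("loadings must be a scalar or named for every indicator")
  } else {
    lo <- lo[inds]
  }
  if (any(lo <= 0 | lo > 1)) abort("loadings must lie in (0, 1]")
  spec$loadings <- lo
  if (!is.null(spec$noise_sd) && any(spec$noise_sd < 0))
    abort("noise_sd must be nonnegative")
  if (is.null(spec$n_samples)) spec$n_samples <- 100L
  spec
}

#' Simulate a treatment-structured soil/enzyme table
#'
#' Draws replicate-level observations for every configured variable from a
#' truncated-at-zero normal with the configured per-treatment mean and SD.
#' Truncation is implemented by resampling (not clipping), so the generated
#' distributions stay continuous. With `sd = 0` every replicate equals its
#' group mean exactly. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()] object.
#' @return A data.frame with columns `treatment` (ordered factor), `replicate`
#'   and one numeric column per configured variable.
#' @export
generate_soil_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  specs <- config$variable_specs
  if (is.null(specs) || nrow(specs) == 0L)
    abort("config has no variable_specs")
  set.seed(substream_seed(config$seed, "soil_table"))
  treatments <- config$treatments
  n_rep <- config$n_replicates
  vars <- unique(specs$variable)
  out <- data.frame(
    treatment = factor(rep(treatments, each = n_rep),
                       levels = treatments, ordered = TRUE),
    replicate = rep(seq_len(n_rep), times = length(treatments)))
  corr <- config$variable_correlation
  corr_vars <- if (is.null(corr)) character(0) else rownames(corr)
  for (v in setdiff(vars, corr_vars)) {
    col <- numeric(nrow(out))
    for (tr in treatments) {
      row <- specs[specs$variable == v & specs$treatment == tr, ]
      col[out$treatment == tr] <- rnorm_truncated(n_rep, row$mean, row$sd)
    }
    out[[v]] <- col
  }
  if (length(corr_vars)) {
    # Gaussian copula: correlated standard normals mapped through each
    # variable's mean/SD; rows with a non-positive value are redrawn whole,
    # preserving the injected correlation
    for (tr in treatments) {
      mu <- vapply(corr_vars, function(v)
        specs$mean[specs$variable == v & specs$treatment == tr], numeric(1))
      sdv <- vapply(corr_vars, function(v)
        specs$sd[specs$variable == v & specs$treatment == tr], numeric(1))
      draw <- function(n) {
        z <- MASS::mvrnorm(n, mu = rep(0, length(corr_vars)), Sigma = corr)
        z <- matrix(z, nrow = n)
        sweep(sweep(z, 2, sdv, `*`), 2, mu, `+`)
      }
      x <- draw(n_rep)
      bad <- which(apply(x, 1, function(r) any(r <= 0)))
      guard <- 0L
      while (length(bad)) {
        x[bad, ] <- draw(length(bad))
        bad <- bad[apply(x[bad, , drop = FALSE], 1, function(r) any(r <= 0))]
        guard <- guard + 1L
        if (guard > 10000L) abort("correlated truncated sampling failed")
      }
      for (ci in seq_along(corr_vars))
        out[[corr_vars[ci]]][out$treatment == tr] <- x[, ci]
    }
    out <- out[, c("treatment", "replicate", vars)]
  }
  out
}

#' Simulate a compositional taxa-by-sample count matrix
#'
#' Per sample, log-scale basis abundances are drawn from a multivariate
#' normal (so the basis is log-normal with the configured mean vector and
#' covariance), treatment fold-changes are applied multiplicatively to the
#' basis of selected taxa, abundances are closed to proportions and counts
#' are drawn from a multinomial at the configured read depth — the generative
#' model under which log-ratio (SparCC-type) correlation inference is
#' well-posed. The true log-scale basis correlation matrix is returned
#' alongside for recovery tests.
#'
#' @param config a [synthetic_config()] object.
#' @return An object of class `count_matrix`: a list with `counts` (integer
#'   taxa x samples matrix whose columns each sum to the read depth),
#'   `treatments` (named character vector mapping sample to treatment),
#'   `true_correlation`, and `read_depth`.
#' @export
generate_count_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- config$count_spec
  set.seed(substream_seed(config$seed, "count_matrix"))
  n_taxa <- spec$n_taxa
  n_per <- spec$n_samples_per_treatment
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  samples <- character(0)
  treatment_of <- character(0)
  counts <- matrix(0L, n_taxa, 0)
  for (tr in config$treatments) {
    z <- MASS::mvrnorm(n_per, mu = spec$log_mean, Sigma = spec$log_cov)
    z <- matrix(z, nrow = n_per)          # keep matrix shape when n_per == 1
    basis <- exp(z)                        # samples x taxa
    fc <- spec$fold_changes[[tr]]
    if (!is.null(fc)) {
      idx <- match(names(fc), taxa)
      if (anyNA(idx)) idx <- as.integer(names(fc))
      basis[, idx] <- sweep(basis[, idx, drop = FALSE], 2, fc, `*`)
    }
    prop <- basis / rowSums(basis)
    cnt <- apply(prop, 1, function(p) stats::rmultinom(1, spec$read_depth, p))
    counts <- cbind(counts, cnt)
    ids <- sprintf("%s_s%02d", tr, seq_len(n_per))
    samples <- c(samples, ids)
    treatment_of <- c(treatment_of, stats::setNames(rep(tr, n_per), ids))
  }
  dimnames(counts) <- list(taxa, samples)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 treatments = treatment_of,
                 true_correlation = stats::cov2cor(spec$log_cov),
                 read_depth = spec$read_depth),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Synthetic count matrix: %d taxa x %d samples, read depth %d\n",
              nrow(x$counts), ncol(x$counts), x$read_depth))
  cat("Treatments:", paste(unique(x$treatments), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a latent-variable dataset with known paths and loadings
#'
#' Exogenous latent scores are standard normal; each endogenous latent is the
#' linear combination of its predecessors given by the true path coefficients
#' plus Gaussian structural noise; each indicator is `loading * latent` plus
#' measurement noise with variance `1 - loading^2`, so indicators have unit
#' theoretical variance. When `noise_sd` is `NULL` the structural noise SDs
#' are chosen so every latent also has unit theoretical variance, making the
#' configured path coefficients standardized coefficients — directly
#' comparable to a fitted path model. Indicator columns are empirically
#' standardized before return.
#'
#' @param config a [synthetic_config()] object with a `latent_spec`.
#' @return A data.frame of indicator columns with attribute `truth`, a list
#'   holding `path_matrix`, `loadings`, `blocks`, and the simulated
#'   `latent_scores`.
#' @export
generate_latent_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- config$latent_spec
  set.seed(substream_seed(config$seed, "latent"))
  blocks <- spec$blocks
  k <- length(blocks)
  n <- spec$n_samples
  pm <- spec$path_matrix
  # theoretical latent covariance, filled in topological (block) order
  C <- diag(k)
  noise_sd <- spec$noise_sd
  auto <- is.null(noise_sd)
  if (auto) noise_sd <- numeric(k)
  eta <- matrix(0, n, k)
  for (j in seq_len(k)) {
    b <- pm[j, ]
    if (all(b == 0)) {
      if (auto) noise_sd[j] <- 1
      eta[, j] <- stats::rnorm(n)
    } else {
      var_sys <- drop(t(b) %*% C %*% b)
      if (auto) {
        if (var_sys >= 1)
          abort("true paths imply latent variance >= 1 for latent %d; supply noise_sd", j)
        noise_sd[j] <- sqrt(1 - var_sys)
      }
      eta[, j] <- drop(eta %*% b) + stats::rnorm(n, sd = noise_sd[j])
      # update theoretical covariance for later latents
      C[j, j] <- var_sys + noise_sd[j]^2
      for (m in seq_len(j - 1)) {
        C[j, m] <- C[m, j] <- drop(C[m, ] %*% b)
      }
    }
  }
  colnames(eta) <- names(blocks)
  inds <- unlist(blocks, use.names = FALSE)
  X <- matrix(0, n, length(inds), dimnames = list(NULL, inds))
  for (j in seq_len(k)) {
    for (v in blocks[[j]]) {
      lo <- spec$loadings[[v]]
      X[, v] <- lo * eta[, j] + stats::rnorm(n, sd = sqrt(max(1 - lo^2, 0)))
    }
  }
  X <- scale(X)
  out <- as.data.frame(X)
  attr(out, "truth") <- list(path_matrix = pm,
                             loadings = spec$loadings,
                             blocks = blocks,
                             noise_sd = noise_sd,
                             latent_scores = eta)
  out
}
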