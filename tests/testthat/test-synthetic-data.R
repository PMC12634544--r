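# Synthetic-data generators: determinism, degenerate noise, moment
# consistency, compositional closure and configuration validation.

test_that("soil table generation is deterministic and respects degenerate noise", {
  specs <- soil_param_table()
  cfg <- synthetic_config(seed = 11, variable_specs = specs)
  t1 <- generate_soil_table(cfg)
  t2 <- generate_soil_table(cfg)
  expect_identical(t1, t2)

  specs0 <- specs
  specs0$sd <- 0
  cfg0 <- synthetic_config(seed = 11, variable_specs = specs0)
  t0 <- generate_soil_table(cfg0)
  for (v in unique(specs0$variable)) {
    for (tr in paste0("B", 1:4)) {
      expect_equal(unique(t0[[v]][t0$treatment == tr]),
                   specs0$mean[specs0$variable == v & specs0$treatment == tr])
    }
  }
})

test_that("generated group means converge to the configured means (3 SE)", {
  cfg <- synthetic_config(seed = 202, n_replicates = 1000)
  tab <- generate_soil_table(cfg)
  ec_b1 <- tab$EC[tab$treatment == "B1"]
  se <- param("EC", "B1", "sd") / sqrt(1000)
  expect_lt(abs(mean(ec_b1) - param("EC", "B1", "mean")), 3 * se)
  # truncation leaves values strictly positive everywhere
  vars <- setdiff(names(tab), c("treatment", "replicate"))
  expect_true(all(as.matrix(tab[vars]) > 0))
})

test_that("soil config rejects invalid parameter tables", {
  bad_sd <- data.frame(variable = "x", treatment = paste0("B", 1:4),
                       mean = 1, sd = c(1, 1, -0.1, 1))
  expect_error(synthetic_config(seed = 1, variable_specs = bad_sd), "negative SD")
  dup <- rbind(soil_param_table(), soil_param_table()[1, ])
  expect_error(synthetic_config(seed = 1, variable_specs = dup), "duplicate")
  expect_error(synthetic_config(seed = 1, n_replicates = 1), "at least 2")
})

test_that("correlation injection reproduces the requested dependence", {
  R <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
              dimnames = list(c("SOC", "TN"), c("SOC", "TN")))
  cfg <- synthetic_config(seed = 5, n_replicates = 500,
                          variable_correlation = R)
  tab <- generate_soil_table(cfg)
  b1 <- tab[tab$treatment == "B1", ]
  expect_gt(cor(b1$SOC, b1$TN), 0.8)
  expect_true(all(tab$SOC > 0 & tab$TN > 0))
})

test_that("count matrices close to the configured read depth and carry truth", {
  cfg <- count_config(seed = 21, n_taxa = 12, n_samples = 5, read_depth = 777)
  cm <- generate_count_matrix(cfg)
  expect_true(all(colSums(cm$counts) == 777))
  expect_identical(storage.mode(cm$counts), "integer")
  expect_equal(dim(cm$counts), c(12L, 20L))
  expect_equal(cm$true_correlation, diag(12))
  expect_identical(generate_count_matrix(cfg)$counts, cm$counts)
})

test_that("count config rejects too few taxa and non-PSD covariance", {
  expect_error(count_config(seed = 1, n_taxa = 3, n_samples = 5), "at least 4")
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(count_config(seed = 1, n_taxa = 5, n_samples = 5, log_cov = bad),
               "positive semi-definite")
  asym <- diag(5); asym[1, 2] <- 0.5
  expect_error(count_config(seed = 1, n_taxa = 5, n_samples = 5, log_cov = asym),
               "symmetric")
})

test_that("independent basis gives near-zero estimated correlations", {
  cfg <- count_config(seed = 31, n_taxa = 10, n_samples = 50)
  cm <- generate_count_matrix(cfg)
  est <- sparcc(cm)
  off <- abs(est$rho[upper.tri(est$rho)])
  expect_lt(mean(off), 0.15)
})

test_that("treatment fold-changes raise the targeted taxon's relative abundance", {
  fc <- list(B3 = c(taxon_001 = 10), B4 = c(taxon_001 = 10))
  cfg <- count_config(seed = 41, n_taxa = 8, n_samples = 50, fold_changes = fc)
  cm <- generate_count_matrix(cfg)
  rel <- cm$counts[1, ] / colSums(cm$counts)
  grp <- cm$treatments[colnames(cm$counts)]
  lo <- mean(rel[grp %in% c("B1", "B2")])
  hi <- mean(rel[grp %in% c("B3", "B4")])
  expect_gt(hi, lo)
})

test_that("latent datasets are deterministic, standardized and carry truth", {
  cfg <- latent_config(seed = 51, n = 200)
  d1 <- generate_latent_dataset(cfg)
  d2 <- generate_latent_dataset(cfg)
  expect_identical(d1, d2)
  expect_equal(unname(colMeans(as.matrix(d1))), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(d1), 2, sd)), rep(1, 6), tolerance = 1e-12)
  truth <- attr(d1, "truth")
  expect_equal(truth$path_matrix[2, 1], 0.8)
  # auto noise keeps the endogenous latent near unit variance
  expect_equal(sd(truth$latent_scores[, "LV2"]), 1, tolerance = 0.15)
})

test_that("cyclic inner models and bad loadings are rejected", {
  cyc <- list(blocks = list(A = "x1", B = "x2"),
              path_matrix = matrix(c(0, 1, 1, 0), 2, 2),
              loadings = 0.9, n_samples = 50)
  expect_error(synthetic_config(seed = 1, variable_specs = NULL,
                                latent_spec = cyc), "acyclic")
  bad_lo <- list(blocks = list(A = "x1", B = "x2"),
                 path_matrix = matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE),
                 loadings = 1.2, n_samples = 50)
  expect_error(synthetic_config(seed = 1, variable_specs = NULL,
                                latent_spec = bad_lo), "loadings")
})

test_that("null inner paths are recovered as near-zero on average", {
  # single-indicator blocks: the fitted path is the indicator correlation,
  # so its null distribution is centred at zero
  betas <- vapply(1:200, function(i) {
    cfg <- synthetic_config(seed = 6000 + i, variable_specs = NULL,
      latent_spec = list(blocks = list(A = "x1", B = "x2"),
                         path_matrix = matrix(c(0, 0, 0, 0), 2, 2),
                         loadings = 1, noise_sd = NULL, n_samples = 60))
    d <- generate_latent_dataset(cfg)
    spec <- plspm_spec(list(A = "x1", B = "x2"),
                       data.frame(from = "A", to = "B"))
    fit_plspm(d, spec)$paths$estimate
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("seed substreams are stable and mutually distinct", {
  s <- substream_seed(42, "soil_table")
  expect_identical(s, substream_seed(42, "soil_table"))
  expect_false(s == substream_seed(42, "count_matrix"))
  expect_true(s >= 0 && s < 2^31)
})
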