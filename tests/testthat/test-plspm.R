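# PLS path modelling: spec validation, closed-form reductions, parameter
# recovery, GoF/AVE identities and bootstrap behaviour.

test_that("model specification validates structure", {
  expect_error(plspm_spec(list(A = "x1", B = "x1"),
                          data.frame(from = "A", to = "B")), "unique")
  expect_error(plspm_spec(list(A = "x1", B = "x2"),
                          data.frame(from = "B", to = "A")), "acyclic")
  expect_error(plspm_spec(list(A = "x1", B = "x2"),
                          data.frame(from = "A", to = "C")), "unknown latent")
  expect_error(plspm_spec(list(A = "x1", B = "x2"),
                          matrix(0, 2, 2)), "no paths")
  s <- plspm_spec(list(A = "x1", B = "x2"), data.frame(from = "A", to = "B"))
  expect_s3_class(s, "plspm_spec")
  expect_equal(s$paths[2, 1], 1)
})

test_that("two single-indicator blocks reduce to the Pearson correlation", {
  set.seed(71)
  d <- data.frame(x1 = rnorm(80))
  d$x2 <- 0.6 * d$x1 + rnorm(80, sd = 0.5)
  spec <- plspm_spec(list(A = "x1", B = "x2"), data.frame(from = "A", to = "B"))
  fit <- fit_plspm(d, spec)
  expect_equal(fit$paths$estimate, cor(d$x1, d$x2), tolerance = 1e-8)
  expect_equal(unname(fit$loadings), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(fit$ave), c(1, 1), tolerance = 1e-12)
})

test_that("single-indicator models reproduce OLS path analysis", {
  set.seed(72)
  n <- 120
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + rnorm(n, sd = 0.8)
  z3 <- 0.4 * z1 - 0.6 * z2 + rnorm(n, sd = 0.6)
  d <- data.frame(z1 = z1, z2 = z2, z3 = z3)
  spec <- plspm_spec(list(L1 = "z1", L2 = "z2", L3 = "z3"),
                     data.frame(from = c("L1", "L1", "L2"),
                                to = c("L2", "L3", "L3")))
  fit <- fit_plspm(d, spec)
  # oracle: standardized OLS on the observed variables
  ds <- as.data.frame(scale(d))
  o1 <- coef(lm(z2 ~ z1, ds))[-1]
  o2 <- coef(lm(z3 ~ z1 + z2, ds))[-1]
  got <- fit$path_coefficients
  expect_equal(got["L2", "L1"], unname(o1["z1"]), tolerance = 1e-8)
  expect_equal(got["L3", "L1"], unname(o2["z1"]), tolerance = 1e-8)
  expect_equal(got["L3", "L2"], unname(o2["z2"]), tolerance = 1e-8)
  expect_equal(unname(fit$r_squared["L3"]),
               summary(lm(z3 ~ z1 + z2, ds))$r.squared, tolerance = 1e-8)
})

test_that("latent scores are unit variance and sign-aligned", {
  cfg <- latent_config(seed = 73, n = 200)
  d <- generate_latent_dataset(cfg)
  truth <- attr(d, "truth")
  spec <- plspm_spec(truth$blocks, data.frame(from = "LV1", to = "LV2"))
  fit <- fit_plspm(d, spec)
  expect_equal(unname(apply(fit$scores, 2, sd)), c(1, 1), tolerance = 1e-12)
  for (b in names(truth$blocks)) {
    lo <- fit$loadings[truth$blocks[[b]]]
    expect_gt(lo[which.max(abs(lo))], 0)
  }
})

test_that("a true path of 0.8 with loadings 0.9 is recovered within 0.1", {
  cfg <- latent_config(seed = 74, beta = 0.8, loadings = 0.9, n = 500)
  d <- generate_latent_dataset(cfg)
  spec <- plspm_spec(attr(d, "truth")$blocks,
                     data.frame(from = "LV1", to = "LV2"))
  fit <- fit_plspm(d, spec)
  expect_lt(abs(fit$paths$estimate - 0.8), 0.1)
  expect_true(all(abs(fit$loadings - 0.9) < 0.1))
})

test_that("null paths stay below 0.1 at n = 500", {
  cfg <- latent_config(seed = 75, beta = 0, loadings = 0.9, n = 500)
  d <- generate_latent_dataset(cfg)
  spec <- plspm_spec(attr(d, "truth")$blocks,
                     data.frame(from = "LV1", to = "LV2"))
  fit <- fit_plspm(d, spec)
  expect_lt(abs(fit$paths$estimate), 0.1)
})

test_that("gof follows its defining identity and classification rule", {
  # exact construction: x fixed, y built so that cor(x, y) = 0.7 exactly
  set.seed(76)
  x <- scale(rnorm(50))[, 1]
  e <- scale(resid(lm(rnorm(50) ~ x)))[, 1]
  y <- 0.7 * x + sqrt(1 - 0.49) * e
  d <- data.frame(x1 = x, x2 = y)
  spec <- plspm_spec(list(A = "x1", B = "x2"), data.frame(from = "A", to = "B"))
  fit <- fit_plspm(d, spec)
  expect_equal(unname(fit$r_squared), 0.49, tolerance = 1e-10)
  expect_equal(fit$gof, 0.7, tolerance = 1e-10)
  # identity: recomputable from stored parts
  expect_equal(fit$gof,
               sqrt(mean(fit$communalities) * mean(fit$r_squared)),
               tolerance = 1e-12)
  expect_identical(classify_gof(fit), "excellent")
  expect_identical(classify_gof(0.59), "modest")
})

test_that("ave equals the mean squared loading per block", {
  cfg <- latent_config(seed = 77, n = 150)
  d <- generate_latent_dataset(cfg)
  truth <- attr(d, "truth")
  spec <- plspm_spec(truth$blocks, data.frame(from = "LV1", to = "LV2"))
  fit <- fit_plspm(d, spec)
  for (b in names(truth$blocks)) {
    expect_equal(unname(fit$ave[b]),
                 mean(fit$loadings[truth$blocks[[b]]]^2), tolerance = 1e-12)
  }
  expect_identical(ave(fit), fit$ave)
  expect_equal(fit$gof,
               sqrt(mean(fit$communalities) * mean(fit$r_squared)),
               tolerance = 1e-12)
})

test_that("centroid and path schemes agree on well-conditioned data", {
  cfg <- latent_config(seed = 78, beta = 0.8, n = 300)
  d <- generate_latent_dataset(cfg)
  blocks <- attr(d, "truth")$blocks
  edges <- data.frame(from = "LV1", to = "LV2")
  f_path <- fit_plspm(d, plspm_spec(blocks, edges, scheme = "path"))
  f_cent <- fit_plspm(d, plspm_spec(blocks, edges, scheme = "centroid"))
  f_fact <- fit_plspm(d, plspm_spec(blocks, edges, scheme = "factorial"))
  expect_equal(sign(f_path$paths$estimate), sign(f_cent$paths$estimate))
  expect_lt(abs(f_path$paths$estimate - f_cent$paths$estimate), 0.05)
  expect_lt(abs(f_path$paths$estimate - f_fact$paths$estimate), 0.05)
})

test_that("constant indicators and unknown columns are rejected", {
  d <- data.frame(x1 = rnorm(30), x2 = rep(1, 30))
  spec <- plspm_spec(list(A = "x1", B = "x2"), data.frame(from = "A", to = "B"))
  expect_error(fit_plspm(d, spec), "constant indicator")
  spec2 <- plspm_spec(list(A = "x1", B = "x9"), data.frame(from = "A", to = "B"))
  expect_error(fit_plspm(d, spec2), "missing")
})

test_that("bootstrap is seeded, covers the truth and excludes zero for strong paths", {
  cfg <- latent_config(seed = 79, beta = 0.8, n = 500)
  d <- generate_latent_dataset(cfg)
  spec <- plspm_spec(attr(d, "truth")$blocks,
                     data.frame(from = "LV1", to = "LV2"))
  b1 <- bootstrap_paths(d, spec, n_boot = 150, seed = 9)
  b2 <- bootstrap_paths(d, spec, n_boot = 150, seed = 9)
  expect_identical(b1$paths, b2$paths)
  expect_gt(b1$paths$ci_lower, 0)
  expect_lt(b1$paths$p, 0.001)
  expect_error(bootstrap_paths(d, spec, n_boot = 50), "at least 100")
})

test_that("the bundled six-latent model file loads with its two pathways", {
  f <- system.file("extdata", "model_sr_os2.yaml", package = "rotastoich")
  spec <- read_plspm_model(f)
  expect_equal(length(spec$blocks), 6L)
  lat <- spec$latents
  pm <- spec$paths
  edge <- function(from, to) pm[match(to, lat), match(from, lat)] == 1
  # biological pathway
  expect_true(edge("Rotation", "SoilProperties"))
  expect_true(edge("SoilProperties", "MicrobialCommunity"))
  expect_true(edge("MicrobialCommunity", "EnzymeRatios"))
  # physicochemical pathway
  expect_true(edge("Rotation", "Micronutrients"))
  expect_true(edge("Micronutrients", "EnzymeActivity"))
  expect_true(edge("EnzymeActivity", "EnzymeRatios"))
})
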