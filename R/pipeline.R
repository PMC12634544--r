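## End-to-end orchestration: one config drives the synthetic generators and
## the analysis stages, writing TSV/JSON/GraphML artifacts plus a run report
## with checksums. All randomness flows from the config seed via named
## substreams, so identical configs give identical outputs.

#' Write / read a soil sample table as TSV
#'
#' Samples x variables with header row and `treatment` / `replicate`
#' columns. The reader validates the schema before any computation.
#'
#' @param table data.frame as produced by [generate_soil_table()].
#' @param path file path.
#' @return `read_soil_table` returns the validated data.frame with
#'   `treatment` as an ordered factor.
#' @export
write_soil_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_soil_table
#' @export
read_soil_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"treatment" %in% names(tb))
    abort("soil table %s lacks a 'treatment' column (expected schema: treatment, replicate, <variables>)", path)
  vars <- setdiff(names(tb), c("treatment", "replicate"))
  bad <- vars[!vapply(tb[vars], is.numeric, logical(1))]
  if (length(bad))
    abort("non-numeric variable column(s) in %s: %s", path, paste(bad, collapse = ", "))
  if (anyNA(tb$treatment)) abort("missing treatment labels in %s", path)
  lv <- sort(unique(tb$treatment))
  tb$treatment <- factor(tb$treatment, levels = lv, ordered = TRUE)
  tb
}

#' Write / read a taxa x sample count matrix as TSV
#'
#' Taxa as rows with a leading `taxon_id` column, samples as further
#' columns.
#'
#' @param m a `count_matrix` or taxa x sample matrix.
#' @param path file path.
#' @return `read_count_table` returns an integer matrix (taxa x samples).
#' @export
write_count_table <- function(m, path) {
  counts <- as_count_input(m)
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "taxon_id")
    abort("count table %s must have 'taxon_id' as its first column", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m < 0) || any(m != round(m)))
    abort("count table %s must hold nonnegative integers", path)
  rownames(m) <- df$taxon_id
  storage.mode(m) <- "integer"
  m
}

#' The bundled demonstration pipeline configuration
#'
#' Synthetic-data pipeline configuration using the bundled soil/enzyme
#' generating parameters, two simulated communities (bacteria and fungi)
#' and the six-latent path model. Micronutrient generating parameters are
#' synthetic placeholders defined in the config file itself.
#'
#' @param seed optional seed override.
#' @return The configuration list.
#' @export
demo_config <- function(seed = NULL) {
  path <- system.file("extdata", "demo_config.yaml", package = "rotastoich",
                      mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- seed
  cfg
}

## internal: merge the micronutrient specs declared in a pipeline config
## into the bundled Table-parameter data.frame
config_variable_specs <- function(cfg) {
  specs <- soil_param_table()
  if (!is.null(cfg$extra_variables)) {
    extra <- do.call(rbind, lapply(cfg$extra_variables, function(v)
      data.frame(variable = v$variable, unit = v$unit,
                 treatment = names(v$means),
                 mean = unlist(v$means), sd = unlist(v$sds))))
    rownames(extra) <- NULL
    specs <- rbind(specs, extra)
  }
  specs
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation (or reading of user
#' tables), treatment statistics, enzyme stoichiometry, community analysis
#' (diversity, Bray-Curtis, PCoA, PERMANOVA), co-occurrence network
#' inference and PLS path modelling; each stage writes its artifacts under
#' `out_dir`. A stage failure aborts the run with the failing stage named;
#' artifacts of earlier stages remain on disk.
#'
#' @param config a configuration list (see [demo_config()]) or the path of
#'   a YAML file holding one.
#' @param out_dir output directory (created if needed).
#' @return An object of class `run_report`: list with `outputs` (paths),
#'   `checksums` (md5 per output file), `config`, `version` and
#'   `wall_time_s`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) abort("config must set an explicit seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  outputs <- character(0)
  seed <- config$seed
  stages <- config$stages
  if (is.null(stages))
    stages <- c("simulate", "stats", "stoich", "community", "network", "plspm")
  emit <- function(path) outputs <<- c(outputs, path)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  soil <- NULL; communities <- list()
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha

  ## ---- simulate (or read user tables) ----
  run_stage("simulate", function() {
    if (!is.null(config$soil_table)) {
      soil <<- read_soil_table(config$soil_table)
    } else {
      scfg <- synthetic_config(
        seed = seed,
        n_replicates = if (is.null(config$n_replicates)) 3L else config$n_replicates,
        variable_specs = config_variable_specs(config))
      soil <<- generate_soil_table(scfg)
    }
    if ("simulate" %in% stages) {
      write_soil_table(soil, file.path(out_dir, "soil_table.tsv"))
      emit(file.path(out_dir, "soil_table.tsv"))
    }
    for (comm in names(config$communities)) {
      cc <- config$communities[[comm]]
      if (!is.null(cc$counts_table)) {
        counts <- read_count_table(cc$counts_table)
        map <- sub("_s[0-9]+$", "", colnames(counts))
        communities[[comm]] <<- structure(
          list(counts = counts,
               treatments = stats::setNames(map, colnames(counts)),
               true_correlation = NULL, read_depth = NA),
          class = "count_matrix")
      } else {
        n_taxa <- if (is.null(cc$n_taxa)) 30L else cc$n_taxa
        rng <- if (is.null(cc$log_mean_range)) c(3, 0) else unlist(cc$log_mean_range)
        fc <- if (is.null(cc$fold_changes)) NULL else
          lapply(cc$fold_changes, function(x) unlist(x))
        log_cov <- diag(n_taxa)
        for (pr in cc$correlated_pairs) {
          log_cov[pr$a, pr$b] <- log_cov[pr$b, pr$a] <- pr$rho
        }
        ccfg <- synthetic_config(
          seed = substream_seed(seed, comm),
          n_replicates = if (is.null(config$n_replicates)) 3L else config$n_replicates,
          variable_specs = NULL,
          count_spec = list(
            n_taxa = n_taxa,
            read_depth = if (is.null(cc$read_depth)) 60000L else cc$read_depth,
            log_mean = seq(rng[1], rng[2], length.out = n_taxa),
            log_cov = log_cov,
            fold_changes = fc))
        communities[[comm]] <<- generate_count_matrix(ccfg)
      }
      f <- file.path(out_dir, sprintf("counts_%s.tsv", comm))
      write_count_table(communities[[comm]], f)
      emit(f)
    }
  })

  ## ---- treatment statistics ----
  if ("stats" %in% stages) run_stage("stats", function() {
    vars <- setdiff(names(soil), c("treatment", "replicate"))
    anova_list <- list()
    for (v in vars) {
      an <- one_way_anova(soil[[v]], soil$treatment)
      ld <- lsd_letters(soil[[v]], soil$treatment, alpha = alpha)
      anova_list[[v]] <- list(F = an$F, df = c(an$df_between, an$df_within),
                              p = an$p, group_means = as.list(an$group_means),
                              letters = as.list(ld$letters))
    }
    cm <- pearson_matrix(soil, vars)
    out <- list(alpha = alpha, anova = anova_list,
                correlation = list(variables = vars, r = cm$r, p = cm$p,
                                   stars = cm$stars))
    f <- file.path(out_dir, "stats.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(f)
  })

  ## ---- enzyme stoichiometry ----
  if ("stoich" %in% stages) run_stage("stoich", function() {
    st <- suppressWarnings(stoichiometry(soil,
      mode = if (is.null(config$stoich_mode)) "literal" else config$stoich_mode))
    f <- file.path(out_dir, "stoichiometry.tsv")
    utils::write.table(st, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(f)
  })

  ## ---- community ----
  if ("community" %in% stages) run_stage("community", function() {
    perms <- if (is.null(config$permutations)) 999 else config$permutations
    res <- list()
    for (comm in names(communities)) {
      m <- communities[[comm]]
      div <- alpha_diversity(m)
      f_div <- file.path(out_dir, sprintf("diversity_%s.tsv", comm))
      utils::write.table(div, f_div, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f_div)
      d <- bray_curtis(m)
      f_d <- file.path(out_dir, sprintf("braycurtis_%s.tsv", comm))
      utils::write.table(as.matrix(d), f_d, sep = "\t", quote = FALSE)
      emit(f_d)
      ord <- pcoa(d)
      f_c <- file.path(out_dir, sprintf("pcoa_%s.tsv", comm))
      utils::write.table(ord$coordinates, f_c, sep = "\t", quote = FALSE)
      emit(f_c)
      pmv <- permanova(d, m$treatments[colnames(m$counts)],
                       n_permutations = perms, seed = substream_seed(seed, comm))
      res[[comm]] <- list(
        permanova = list(F = pmv$F, R2 = pmv$R2, p = pmv$p,
                         n_permutations = perms),
        pcoa_correction = ord$correction,
        pcoa_explained = ord$proportion_explained[1:2])
    }
    f <- file.path(out_dir, "community.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(f)
  })

  ## ---- co-occurrence network ----
  if ("network" %in% stages) run_stage("network", function() {
    rho_min <- if (is.null(config$rho_min)) 0.6 else config$rho_min
    q_max <- if (is.null(config$q_max)) 0.01 else config$q_max
    net_perms <- if (is.null(config$network_permutations)) 99 else config$network_permutations
    topo_all <- list()
    for (comm in names(communities)) {
      m <- communities[[comm]]
      est <- sparcc(m, seed = substream_seed(seed, paste0("sparcc_", comm)))
      # pooled null: per-pair permutation p-values cannot resolve below
      # 1/(B+1), which the q < 0.01 retention rule would never pass at
      # feasible B; pooling permuted values across pairs restores resolution
      est <- sparcc_pvalues(est, m, n_permutations = net_perms,
                            seed = substream_seed(seed, paste0("perm_", comm)),
                            pool = TRUE)
      net <- build_network(est, rho_min = rho_min, q_max = q_max)
      f_e <- file.path(out_dir, sprintf("edges_%s.tsv", comm))
      utils::write.table(net$edges, f_e, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f_e)
      if (nrow(net$edges)) {
        f_g <- file.path(out_dir, sprintf("network_%s.graphml", comm))
        igraph::write_graph(as_igraph(net), f_g, format = "graphml")
        emit(f_g)
      }
      topo <- network_topology(net)
      topo_all[[comm]] <- unclass(topo)
    }
    f <- file.path(out_dir, "network_topology.json")
    jsonlite::write_json(topo_all, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(f)
  })

  ## ---- PLS path model ----
  if ("plspm" %in% stages) run_stage("plspm", function() {
    model_path <- if (is.null(config$model)) {
      system.file("extdata", "model_sr_os2.yaml", package = "rotastoich",
                  mustWork = TRUE)
    } else config$model
    spec <- read_plspm_model(model_path)
    merged <- assemble_plspm_table(soil, communities)
    n_boot <- if (is.null(config$n_boot)) 0 else config$n_boot
    fit <- fit_plspm(merged, spec)
    out <- list(gof = fit$gof,
                r_squared = as.list(fit$r_squared),
                ave = as.list(fit$ave),
                loadings = as.list(fit$loadings),
                paths = fit$paths,
                iterations = fit$iterations)
    if (n_boot >= 100) {
      bt <- bootstrap_paths(merged, spec, n_boot = n_boot,
                            seed = substream_seed(seed, "plspm"))
      out$bootstrap <- bt$paths
      out$n_boot <- n_boot
    }
    f <- file.path(out_dir, "plspm.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(f)
  })

  checksums <- tools::md5sum(outputs)
  structure(list(outputs = outputs, checksums = checksums, config = config,
                 version = as.character(utils::packageVersion("rotastoich")),
                 wall_time_s = proc.time()[["elapsed"]] - t0),
            class = "run_report")
}

## internal: replicate-level merged table for the six-latent model —
## soil/enzyme variables + per-sample diversity of each community + enzyme
## ratios + ordinal rotation stage
assemble_plspm_table <- function(soil, communities) {
  merged <- soil
  merged$rotation <- as.integer(merged$treatment)
  rt <- enzyme_ratios(soil$BG, soil$NAG, soil$LAP, soil$ALP, soil$PPO)
  merged <- cbind(merged, rt[, c("ratio_cn", "ratio_nagl", "ratio_cp", "ratio_cppo")])
  for (comm in names(communities)) {
    div <- alpha_diversity(communities[[comm]])
    # align count samples to soil replicates within treatment, in order
    div <- div[order(div$treatment, div$sample), ]
    key <- unlist(lapply(split(seq_len(nrow(div)), div$treatment), seq_along))
    div$replicate <- key
    pre <- substr(comm, 1, 4)
    idx <- match(paste(merged$treatment, merged$replicate),
                 paste(div$treatment, div$replicate))
    merged[[paste0(pre, "_chao1")]] <- div$chao1[idx]
    merged[[paste0(pre, "_simpson")]] <- div$simpson[idx]
  }
  merged
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (%.1f s, version %s): %d artifact(s)\n",
              x$wall_time_s, x$version, length(x$outputs)))
  for (f in x$outputs) cat("  ", basename(f), "\n")
  invisible(x)
}
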