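# Pipeline orchestration: simulate -> TIS -> DOE -> explore -> train, driven
# by a validated configuration (R list or YAML file), with per-stage
# artifacts, seeds and output hashes logged to a summary report.

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = "waxnose_out",
    generator = list(noise_sd = 0.02, lot_sd = 0.05, peak_width = 1.5),
    tis = list(mz_lo = 50L, mz_hi = 550L),
    doe = list(responses_csv = NULL),  # NULL: bundled reference experiment
    explore = list(hca_method = "ward", n_components = 2L),
    train = list(
      models = c("svm", "rf", "pls", "svr"),
      train_fraction = 0.7,
      log2_C_grid = seq(0, 10, by = 2),
      log2_sigma_grid = seq(-8, 2, by = 2),
      epsilon = 0.1,
      max_components = 10L))
}

# Recursively overlay user values on the defaults; unknown keys are errors
# (they are almost always typos in hyperparameter names).
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
                          !is.null(names(defaults[[nm]])))
      .merge_config(defaults[[nm]], user[[nm]], paste0(path, nm, "$"))
    else user[[nm]]
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' @param config Named list of overrides, or a path to a YAML file with the
#'   same structure. Unknown keys are rejected. A single master `seed`
#'   deterministically derives every stage seed.
#' @return The full configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .merge_config(.default_config(), config)
}

.stage_seed <- function(master, stage_index)
  (as.integer(master) %% 1000003L) * 211L + stage_index * 7919L

.file_hash <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sum(as.integer(readBin(con, "raw", file.size(path))) *
        (seq_len(file.size(path)) %% 251 + 1)) %% 2147483647
}

#' Run the full analysis pipeline
#'
#' Stages: simulate the 75-run study, collapse to the normalized TIS matrix,
#' fit the response-surface model (to responses supplied in the config or to
#' the bundled reference experiment), run HCA + PCA, and train the requested
#' supervised models. Every stage writes its artifacts under `out_dir` and
#' logs its seed and output hashes; rerunning with the same config reproduces
#' the outputs byte for byte.
#'
#' @param config A [pipeline_config()], a plain override list, or a YAML
#'   path.
#' @return The report list (also written to `out_dir/report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.list(config) && !is.null(config$train)) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, stages = list())
  log_stage <- function(name, seed, files, info = list()) {
    report$stages[[name]] <<- c(list(
      seed = seed, files = as.list(files),
      hashes = lapply(stats::setNames(files, basename(unlist(files))),
                      .file_hash)), info)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  out <- function(...) file.path(cfg$out_dir, ...)

  # -- simulate ---------------------------------------------------------
  seed_sim <- .stage_seed(cfg$seed, 1L)
  study <- run_stage("simulate", {
    params <- generator_params(noise_sd = cfg$generator$noise_sd,
                               lot_sd = cfg$generator$lot_sd,
                               peak_width = cfg$generator$peak_width)
    make_study(params, seed = seed_sim)
  })
  md_file <- out("sample_metadata.csv")
  utils::write.csv(study$metadata, md_file, row.names = FALSE)
  log_stage("simulate", seed_sim, md_file,
            list(n_runs = length(study$runs)))

  # -- tis --------------------------------------------------------------
  tm <- run_stage("tis",
    study_tis_matrix(study, cfg$tis$mz_lo, cfg$tis$mz_hi))
  tis_file <- out("tis_matrix.csv")
  write_tis_matrix(tm, tis_file)
  log_stage("tis", NA, c(tis_file, out("tis_matrix_metadata.csv")),
            list(n_channels = nrow(tm$D), n_samples = ncol(tm$D)))

  # -- doe --------------------------------------------------------------
  doe <- run_stage("doe", {
    study_doe <- if (!is.null(cfg$doe$responses_csv)) {
      resp <- utils::read.csv(cfg$doe$responses_csv)
      need <- c("x1", "x2", "x3", "response")
      if (!all(need %in% names(resp)))
        stop("responses CSV must have columns x1, x2, x3, response")
      design <- resp[c("x1", "x2", "x3")]
      design$run_order <- seq_len(nrow(design))
      set_responses(structure(list(factors = headspace_factors(),
                                   design = design, responses = NULL),
                              class = "bbd_study"),
                    resp$response)
    } else example_bbd_study()
    fit <- fit_quadratic(study_doe)
    opt <- optimize_surface(fit, seed = .stage_seed(cfg$seed, 3L))
    list(fit = fit, opt = opt)
  })
  doe_file <- out("doe_model.json")
  lof <- lack_of_fit(doe$fit)
  jsonlite::write_json(list(
    coefficients = as.list(doe$fit$coefficients),
    r_squared_percent = 100 * doe$fit$r_squared,
    anova = anova_table(doe$fit),
    lack_of_fit = list(f = lof$f, p = lof$p),
    optimum = list(coded = as.list(doe$opt$coded),
                   natural = as.list(doe$opt$natural),
                   predicted = doe$opt$predicted)),
    doe_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("doe", .stage_seed(cfg$seed, 3L), doe_file)

  # -- explore ----------------------------------------------------------
  expl <- run_stage("explore", {
    hca <- run_hca(tm, method = cfg$explore$hca_method)
    pca <- run_pca(tm, n_components = cfg$explore$n_components)
    list(hca = hca, pca = pca)
  })
  newick_file <- out("dendrogram.nwk")
  export_dendrogram(expl$hca, newick_file, out("hca_merges.csv"))
  utils::write.csv(data.frame(sample_id = rownames(expl$pca$scores),
                              expl$pca$scores),
                   out("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mz = rownames(expl$pca$loadings),
                              expl$pca$loadings),
                   out("pca_loadings.csv"), row.names = FALSE)
  log_stage("explore", NA,
            c(newick_file, out("hca_merges.csv"), out("pca_scores.csv"),
              out("pca_loadings.csv")),
            list(agglomerative_coefficient =
                   expl$hca$agglomerative_coefficient,
                 explained_variance_percent =
                   as.list(100 * expl$pca$explained_variance_fraction)))

  # -- train ------------------------------------------------------------
  seed_tr <- .stage_seed(cfg$seed, 5L)
  models <- run_stage("train", {
    sp <- split_data(tm, cfg$train$train_fraction, seed = seed_tr)
    res <- list()
    tr <- sp$train
    if ("svm" %in% cfg$train$models) {
      tuned <- tune_svm(tr, "classify", cfg$train$log2_C_grid,
                        cfg$train$log2_sigma_grid, seed = seed_tr)
      res$svm <- assess_model(
        train_svm(tr, tuned$C, tuned$sigma, folds = tuned$folds), sp$test)
    }
    if ("rf" %in% cfg$train$models) {
      folds <- make_cv_folds(.xy(tr, "classify")$y, seed = seed_tr)
      res$rf <- assess_model(rf_fit(tr, "classify", folds = folds,
                                    seed = seed_tr), sp$test)
    }
    if ("pls" %in% cfg$train$models)
      res$pls <- assess_model(pls_fit(tr, cfg$train$max_components,
                                      seed = seed_tr), sp$test)
    if ("svr" %in% cfg$train$models) {
      tuned <- tune_svm(tr, "regress", cfg$train$log2_C_grid,
                        cfg$train$log2_sigma_grid,
                        epsilon = cfg$train$epsilon, seed = seed_tr)
      res$svr <- assess_model(
        train_svr(tr, tuned$C, tuned$sigma, cfg$train$epsilon,
                  folds = tuned$folds), sp$test)
    }
    res
  })
  model_file <- out("model_report.json")
  jsonlite::write_json(lapply(models, function(m) list(
    algorithm = m$algorithm, task = m$task,
    hyperparameters = m$hyperparameters,
    cv_metrics = m$cv_metrics, test_metrics = m$test_metrics,
    n_support_vectors = m$n_support_vectors, oob_error = m$oob_error)),
    model_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("train", seed_tr, model_file,
            list(models = names(models)))

  report_file <- out("report.json")
  jsonlite::write_json(report$stages, report_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(c(report, list(models = models, doe = doe, explore = expl)))
}
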