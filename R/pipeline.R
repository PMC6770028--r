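# End-to-end orchestration: data in (synthetic or files), split, charges,
# alignment, fields, PLS, validation, contour export, JSON report.

default_config <- function() {
  list(
    input = list(synthetic = list(seed = 42L)),
    split = list(fraction = 0.10, seed = 42L),
    charges = list(method = "peoe", iterations = 8L),
    alignment = list(max_dist = 4.0),
    fields = list(spacing = 2.0, margin = 4.0, min_sigma = 2.0,
                  probe_charge = 1.0),
    pls = list(max_components = 10L),
    scrambling = list(enabled = TRUE, components = 2:7, bins = 2:10,
                      reps_per_bin = 10L, critical_point = 0.85, seed = 42L),
    output = NULL)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  inp <- cfg$input
  if (is.null(inp)) stopf("config error: missing 'input' section")
  if (!is.null(inp$synthetic)) return(invisible(cfg))
  for (field in c("poses", "activities", "receptor")) {
    if (is.null(inp[[field]])) {
      stopf("config error: input needs either 'synthetic' or 'poses' + 'activities' + 'receptor'; missing '%s'", field)
    }
  }
  for (field in c("pdb", "resno")) {
    if (is.null(inp$receptor[[field]])) {
      stopf("config error: input$receptor missing '%s'", field)
    }
  }
  invisible(cfg)
}

#' Run the CoMFA pipeline end to end
#'
#' Stages: load or generate the aligned dataset; stratified train/test
#' split; charge assignment (file inputs); field computation on a common
#' lattice; minimum-sigma filter and CoMFA-STD scaling fit on the training
#' set; leave-one-out component selection and PLS fit; training statistics
#' and field contributions; external test-set prediction; progressive
#' scrambling; STDEV*COEFF contour export. Re-running with an identical
#' configuration reproduces the report bit-identically.
#'
#' @param config a nested list, or path to a YAML file with the same shape;
#'   see `comfa:::default_config()` for the schema and defaults. Provide
#'   either `input$synthetic` (arguments of [synthetic_spec]) or
#'   `input$poses`/`input$activities`/`input$receptor` file paths.
#' @param quiet suppress progress messages.
#' @return the run report (list), invisibly if an output directory is set.
#' @export
run_comfa <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  # an explicit file-based input section replaces the default synthetic one
  if (!is.null(config$input) && is.null(config$input$synthetic)) {
    cfg$input$synthetic <- NULL
  }
  validate_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  outdir <- cfg$output
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$input$synthetic)) {
    say("generating synthetic benchmark")
    spec <- do.call(synthetic_spec, cfg$input$synthetic)
    gen <- generate_dataset(spec)
    if (isTRUE(spec$multi_pose)) {
      say("aligning %d poses", length(gen$all_poses))
      dataset <- build_aligned_dataset(gen$all_poses, gen$dataset$activities,
                                       gen$dataset$anchor,
                                       cfg$alignment$max_dist)
    } else {
      dataset <- gen$dataset
    }
    truth <- gen$truth
  } else {
    say("reading poses from %s", cfg$input$poses)
    poses <- read_poses(cfg$input$poses)
    poses <- lapply(poses, assign_charges, method = cfg$charges$method,
                    iterations = cfg$charges$iterations)
    activities <- read_activities(cfg$input$activities)
    anchor <- locate_anchor(cfg$input$receptor$pdb,
                            chain = cfg$input$receptor$chain %||% NA,
                            resno = cfg$input$receptor$resno,
                            resname = cfg$input$receptor$resname %||% "ASP")
    dataset <- build_aligned_dataset(poses, activities, anchor,
                                     cfg$alignment$max_dist)
    truth <- NULL
  }
  act <- dataset$activities
  say("aligned dataset: %d compounds (%d dropped)",
      length(dataset$poses), nrow(dataset$dropped))

  # --- split --------------------------------------------------------------
  split <- split_train_test(act, fraction = cfg$split$fraction,
                            seed = cfg$split$seed)
  act <- apply_split(act, split)
  say("split: %d training / %d test", length(split$training_ids),
      length(split$test_ids))

  # --- fields -------------------------------------------------------------
  probe <- probe_spec(charge = cfg$fields$probe_charge)
  grid <- build_grid(dataset, spacing = cfg$fields$spacing,
                     margin = cfg$fields$margin)
  say("grid: %s points", paste(grid$dims, collapse = " x "))
  fm <- compute_field_matrix(dataset, grid, probe)
  fm_train <- subset_field_matrix(fm, split$training_ids)
  prep <- filter_and_scale(fm_train, min_sigma = cfg$fields$min_sigma)
  say("retained %d of %d field columns", sum(prep$retained),
      length(prep$retained))
  y_train <- act$pic50[match(split$training_ids, act$compound_id)]

  # --- PLS ----------------------------------------------------------------
  sel <- select_onc(prep$X, y_train, max_components = cfg$pls$max_components)
  model <- fit_pls(prep$X, y_train, sel$onc, fields = prep$fields)
  fit_stats <- regression_stats(model, prep$X, y_train)
  contributions <- field_contributions(model, prep$X)
  say("ONC = %d, Q2 = %.3f, R2 = %.3f, F = %.1f", sel$onc, sel$q2,
      fit_stats$r2, fit_stats$f)

  ext <- NULL
  if (length(split$test_ids)) {
    X_test <- apply_field_prep(prep, fm$values[split$test_ids, , drop = FALSE])
    y_test <- act$pic50[match(split$test_ids, act$compound_id)]
    pred_test <- predict(model, X_test)
    ext <- list(r2 = external_r2(y_test, pred_test),
                predictions = data.frame(compound_id = split$test_ids,
                                         observed = y_test,
                                         predicted = pred_test))
    say("external test R2 = %.3f", ext$r2)
  }

  # --- progressive scrambling ----------------------------------------------
  scramb <- NULL
  if (isTRUE(cfg$scrambling$enabled)) {
    say("progressive scrambling (%d x %d perturbations)",
        length(cfg$scrambling$bins), cfg$scrambling$reps_per_bin)
    scramb <- progressive_scrambling(
      prep$X, y_train,
      component_range = cfg$scrambling$components,
      bins_range = cfg$scrambling$bins,
      reps_per_bin = cfg$scrambling$reps_per_bin,
      critical_point = cfg$scrambling$critical_point,
      seed = cfg$scrambling$seed)
  }

  # --- contours -----------------------------------------------------------
  cf <- stdev_coeff_field(model, prep)

  report <- list(
    n_compounds = length(dataset$poses),
    n_dropped = nrow(dataset$dropped),
    n_train = length(split$training_ids),
    n_test = length(split$test_ids),
    grid_dims = grid$dims,
    columns_retained = sum(prep$retained),
    onc = sel$onc,
    q2 = sel$q2, sep = sel$sep,
    r2 = fit_stats$r2, see = fit_stats$see, f = fit_stats$f,
    contributions = as.list(contributions),
    external_r2 = if (!is.null(ext)) ext$r2 else NULL,
    q2_path = sel$q2_path,
    scrambling = if (!is.null(scramb)) scramb$table else NULL)
  if (!is.null(truth)) {
    report$recovery <- recovery_report(model, prep, truth,
                                       stats = list(q2 = sel$q2))
  }

  if (!is.null(outdir)) {
    utils::write.csv(act, file.path(outdir, "activities_split.csv"),
                     row.names = FALSE)
    if (nrow(dataset$dropped)) {
      utils::write.csv(dataset$dropped, file.path(outdir, "excluded.csv"),
                       row.names = FALSE)
    }
    write_poses(unname(dataset$poses), file.path(outdir, "aligned.sdf"))
    if (!is.null(scramb)) {
      write_scrambling_csv(scramb, file.path(outdir, "scrambling.csv"))
    }
    if (!is.null(ext)) {
      utils::write.csv(ext$predictions,
                       file.path(outdir, "test_predictions.csv"),
                       row.names = FALSE)
    }
    export_contours(cf, file.path(outdir, "contours"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
    say("report written to %s", file.path(outdir, "report.json"))
    return(invisible(c(report, list(model = model, prep = prep,
                                    contour_field = cf, split = split))))
  }
  c(report, list(model = model, prep = prep, contour_field = cf,
                 split = split))
}
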