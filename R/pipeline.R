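#' End-to-end rad-score prognosis pipeline
#'
#' Reproduces the full analysis workflow on a cohort: extract the
#' 110-feature texture vector per lesion, fit the lasso-logistic
#' rad-score on the training split's five-year outcome, find the
#' log-rank-optimal cutpoint on the training split, apply the frozen
#' score and cutoff to the validation split, run Kaplan-Meier / log-rank
#' and univariate-then-multivariate Cox analyses per endpoint, and (for
#' the full stage set) build nomograms, bootstrap calibration, a C-index
#' model comparison, and a mask-perturbation ICC reproducibility check.
#'
#' Every training-derived parameter (feature standardization, penalty,
#' coefficients, cutoff) is computed from the training split only and
#' frozen before any validation data are touched; the returned
#' `provenance` records the training ids those parameters were computed
#' from, and results are deterministic given the seed.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or `NULL`
#'   to generate one from `sim_config`.
#' @param sim_config Simulation settings used when `cohort` is `NULL`.
#' @param score_endpoint Endpoint defining the five-year outcome and the
#'   cutpoint search: `"os"` (default) or `"ttr"`.
#' @param rule Lasso penalty selection rule (`"one_se"` or `"min"`).
#' @param n_folds Cross-validation folds for the penalty search.
#' @param min_group_fraction Cutpoint group-size floor (default 0.10).
#' @param entry_p Univariate p threshold for multivariate entry.
#' @param ties Cox tie handling.
#' @param horizons_months Nomogram/calibration horizons (default 36, 60).
#' @param calibration_B,compare_B Bootstrap replicate counts.
#' @param icc_n_images Training images re-read for the ICC stage
#'   (default 60).
#' @param n_levels Gray levels for quantization.
#' @param stages Subset of `c("survival", "nomogram", "calibration",
#'   "compare", "icc")` to run after scoring; `"all"` (default) runs
#'   everything. Scoring and cutpoint search always run.
#' @param seed Seed controlling fold assignment and every bootstrap.
#' @param out_dir Optional directory: results are written as CSV/JSON
#'   with the seed and a config hash in `run_info.json`.
#' @return An object of class `radsurv_run`; see Details for elements.
#' @details The returned list contains `clinical` (with `rad_score` and
#'   `rad_group` columns), `model`, `cutpoint`, `km` and `logrank` per
#'   split and endpoint, `cox` screening tables, `nomogram`,
#'   `calibration`, `model_comparison`, `icc`, `provenance` and `log`.
#' @export
run_pipeline <- function(cohort = NULL,
                         sim_config = simulation_config(),
                         score_endpoint = c("os", "ttr"),
                         rule = c("one_se", "min"),
                         n_folds = 10L,
                         min_group_fraction = 0.10,
                         entry_p = 0.05,
                         ties = "breslow",
                         horizons_months = c(36, 60),
                         calibration_B = 50L,
                         compare_B = 200L,
                         icc_n_images = 60L,
                         n_levels = 32L,
                         stages = "all",
                         seed = 1L,
                         out_dir = NULL) {
  score_endpoint <- match.arg(score_endpoint)
  rule <- match.arg(rule)
  if (identical(stages, "all")) {
    stages <- c("survival", "nomogram", "calibration", "compare", "icc")
  }
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  stage <- "setup"
  result <- list()
  tryCatch({
    stage <- "cohort"
    if (is.null(cohort)) cohort <- generate_cohort(sim_config)
    stopifnot(inherits(cohort, "synthetic_cohort"))
    cl <- cohort$clinical
    train <- cl$split == "train"
    say("cohort: %d patients (%d train / %d validation)",
        nrow(cl), sum(train), sum(!train))

    stage <- "extract"
    catalog <- feature_catalog(n_levels)
    if (is.null(cohort$images)) stop_input("cohort carries no images")
    feats <- extract_feature_table(cohort$images, catalog)
    stopifnot(identical(feats$patient_id, cl$patient_id))
    X <- as.matrix(feats[, catalog$name])
    say("extracted %d features for %d lesions", ncol(X), nrow(X))

    stage <- "fit-score"
    tm <- cl[[paste0(score_endpoint, "_months")]]
    ev <- cl[[paste0(score_endpoint, "_event")]]
    y <- make_five_year_label(tm, ev)
    y_train <- ifelse(train, y, NA)     # training rows only enter the fit
    say("five-year %s labels (training): %d events, %d event-free, %d excluded",
        score_endpoint, sum(y_train == 1, na.rm = TRUE),
        sum(y_train == 0, na.rm = TRUE), sum(train & is.na(y)))
    model <- fit_radscore(X, y_train, rule = rule, n_folds = n_folds,
                          seed = seed)
    cl$rad_score <- compute_rad_score(model, X)
    say("lasso kept %d features at lambda = %.5g (%s rule)",
        model$n_nonzero, model$lambda, model$rule)

    stage <- "cutpoint"
    cut <- find_cutpoint(cl$rad_score[train], tm[train], ev[train],
                         min_group_fraction = min_group_fraction)
    cl$rad_group <- factor(ifelse(cl$rad_score <= cut$cutoff, "low", "high"),
                           levels = c("high", "low"))
    say("training cutpoint %.4g (chi-square %.2f); low group carries the risk",
        cut$cutoff, cut$statistic)

    provenance <- list(
      train_ids = cl$patient_id[train],
      frozen = list(lambda = model$lambda,
                    standardization = model$standardization,
                    cutoff = cut$cutoff),
      seed = as.integer(seed))

    result <- list(clinical = cl, model = model, cutpoint = cut,
                   catalog = catalog, features = feats,
                   provenance = provenance,
                   score_endpoint = score_endpoint)

    splits <- list(train = train, validation = !train)
    endpoints <- c("ttr", "os")

    if ("survival" %in% stages) {
      stage <- "survival"
      km <- list()
      lr <- list()
      cox <- list()
      covars <- c("tumor_size_class", "vascular_invasion", "encapsulation",
                  "GGT", "AFP")
      for (ep in endpoints) {
        t_ep <- cl[[paste0(ep, "_months")]]
        e_ep <- cl[[paste0(ep, "_event")]]
        for (sp in names(splits)) {
          sel <- splits[[sp]]
          for (g in levels(cl$rad_group)) {
            gi <- sel & cl$rad_group == g
            km[[paste(ep, sp, g, sep = ".")]] <-
              km_estimate(t_ep[gi], e_ep[gi])
          }
          lr[[paste(ep, sp, sep = ".")]] <-
            log_rank_test(t_ep[sel], e_ep[sel], cl$rad_group[sel])
        }
        cdat <- cl[, covars]
        cdat$rad_low <- as.integer(cl$rad_group == "low")
        cox[[ep]] <- cox_screen(t_ep[train], e_ep[train],
                                cdat[train, , drop = FALSE],
                                entry_p = entry_p, ties = ties)
        say("%s: %d covariates entered the multivariate model", ep,
            length(cox[[ep]]$entered))
      }
      result$km <- km
      result$logrank <- lr
      result$cox <- cox
    }

    if ("nomogram" %in% stages && !is.null(result$cox)) {
      stage <- "nomogram"
      noms <- list()
      for (ep in endpoints) {
        fit <- result$cox[[ep]]$multivariate
        if (is.null(fit)) next
        vr <- lapply(names(fit$coefficients), function(v) {
          range(if (v == "rad_low") c(0, 1) else cl[[v]][train])
        })
        names(vr) <- names(fit$coefficients)
        noms[[ep]] <- build_nomogram(fit, vr, horizons_months)
      }
      result$nomogram <- noms
    }

    if ("calibration" %in% stages && !is.null(result$cox)) {
      stage <- "calibration"
      calib <- list()
      for (ep in endpoints) {
        fit <- result$cox[[ep]]$multivariate
        if (is.null(fit)) next
        vars <- names(fit$coefficients)
        cdat <- cl[, setdiff(vars, "rad_low"), drop = FALSE]
        if ("rad_low" %in% vars) {
          cdat$rad_low <- as.integer(cl$rad_group == "low")
        }
        for (sp in names(splits)) {
          sel <- splits[[sp]]
          for (h in horizons_months) {
            calib[[paste(ep, sp, h, sep = ".")]] <- bootstrap_calibration(
              cl[[paste0(ep, "_months")]][sel],
              cl[[paste0(ep, "_event")]][sel],
              cdat[sel, , drop = FALSE], h, B = calibration_B,
              seed = seed, ties = ties)
          }
        }
      }
      result$calibration <- calib
    }

    if ("compare" %in% stages && !is.null(result$cox)) {
      stage <- "compare"
      comp <- list()
      for (ep in endpoints) {
        fit <- result$cox[[ep]]$multivariate
        # clinicopathological-only counterpart, fitted on training data
        clin_vars <- setdiff(result$cox[[ep]]$entered, "rad_low")
        clin_fit <- if (length(clin_vars)) {
          cox_fit(cl[[paste0(ep, "_months")]][train],
                  cl[[paste0(ep, "_event")]][train],
                  cl[train, clin_vars, drop = FALSE], ties = ties)
        }
        for (sp in names(splits)) {
          sel <- splits[[sp]]
          preds <- list(rad_score = -cl$rad_score[sel])  # low score = risk
          if (!is.null(fit)) {
            vars <- names(fit$coefficients)
            cdat <- cl[, setdiff(vars, "rad_low"), drop = FALSE]
            if ("rad_low" %in% vars) {
              cdat$rad_low <- as.integer(cl$rad_group == "low")
            }
            lp <- as.matrix(cdat[sel, vars, drop = FALSE]) %*%
              fit$coefficients
            preds$nomogram <- drop(lp)
          }
          if (!is.null(clin_fit)) {
            preds$clinical_nomogram <- drop(
              as.matrix(cl[sel, clin_vars, drop = FALSE]) %*%
                clin_fit$coefficients)
          }
          for (st in c("TNM", "BCLC", "JIS", "HKLC")) {
            preds[[st]] <- cl[[st]][sel]
          }
          comp[[paste(ep, sp, sep = ".")]] <- compare_models(
            preds, cl[[paste0(ep, "_months")]][sel],
            cl[[paste0(ep, "_event")]][sel], B = compare_B, seed = seed)
        }
      }
      result$model_comparison <- comp
    }

    if ("icc" %in% stages) {
      stage <- "icc"
      tr_ids <- cl$patient_id[train]
      pick <- with_seed(seed + 1L, {
        sample(tr_ids, min(icc_n_images, length(tr_ids)))
      })
      rr <- perturbed_rereads(cohort$images[pick], radius = 1L,
                              boundary_prob = 0.2, catalog = catalog,
                              seed = seed + 2L)
      result$icc <- icc_feature_table(rr$original, rr$perturbed)
      say("icc: median ICC %.3f over %d features on %d images",
          stats::median(result$icc$icc), nrow(result$icc), length(pick))
    }
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result$log <- log
  result$seed <- as.integer(seed)
  class(result) <- "radsurv_run"
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' @export
print.radsurv_run <- function(x, ...) {
  cat("<radsurv_run>\n")
  for (l in x$log) cat(" -", l, "\n")
  if (!is.null(x$logrank)) {
    for (nm in names(x$logrank)) {
      cat(sprintf("  log-rank %s: chi-square %.2f, p = %.3g\n", nm,
                  x$logrank[[nm]]$chi_square, x$logrank[[nm]]$p))
    }
  }
  invisible(x)
}

# Persist the run: CSV tables, JSON model, run metadata with config hash.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$clinical, file.path(out_dir, "clinical_scored.csv"),
                   row.names = FALSE)
  write_feature_table(run$features, file.path(out_dir, "features.csv"),
                      run$catalog)
  write_radscore_model(run$model, file.path(out_dir, "radscore_model.json"))
  utils::write.csv(run$cutpoint$scan, file.path(out_dir, "cutpoint_scan.csv"),
                   row.names = FALSE)
  if (!is.null(run$cox)) {
    for (ep in names(run$cox)) {
      utils::write.csv(run$cox[[ep]]$univariate,
                       file.path(out_dir, paste0("cox_univariate_", ep, ".csv")),
                       row.names = FALSE)
      if (!is.null(run$cox[[ep]]$multivariate)) {
        utils::write.csv(run$cox[[ep]]$multivariate$table,
                         file.path(out_dir, paste0("cox_multivariate_", ep, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(run$model_comparison)) {
    comp <- do.call(rbind, lapply(names(run$model_comparison), function(nm) {
      cbind(setting = nm, run$model_comparison[[nm]])
    }))
    utils::write.csv(comp, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$icc)) {
    utils::write.csv(run$icc, file.path(out_dir, "icc.csv"),
                     row.names = FALSE)
  }
  info <- list(seed = run$seed,
               config_hash = config_hash(run$provenance$frozen),
               train_n = length(run$provenance$train_ids),
               log = run$log)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Small deterministic hash (djb2 over the deparsed object) for run metadata.
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
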