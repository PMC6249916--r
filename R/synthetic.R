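#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the simulator emulates: a cohort of
#' patients, each carrying one tumor slice whose texture class is
#' statistically linked to censored recurrence (TTR) and survival (OS)
#' times, with clinical covariates correlated to the same latent class.
#' Defaults mirror a 319-patient solitary-HCC resection cohort split
#' 212/107 into training and validation.
#'
#' @param n_patients Cohort size (default 319).
#' @param train_fraction Proportion assigned to the training split
#'   (default 212/319, giving a 212/107 split at the default size).
#' @param seed Integer seed; identical configurations generate bitwise
#'   identical cohorts.
#' @param image_size Pixels per side of the square slice (default 64).
#' @param class_probs Marginal probabilities of the latent aggressiveness
#'   classes (default two equiprobable classes). Class indices count up
#'   from 1 = indolent; higher classes are more aggressive.
#' @param texture_params Per-class list of `corr_len` (spatial correlation
#'   length of the intensity field, pixels), `noise_var` (marginal variance
#'   of the textured component) and `mean` (mean in-mask intensity).
#' @param survival_params List with elements `ttr` and `os`, each a list of
#'   `shape` (Weibull shape, shared) and `scale` (per-class Weibull scale,
#'   months).
#' @param texture_jitter Per-patient heterogeneity of the texture
#'   parameters around their class values: `mean_sd` (additive, intensity
#'   units), `log_noise_sd` and `log_corr_sd` (multiplicative, log scale).
#'   Real lesions vary continuously within a phenotype; zero everywhere
#'   makes all lesions of a class statistically identical.
#' @param censor_rate Target probability that a subject is censored rather
#'   than observed to fail, in `[0, 1)`; censoring times are uniform on
#'   `[0, t_max]` with `t_max` solved per class to hit this rate.
#' @param covariate_assoc Named list of per-covariate log-odds (binary) or
#'   log-scale mean (continuous) shifts per unit increase of latent class;
#'   zero everywhere makes covariates independent of class.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 319L,
                              train_fraction = 212 / 319,
                              seed = 1L,
                              image_size = 64L,
                              class_probs = c(0.5, 0.5),
                              texture_params = list(
                                list(corr_len = 1, noise_var = 1, mean = 100),
                                list(corr_len = 5, noise_var = 1, mean = 110)),
                              texture_jitter = list(mean_sd = 3,
                                                    log_noise_sd = 0.5,
                                                    log_corr_sd = 0.3),
                              survival_params = list(
                                ttr = list(shape = 1.1, scale = c(90, 45)),
                                os = list(shape = 1.3, scale = c(130, 65))),
                              censor_rate = 0.3,
                              covariate_assoc = list(
                                tumor_size_class = 1.0,
                                vascular_invasion = 1.2,
                                encapsulation = -0.8,
                                GGT = 0.4,
                                AFP = 1.0,
                                TNM = 0.8, BCLC = 0.8, JIS = 0.6, HKLC = 0.6)) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop_input("'n_patients' must be positive")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_input("'train_fraction' must lie in (0, 1)")
  }
  if (as.integer(image_size) < 16L) stop_input("'image_size' must be >= 16")
  n_classes <- length(class_probs)
  if (length(texture_params) != n_classes) {
    stop_input("one texture_params entry required per class")
  }
  for (tp in texture_params) {
    if (tp$corr_len < 0 || tp$noise_var < 0) {
      stop_input("correlation length and noise variance must be >= 0")
    }
  }
  for (ep in survival_params) {
    if (ep$shape <= 0) stop_input("Weibull shape must be > 0")
    if (length(ep$scale) != n_classes || any(ep$scale <= 0)) {
      stop_input("one positive Weibull scale required per class")
    }
  }
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stop_input("'censor_rate' must lie in [0, 1)")
  }
  structure(list(n_patients = n_patients, train_fraction = train_fraction,
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 n_classes = n_classes, class_probs = class_probs / sum(class_probs),
                 texture_params = texture_params,
                 texture_jitter = texture_jitter,
                 survival_params = survival_params,
                 censor_rate = censor_rate, covariate_assoc = covariate_assoc),
            class = "sim_config")
}

# Moving-average smoothing of a white-noise field: square kernel of
# half-width L, rescaled afterwards so the marginal variance is preserved.
smooth_field <- function(z, corr_len) {
  L <- as.integer(round(corr_len))
  if (L <= 0L) return(z)
  k <- rep(1, 2L * L + 1L)
  pad <- function(m, n) {
    top <- m[rep(1L, n), , drop = FALSE]
    bot <- m[rep(nrow(m), n), , drop = FALSE]
    m <- rbind(top, m, bot)
    left <- m[, rep(1L, n), drop = FALSE]
    right <- m[, rep(ncol(m), n), drop = FALSE]
    cbind(left, m, right)
  }
  zp <- pad(z, L)
  zs <- apply(zp, 2, function(col) stats::filter(col, k / length(k), sides = 2))
  zs <- t(apply(zs, 1, function(rw) stats::filter(rw, k / length(k), sides = 2)))
  out <- zs[(L + 1):(L + nrow(z)), (L + 1):(L + ncol(z)), drop = FALSE]
  s <- stats::sd(as.vector(out))
  if (s > 0) out <- out / s
  out
}

#' Generate one textured tumor slice
#'
#' Draws an elliptical tumor mask (jittered radii, covering at least 10%
#' of the slice) and fills the image with a smoothed Gaussian random
#' field: class parameters set the mean intensity, the spatial correlation
#' length of the field and its marginal variance, so texture features
#' separate classes in expectation. Intended as a stand-in for an
#' arterial-phase CT slice.
#'
#' @param class_params List with `corr_len`, `noise_var`, `mean`.
#' @param image_size Pixels per side (>= 16).
#' @param id Lesion identifier.
#' @return A [roi_image]. Uses the current RNG state; seed externally (or
#'   via [generate_cohort()]) for reproducibility.
#' @export
generate_texture_image <- function(class_params, image_size = 64L, id = "sim") {
  image_size <- as.integer(image_size)
  if (image_size < 16L) stop_input("'image_size' must be >= 16")
  if (class_params$corr_len < 0) stop_input("correlation length must be >= 0")
  n <- image_size
  z <- matrix(stats::rnorm(n * n), n, n)
  fld <- smooth_field(z, class_params$corr_len) * sqrt(class_params$noise_var)
  px <- class_params$mean + fld
  # elliptical mask: jittered radii, guaranteed >= 10% coverage
  cx <- n / 2 + stats::runif(1, -n / 16, n / 16)
  cy <- n / 2 + stats::runif(1, -n / 16, n / 16)
  rx <- n * stats::runif(1, 0.22, 0.42)
  ry <- n * stats::runif(1, 0.22, 0.42)
  xs <- matrix(seq_len(n), n, n)
  ys <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  if (mean(mask) < 0.10) {            # numerically impossible at these radii,
    mask <- ((xs - n / 2) / (0.35 * n))^2 +   # but keep the contract explicit
      ((ys - n / 2) / (0.35 * n))^2 <= 1
  }
  # surrounding parenchyma: modestly darker than the lesion (1.5 noise
  # SDs, a visible but realistic soft-tissue contrast), matched noise
  s <- sqrt(max(class_params$noise_var, 1e-12))
  px[!mask] <- class_params$mean - 1.5 * s +
    stats::rnorm(sum(!mask), sd = s)
  roi_image(px, mask, id = id)
}

# Solve the uniform-censoring horizon t_max so that P(censored) equals
# censor_rate when event times are Weibull(shape, scale):
#   P(C < T) = (1/t_max) * integral_0^t_max S(t) dt
censor_horizon <- function(shape, scale, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  pc <- function(tmax) {
    stats::integrate(function(t) exp(-(t / scale)^shape), 0, tmax,
                     rel.tol = 1e-9)$value / tmax - censor_rate
  }
  upper <- scale
  while (pc(upper) > 0) upper <- upper * 2   # pc decreases with tmax
  stats::uniroot(pc, c(1e-6, upper), tol = 1e-8)$root
}

#' Simulate censored event times for latent classes
#'
#' Event times are Weibull with class-specific scale; independent
#' censoring times are uniform on `[0, t_max]` with `t_max` chosen per
#' class so the expected censoring probability equals `censor_rate`.
#' The observed time is the minimum, with an event indicator.
#'
#' @param latent_class Integer vector of class indices (1-based).
#' @param params List with `shape` (scalar) and `scale` (per-class vector).
#' @param censor_rate Censoring probability in `[0, 1)`; 0 disables
#'   censoring.
#' @return Data frame with columns `time` (months) and `event` (0/1).
#'   Uses the current RNG state.
#' @export
simulate_survival <- function(latent_class, params, censor_rate = 0) {
  k <- length(params$scale)
  latent_class <- as.integer(latent_class)
  if (any(latent_class < 1L | latent_class > k)) {
    stop_input("unknown latent class: no Weibull scale configured for it")
  }
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stop_input("'censor_rate' must lie in [0, 1)")
  }
  n <- length(latent_class)
  t_event <- stats::rweibull(n, shape = params$shape,
                             scale = params$scale[latent_class])
  if (censor_rate == 0) {
    return(data.frame(time = t_event, event = rep(1L, n)))
  }
  tmax <- vapply(seq_len(k), function(cl) {
    censor_horizon(params$shape, params$scale[cl], censor_rate)
  }, numeric(1))
  t_cens <- stats::runif(n, 0, tmax[latent_class])
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

# Class-conditional covariates; `assoc` entries are per-class-step shifts.
draw_covariates <- function(cls, assoc) {
  n <- length(cls)
  d <- cls - 1L                    # 0 for the indolent reference class
  bin <- function(base_logit, name) {
    shift <- assoc[[name]] %||% 0
    stats::rbinom(n, 1L, stats::plogis(base_logit + shift * d))
  }
  ord <- function(name, k = 4L) {
    # latent continuous stage propensity, cut into k ordinal grades
    shift <- assoc[[name]] %||% 0
    z <- stats::rnorm(n, mean = shift * d)
    cut_pts <- stats::qnorm(c(0.45, 0.75, 0.92), mean = mean(shift) * 0.5)
    1L + findInterval(z, cut_pts)
  }
  data.frame(
    tumor_size_class = bin(0.3, "tumor_size_class"),     # > 3 cm
    vascular_invasion = bin(-2.5, "vascular_invasion"),
    encapsulation = bin(0.2, "encapsulation"),
    GGT = exp(stats::rnorm(n, 4.0 + (assoc$GGT %||% 0) * d, 0.8)),
    AFP = exp(stats::rnorm(n, 5.5 + (assoc$AFP %||% 0) * d, 2.0)),
    TNM = ord("TNM"), BCLC = ord("BCLC"), JIS = ord("JIS"), HKLC = ord("HKLC"))
}

#' Generate a synthetic cohort
#'
#' Draws latent aggressiveness classes, one textured slice per patient,
#' class-linked clinical covariates, censored TTR and OS times, and a
#' random train/validation split. Identical configurations produce
#' identical cohorts.
#'
#' @param config A [simulation_config()].
#' @param with_images Set `FALSE` to skip image synthesis (covariates and
#'   outcomes only), e.g. for large purely statistical simulations.
#' @return An object of class `synthetic_cohort`: `clinical` (data frame
#'   with patient_id, split, latent_class, covariates, `ttr_months`,
#'   `ttr_event`, `os_months`, `os_event`), `images` (named list of
#'   [roi_image], or `NULL`), and `config`.
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 20, image_size = 16))
#' table(coh$clinical$split)
#' @export
generate_cohort <- function(config, with_images = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    cls <- sample.int(config$n_classes, n, replace = TRUE,
                      prob = config$class_probs)
    covs <- draw_covariates(cls, config$covariate_assoc)
    ttr <- simulate_survival(cls, config$survival_params$ttr,
                             config$censor_rate)
    os <- simulate_survival(cls, config$survival_params$os,
                            config$censor_rate)
    # recurrence cannot be observed after death: truncate TTR at OS time
    later <- ttr$time > os$time
    ttr$time[later] <- os$time[later]
    ttr$event[later] <- 0L
    n_train <- round(n * config$train_fraction)
    split <- rep("validation", n)
    split[sample.int(n, n_train)] <- "train"
    images <- NULL
    if (with_images) {
      jt <- config$texture_jitter %||%
        list(mean_sd = 0, log_noise_sd = 0, log_corr_sd = 0)
      images <- lapply(seq_len(n), function(i) {
        tp <- config$texture_params[[cls[i]]]
        tp$mean <- tp$mean + stats::rnorm(1, sd = jt$mean_sd)
        tp$noise_var <- tp$noise_var * exp(stats::rnorm(1, sd = jt$log_noise_sd))
        tp$corr_len <- tp$corr_len * exp(stats::rnorm(1, sd = jt$log_corr_sd))
        generate_texture_image(tp, config$image_size, id = ids[i])
      })
      names(images) <- ids
    }
    clinical <- cbind(
      data.frame(patient_id = ids, split = split, latent_class = cls,
                 stringsAsFactors = FALSE),
      covs,
      data.frame(ttr_months = ttr$time, ttr_event = ttr$event,
                 os_months = os$time, os_event = os$event))
    structure(list(clinical = clinical, images = images, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cl <- x$clinical
  cat(sprintf("<synthetic_cohort> %d patients (%d train / %d validation)%s\n",
              nrow(cl), sum(cl$split == "train"),
              sum(cl$split == "validation"),
              if (is.null(x$images)) ", no images" else ""))
  cat(sprintf("  events: TTR %d, OS %d; seed %d\n",
              sum(cl$ttr_event), sum(cl$os_event), x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes the clinical table as CSV, each image (min-max normalized) and
#' mask as grayscale PNG under `images/` and `masks/`, and the
#' configuration as a YAML file. PNG export quantizes intensities; use the
#' in-memory images or NIfTI for lossless round trips.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$images)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop_input("writing image fixtures requires the 'png' package")
    }
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (id in names(cohort$images)) {
      im <- cohort$images[[id]]
      px <- im$pixels
      px <- (px - min(px)) / max(max(px) - min(px), .Machine$double.eps)
      png::writePNG(px, file.path(dir, "images", paste0(id, ".png")))
      png::writePNG(im$mask * 1, file.path(dir, "masks", paste0(id, ".png")))
    }
  }
  cfg <- cohort$config
  cfg_list <- unclass(cfg)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  } else {
    dput(cfg_list, file.path(dir, "config.R"))
  }
  invisible(dir)
}
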