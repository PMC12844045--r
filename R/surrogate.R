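#' Surrogate training configuration
#'
#' Architectures and optimization protocol for the two feed-forward
#' surrogates: a three-hidden-layer network (1024, 512, 64 neurons) for the
#' oxygen-transfer label and a two-hidden-layer network (64, 16 neurons) for
#' the hemolysis label, both trained with AdamW (learning rate 1e-4, weight
#' decay 0.01) to minimize mean squared error with early stopping, on a
#' 70/15/15 train/validation/test partition.
#'
#' @param otr_hidden Hidden-layer widths of the oxygen-transfer net.
#' @param hem_hidden Hidden-layer widths of the hemolysis net.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param split Train/validation/test fractions (must sum to 1).
#' @param otr_max_epochs,hem_max_epochs Epoch caps per net (the wide net costs
#'   far more per epoch, so the caps differ).
#' @param otr_patience,hem_patience Early-stopping patience per net (epochs
#'   without validation improvement).
#' @param batch_size Minibatch size.
#' @param seed Seed for weight init and shuffling.
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(otr_hidden = c(1024, 512, 64),
                             hem_hidden = c(64, 16),
                             lr = 1e-4, weight_decay = 0.01,
                             split = c(0.70, 0.15, 0.15),
                             otr_max_epochs = 18, hem_max_epochs = 400,
                             otr_patience = 4, hem_patience = 30,
                             batch_size = 128, seed = 42L) {
  if (abs(sum(split) - 1) > 1e-9 || length(split) != 3L || any(split < 0)) {
    abort("`split` must be three non-negative fractions summing to 1.")
  }
  if (any(c(otr_hidden, hem_hidden) <= 0)) abort("Layer widths must be positive.")
  structure(list(otr_hidden = as.integer(otr_hidden),
                 hem_hidden = as.integer(hem_hidden),
                 lr = lr, weight_decay = weight_decay, split = split,
                 otr_max_epochs = otr_max_epochs,
                 hem_max_epochs = hem_max_epochs,
                 otr_patience = otr_patience, hem_patience = hem_patience,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "surrogate_config")
}

#' Sample waveform specifications for the surrogate corpus
#'
#' Draws a reproducible set of family/parameter specifications covering the
#' five waveform families. Target means are sampled within a range chosen so
#' every normalized profile stays strictly positive and inside the pump's
#' operating and slew limits at the corpus grid spacing.
#'
#' @param n_profiles Number of waveforms.
#' @param seed Seed; the per-profile generator seeds are derived from it.
#' @param families Families to draw from.
#' @param target_mean_range Range of period-average flows (L/min).
#' @param period Pulsation period (s).
#' @return A tibble with columns `profile_id`, `family`, `target_mean`,
#'   `period`, `seed`.
#' @export
sample_waveform_specs <- function(n_profiles = 2000, seed = 42L,
                                  families = c("hspp", "sine",
                                               "pulmonary_artery",
                                               "composite_gaussian",
                                               "gaussian_exponential"),
                                  target_mean_range = c(0.6, 1.3),
                                  period = 0.8) {
  withr::with_seed(seed, {
    tibble::tibble(
      profile_id = seq_len(n_profiles),
      family = sample(families, n_profiles, replace = TRUE),
      target_mean = runif(n_profiles, target_mean_range[1],
                          target_mean_range[2]),
      period = period,
      seed = sample.int(.Machine$integer.max - 1L, n_profiles))
  })
}

#' Build a labelled feature/label dataset from waveform specs
#'
#' Generates each waveform, discretizes it at `dt`, computes the feature
#' series (flow, first and second derivative, curvature) and oracle labels at
#' each time point, and collects everything with a provenance manifest. One
#' sample corresponds to one time point of one profile.
#'
#' @param specs A tibble from [sample_waveform_specs()] (columns `profile_id`,
#'   `family`, `target_mean`, `period`, `seed`).
#' @param op,hp Oracle and hemolysis parameter objects.
#' @param dt Corpus sample interval (s); 0.01 s by default.
#' @param limits Pump limits; generator infeasibility propagates as an error.
#' @return A list of class `pulse_dataset` with elements `data` (tibble:
#'   `profile_id`, `time_s`, `q`, `dq`, `d2q`, `kappa`, `y_otr`, `y_hem`),
#'   `manifest` (per-profile provenance incl. realized parameters as JSON),
#'   and `params`.
#' @export
build_dataset <- function(specs, op = oracle_params(), hp = hemolysis_params(),
                          dt = 0.01, limits = pump_limits()) {
  if (nrow(specs) == 0L) abort("`specs` must be non-empty.")
  rows <- purrr::pmap(specs, function(profile_id, family, target_mean, period,
                                      seed, ...) {
    ws <- waveform_spec(family, target_mean = target_mean, period = period)
    prof <- generate_waveform(ws, seed = seed, dt = dt, limits = limits)
    feats <- compute_features(prof)
    labs <- oracle_labels(prof, op, hp, limits)
    list(
      data = dplyr::mutate(feats, profile_id = profile_id,
                           y_otr = labs$labels$otr_inst,
                           y_hem = labs$labels$hem_inst,
                           .before = 1),
      manifest = tibble::tibble(
        profile_id = profile_id, family = family, target_mean = target_mean,
        period = period, seed = seed, dt = dt, n_steps = nrow(feats),
        otr_episode = labs$otr_episode, hem_episode = labs$hem_episode,
        params_json = as.character(jsonlite::toJSON(attr(prof, "params"),
                                                    auto_unbox = TRUE,
                                                    digits = NA))))
  })
  structure(list(
    data = dplyr::bind_rows(purrr::map(rows, "data")),
    manifest = dplyr::bind_rows(purrr::map(rows, "manifest")),
    params = list(oracle = unclass(op), hemolysis = unclass(hp), dt = dt)),
    class = "pulse_dataset")
}

#' @export
print.pulse_dataset <- function(x, ...) {
  cat(sprintf("<pulse_dataset: %d profiles, %d samples%s>\n",
              nrow(x$manifest), nrow(x$data),
              if ("split" %in% names(x$manifest)) ", split assigned" else ""))
  invisible(x)
}

#' Assign train/validation/test splits by profile
#'
#' Splitting is by whole profile, not by time point, so held-out waveform
#' shapes are genuinely unseen (time-point splits would leak near-duplicate
#' neighbours into the test set). Split sizes are within one profile of the
#' exact ratios; assignment is reproducible from the seed.
#'
#' @param ds A `pulse_dataset`.
#' @param ratios Train/validation/test fractions summing to 1, all positive.
#' @param seed Seed for the assignment permutation.
#' @return The dataset with a `split` column (`"train"`, `"val"`, `"test"`)
#'   on both `data` and `manifest`.
#' @export
split_dataset <- function(ds, ratios = c(0.70, 0.15, 0.15), seed = 42L) {
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    abort("`ratios` must be three positive fractions summing to 1.")
  }
  n <- nrow(ds$manifest)
  if (n < 3L) abort("Need at least 3 profiles to split.")
  counts <- floor(n * ratios)
  # hand out the remainder by largest fractional part (ties: earlier split)
  frac <- n * ratios - counts
  for (k in order(frac, decreasing = TRUE)[seq_len(n - sum(counts))]) {
    counts[k] <- counts[k] + 1L
  }
  lab <- rep(c("train", "val", "test"), times = counts)
  perm <- withr::with_seed(seed, sample.int(n))
  assignment <- tibble::tibble(profile_id = ds$manifest$profile_id[perm],
                               split = lab)
  ds$manifest <- dplyr::left_join(ds$manifest, assignment, by = "profile_id")
  ds$data <- dplyr::left_join(ds$data, assignment, by = "profile_id")
  ds
}

feature_matrix <- function(data) {
  as.matrix(data[, c("q", "dq", "d2q", "kappa")])
}

he_init <- function(widths, seed) {
  # widths: c(n_in, hidden..., 1)
  withr::with_seed(seed, {
    W <- list()
    b <- list()
    for (l in seq_len(length(widths) - 1L)) {
      fan_in <- widths[l]
      W[[l]] <- matrix(rnorm(fan_in * widths[l + 1], sd = sqrt(2 / fan_in)),
                       nrow = fan_in)
      b[[l]] <- matrix(0, nrow = 1, ncol = widths[l + 1])
    }
    list(W = W, b = b)
  })
}

#' Train a surrogate network on an oracle-labelled dataset
#'
#' Fits the configured fully-connected network to one of the two labels.
#' Features are z-scored on the training split; the oxygen-transfer label is
#' z-scored, while the hemolysis label — a power law spanning several orders
#' of magnitude — is log-transformed before z-scoring so the mean-squared
#' error objective weights all magnitudes evenly. Training stops when the
#' validation loss fails to improve for `patience` epochs and the best
#' weights are restored.
#'
#' @param ds A split `pulse_dataset` (see [split_dataset()]).
#' @param cfg A [surrogate_config()].
#' @param target `"otr"` or `"hem"`.
#' @return A `pulse_surrogate` object with the weights, normalization
#'   statistics, training log, and the training-feature percentile box used
#'   for the out-of-distribution guard.
#' @export
train_surrogate <- function(ds, cfg = surrogate_config(),
                            target = c("otr", "hem")) {
  target <- match.arg(target)
  if (!"split" %in% names(ds$data)) abort("Dataset has no split; call split_dataset() first.")
  hidden <- if (target == "otr") cfg$otr_hidden else cfg$hem_hidden
  max_epochs <- if (target == "otr") cfg$otr_max_epochs else cfg$hem_max_epochs
  patience <- if (target == "otr") cfg$otr_patience else cfg$hem_patience
  ycol <- if (target == "otr") "y_otr" else "y_hem"

  tr <- ds$data[ds$data$split == "train", ]
  va <- ds$data[ds$data$split == "val", ]
  Xtr <- feature_matrix(tr)
  Xva <- feature_matrix(va)
  mu_x <- colMeans(Xtr)
  sd_x <- apply(Xtr, 2, sd)
  sd_x[sd_x < 1e-12] <- 1
  scale_x <- function(X) sweep(sweep(X, 2, mu_x), 2, sd_x, "/")

  transform <- if (target == "hem") "log" else "identity"
  fwd <- function(y) if (transform == "log") log(y + 1e-12) else y
  ytr_t <- fwd(tr[[ycol]])
  y_center <- mean(ytr_t)
  y_scale <- sd(ytr_t)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  zy <- function(y) (fwd(y) - y_center) / y_scale

  init <- he_init(c(4L, hidden, 1L), cfg$seed)
  fit <- mlp_fit_cpp(scale_x(Xtr), zy(tr[[ycol]]), scale_x(Xva),
                     zy(va[[ycol]]), init$W, init$b, cfg$lr, cfg$weight_decay,
                     max_epochs, patience, cfg$batch_size, cfg$seed)

  box <- apply(Xtr, 2, quantile, probs = c(0.005, 0.995), names = FALSE)
  structure(list(
    target = target, W = fit$W, b = fit$b, mu_x = mu_x, sd_x = sd_x,
    y_center = y_center, y_scale = y_scale, y_transform = transform,
    feature_box = box, cfg = cfg, best_epoch = fit$best_epoch,
    log = tibble::tibble(epoch = seq_along(fit$train_loss),
                         train_loss = fit$train_loss,
                         val_loss = fit$val_loss)),
    class = "pulse_surrogate")
}

#' @export
print.pulse_surrogate <- function(x, ...) {
  cat(sprintf(
    "<pulse_surrogate [%s]: layers %s, best epoch %d, val loss %.3g>\n",
    x$target, paste(vapply(x$W, nrow, 1L), collapse = "-"), x$best_epoch,
    min(x$log$val_loss)))
  invisible(x)
}

#' Predict oracle labels with a trained surrogate
#'
#' Inputs outside the 0.5–99.5 percentile box of the training features are
#' flagged as out-of-distribution (`.ood`) and a warning is raised: the
#' control loop can drive the surrogate off the corpus it was fitted on, and
#' flagged extrapolations should not be trusted silently.
#'
#' @param object A `pulse_surrogate`.
#' @param new_data A data frame with columns `q`, `dq`, `d2q`, `kappa` (e.g.
#'   from [compute_features()]), or a 4-column matrix.
#' @param ... Unused.
#' @return A tibble with columns `.pred` (label units) and `.ood` (logical).
#' @export
predict.pulse_surrogate <- function(object, new_data, ...) {
  X <- if (is.matrix(new_data)) new_data else feature_matrix(new_data)
  Xs <- sweep(sweep(X, 2, object$mu_x), 2, object$sd_x, "/")
  z <- mlp_forward_cpp(Xs, object$W, object$b)
  y <- z * object$y_scale + object$y_center
  if (object$y_transform == "log") y <- exp(y) - 1e-12
  ood <- rowSums(t(t(X) < object$feature_box[1, ]) |
                   t(t(X) > object$feature_box[2, ])) > 0
  if (any(ood)) {
    warn(sprintf("%d of %d inputs are outside the training feature range.",
                 sum(ood), length(ood)))
  }
  tibble::tibble(.pred = as.numeric(y), .ood = ood)
}

#' @export
tidy.pulse_surrogate <- function(x, ...) x$log

#' @export
glance.pulse_surrogate <- function(x, ...) {
  tibble::tibble(target = x$target, best_epoch = x$best_epoch,
                 val_loss = min(x$log$val_loss), epochs_run = nrow(x$log))
}

#' @export
autoplot.pulse_surrogate <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "set",
                            values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "MSE (normalized labels)", colour = NULL)
}

#' Relative-error threshold accuracy
#'
#' For each threshold (in percent), the fraction of predictions whose
#' relative error `|pred - truth| / max(|truth|, eps_floor)` is within the
#' threshold — the metric used to report surrogate quality at 1–5% levels.
#'
#' @param pred,truth Numeric vectors of equal, positive length.
#' @param thresholds Thresholds in percent.
#' @param eps_floor Denominator floor; defaults to `1e-8 * max(abs(truth))`.
#' @return A tibble with columns `threshold_pct`, `accuracy`.
#' @export
#' @examples
#' threshold_accuracy(c(1, 1.05), c(1, 1), thresholds = 3)  # 0.5
threshold_accuracy <- function(pred, truth, thresholds = 1:5,
                               eps_floor = NULL) {
  if (length(pred) != length(truth)) abort("`pred` and `truth` lengths differ.")
  if (length(pred) == 0L) abort("Empty vectors.")
  eps_floor <- eps_floor %||% (1e-8 * max(abs(truth)))
  rel <- abs(pred - truth) / pmax(abs(truth), eps_floor)
  tibble::tibble(
    threshold_pct = thresholds,
    accuracy = vapply(thresholds, function(th) mean(rel <= th / 100), 0))
}

#' Evaluate a surrogate on the held-out test split
#'
#' @param model A `pulse_surrogate`.
#' @param ds The split `pulse_dataset` it was trained on.
#' @param thresholds Relative-error thresholds in percent.
#' @return A `threshold_accuracy` tibble for the test split.
#' @export
surrogate_test_accuracy <- function(model, ds, thresholds = 1:5) {
  te <- ds$data[ds$data$split == "test", ]
  ycol <- if (model$target == "otr") "y_otr" else "y_hem"
  pred <- suppressWarnings(predict(model, te)$.pred)
  threshold_accuracy(pred, te[[ycol]], thresholds)
}

#' Write / read a dataset as CSV + JSON manifest
#'
#' @param ds A `pulse_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a `pulse_dataset` (read).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(ds$data, file.path(dir, "samples.csv"))
  readr::write_csv(ds$manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(ds$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  structure(list(
    data = readr::read_csv(file.path(dir, "samples.csv"),
                           show_col_types = FALSE),
    manifest = readr::read_csv(file.path(dir, "manifest.csv"),
                               show_col_types = FALSE),
    params = jsonlite::read_json(file.path(dir, "params.json"),
                                 simplifyVector = TRUE)),
    class = "pulse_dataset")
}
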