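#' Configuration of the two-view NSA fusion network
#'
#' The fusion model is a fully connected network with 2 inputs (the
#' computer-vision AP and lateral NSAs), two hidden layers of 128 ReLU
#' units, and a sigmoid output trained against the clinician AP NSA. All
#' angles are affinely scaled from `[nsa_scale_min, nsa_scale_max]` degrees
#' to `[0, 1]`; the default loss is binary cross entropy on the scaled
#' target (a proper scoring rule for a `[0, 1]` target), with plain
#' squared error available as an alternative.
#'
#' @param hidden_layers number of hidden layers (the architecture is fixed
#'   at 2).
#' @param hidden_width neurons per hidden layer.
#' @param optimizer only `"adam"` is supported.
#' @param loss `"bce_on_scaled"` or `"mse"`.
#' @param nsa_scale_min,nsa_scale_max angle scaling range, degrees.
#' @param learning_rate Adam step size.
#' @param epochs full-batch training epochs.
#' @param train_fraction training share of the train/test split.
#' @param split_by `"patient"` (default; hips of one patient never straddle
#'   the split) or `"hip"`.
#' @param seed integer seed controlling the shuffle and weight
#'   initialization.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(hidden_layers = 2, hidden_width = 128,
                          optimizer = "adam",
                          loss = c("bce_on_scaled", "mse"),
                          nsa_scale_min = 90, nsa_scale_max = 180,
                          learning_rate = 1e-3, epochs = 500,
                          train_fraction = 0.8,
                          split_by = c("patient", "hip"), seed = 1L) {
  loss <- match.arg(loss)
  split_by <- match.arg(split_by)
  if (!identical(optimizer, "adam"))
    stop("only the Adam optimizer is supported", call. = FALSE)
  if (hidden_layers != 2)
    stop("the fusion architecture has exactly 2 hidden layers",
         call. = FALSE)
  if (hidden_width < 1 || epochs < 1 || learning_rate <= 0)
    stop("invalid width, epochs, or learning rate", call. = FALSE)
  if (nsa_scale_min >= nsa_scale_max)
    stop("nsa_scale_min must be < nsa_scale_max", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  structure(list(hidden_layers = 2L, hidden_width = as.integer(hidden_width),
                 optimizer = "adam", loss = loss,
                 nsa_scale_min = nsa_scale_min,
                 nsa_scale_max = nsa_scale_max,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 train_fraction = train_fraction, split_by = split_by,
                 seed = as.integer(seed)), class = "fusion_config")
}

#' Scale an NSA to the unit interval and back
#'
#' Affine map from `[nsa_scale_min, nsa_scale_max]` degrees onto `[0, 1]`;
#' the round trip is exact to floating precision.
#'
#' @param nsa angle(s) in degrees.
#' @param u value(s) in `[0, 1]`.
#' @param config a [fusion_config()].
#' @return Scaled value(s) / angle(s) in degrees.
#' @export
scale_nsa <- function(nsa, config = fusion_config()) {
  if (any(nsa < config$nsa_scale_min | nsa > config$nsa_scale_max))
    stop(sprintf("NSA outside the scale range [%g, %g]",
                 config$nsa_scale_min, config$nsa_scale_max), call. = FALSE)
  (nsa - config$nsa_scale_min) / (config$nsa_scale_max - config$nsa_scale_min)
}

#' @rdname scale_nsa
#' @export
unscale_nsa <- function(u, config = fusion_config()) {
  config$nsa_scale_min + u * (config$nsa_scale_max - config$nsa_scale_min)
}

.check_records <- function(records) {
  need <- c("hip_id", "nsa_ap_cv", "nsa_lateral_cv", "nsa_ap_clinician")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ang <- unlist(records[, c("nsa_ap_cv", "nsa_lateral_cv",
                            "nsa_ap_clinician")])
  if (any(!is.finite(ang)) || any(ang <= 0 | ang >= 180))
    stop("all NSA values must be finite and in (0, 180)", call. = FALSE)
  if (is.null(records$patient_id)) records$patient_id <- records$hip_id
  records
}

# shuffled train/test split; by patient, whole patients are added in
# shuffled order until the training side reaches floor(fraction * n) hips
.split_records <- function(records, fraction, by) {
  n <- nrow(records)
  target <- floor(fraction * n)
  if (by == "hip") {
    ord <- sample.int(n)
    train <- sort(ord[seq_len(target)])
  } else {
    pats <- sample(unique(records$patient_id))
    train <- integer(0)
    for (p in pats) {
      if (length(train) >= target) break
      train <- c(train, which(records$patient_id == p))
    }
    train <- sort(train)
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Train the AP/lateral NSA fusion network
#'
#' Shuffles and splits the records (by patient by default), scales the two
#' computer-vision NSA features and the clinician target to `[0, 1]`, and
#' trains the 2 x 128 ReLU network with full-batch Adam. Records with any
#' angle outside the scale range are excluded with a warning. Training is
#' reproducible for a fixed `config$seed`.
#'
#' @param records data frame with columns `hip_id`, `nsa_ap_cv`,
#'   `nsa_lateral_cv`, `nsa_ap_clinician`, and optionally `patient_id`.
#' @param config a [fusion_config()].
#' @return An object of class `nsa_fusion`: the trained weights, the
#'   config, the split (row indices `train` and `test` into the retained
#'   records), the retained `records`, any `excluded` records, and the
#'   per-epoch `loss_history`. Standard methods `print()`, `summary()`,
#'   `predict()`, and `coef()` apply.
#' @export
train_fusion <- function(records, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  records <- .check_records(records)
  if (nrow(records) < 5)
    stop("at least 5 records are required", call. = FALSE)
  in_range <- records$nsa_ap_cv >= config$nsa_scale_min &
    records$nsa_ap_cv <= config$nsa_scale_max &
    records$nsa_lateral_cv >= config$nsa_scale_min &
    records$nsa_lateral_cv <= config$nsa_scale_max &
    records$nsa_ap_clinician >= config$nsa_scale_min &
    records$nsa_ap_clinician <= config$nsa_scale_max
  excluded <- records[!in_range, , drop = FALSE]
  if (nrow(excluded) > 0)
    warning(sprintf("%d record(s) outside the NSA scale range excluded",
                    nrow(excluded)), call. = FALSE)
  records <- records[in_range, , drop = FALSE]
  rownames(records) <- NULL

  with_seed(config$seed, {
    split <- .split_records(records, config$train_fraction, config$split_by)
    if (length(split$train) < 2)
      stop("fewer than 2 training records", call. = FALSE)
    h <- config$hidden_width
    init <- list(
      W1 = matrix(stats::rnorm(2 * h, 0, sqrt(2 / 2)), 2, h),
      b1 = matrix(0, 1, h),
      W2 = matrix(stats::rnorm(h * h, 0, sqrt(2 / h)), h, h),
      b2 = matrix(0, 1, h),
      W3 = matrix(stats::rnorm(h, 0, sqrt(2 / h)), h, 1),
      b3 = 0)
    tr <- records[split$train, ]
    X <- cbind(scale_nsa(tr$nsa_ap_cv, config),
               scale_nsa(tr$nsa_lateral_cv, config))
    y <- scale_nsa(tr$nsa_ap_clinician, config)
    loss_code <- if (config$loss == "bce_on_scaled") "bce" else "mse"
    fit <- mlp_train_cpp(X, y, init, config$learning_rate, config$epochs,
                         loss_code)
    structure(list(weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3")],
                   loss_history = as.numeric(fit$loss_history),
                   config = config, split = split, records = records,
                   excluded = excluded), class = "nsa_fusion")
  })
}

.mlp_forward <- function(weights, X) {
  a1 <- pmax(sweep(X %*% weights$W1, 2, -as.numeric(weights$b1)), 0)
  a2 <- pmax(sweep(a1 %*% weights$W2, 2, -as.numeric(weights$b2)), 0)
  z <- drop(a2 %*% as.matrix(weights$W3)) + as.numeric(weights$b3)
  1 / (1 + exp(-z))
}

#' Predict corrected AP NSAs from a trained fusion model
#'
#' @param object an `nsa_fusion` model.
#' @param newdata data frame with columns `nsa_ap_cv` and `nsa_lateral_cv`;
#'   defaults to the model's held-out test records.
#' @param ... unused.
#' @return Numeric vector of corrected AP NSAs in degrees (bounded by the
#'   scale range through the sigmoid output).
#' @export
predict.nsa_fusion <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- object$records[object$split$test, , drop = FALSE]
  cfg <- object$config
  X <- cbind(scale_nsa(newdata$nsa_ap_cv, cfg),
             scale_nsa(newdata$nsa_lateral_cv, cfg))
  unscale_nsa(.mlp_forward(object$weights, X), cfg)
}

#' Corrected AP NSA for a single pair of view measurements
#'
#' @param model a trained `nsa_fusion` object.
#' @param nsa_ap_cv,nsa_lateral_cv computer-vision NSAs in degrees, inside
#'   the model's scale range.
#' @return Corrected AP NSA(s) in degrees.
#' @export
predict_fused <- function(model, nsa_ap_cv, nsa_lateral_cv) {
  if (!inherits(model, "nsa_fusion"))
    stop("`model` must be a trained nsa_fusion object", call. = FALSE)
  predict(model, data.frame(nsa_ap_cv = nsa_ap_cv,
                            nsa_lateral_cv = nsa_lateral_cv))
}

#' @export
print.nsa_fusion <- function(x, ...) {
  cat(sprintf(paste0("nsa_fusion: 2-%d-%d-1 network (%s loss), ",
                     "%d train / %d test records\n"),
              x$config$hidden_width, x$config$hidden_width, x$config$loss,
              length(x$split$train), length(x$split$test)))
  cat(sprintf("final training loss: %.6f\n",
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.nsa_fusion <- function(object, ...) {
  test <- object$records[object$split$test, , drop = FALSE]
  out <- list(model = object)
  if (nrow(test) >= 2) {
    fused <- predict(object)
    out$test_metrics <- agreement_metrics(fused, test$nsa_ap_clinician)
    out$baseline_metrics <- agreement_metrics(test$nsa_ap_cv,
                                              test$nsa_ap_clinician)
  }
  class(out) <- "summary.nsa_fusion"
  out
}

#' @export
print.summary.nsa_fusion <- function(x, ...) {
  print(x$model)
  if (!is.null(x$test_metrics)) {
    cat("held-out test fold, fused vs clinician:\n")
    print(x$test_metrics)
    cat("held-out test fold, raw AP CV vs clinician:\n")
    print(x$baseline_metrics)
  }
  invisible(x)
}

#' @export
coef.nsa_fusion <- function(object, ...) object$weights
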