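#' Pipeline configuration
#'
#' Collects every tunable of the NSA pipeline in one nested list:
#' `preprocess` ([filter_params()]), `detect` (template-matching scales,
#' raw-vs-normalized comparison, femur extent factor, prosthesis ROI
#' padding), `hough` ([hough_params()]), `fusion` ([fusion_config()]), and
#' the run `seed`.
#'
#' @param preprocess a [filter_params()].
#' @param detect list with `scales`, `normalize`, `extent_factor`,
#'   `roi_pad`, `roi_pad_bottom`.
#' @param hough a [hough_params()].
#' @param fusion a [fusion_config()].
#' @param seed integer run seed (drives the fusion split/initialization).
#' @return An object of class `nsa_config`.
#' @export
nsa_config <- function(preprocess = filter_params(),
                       detect = list(scales = c(0.8, 1, 1.25),
                                     normalize = FALSE,
                                     extent_factor = 2, roi_pad = 6,
                                     roi_pad_bottom = 2),
                       hough = hough_params(),
                       fusion = fusion_config(),
                       seed = 1L) {
  stopifnot(inherits(preprocess, "filter_params"),
            inherits(hough, "hough_params"),
            inherits(fusion, "fusion_config"))
  det_defaults <- list(scales = c(0.8, 1, 1.25), normalize = FALSE,
                       extent_factor = 2, roi_pad = 6, roi_pad_bottom = 2)
  detect <- utils::modifyList(det_defaults, detect)
  structure(list(preprocess = preprocess, detect = detect, hough = hough,
                 fusion = fusion, seed = as.integer(seed)),
            class = "nsa_config")
}

#' Read and write pipeline configuration files
#'
#' Configurations are stored as YAML with the same nesting as
#' [nsa_config()]; keys absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @param config an [nsa_config()] object.
#' @return `read_config()` returns an [nsa_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- nsa_config()
  merge_into <- function(obj, upd) {
    if (is.null(upd)) return(obj)
    cls <- class(obj)
    out <- utils::modifyList(unclass(obj), upd)
    class(out) <- cls
    out
  }
  nsa_config(
    preprocess = do.call(filter_params,
                         utils::modifyList(unclass(base$preprocess),
                                           raw$preprocess %||% list())),
    detect = utils::modifyList(base$detect, raw$detect %||% list()),
    hough = do.call(hough_params,
                    utils::modifyList(unclass(base$hough),
                                      raw$hough %||% list())),
    fusion = do.call(fusion_config,
                     utils::modifyList(unclass(base$fusion),
                                       raw$fusion %||% list())),
    seed = raw$seed %||% base$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nsa_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

.read_truth <- function(landmarks_or_truth) {
  if (is.data.frame(landmarks_or_truth)) df <- landmarks_or_truth
  else df <- utils::read.csv(landmarks_or_truth, stringsAsFactors = FALSE)
  if ("structure" %in% names(df)) {
    nsa <- landmarks_nsa(df)
    nsa$patient_id <- nsa$hip_id
    names(nsa)[names(nsa) == "nsa_clinician"] <- "nsa_ap_clinician"
    return(nsa)
  }
  if (!"nsa_ap_clinician" %in% names(df)) {
    if ("true_nsa_ap" %in% names(df)) df$nsa_ap_clinician <- df$true_nsa_ap
    else stop("truth table needs a nsa_ap_clinician column (or landmarks)",
              call. = FALSE)
  }
  if (is.null(df$patient_id)) df$patient_id <- df$hip_id
  df[, c("hip_id", "patient_id", "nsa_ap_clinician")]
}

.classify_failure <- function(msg) {
  if (grepl("no lines detected", msg, fixed = TRUE)) "angles"
  else if (grepl("template|placement", msg)) "detect"
  else "process"
}

#' Run the NSA pipeline over a cohort directory
#'
#' Discovers matched `<hipID>_AP.png` / `<hipID>_LAT.png` pairs, measures
#' the AP and lateral NSA of every hip ([estimate_view_nsa()]), joins the
#' clinician ground truth, trains the fusion network on the resulting
#' records, and computes held-out agreement metrics for the fused and the
#' CV-only predictions. Hips failing any stage are recorded as failures
#' (with their stage and reason) and never silently dropped; a failure in
#' one hip does not affect the others.
#'
#' @param image_dir directory of PNG pairs.
#' @param templates template bank (list of matrices) or a directory of
#'   template PNG files.
#' @param landmarks_or_truth clinician ground truth: a CSV path or data
#'   frame, either per-hip NSAs (`hip_id,nsa_ap_clinician`, as written by
#'   [generate_cohort()]) or per-segment landmarks
#'   (`hip_id,structure,x1,y1,x2,y2`).
#' @param config an [nsa_config()].
#' @param out_dir optional output directory; when given, writes
#'   `records.csv`, `failures.csv`, `metrics.json`, and
#'   `run_config.resolved`.
#' @return An object of class `cohort_run`: list with `records` (one row
#'   per processed hip: ids, CV AP/lateral NSA, clinician NSA, fused NSA,
#'   detection center), `failures`, `metrics` (held-out
#'   [agreement_metrics()] for fused and CV-only), `model`, `config`, and
#'   `seed`.
#' @export
run_cohort <- function(image_dir, templates, landmarks_or_truth,
                       config = nsa_config(), out_dir = NULL) {
  stopifnot(inherits(config, "nsa_config"))
  if (is.character(templates) && length(templates) == 1L &&
      dir.exists(templates)) {
    files <- sort(list.files(templates, pattern = "\\.png$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("no template PNG files found in ", templates, call. = FALSE)
    templates <- lapply(files, read_radiograph)
  }
  truth <- .read_truth(landmarks_or_truth)

  files <- list.files(image_dir, pattern = "_(AP|LAT)\\.png$")
  ids <- sort(unique(sub("_(AP|LAT)\\.png$", "", files)))
  if (length(ids) == 0L)
    stop("no '<hipID>_AP.png' / '<hipID>_LAT.png' images found in ",
         image_dir, call. = FALSE)

  records <- list()
  failures <- list()
  fail <- function(id, stage, reason)
    data.frame(hip_id = id, stage = stage, reason = reason,
               stringsAsFactors = FALSE)
  for (id in ids) {
    ap_path <- file.path(image_dir, paste0(id, "_AP.png"))
    lat_path <- file.path(image_dir, paste0(id, "_LAT.png"))
    if (!file.exists(ap_path) || !file.exists(lat_path)) {
      failures[[id]] <- fail(id, "input", "missing AP or lateral view")
      next
    }
    trow <- truth[truth$hip_id == id, , drop = FALSE]
    if (nrow(trow) != 1L) {
      failures[[id]] <- fail(id, "input", "missing clinician ground truth")
      next
    }
    res <- tryCatch({
      ap <- estimate_view_nsa(read_radiograph(ap_path), templates, config,
                              "AP")
      lat <- estimate_view_nsa(read_radiograph(lat_path), templates,
                               config, "lateral")
      pr <- ap$match$roi
      data.frame(hip_id = id, patient_id = trow$patient_id,
                 nsa_ap_cv = ap$estimate$nsa,
                 nsa_lateral_cv = lat$estimate$nsa,
                 nsa_ap_clinician = trow$nsa_ap_clinician,
                 det_center_x = pr$x + (pr$width - 1) / 2,
                 det_center_y = pr$y + (pr$height - 1) / 2,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures[[id]] <- fail(id, .classify_failure(conditionMessage(res)),
                             conditionMessage(res))
    else records[[id]] <- res
  }
  records <- if (length(records)) do.call(rbind, c(records,
                                                   make.row.names = FALSE))
  else data.frame()
  failures <- if (length(failures))
    do.call(rbind, c(failures, make.row.names = FALSE))
  else data.frame(hip_id = character(0), stage = character(0),
                  reason = character(0))

  model <- NULL
  metrics <- NULL
  if (nrow(records) >= 5) {
    cfg_f <- config$fusion
    cfg_f$seed <- config$seed
    model <- train_fusion(records, cfg_f)
    records$nsa_ap_fused <- predict(model, records)
    test <- model$records[model$split$test, , drop = FALSE]
    if (nrow(test) >= 3)
      metrics <- list(
        fused = agreement_metrics(predict(model), test$nsa_ap_clinician),
        cv_only = agreement_metrics(test$nsa_ap_cv,
                                    test$nsa_ap_clinician))
  }

  run <- structure(list(records = records, failures = failures,
                        metrics = metrics, model = model, config = config,
                        seed = config$seed, n_hips = length(ids)),
                   class = "cohort_run")
  if (!is.null(out_dir)) .write_cohort_run(run, out_dir)
  run
}

# fixed-format CSV writer so identical runs are byte-identical
.write_records_csv <- function(records, path) {
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.6f", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
}

.write_cohort_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_records_csv(run$records, file.path(out_dir, "records.csv"))
  utils::write.csv(run$failures, file.path(out_dir, "failures.csv"),
                   row.names = FALSE)
  if (!is.null(run$metrics))
    jsonlite::write_json(
      list(fused = unclass(run$metrics$fused),
           cv_only = unclass(run$metrics$cv_only)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  write_config(run$config, file.path(out_dir, "run_config.resolved"))
  invisible(out_dir)
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("cohort_run: %d hip(s) discovered, %d processed, %d failed\n",
              x$n_hips, nrow(x$records), nrow(x$failures)))
  if (!is.null(x$metrics)) {
    cat("held-out metrics, fused:\n")
    print(x$metrics$fused)
    cat("held-out metrics, CV-only baseline:\n")
    print(x$metrics$cv_only)
  }
  invisible(x)
}
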