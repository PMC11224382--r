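# End-to-end experiment driver: the three-way source comparison
# (RGB vs hyperspectral vs fused) across the four baselines and the
# residual network, with optional distance-correlation band ablation.

#' Load a paired dataset from a manifest
#'
#' Reads the JSON manifest written by [write_dataset()]: a spectra CSV
#' (wavelength header, final `label` column) and one PNG per sample, with
#' the manifest linking image files to spectrum rows and labels. Row
#' counts, file existence and label range are validated.
#'
#' @param path manifest JSON path.
#' @return a list shaped like a [generate_dataset()] result (`spectra`,
#'   `wavelengths`, `images`, `labels`), class `"synthetic_dataset"`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path)
  dir <- dirname(path)
  csv <- file.path(dir, man$spectra_csv)
  if (!file.exists(csv)) stop("consistency error: spectra CSV missing")
  df <- utils::read.csv(csv, check.names = FALSE)
  if (!"label" %in% names(df)) stop("spectra CSV lacks a label column")
  labels_csv <- as.integer(df$label)
  spectra <- as.matrix(df[, setdiff(names(df), "label")])
  wavelengths <- as.numeric(setdiff(names(df), "label"))
  n <- length(man$samples)
  if (n != nrow(spectra))
    stop(sprintf("consistency error: %d manifest samples vs %d spectra rows",
                 n, nrow(spectra)))
  images <- vector("list", n)
  labels <- integer(n)
  for (i in seq_len(n)) {
    s <- man$samples[[i]]
    f <- file.path(dir, s$image)
    if (!file.exists(f))
      stop(sprintf("consistency error: image missing for sample %d (%s)",
                   i, s$image))
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L && dim(img)[3] > 3L)
      img <- img[, , 1:3, drop = FALSE] # drop alpha
    images[[s$row]] <- img
    labels[s$row] <- as.integer(s$label)
  }
  if (any(labels < 0L | labels > 3L))
    stop("label error: labels must lie in 0..3")
  if (!identical(labels, labels_csv))
    stop("consistency error: manifest labels disagree with the CSV")
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 images = images, labels = labels, truth = NULL),
            class = "synthetic_dataset")
}

#' Run the full source-by-model comparison
#'
#' Preprocesses a paired dataset (MSC on the spectra, crop/box-downsample
#' on the images, per-sample fusion), makes one stratified 70/30 split
#' shared by every model, and fits each requested model on each data
#' source: RGB-only (3 channels / 1386 flattened features), hyperspectral
#' only (1 channel / 462 features) and fused (4 channels / 1848 features).
#' Optionally ablates spectral bands first: distance-correlation scores
#' are computed on the training rows only and unselected bands zeroed
#' everywhere.
#'
#' @param dataset a paired dataset ([generate_dataset()] or
#'   [read_manifest()]); `NULL` generates one from `config`.
#' @param config a [generator_config()], used when `dataset` is `NULL`.
#' @param models subset of `c("decision_tree", "random_forest",
#'   "adaboost", "knn", "resnet_rh")`.
#' @param sources subset of `c("rgb", "hyperspectral", "fusion")`.
#' @param train_fraction training fraction (default 0.70; test size is the
#'   ceiling of the 30%).
#' @param seed seed for the split, baseline ensembles and network training.
#' @param band_ablation zero bands whose label distance correlation does
#'   not exceed `threshold` (default FALSE).
#' @param threshold band-selection cut (default 0.7).
#' @param msc apply multiplicative scatter correction (default TRUE).
#' @param resnet_args list of overrides for [resnet_rh()] (width, epochs,
#'   batch_size, lr, keep_best).
#' @param out_dir if non-NULL, write the summary CSV, per-pair JSON
#'   reports and confusion CSVs there.
#' @return object of class `"freshness_experiment"`: list with `summary`
#'   (data frame: source, model, accuracy, macro metrics, Wilson bounds),
#'   `reports` (named list of [metrics()] reports), `confusions`, `split`,
#'   `band_mask` (when ablated), `fits`.
#' @export
run_experiment <- function(dataset = NULL, config = generator_config(),
                           models = c(BASELINE_NAMES, "resnet_rh"),
                           sources = c("rgb", "hyperspectral", "fusion"),
                           train_fraction = 0.7, seed = 1L,
                           band_ablation = FALSE, threshold = 0.7,
                           msc = TRUE,
                           resnet_args = list(width = 16L, epochs = 30L),
                           out_dir = NULL) {
  stopifnot(length(models) >= 1L, length(sources) >= 1L)
  bad <- setdiff(models, c(BASELINE_NAMES, "resnet_rh"))
  if (length(bad) > 0) stop("unsupported model(s): ", paste(bad, collapse = ", "))
  if (is.null(dataset)) dataset <- generate_dataset(config)
  set.seed(seed)
  split <- stratified_split(dataset$labels, train_fraction)
  band_mask <- NULL
  # scatter-correct first: ablated bands must stay exactly zero in what the
  # models consume, so zeroing happens after MSC, never before
  sp <- if (msc) msc_correct(dataset$spectra)$corrected else dataset$spectra
  if (band_ablation) {
    band_mask <- score_bands(sp[split$train, , drop = FALSE],
                             dataset$labels[split$train],
                             threshold = threshold,
                             wavelengths = dataset$wavelengths)
    sp <- ablate_bands(sp, band_mask)
  }
  dataset$spectra <- sp
  fused <- fuse_dataset(dataset, msc = FALSE)
  labels <- fused$labels
  stacks <- list(
    rgb = fused$tensors[, , , 1:3, drop = FALSE],
    hyperspectral = fused$tensors[, , , 4, drop = FALSE],
    fusion = fused$tensors)
  summary_rows <- list()
  reports <- list()
  confusions <- list()
  fits <- list()
  for (src in sources) {
    xs <- stacks[[src]]
    feats <- flatten_features(xs, labels, source = src)
    for (mod in models) {
      key <- paste(src, mod, sep = ".")
      if (mod == "resnet_rh") {
        args <- c(list(x = xs, y = labels, split = split, seed = seed),
                  resnet_args)
        fit <- do.call(resnet_rh, args)
        pred <- predict(fit, xs[split$test, , , , drop = FALSE])
      } else {
        fit <- fit_baseline(mod,
                            feats$matrix[split$train, , drop = FALSE],
                            labels[split$train], seed = seed)
        pred <- predict(fit, feats$matrix[split$test, , drop = FALSE])
      }
      cm <- confusion(labels[split$test], pred)
      rep <- metrics(cm)
      wi <- wilson_interval(rep$n, rep$accuracy, 0.95)
      summary_rows[[key]] <- data.frame(
        source = src, model = mod, accuracy = rep$accuracy,
        macro_precision = rep$macro_precision,
        macro_recall = rep$macro_recall, macro_f1 = rep$macro_f1,
        wilson_lower = wi[["lower"]], wilson_upper = wi[["upper"]],
        n_test = rep$n)
      reports[[key]] <- rep
      confusions[[key]] <- cm
      fits[[key]] <- fit
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  out <- structure(list(summary = summary, reports = reports,
                        confusions = confusions, split = split,
                        band_mask = band_mask, fits = fits,
                        seed = seed),
                   class = "freshness_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  for (key in names(x$reports)) {
    rep <- x$reports[[key]]
    jsonlite::write_json(
      list(accuracy = rep$accuracy, macro_precision = rep$macro_precision,
           macro_recall = rep$macro_recall, macro_f1 = rep$macro_f1,
           per_class = rep$per_class, n = rep$n, seed = x$seed),
      file.path(out_dir, paste0(key, ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(unclass(x$confusions[[key]])),
                     file.path(out_dir, paste0(key, "_confusion.csv")))
  }
  if (!is.null(x$band_mask))
    write_band_mask(x$band_mask, file.path(out_dir, "band_mask.json"))
  for (key in names(x$fits)) {
    f <- x$fits[[key]]
    if (inherits(f, "resnet_rh") && !is.null(f$history))
      utils::write.csv(f$history,
                       file.path(out_dir, paste0(key, "_history.csv")),
                       row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.freshness_experiment <- function(x, ...) {
  cat("Freshness classification experiment\n")
  cat(sprintf("  %d train / %d test samples, seed %d\n",
              length(x$split$train), length(x$split$test), x$seed))
  if (!is.null(x$band_mask))
    cat(sprintf("  band ablation: %d/%d bands kept\n",
                sum(x$band_mask$selected), length(x$band_mask$selected)))
  df <- x$summary
  df[3:8] <- round(df[3:8], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
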