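BASE_BLOCKS <- c("max", "in_min", "iso", "sum", "lbp", "elbp", "mlbp")

# Map a base block name to its measure configuration / extractor.
.block_extractor <- function(name) {
  switch(name,
    max    = function(x, m) mf_descriptor(x, m, mf_config("maximum"),
                                          normalize = FALSE),
    in_min = function(x, m) mf_descriptor(x, m, mf_config("inverse_minimum"),
                                          normalize = FALSE),
    iso    = function(x, m) mf_descriptor(x, m, mf_config("iso"),
                                          normalize = FALSE),
    sum    = function(x, m) mf_descriptor(x, m, mf_config("summation"),
                                          normalize = FALSE),
    lbp    = function(x, m) lbp_descriptor(x, m),
    elbp   = function(x, m) elbp_descriptor(x, m),
    mlbp   = function(x, m) mlbp_descriptor(x, m),
    stop("unknown descriptor block: ", name, call. = FALSE))
}

# Parse "iso+mlbp" into its base blocks, validating names.
.descriptor_blocks <- function(descriptor) {
  parts <- strsplit(descriptor, "+", fixed = TRUE)[[1L]]
  bad <- setdiff(parts, BASE_BLOCKS)
  if (length(bad))
    stop("unknown descriptor: ", paste(bad, collapse = ", "),
         " (available: ", paste(BASE_BLOCKS, collapse = ", "), ")",
         call. = FALSE)
  parts
}

#' Run configuration for an end-to-end experiment
#'
#' @param source `"synthetic"` or a directory containing a `manifest.csv`
#'   written by [write_dataset()].
#' @param n_per_class phantoms per class when `source = "synthetic"`.
#' @param dataset_seed base seed of the synthetic dataset.
#' @param view phantom view for synthetic data.
#' @param image_size phantom size `(H, W)`.
#' @param descriptors list of descriptor requests. Each entry is either a
#'   descriptor name (`"iso"`, `"mlbp"`, `"iso+mlbp"`, ...) or a list with
#'   `name` plus optional `selection` (`"pca"`/`"autoencoder"`) and
#'   `n_components` / `ae` settings.
#' @param reference name of the reference descriptor for pairwise t-tests
#'   (default: the last one listed).
#' @param roi `"segmented"` (run the segmentation pipeline) or
#'   `"ground_truth"` (use generator masks; synthetic source only).
#' @param k,cv_seed cross-validation folds and seed.
#' @param binary collapse BI-RADS labels to low/high before evaluation.
#' @param grid SVM hyper-parameter grid.
#' @return a `run_config` list.
#' @export
run_config <- function(source = "synthetic", n_per_class = 20L,
                       dataset_seed = 42L, view = "MLO",
                       image_size = c(256L, 256L),
                       descriptors = list("iso", "mlbp",
                         list(name = "iso+mlbp", selection = "pca",
                              n_components = 45L)),
                       reference = NULL, roi = c("segmented", "ground_truth"),
                       k = 5L, cv_seed = 1L, binary = FALSE,
                       grid = svm_param_grid()) {
  roi <- match.arg(roi)
  descriptors <- lapply(descriptors, function(d) {
    if (is.character(d)) d <- list(name = d)
    if (is.null(d$selection)) d$selection <- "none"
    if (is.null(d$n_components)) d$n_components <- 45L
    .descriptor_blocks(d$name)  # validate early
    d
  })
  if (length(descriptors) == 0L)
    stop("at least one descriptor is required", call. = FALSE)
  names_ <- vapply(descriptors, `[[`, character(1), "name")
  if (anyDuplicated(names_))
    stop("duplicate descriptor requested", call. = FALSE)
  if (is.null(reference)) reference <- names_[length(names_)]
  if (!reference %in% names_)
    stop("reference descriptor not among the requested ones", call. = FALSE)
  structure(list(source = source, n_per_class = as.integer(n_per_class),
                 dataset_seed = as.integer(dataset_seed), view = view,
                 image_size = as.integer(image_size),
                 descriptors = descriptors, reference = reference, roi = roi,
                 k = as.integer(k), cv_seed = as.integer(cv_seed),
                 binary = isTRUE(binary), grid = grid),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  o <- yaml::read_yaml(path)
  do.call(run_config, o[intersect(names(o),
    names(formals(run_config)))])
}

# Load samples for a config: synthesize or read a written dataset.
.load_samples <- function(cfg) {
  if (identical(cfg$source, "synthetic")) {
    defaults <- phantom_spec(view = cfg$view, image_size = cfg$image_size)
    generate_dataset(cfg$n_per_class, base_seed = cfg$dataset_seed,
                     spec_defaults = defaults)
  } else {
    man <- utils::read.csv(file.path(cfg$source, "manifest.csv"),
                           stringsAsFactors = FALSE)
    samples <- lapply(seq_len(nrow(man)), function(i) {
      list(image = read_image(man$file[i], view = cfg$view),
           breast_mask = read_mask(man$mask[i]),
           pectoral_mask = read_mask(man$pectoral_mask[i]),
           label = man$label[i],
           realized_dense_fraction = man$dense_fraction[i])
    })
    list(samples = samples, manifest = man)
  }
}

#' Extract descriptor feature blocks from samples
#'
#' Per sample: normalize, 3x3 median filter, then either the segmentation
#' pipeline ([segment_breast()] + [remove_pectoral()]) or the ground-truth
#' breast mask, then every requested base block over the ROI. Each base
#' block is computed once and shared between fused descriptors. Samples
#' whose preprocessing or extraction fails are recorded and skipped.
#'
#' @param samples list of `synthetic_sample`-like objects.
#' @param blocks base block names (subset of
#'   `max, in_min, iso, sum, lbp, elbp, mlbp`).
#' @param roi `"segmented"` or `"ground_truth"`.
#' @return list: `blocks` (named list of M x p matrices), `labels`,
#'   `errors` (per-sample messages, NULL when clean), `kept` (indices).
#' @export
extract_features <- function(samples, blocks,
                             roi = c("segmented", "ground_truth")) {
  roi <- match.arg(roi)
  bad <- setdiff(blocks, BASE_BLOCKS)
  if (length(bad)) stop("unknown descriptor block: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- stats::setNames(vector("list", length(blocks)), blocks)
  labels <- character(0)
  errors <- list()
  kept <- integer(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    row <- tryCatch({
      x <- normalize_intensity(s$image)
      x <- median_filter3(x)
      mask <- if (roi == "ground_truth") s$breast_mask
              else {
                m0 <- segment_breast(x)
                remove_pectoral(x, m0, view = s$image$view)
              }
      if (!any(mask)) stop("empty ROI after segmentation")
      lapply(blocks, function(b) .block_extractor(b)(x, mask))
    }, error = function(e) e)
    if (inherits(row, "error")) {
      errors[[length(errors) + 1L]] <-
        sprintf("sample %d: %s", i, conditionMessage(row))
      next
    }
    kept <- c(kept, i)
    labels <- c(labels, s$label)
    for (bi in seq_along(blocks))
      out[[bi]] <- rbind(out[[bi]], row[[bi]])
  }
  if (length(kept) == 0L) stop("no sample could be processed", call. = FALSE)
  list(blocks = out, labels = factor(labels, levels = c("I", "II", "III", "IV")),
       errors = if (length(errors)) unlist(errors) else NULL, kept = kept)
}

#' Extract a feature table and optionally write it to CSV
#'
#' One row per image: label plus every requested descriptor's columns.
#' Deterministic for a fixed configuration.
#'
#' @param cfg a [run_config()].
#' @param out_csv optional path for the feature CSV.
#' @return list: `features` (named list of descriptor matrices), `labels`,
#'   `table` (data frame as written), `manifest`, `errors`.
#' @export
run_extract <- function(cfg, out_csv = NULL) {
  ds <- .load_samples(cfg)
  names_ <- vapply(cfg$descriptors, `[[`, character(1), "name")
  blocks <- unique(unlist(lapply(names_, .descriptor_blocks)))
  ex <- extract_features(ds$samples, blocks, roi = cfg$roi)
  feats <- lapply(names_, function(nm) {
    parts <- .descriptor_blocks(nm)
    m <- do.call(cbind, ex$blocks[parts])
    rownames(m) <- NULL
    m
  })
  names(feats) <- names_
  tab <- data.frame(label = ex$labels,
                    do.call(cbind, feats), check.names = FALSE)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  list(features = feats, labels = ex$labels, table = tab,
       manifest = ds$manifest[ex$kept, , drop = FALSE], errors = ex$errors)
}

#' Run a full descriptor-comparison experiment
#'
#' Synthesizes (or loads) the dataset, extracts every requested descriptor,
#' cross-validates each with its configured feature selection on identical
#' folds, and computes paired t-tests of fold-wise accuracy against the
#' reference descriptor (the reference's own cell is NA, mirroring the dash
#' in a comparison table).
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory for `report.json` and `report.md`.
#' @return a `run_report`: `results` (named list of `cv_result`),
#'   `p_values`, `reference`, `summary` (data frame), `config`.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  ex <- run_extract(cfg)
  y <- ex$labels
  if (cfg$binary) y <- binarize_labels(y)
  results <- list()
  for (d in cfg$descriptors) {
    X <- ex$features[[d$name]]
    ae <- if (d$selection == "autoencoder")
      autoencoder_spec(ncol(X), seed = cfg$cv_seed) else NULL
    results[[d$name]] <- cross_validate(
      X, y, k = cfg$k, seed = cfg$cv_seed, selector = d$selection,
      n_components = d$n_components, ae_spec = ae, grid = cfg$grid)
  }
  ref <- cfg$reference
  p_values <- vapply(names(results), function(nm) {
    if (nm == ref) NA_real_
    else paired_ttest(results[[nm]]$per_fold_accuracy,
                      results[[ref]]$per_fold_accuracy)
  }, numeric(1))
  summary <- data.frame(
    descriptor = names(results),
    accuracy = vapply(results, `[[`, numeric(1), "accuracy"),
    auc_mean = vapply(results, `[[`, numeric(1), "auc_mean"),
    auc_sd = vapply(results, `[[`, numeric(1), "auc_sd"),
    kappa = vapply(results, `[[`, numeric(1), "kappa"),
    f1_weighted = vapply(results, `[[`, numeric(1), "f1_weighted"),
    p_value = p_values, row.names = NULL)
  rep <- structure(list(results = results, p_values = p_values,
                        reference = ref, summary = summary, config = cfg),
                   class = "run_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> reference:", x$reference, "\n")
  s <- x$summary
  s$accuracy <- sprintf("%.1f%%", 100 * s$accuracy)
  s$auc_mean <- sprintf("%.1f%%", 100 * s$auc_mean)
  print(s[, c("descriptor", "accuracy", "auc_mean", "kappa", "p_value")])
  invisible(x)
}

#' Write a run report as JSON and Markdown
#' @param rep a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    reference = rep$reference,
    summary = rep$summary,
    confusion = lapply(rep$results, function(r)
      unclass(as.matrix(r$confusion))),
    per_fold_accuracy = lapply(rep$results, `[[`, "per_fold_accuracy"),
    best_configs = lapply(rep$results, function(r)
      lapply(r$best_configs, as.list)))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  s <- rep$summary
  lines <- c("# Descriptor comparison", "",
             "| Descriptor | CA (%) | AUC (%) | Kappa | F1 | p-Value |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %.1f | %.1f ± %.1f | %.2f | %.2f | %s |",
                     s$descriptor, 100 * s$accuracy, 100 * s$auc_mean,
                     100 * s$auc_sd, s$kappa, s$f1_weighted,
                     ifelse(is.na(s$p_value), "—",
                            formatC(s$p_value, format = "g", digits = 3))))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
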