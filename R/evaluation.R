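# Clinical-form classification tasks, patient-grouped stratified k-fold
# cross-validation, precision/recall/F1 reporting and the experiment grid
# over atlases x distances x thresholds x normalization modes.

TASK_NAMES <- c("RR_vs_PP", "RR_vs_SP", "PP_vs_SP", "RR_vs_PPSP",
                "RR_vs_PP_vs_SP", "MS_vs_HC")

#' Define one of the six classification tasks
#'
#' Tasks: `RR_vs_PP`, `RR_vs_SP`, `PP_vs_SP`, `RR_vs_PPSP` (PP and SP merged
#' into one neurodegenerative class), `RR_vs_PP_vs_SP` (three classes) and
#' `MS_vs_HC` (all clinical forms merged against healthy controls).
#'
#' @param name Task name.
#' @return Object of class `task_spec` with fields `name`, `mapping` (named
#'   character vector original label -> task class) and `C`.
#' @export
task_spec <- function(name) {
  if (!name %in% TASK_NAMES) {
    stop("unknown task '", name, "'; tasks are: ", paste(TASK_NAMES, collapse = ", "))
  }
  mapping <- switch(name,
    RR_vs_PP = c(RR = "RR", PP = "PP"),
    RR_vs_SP = c(RR = "RR", SP = "SP"),
    PP_vs_SP = c(PP = "PP", SP = "SP"),
    RR_vs_PPSP = c(RR = "RR", PP = "PPSP", SP = "PPSP"),
    RR_vs_PP_vs_SP = c(RR = "RR", PP = "PP", SP = "SP"),
    MS_vs_HC = c(RR = "MS", PP = "MS", SP = "MS", HC = "HC")
  )
  structure(list(name = name, mapping = mapping,
                 C = length(unique(mapping))),
            class = "task_spec")
}

#' Filter and relabel scan metadata for a task
#'
#' Keeps only scans whose clinical form participates in the task and adds a
#' `task_label` column with the task's class names.
#'
#' @param meta Metadata `data.frame` with a `label` column.
#' @param task A [task_spec()] or task name.
#' @return The filtered metadata with `task_label`.
#' @export
make_task_dataset <- function(meta, task) {
  if (is.character(task)) task <- task_spec(task)
  stopifnot(inherits(task, "task_spec"))
  meta <- as.data.frame(meta)
  keep <- meta$label %in% names(task$mapping)
  out <- meta[keep, , drop = FALSE]
  out$task_label <- unname(task$mapping[out$label])
  out
}

#' Patient-grouped stratified k-fold assignment
#'
#' All scans of one patient land in exactly one fold, so no patient ever
#' appears in both train and test. Patients are processed in decreasing
#' order of scan count (ties broken by a seeded shuffle) and greedily
#' assigned to the fold that minimizes the squared deviation of per-fold
#' class scan counts from the global proportions.
#'
#' @param meta Metadata with `patient_id`, and class labels in
#'   `label_col` (default `"task_label"`, falling back to `"label"`).
#' @param k Number of folds (>= 2).
#' @param seed Seed for the tie-breaking shuffle.
#' @param label_col Column holding the class label.
#' @return Object of class `fold_split`: list with `fold` (named integer
#'   vector patient -> fold), `scan_fold` (named integer vector scan ->
#'   fold) and `k`.
#' @export
stratified_group_kfold <- function(meta, k = 5L, seed = 1L,
                                   label_col = NULL) {
  meta <- as.data.frame(meta)
  if (is.null(label_col)) {
    label_col <- if ("task_label" %in% names(meta)) "task_label" else "label"
  }
  if (k < 2) stop("k must be at least 2")
  lab <- meta[[label_col]]
  pat <- meta$patient_id
  ptab <- unique(data.frame(patient_id = pat, label = lab,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(ptab$patient_id)) {
    stop("patients with more than one class label; stratification is per patient")
  }
  cls_pat <- table(ptab$label)
  if (any(cls_pat < k)) {
    stop("class(es) with fewer patients than folds: ",
         paste(names(cls_pat)[cls_pat < k], collapse = ", "))
  }
  counts <- table(pat)
  ptab$n_scans <- as.integer(counts[ptab$patient_id])
  set.seed(seed)
  ptab <- ptab[sample.int(nrow(ptab)), , drop = FALSE]
  ptab <- ptab[order(-ptab$n_scans), , drop = FALSE]

  classes <- sort(unique(ptab$label))
  total <- vapply(classes, function(cl) sum(ptab$n_scans[ptab$label == cl]), 0)
  target <- total / k
  fold_counts <- matrix(0, nrow = k, ncol = length(classes),
                        dimnames = list(NULL, classes))
  fold_of <- integer(nrow(ptab))
  for (i in seq_len(nrow(ptab))) {
    cl <- ptab$label[i]
    add <- ptab$n_scans[i]
    # change in total squared deviation if the patient joins fold f: only
    # fold f's own class-cl term moves, so minimize that increment
    cost <- (fold_counts[, cl] + add - target[[cl]])^2 -
      (fold_counts[, cl] - target[[cl]])^2
    best <- which(cost <= min(cost) + 1e-9)
    if (length(best) > 1) best <- best[order(rowSums(fold_counts)[best])]
    f <- best[1]
    fold_counts[f, cl] <- fold_counts[f, cl] + add
    fold_of[i] <- f
  }
  fold <- stats::setNames(fold_of, ptab$patient_id)
  scan_fold <- stats::setNames(fold[pat], meta$scan_id)
  structure(list(fold = fold, scan_fold = scan_fold, k = as.integer(k)),
            class = "fold_split")
}

#' Precision, recall and F1 from label vectors
#'
#' Support-weighted averages by default; macro and per-class values are
#' always reported alongside, plus the confusion matrix.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class set (default: union of observed labels, sorted).
#' @return List with `confusion`, `per_class` (data.frame precision, recall,
#'   f1, support), `weighted` and `macro` (each c(precision, recall, f1)).
#' @export
compute_metrics <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) == 0) stop("empty label vectors")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm)
  w <- support / sum(support)
  per_class <- data.frame(class = classes, precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          support = as.numeric(support))
  list(confusion = cm, per_class = per_class,
       weighted = c(precision = sum(w * prec), recall = sum(w * rec),
                    f1 = sum(w * f1)),
       macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)))
}

#' Fixed train/test split for the MS-versus-healthy task
#'
#' A fixed-composition hold-out: the test set holds 42 MS
#' scans (24 RR, 10 PP, 8 SP), all protocol-matched HC scans and 24
#' population-cohort HC scans; the training set holds every scan of patients
#' with no scan in the test set (patients contributing test scans are
#' excluded entirely, preserving group integrity).
#'
#' @param meta Metadata including HC scans; a `cohort` column distinguishes
#'   protocol (`"AMSEP"`) from population (`"IXI"`) controls when present.
#' @param seed Seed for the scan selection.
#' @param ms_test Named vector of MS test scan counts,
#'   default `c(RR = 24, PP = 10, SP = 8)`.
#' @param hc_ixi_test Population HC scans in the test set (default 24).
#' @return List with `train_ids` and `test_ids` (scan ids).
#' @export
make_ms_hc_split <- function(meta, seed = 1L,
                             ms_test = c(RR = 24L, PP = 10L, SP = 8L),
                             hc_ixi_test = 24L) {
  meta <- as.data.frame(meta)
  set.seed(seed)
  test_ids <- character(0)
  for (cl in names(ms_test)) {
    pool <- meta$scan_id[meta$label == cl]
    if (length(pool) < ms_test[[cl]]) stop("not enough ", cl, " scans for the fixed split")
    test_ids <- c(test_ids, sample(pool, ms_test[[cl]]))
  }
  hc <- meta[meta$label == "HC", , drop = FALSE]
  if ("cohort" %in% names(hc) && any(hc$cohort %in% "AMSEP")) {
    test_ids <- c(test_ids, hc$scan_id[hc$cohort %in% "AMSEP"])
    ixi <- hc$scan_id[hc$cohort %in% "IXI"]
    test_ids <- c(test_ids, sample(ixi, min(hc_ixi_test, length(ixi))))
  } else {
    n_hc_test <- min(nrow(hc), 21L + hc_ixi_test)
    test_ids <- c(test_ids, sample(hc$scan_id, n_hc_test))
  }
  test_pat <- unique(meta$patient_id[meta$scan_id %in% test_ids])
  train_ids <- meta$scan_id[!meta$patient_id %in% test_pat]
  list(train_ids = train_ids, test_ids = test_ids)
}

#' Cross-validated GCN evaluation of one task on prepared graphs
#'
#' Runs patient-grouped stratified k-fold CV: per fold, a fresh model is
#' trained on the training folds and evaluated on the held-out fold.
#'
#' @param graphs Named list of `brain_graph`s (names are scan ids).
#' @param meta Metadata covering the graphs (`scan_id`, `patient_id`,
#'   `label`).
#' @param task A [task_spec()] or task name.
#' @param k Folds (default 5).
#' @param config A [train_config()].
#' @param seed Master seed; fold assignment, per-fold model initialization
#'   and training randomness derive from it.
#' @param hidden GCN channels (default 64).
#' @param val_fraction Fraction of training-fold patients held out (grouped,
#'   stratified) as an inner validation set for early stopping; 0 disables
#'   early stopping (default 0.15).
#' @return Object of class `metrics_report`: list with `task`, `folds`
#'   (per-fold metric lists), `summary` (mean and sd of weighted/macro
#'   precision, recall, F1), `split`.
#' @export
cross_validate_gcn <- function(graphs, meta, task, k = 5L,
                               config = train_config(), seed = 1L,
                               hidden = 64L, val_fraction = 0.15) {
  if (is.character(task)) task <- task_spec(task)
  dat <- make_task_dataset(meta, task)
  dat <- dat[dat$scan_id %in% names(graphs), , drop = FALSE]
  split <- stratified_group_kfold(dat, k = k, seed = seed)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- dat$scan_id[split$scan_fold[dat$scan_id] == f]
    train_ids <- dat$scan_id[split$scan_fold[dat$scan_id] != f]
    cfg <- config
    cfg$seed <- (seed * 131L + f) %% 2147483647L
    val_ids <- character(0)
    if (val_fraction > 0) {
      trdat <- dat[dat$scan_id %in% train_ids, , drop = FALSE]
      k_in <- max(2L, as.integer(round(1 / val_fraction)))
      inner <- tryCatch(
        stratified_group_kfold(trdat, k = k_in, seed = cfg$seed),
        error = function(e) NULL)  # too few patients: skip early stopping
      if (!is.null(inner)) {
        val_ids <- trdat$scan_id[inner$scan_fold[trdat$scan_id] == 1L]
        train_ids <- setdiff(train_ids, val_ids)
      }
    }
    ytr <- dat$task_label[match(train_ids, dat$scan_id)]
    yte <- dat$task_label[match(test_ids, dat$scan_id)]
    model <- gcn_model(task$C, dropout = 0.3, hidden = hidden,
                       seed = cfg$seed)
    model$classes <- sort(unique(dat$task_label))
    if (length(val_ids)) {
      yval <- dat$task_label[match(val_ids, dat$scan_id)]
      model <- train_gcn(model, graphs[train_ids], ytr, cfg,
                         val_graphs = graphs[val_ids], val_labels = yval)
    } else {
      model <- train_gcn(model, graphs[train_ids], ytr, cfg)
    }
    pred <- predict_gcn(model, graphs[test_ids])
    fold_metrics[[f]] <- compute_metrics(yte, pred$labels,
                                         classes = model$classes)
  }
  summarize_folds(fold_metrics, task, split)
}

summarize_folds <- function(fold_metrics, task, split = NULL) {
  pull <- function(which, stat) {
    vapply(fold_metrics, function(m) m[[which]][[stat]], 0)
  }
  summary <- data.frame(
    average = rep(c("weighted", "macro"), each = 3),
    metric = rep(c("precision", "recall", "f1"), 2),
    mean = c(mean(pull("weighted", "precision")), mean(pull("weighted", "recall")),
             mean(pull("weighted", "f1")), mean(pull("macro", "precision")),
             mean(pull("macro", "recall")), mean(pull("macro", "f1"))),
    sd = c(sd(pull("weighted", "precision")), sd(pull("weighted", "recall")),
           sd(pull("weighted", "f1")), sd(pull("macro", "precision")),
           sd(pull("macro", "recall")), sd(pull("macro", "f1")))
  )
  structure(list(task = task$name, folds = fold_metrics, summary = summary,
                 split = split),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report:", x$task, "(", length(x$folds), "folds )\n")
  w <- x$summary[x$summary$average == "weighted", ]
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  weighted %-9s %.3f +/- %.3f\n", w$metric[i], w$mean[i], w$sd[i]))
  }
  invisible(x)
}

#' Mean weighted F1 of a metrics report
#' @param report A `metrics_report`.
#' @param average `"weighted"` or `"macro"`.
#' @return Named vector `c(mean, sd)` of the F1 across folds.
#' @export
report_f1 <- function(report, average = "weighted") {
  s <- report$summary
  row <- s[s$average == average & s$metric == "f1", ]
  c(mean = row$mean, sd = row$sd)
}

#' Enumerate the experiment grid
#'
#' Cartesian product of atlases, distance metrics, rejection quantiles and
#' normalization modes. The defaults (3 atlases x 2 distances x 4 thresholds
#' x 3 normalization modes) give 72 GCN configurations.
#'
#' @param atlases Character vector of atlas names.
#' @param metrics Distance metrics.
#' @param taus Rejection quantiles.
#' @param normalizations Normalization modes.
#' @return `data.frame` with one row per configuration.
#' @export
enumerate_grid <- function(atlases = c("desikan-killiany", "destrieux", "glasser"),
                           metrics = c("mahalanobis", "taxicab"),
                           taus = c(0, 0.6, 0.7, 0.8),
                           normalizations = c("none", "proportional", "residual")) {
  expand.grid(atlas = atlases, metric = metrics, tau = taus,
              normalization = normalizations,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run (a sub-grid of) the full experiment grid on a cohort
#'
#' For each grid cell, region features are normalized as requested, brain
#' graphs are built at the cell's metric and threshold, and every requested
#' task is evaluated with patient-grouped stratified k-fold CV. Failures in
#' a cell are recorded and the grid continues.
#'
#' @param cohort A `scan_cohort` (the patient cohort; may include HC scans
#'   for the MS_vs_HC task).
#' @param healthy Optional `scan_cohort` of healthy reference scans used to
#'   fit the normalization models; defaults to the HC scans of `cohort`.
#' @param grid `data.frame` from [enumerate_grid()] (or a subset).
#' @param tasks Task names to evaluate.
#' @param k CV folds.
#' @param config A [train_config()].
#' @param seed Master seed.
#' @return `data.frame` with one row per cell x task: grid coordinates,
#'   `mean_f1`, `sd_f1`, `mean_precision`, `mean_recall` (weighted), and an
#'   `error` column (`NA` on success); the full `metrics_report`s are in
#'   `attr(, "reports")`.
#' @export
run_experiment_grid <- function(cohort, grid = enumerate_grid(),
                                tasks = "RR_vs_PPSP", healthy = NULL,
                                k = 5L, config = train_config(), seed = 1L) {
  stopifnot(inherits(cohort, "scan_cohort"))
  rows <- list(); reports <- list()
  atlas_cache <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    key <- as.character(cell$atlas)
    res <- tryCatch({
    if (is.null(atlas_cache[[key]])) {
      parc <- if (key %in% c("desikan-killiany", "destrieux", "glasser")) {
        parcellation(key)
      } else {
        parcellation("custom", n_regions = cohort$config$atlas_size)
      }
      feats <- featurize_cohort(cohort, parc)
      hc <- healthy
      norm_models <- list()
      cth <- NULL
      scan_id <- thickness_mm <- NULL
      cth_tab <- cohort$thickness[, list(cth = mean(thickness_mm)), by = "scan_id"]
      cth <- stats::setNames(cth_tab$cth, cth_tab$scan_id)
      if (any(c("proportional", "residual") %in% grid$normalization)) {
        if (is.null(hc)) {
          if (!any(cohort$metadata$label == "HC")) {
            stop("normalization requested but no healthy scans available")
          }
          hc_meta <- cohort$metadata[cohort$metadata$label == "HC", ]
          hc_feats <- feats[hc_meta$scan_id]
          hc_cth <- data.frame(age_years = hc_meta$age_years, sex = hc_meta$sex,
                               cth = cth[hc_meta$scan_id])
        } else {
          hc_meta <- hc$metadata
          hc_feats <- featurize_cohort(hc, parc)
          hcth <- hc$thickness[, list(cth = mean(thickness_mm)), by = "scan_id"]
          hc_cth <- data.frame(age_years = hc_meta$age_years, sex = hc_meta$sex,
                               cth = hcth$cth[match(hc_meta$scan_id, hcth$scan_id)])
        }
        norm_models$proportional <- fit_proportional(hc_cth)
        norm_models$residual <- fit_residual(hc_feats, hc_meta)
      }
      atlas_cache[[key]] <- list(feats = feats, cth = cth, models = norm_models)
    }
    cache <- atlas_cache[[key]]
      feats_n <- normalize_features(cache$feats, cohort$metadata,
                                    mode = as.character(cell$normalization),
                                    model = cache$models[[as.character(cell$normalization)]],
                                    cth = cache$cth)
      graphs <- lapply(feats_n, build_brain_graph,
                       metric = as.character(cell$metric), tau = cell$tau)
      cell_rows <- list()
      for (tk in tasks) {
        rep <- cross_validate_gcn(graphs, cohort$metadata, tk, k = k,
                                  config = config,
                                  seed = (seed + ci * 101L) %% 2147483647L)
        reports[[paste(key, cell$metric, cell$tau, cell$normalization, tk,
                       sep = "|")]] <- rep
        w <- rep$summary[rep$summary$average == "weighted", ]
        cell_rows[[tk]] <- data.frame(
          atlas = key, metric = cell$metric, tau = cell$tau,
          normalization = cell$normalization, task = tk,
          mean_f1 = w$mean[w$metric == "f1"], sd_f1 = w$sd[w$metric == "f1"],
          mean_precision = w$mean[w$metric == "precision"],
          mean_recall = w$mean[w$metric == "recall"], error = NA_character_)
      }
      do.call(rbind, cell_rows)
    }, error = function(e) {
      data.frame(atlas = key, metric = cell$metric, tau = cell$tau,
                 normalization = cell$normalization, task = NA_character_,
                 mean_f1 = NA_real_, sd_f1 = NA_real_,
                 mean_precision = NA_real_, mean_recall = NA_real_,
                 error = conditionMessage(e))
    })
    rows[[ci]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
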