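# End-to-end orchestration: one configuration drives simulation/ingest,
# segment + peak feature extraction, DEG labeling, feature selection +
# cross-validated classification, and precision-ranked candidate selection,
# with a provenance record for reproducibility.

#' Pipeline configuration
#'
#' All thresholds default to the study-scale settings: DEG fold change 1.5
#' with RPKM floor 1; differential peaks at |M| >= 0.4, p <= 0.05; 5 kb
#' nearest-gene cap; top 5% features by information gain; 80/20 stratified
#' split; 10-fold CV; candidate pool = top 60% expressed; 200-gene bins with
#' cumulative precision cutoff 0.95; cross-genotype evaluation at |FC| > 4.
#'
#' @param simulate optional [simulation_config()] — when given, inputs are
#'   generated instead of read from files.
#' @param annotation,chrom_lengths,tracks,peaks,expression,truth_labels
#'   input paths (annotation file; TSV of chrom lengths; named lists of BED
#'   and narrowPeak paths keyed `"{genotype}.{mark}.{condition}"`; named
#'   list of expression TSVs keyed by genotype; optional truth TSV).
#' @param genotypes,marks,conditions,responsive_genotype vocabularies.
#' @param fc_threshold,rpkm_threshold DEG labeling thresholds.
#' @param m_threshold,p_threshold differential-peak thresholds.
#' @param max_distance peak-to-gene cap (bp).
#' @param selector,classifier,top_fraction model choices.
#' @param split_fraction,folds evaluation protocol.
#' @param expressed_fraction candidate-pool fraction.
#' @param bin_size,precision_threshold candidate-selection rule.
#' @param min_abs_fc cross-genotype evaluation fold-change filter.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, annotation = NULL,
                            chrom_lengths = NULL, tracks = NULL,
                            peaks = NULL, expression = NULL,
                            truth_labels = NULL,
                            genotypes = c("C", "e"),
                            marks = c("K9", "K14", "K23"),
                            conditions = c("A", "C"),
                            responsive_genotype = "C",
                            fc_threshold = 1.5, rpkm_threshold = 1.0,
                            m_threshold = 0.4, p_threshold = 0.05,
                            max_distance = 5000,
                            selector = "infogain", classifier = "logistic",
                            top_fraction = 0.05, split_fraction = 0.8,
                            folds = 10, expressed_fraction = 0.6,
                            bin_size = 200, precision_threshold = 0.95,
                            min_abs_fc = 4.0, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(fc_threshold > 0, rpkm_threshold >= 0, m_threshold >= 0,
            p_threshold > 0, p_threshold <= 1, max_distance >= 0,
            top_fraction > 0, top_fraction <= 1, split_fraction > 0,
            split_fraction < 1, folds >= 2, expressed_fraction > 0,
            expressed_fraction <= 1, bin_size >= 1,
            precision_threshold > 0, precision_threshold <= 1,
            min_abs_fc >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `simulate`
#' block is handed to [simulation_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  if (!is.null(raw$simulate))
    raw$simulate <- do.call(simulation_config, raw$simulate)
  do.call(pipeline_config, raw)
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    bundle <- generate_dataset(config$simulate)
    return(bundle)
  }
  if (is.null(config$annotation) || is.null(config$tracks) ||
      is.null(config$peaks) || is.null(config$expression))
    stop("without a simulate block the config must name annotation, ",
         "tracks, peaks and expression inputs")
  genes <- read_annotation(config$annotation)
  chl <- if (!is.null(config$chrom_lengths)) {
    tab <- read_tsv_table(config$chrom_lengths)
    stats::setNames(tab$length, tab$chrom)
  } else {
    ends <- vapply(genes, function(g) g$exons[nrow(g$exons), 2], numeric(1))
    chs <- vapply(genes, `[[`, character(1), "chrom")
    tapply(ends, chs, max) + 5000
  }
  # expression stays as paths: it is read (and can fail) in the deg_labels
  # stage, which owns that input
  list(genes = genes, chrom_lengths = chl,
       tracks = lapply(config$tracks, read_bed_reads),
       peaks = lapply(config$peaks, read_narrowpeak),
       expression = as.list(config$expression),
       labels = if (!is.null(config$truth_labels))
         read_tsv_table(config$truth_labels) else NULL)
}

# Expression entries may be in-memory tables (simulated bundle) or paths.
resolve_expression <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("expression file not found: ", x)
    read_tsv_table(x)
  } else x
}

#' Build the combined feature matrix from a loaded bundle
#'
#' Segment-signal features plus peak features (peak read counts recovered by
#' overlap with the matching read track), missing values imputed to 0.
#'
#' @param bundle list with genes, chrom_lengths, tracks, peaks.
#' @param config `pipeline_config`.
#' @return imputed numeric feature matrix (genes x features).
#' @export
build_features <- function(bundle, config) {
  vocab <- default_vocabulary(config$genotypes, config$marks,
                              config$conditions)
  segs <- extract_all_segments(bundle$genes, bundle$chrom_lengths)
  tracks <- lapply(bundle$tracks, function(r) list(reads = r))
  seg_mat <- build_segment_feature_matrix(tracks, segs, vocab)
  peaks <- lapply(names(bundle$peaks), function(key)
    add_peak_counts(bundle$peaks[[key]], bundle$tracks[[key]]))
  names(peaks) <- names(bundle$peaks)
  peak_mat <- build_peak_feature_matrix(
    peaks, bundle$genes, vocab, max_distance = config$max_distance,
    m_threshold = config$m_threshold, p_threshold = config$p_threshold)
  impute_missing(cbind(seg_mat, peak_mat[rownames(seg_mat), , drop = FALSE]))
}

#' Run the full pipeline
#'
#' Stages: load (or simulate) inputs; extract features; label DEGs from the
#' responsive genotype's expression; stratified 80/20 split and k-fold CV
#' with in-fold feature selection; final model on the training set; rank the
#' top-expressed candidate pool by class probability; bin-precision cutoff;
#' cross-genotype direction agreement and hypergeometric overlap test. All
#' stage outputs land in `out_dir` together with a provenance record; a
#' rerun with the identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return list with `features`, `deg_labels`, `split`, `cv`, `test_metrics`,
#'   `ranked`, `precision_table`, `selected`, `report`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("epideg_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_stage(stage, conditionMessage(e)))
  }

  logf("load", "loading inputs")
  bundle <- run_stage("load", load_inputs(config))

  logf("features", "building feature matrix")
  features <- run_stage("features", build_features(bundle, config))
  write_tsv_table(data.table::data.table(gene_id = rownames(features),
                                         features),
                  file.path(out_dir, "features.tsv"))

  logf("deg_labels", "labeling DEGs from expression")
  resp <- config$responsive_genotype
  labs <- run_stage("deg_labels", {
    expr <- bundle$expression[[resp]]
    if (is.null(expr)) stop("no expression table for genotype ", resp)
    expr <- resolve_expression(expr)
    summary_resp <- expression_summary(expr, config$conditions)
    list(summary = summary_resp,
         degs = call_degs(summary_resp, config$fc_threshold,
                          config$rpkm_threshold))
  })
  write_tsv_table(labs$degs, file.path(out_dir, "deg_labels.tsv"))

  logf("ml_core", "split, cross-validation, final model")
  ml <- run_stage("ml_core", {
    labeled <- labs$degs[labs$degs$label != "none", ]
    labeled <- labeled[labeled$gene_id %in% rownames(features), ]
    if (nrow(labeled) < 4L * config$folds)
      stop("too few labeled DEGs (", nrow(labeled), ") for ",
           config$folds, "-fold CV")
    split <- stratified_split(labeled$gene_id, labeled$label,
                              config$split_fraction,
                              seed = derive_seed(config$seed, "split"))
    xtr <- features[split$train, , drop = FALSE]
    ytr <- labeled$label[match(split$train, labeled$gene_id)]
    cv <- cross_validate(config$classifier, xtr, ytr, folds = config$folds,
                         seed = derive_seed(config$seed, "cv"),
                         selector = config$selector,
                         top_fraction = config$top_fraction)
    ranking <- switch(config$selector,
      infogain = info_gain_ranking(xtr, ytr),
      relieff = relieff(xtr, ytr),
      cfs = NULL)
    feats <- if (is.null(ranking)) {
      s <- cfs_select(xtr, ytr)$features
      if (length(s)) s else colnames(features)
    } else select_top_fraction(ranking, ncol(features),
                               config$top_fraction)
    model <- train_classifier(config$classifier,
                              xtr[, feats, drop = FALSE], ytr,
                              seed = derive_seed(config$seed, "model"))
    xte <- features[split$test, feats, drop = FALSE]
    yte <- labeled$label[match(split$test, labeled$gene_id)]
    pte <- predict(model, xte)
    pred <- ifelse(pte >= 0.5, "up", "down")
    test_metrics <- compute_metrics(
      tp = sum(pred == "up" & yte == "up"),
      fp = sum(pred == "up" & yte != "up"),
      fn = sum(pred != "up" & yte == "up"),
      tn = sum(pred != "up" & yte != "up"))
    list(labeled = labeled, split = split, cv = cv, features = feats,
         model = model, test_metrics = test_metrics)
  })
  write_tsv_table(ml$cv$roc, file.path(out_dir, "roc_points.tsv"))

  logf("prediction", "candidate ranking and precision cutoff")
  sel <- run_stage("prediction", {
    pool <- select_top_expressed(labs$summary, config$expressed_fraction)
    pool <- intersect(pool, rownames(features))
    probs <- predict(ml$model, features[pool, ml$features, drop = FALSE])
    names(probs) <- pool
    ranked <- rank_and_bin(probs, config$bin_size)
    known <- labs$degs[labs$degs$label != "none",
                       c("gene_id", "label")]
    ptab <- bin_precision(ranked, known)
    selected <- precision_cutoff(ranked, ptab, config$precision_threshold)
    other <- setdiff(config$genotypes, resp)[1L]
    eval_set <- if (!is.na(other) && !is.null(bundle$expression[[other]])) {
      abs_fc_filter(expression_summary(
        resolve_expression(bundle$expression[[other]]), config$conditions),
        config$min_abs_fc)
    } else data.table::data.table(gene_id = character(0),
                                  direction = character(0))
    agree <- direction_agreement(selected, eval_set)
    known_in_pool <- intersect(known$gene_id, pool)
    ov <- length(intersect(selected$gene_id, known_in_pool))
    p_overlap <- if (nrow(selected) > 0L)
      overlap_test(nrow(selected), ov, length(known_in_pool), length(pool))
    else 1
    list(pool = pool, ranked = ranked, precision_table = ptab,
         selected = selected, agreement = agree, overlap = ov,
         overlap_p = p_overlap, known_in_pool = length(known_in_pool))
  })
  write_tsv_table(sel$ranked, file.path(out_dir, "predictions_ranked.tsv"))
  write_tsv_table(sel$precision_table,
                  file.path(out_dir, "precision_curve.tsv"))
  write_tsv_table(sel$selected, file.path(out_dir, "selected_genes.tsv"))

  provenance <- list(
    package = "epideg",
    version = as.character(utils::packageVersion("epideg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = digest::digest(unclass(config), algo = "sha256"))
  report <- list(
    n_genes = nrow(features), n_features = ncol(features),
    n_labeled = nrow(ml$labeled),
    n_train = length(ml$split$train), n_test = length(ml$split$test),
    selected_features = ml$features,
    cv = ml$cv$pooled[c("accuracy", "precision", "recall", "f_measure",
                        "f_weighted", "mcc")],
    cv_auc = ml$cv$auc,
    test = ml$test_metrics[c("accuracy", "f_measure", "mcc")],
    pool_size = length(sel$pool),
    n_selected = nrow(sel$selected),
    n_bins_selected = attr(sel$selected, "n_bins"),
    cumulative_precision = if (attr(sel$selected, "n_bins") > 0)
      sel$precision_table$cum_precision[attr(sel$selected, "n_bins")]
    else NA_real_,
    n_newly_predicted = sum(!sel$selected$gene_id %in%
                              ml$labeled$gene_id),
    tp = sel$agreement$tp, fp = sel$agreement$fp,
    overlap_known = sel$overlap, overlap_p_value = sel$overlap_p,
    provenance = provenance)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done", "run complete: ", out_dir)

  invisible(list(features = features, deg_labels = labs$degs,
                 split = ml$split, cv = ml$cv,
                 test_metrics = ml$test_metrics, model = ml$model,
                 selected_features = ml$features, ranked = sel$ranked,
                 precision_table = sel$precision_table,
                 selected = sel$selected, report = report,
                 provenance = provenance, out_dir = out_dir))
}
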