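#' Leave-one-subject-out splits
#'
#' One split per subject, in deterministic (sorted) order: that subject's
#' windows form the unlabeled target/test domain, all remaining subjects the
#' labeled source domain.
#'
#' @param subject_ids vector of unique subject identifiers.
#' @return list of splits, each `list(source, target)`.
#' @export
#' @examples
#' make_loso_splits(1:4)
make_loso_splits <- function(subject_ids) {
  ids <- sort(unique(subject_ids))
  if (length(ids) != length(subject_ids)) abort("duplicate subject ids", "invalid_data")
  if (length(ids) < 2L) abort("need at least 2 subjects", "invalid_data")
  lapply(ids, function(t) list(source = setdiff(ids, t), target = t))
}

#' Ablation variants
#'
#' The six model variants compared in the ablation study: single-branch
#' extractors (SAE = activity/CNN only, STE = topology/attention only), the
#' fused extractor without domain adaptation (SAE-STE), single branches with
#' domain-adversarial training (SAE-DANN, STE-DANN), and the full fused
#' adversarial model (DSP).
#'
#' @param id one of `"SAE"`, `"STE"`, `"SAE-STE"`, `"SAE-DANN"`,
#'   `"STE-DANN"`, `"DSP"`.
#' @return list with `id`, `use_activity_branch`, `use_topology_branch`,
#'   `use_dann`.
#' @export
ablation_variant <- function(id = c("DSP", "SAE", "STE", "SAE-STE", "SAE-DANN", "STE-DANN")) {
  id <- match.arg(id)
  flags <- switch(id,
    "SAE"      = c(TRUE, FALSE, FALSE),
    "STE"      = c(FALSE, TRUE, FALSE),
    "SAE-STE"  = c(TRUE, TRUE, FALSE),
    "SAE-DANN" = c(TRUE, FALSE, TRUE),
    "STE-DANN" = c(FALSE, TRUE, TRUE),
    "DSP"      = c(TRUE, TRUE, TRUE))
  list(id = id, use_activity_branch = flags[1], use_topology_branch = flags[2],
       use_dann = flags[3])
}

#' Train and evaluate one LOSO split
#'
#' Fits per-feature normalisation on the source windows, trains the variant's
#' model (transductively feeding the target subject's unlabeled windows to
#' the domain loss when DANN is on), and scores window-level predictions on
#' the target subject.
#'
#' @param ds a `cohort_dataset` from [cohort_features()].
#' @param split one element of [make_loso_splits()].
#' @param variant an [ablation_variant()].
#' @param satfem_cfg a [satfem_config()]; its branch switches are overridden
#'   by the variant.
#' @param train_cfg a [dann_config()].
#' @param layout,adjacency electrode layout and graph adjacency.
#' @param vote `"window"` (default) scores each 4-s window independently;
#'   `"trial"` takes a majority vote per trial before scoring.
#' @return list with `metrics` (a `metrics_report`), `model`, `norm`.
#' @export
run_loso_split <- function(ds, split, variant = ablation_variant("DSP"),
                           satfem_cfg = satfem_config(), train_cfg = dann_config(),
                           layout = electrode_layout(),
                           adjacency = build_adjacency(layout, "knn", 4),
                           vote = c("window", "trial")) {
  vote <- match.arg(vote)
  cfg <- satfem_cfg
  cfg$use_activity <- variant$use_activity_branch
  cfg$use_topology <- variant$use_topology_branch
  src_idx <- which(ds$subject %in% split$source)
  tgt_idx <- which(ds$subject == split$target)
  if (!length(src_idx) || !length(tgt_idx)) abort("empty LOSO domain", "invalid_data")

  norm <- fit_normalizer(ds$features[, , src_idx, drop = FALSE])
  source <- dataset_inputs(ds, src_idx, norm, layout)
  target_unlab <- dataset_inputs(ds, tgt_idx, norm, layout, keep_labels = FALSE)

  K <- max(ds$labels) + 1L
  model <- dann_model(K, cfg, adjacency = adjacency, in_size = layout$H,
                      seed = train_cfg$seed)
  dann_train(model, source,
             target = if (variant$use_dann) target_unlab else NULL,
             cfg = train_cfg, use_dann = variant$use_dann)

  pred <- dann_predict(model, target_unlab)
  y_true <- ds$labels[tgt_idx]
  y_pred <- pred$labels
  if (vote == "trial") {
    key <- paste(ds$subject[tgt_idx], y_true, cumsum(ds$window[tgt_idx] == 1))
    agg <- tapply(y_pred, key, function(v) as.integer(names(which.max(table(v)))))
    y_true <- tapply(y_true, key, function(v) v[1])
    y_pred <- agg[names(y_true)]
  }
  list(metrics = compute_metrics(y_true, y_pred, K), model = model, norm = norm)
}

#' Run a full LOSO experiment for one variant
#'
#' @inheritParams run_loso_split
#' @param seed base seed; split `i` trains with seed `derive_seed(seed,
#'   "split", i)`.
#' @return list with `per_split` (data.frame of accuracy / macro F1 / kappa
#'   per held-out subject), `summary` (mean and sd of each metric), and
#'   `reports` (the per-split `metrics_report`s).
#' @export
run_loso <- function(ds, variant = ablation_variant("DSP"),
                     satfem_cfg = satfem_config(), train_cfg = dann_config(),
                     layout = electrode_layout(),
                     adjacency = build_adjacency(layout, "knn", 4),
                     seed = train_cfg$seed, vote = "window") {
  splits <- make_loso_splits(unique(ds$subject))
  reports <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    tc <- train_cfg
    tc$seed <- derive_seed(seed, "split", i)
    reports[[i]] <- run_loso_split(ds, splits[[i]], variant, satfem_cfg, tc,
                                   layout, adjacency, vote)$metrics
  }
  per_split <- data.frame(
    target = vapply(splits, function(s) s$target, splits[[1]]$target),
    accuracy = vapply(reports, function(r) r$accuracy, 0),
    macro_f1 = vapply(reports, function(r) r$macro_f1, 0),
    kappa = vapply(reports, function(r) r$kappa, 0)
  )
  summary <- data.frame(
    metric = c("accuracy", "macro_f1", "kappa"),
    mean = c(mean(per_split$accuracy), mean(per_split$macro_f1), mean(per_split$kappa)),
    sd = c(stats::sd(per_split$accuracy), stats::sd(per_split$macro_f1), stats::sd(per_split$kappa))
  )
  list(per_split = per_split, summary = summary, reports = reports, variant = variant$id)
}

#' Run the ablation study
#'
#' Runs LOSO for each requested variant over one or more seeds and collects
#' mean-over-splits metrics per (variant, seed) plus a per-variant summary
#' (median over seeds of the mean accuracy, as the seed-robust comparison
#' statistic).
#'
#' @inheritParams run_loso
#' @param variants character vector of variant ids.
#' @param seeds integer vector of seeds.
#' @return list with `runs` (data.frame: variant, seed, mean accuracy/F1/
#'   kappa over splits) and `summary` (per-variant median over seeds).
#' @export
run_ablation <- function(ds, variants = c("SAE", "STE", "SAE-STE", "SAE-DANN",
                                          "STE-DANN", "DSP"),
                         seeds = 1L, satfem_cfg = satfem_config(),
                         train_cfg = dann_config(),
                         layout = electrode_layout(),
                         adjacency = build_adjacency(layout, "knn", 4),
                         vote = "window") {
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      res <- run_loso(ds, ablation_variant(v), satfem_cfg, train_cfg,
                      layout, adjacency, seed = as.integer(s), vote = vote)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = as.integer(s),
        accuracy = mean(res$per_split$accuracy),
        macro_f1 = mean(res$per_split$macro_f1),
        kappa = mean(res$per_split$kappa),
        accuracy_sd = stats::sd(res$per_split$accuracy)
      )
    }
  }
  runs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(runs, runs$variant), function(g) {
    data.frame(variant = g$variant[1],
               median_accuracy = stats::median(g$accuracy),
               median_macro_f1 = stats::median(g$macro_f1),
               median_kappa = stats::median(g$kappa),
               n_seeds = nrow(g))
  }))
  summary <- summary[match(variants, summary$variant), ]
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}
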