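# Shared desk-scale study conditions and lazily built, cached fixtures.
# All sizes here are the package's desk-scale test conditions: 64 px ROIs
# randomly cropped to a 56 px network input (the same 0.9 crop ratio as the
# full-scale 250 -> 224 protocol, and 56 / 2^3 gives the same 7x7 feature
# map), a 3-pool-stage mini backbone, and Adam at 1e-3. Small enough to
# train on one CPU; large enough that the planted failure morphology is the
# only thing a model can learn.

desk_synth_config <- function(effect_size, seed) {
  synth_config(img_size = 64, nucleus_density = 14,
               nucleus_radius_nonfailure = c(2.4, 0.5),
               nucleus_radius_failure = c(3.2, 0.6),
               effect_size = effect_size, seed = seed)
}

desk_spec <- function() backbone_spec("mini", input_size = 56, n_pool_stages = 3)

desk_train_config <- function(epochs, seed) {
  train_config(epochs = epochs, learning_rate = 1e-3, batch_size = 32,
               crop = TRUE, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A 209-case x 11-ROI manifest CSV (labels only, no images) mirroring the
# reference cohort: 94 failure, 115 non-failure.
fx_cohort_manifest <- function() fixture("cohort", function() {
  n <- 209
  labels <- rep(c("failure", "non_failure"), c(94, 115))
  ids <- sprintf("case_%03d", seq_len(n))
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(case_id = ids[i], label = labels[i],
               roi_path = sprintf("images/%s_roi%02d.png", ids[i], 1:11))
  }))
  path <- file.path(tempdir(), "cohort_manifest.csv")
  utils::write.csv(df, path, row.names = FALSE)
  load_manifest(path)
})

# Training fixture: 40 training / 20 validation cases, mini backbone,
# <= 10 epochs; a further 15 cases held out for localization / embedding
# checks. Effect size 2 is the learnability/localization condition (6
# epochs suffice); effect size 1 is the subtler feature-space condition
# used for the trained-vs-random embedding contrast (8 epochs); effect
# size 0 is the null.
fx_trained <- function(effect_size) {
  fixture(paste0("trained_e", effect_size), function() {
    cfg <- desk_synth_config(effect_size, 11)
    ds <- generate_dataset(75, 0.5, cfg, out_dir = NULL)
    man <- ds$manifest
    part <- split_dev_test(man, 60, seed = 1)
    dev <- part$dev_case_ids
    labs <- manifest_labels_of(man, dev)
    set.seed(2)
    val <- c(sample(dev[labs == "failure"], 10),
             sample(dev[labs == "non_failure"], 10))
    trn <- setdiff(dev, val)
    rs_tr <- roi_set_of(man, trn, ds$images)
    rs_va <- roi_set_of(man, val, ds$images)
    model <- build_model(desk_spec(), seed = 3)
    epochs <- if (effect_size == 1) 8L else 6L
    fit <- train_cnn(model, rs_tr, rs_va, desk_train_config(epochs, seed = 7))
    val_auc <- roc_auc(predict(fit, rs_va$images)$p_F, rs_va$labels)$auc
    list(fit = fit, ds = ds, manifest = man, partition = part,
         train_cases = trn, val_cases = val, val_set = rs_va,
         val_auc = val_auc)
  })
}

# Ensemble fixtures: effect size 1 exercises the ensemble-vs-members
# property with deliberately weak sub-models; effect size 2 is the
# end-to-end pipeline condition (60 simulated cases).
fx_ensemble <- function(effect_size) {
  fixture(paste0("ensemble_e", effect_size), function() {
    seed0 <- if (effect_size == 1) 50L else 70L
    n_cases <- if (effect_size == 1) 40L else 60L
    n_dev <- if (effect_size == 1) 25L else 30L
    epochs <- if (effect_size == 1) 4L else 8L
    cfg <- desk_synth_config(effect_size, seed0)
    t0 <- proc.time()
    ds <- generate_dataset(n_cases, 0.5, cfg, out_dir = NULL)
    man <- ds$manifest
    part <- split_dev_test(man, n_dev, seed = seed0 + 1)
    folds <- assign_folds(part, man, K = 5, seed = seed0 + 2)
    ens <- run_ensemble(man, part, folds, enumerate_subsets(5, 3),
                        desk_train_config(epochs, seed = seed0 + 3),
                        desk_spec(), images = ds$images)
    elapsed <- unname((proc.time() - t0)[3])
    tp <- ens$predictions[ens$predictions$split == "test", ]
    agg <- stats::aggregate(p_F ~ case_id + roi_index + label, tp, mean)
    sub_aucs <- vapply(names(ens$models), function(mid) {
      d <- tp[tp$model_id == mid, ]
      roc_auc(d$p_F, d$label)$auc
    }, 0)
    list(ens = ens, ds = ds, manifest = man, partition = part,
         test_pred = tp, test_agg = agg, sub_aucs = sub_aucs,
         elapsed = elapsed)
  })
}

# Small conveniences over non-exported internals.
manifest_labels_of <- function(man, ids) {
  unname(vapply(man$cases[ids], `[[`, "", "label"))
}

roi_set_of <- function(man, ids, images = NULL) {
  embscope:::manifest_roi_set(man, ids, images)
}

# Fixed "simple classifier" for separability checks: the densest dark
# window in the ROI (box-filtered dark-pixel mask), a crude proxy for the
# largest nuclear cross-section.
clump_score <- function(img, thr = 0.55, r = 3L) {
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  dark <- (g < thr) * 1
  S <- nrow(dark)
  P <- matrix(0, S + 1, S + 1)
  P[-1, -1] <- apply(apply(dark, 2, cumsum), 1, cumsum)
  w <- 2L * r + 1L
  i1 <- seq_len(S - w + 1L)
  i2 <- i1 + w
  box <- P[i2, i2] - P[i1, i2] - P[i2, i1] + P[i1, i1]
  max(box) / w^2
}

# Centred square crop of a matrix (e.g. a lesion mask), matching the
# centre crop the network applies to its input.
center_crop_mat <- function(m, size) {
  r0 <- (nrow(m) - size) %/% 2L
  c0 <- (ncol(m) - size) %/% 2L
  m[r0 + seq_len(size), c0 + seq_len(size), drop = FALSE]
}

# Mean silhouette width of the class labels in a 2-D embedding.
label_silhouette <- function(emb, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(cbind(emb$x, emb$y)))
  mean(sil[, 3])
}
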