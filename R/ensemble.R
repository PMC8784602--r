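# The C(K,m) multi-model ensemble: every m-element choice of training folds
# defines one sub-model, the complementary folds are its validation set, and
# each development case is predicted only by the sub-models that never
# trained on it. With K = 5 and m = 3 this yields 10 sub-models and every
# fold is validated C(K-1, m) = 4 times.

#' Enumerate the C(K,m) train/validation fold subsets
#'
#' All m-element subsets of folds 1..K in lexicographic order; each subset's
#' validation folds are its complement.
#'
#' @param K number of folds (default 5)
#' @param m training folds per sub-model, `1 <= m < K` (default 3)
#' @return an `"ensemble_design"`: list with `K`, `m`, and `subsets` — a
#'   list of `list(train_folds, val_folds)` of length `choose(K, m)`
#' @examples
#' length(enumerate_subsets(5, 3)$subsets)  # 10
#' @export
enumerate_subsets <- function(K = 5L, m = 3L) {
  K <- as.integer(K)
  m <- as.integer(m)
  if (m < 1L || m >= K) stop("m must satisfy 1 <= m < K")
  combs <- utils::combn(K, m)
  subsets <- lapply(seq_len(ncol(combs)), function(j) {
    tr <- combs[, j]
    list(train_folds = tr, val_folds = setdiff(seq_len(K), tr))
  })
  structure(list(K = K, m = m, subsets = subsets), class = "ensemble_design")
}

#' @export
print.ensemble_design <- function(x, ...) {
  cat("C(", x$K, ",", x$m, ") ensemble design: ", length(x$subsets),
      " sub-models, each fold validated ", choose(x$K - 1, x$m), " times\n",
      sep = "")
  invisible(x)
}

#' How many sub-models validate each fold
#'
#' A fold validates a sub-model exactly when it is not among its training
#' folds, so every fold is validated `choose(K - 1, m)` times.
#'
#' @param design an [enumerate_subsets()] design
#' @return named integer vector, one count per fold
#' @export
validation_coverage <- function(design) {
  counts <- vapply(seq_len(design$K), function(f) {
    sum(vapply(design$subsets,
               function(s) !(f %in% s$train_folds), logical(1)))
  }, integer(1))
  names(counts) <- paste0("fold", seq_len(design$K))
  counts
}

#' Assemble a per-case prediction grid
#'
#' Rows are the case's ROIs, columns the contributing sub-models. The
#' constructor enforces the no-leakage invariant: a sub-model that trained
#' on the case may not contribute a column.
#'
#' @param case_id the case
#' @param mat numeric matrix of failure probabilities (ROIs x models)
#' @param model_ids column labels (sub-model identifiers)
#' @param trained_on list mapping each model id to the case ids it trained on
#' @param label the case's true label
#' @return a `"prediction_grid"` matrix with case metadata attributes
#' @export
prediction_grid <- function(case_id, mat, model_ids, trained_on, label) {
  mat <- as.matrix(mat)
  if (any(mat < 0 | mat > 1)) stop("grid entries must be probabilities")
  if (length(model_ids) != ncol(mat)) stop("one model id per column required")
  leaky <- vapply(model_ids,
                  function(mid) case_id %in% trained_on[[mid]], logical(1))
  if (any(leaky)) {
    stop("leakage: sub-model(s) ", paste(model_ids[leaky], collapse = ", "),
         " trained on case ", case_id)
  }
  structure(mat, case_id = case_id, model_ids = model_ids, label = label,
            class = c("prediction_grid", "matrix"))
}

#' Average a prediction grid over its sub-models
#'
#' Row-wise arithmetic mean of the per-model failure probabilities — the
#' ensemble's per-ROI score.
#'
#' @param grid a [prediction_grid()] (or bare matrix, ROIs x models)
#' @return numeric vector of per-ROI mean failure probabilities
#' @export
ensemble_average <- function(grid) {
  if (!length(grid)) stop("empty prediction grid")
  rowMeans(unclass(grid))
}

#' Train and apply the C(K,m) multi-model ensemble
#'
#' Trains one sub-model per fold subset (training folds as listed,
#' complementary folds as validation) with per-subset derived seeds, then
#' assembles prediction grids: development cases collect predictions only
#' from the sub-models that never trained on them (`choose(K-1, m)`
#' columns); held-out test cases collect all `choose(K, m)` sub-models'
#' predictions.
#'
#' @param manifest an `"emb_manifest"`
#' @param partition an `"emb_partition"`
#' @param folds an `"emb_folds"` covering the development cases
#' @param design an [enumerate_subsets()] design with `K == folds$K`
#' @param cfg a [train_config()]
#' @param spec a [backbone_spec()] for the sub-models
#' @param images optional in-memory image store (named by roi path), as
#'   returned by [generate_dataset()] in-memory mode
#' @param verbose print per-sub-model progress
#' @return an `"emb_ensemble"`: sub-models, per-case prediction grids, the
#'   long-format ROI prediction table, and the design/fold bookkeeping
#' @export
run_ensemble <- function(manifest, partition, folds, design = enumerate_subsets(),
                         cfg = train_config(), spec = backbone_spec("mini"),
                         images = NULL, verbose = FALSE) {
  if (design$K != folds$K) stop("design K and fold assignment K differ")
  dev_ids <- partition$dev_case_ids
  test_ids <- partition$test_case_ids
  if (!all(dev_ids %in% names(folds$fold_of))) {
    stop("fold assignment does not cover the development set")
  }
  dev_set <- manifest_roi_set(manifest, dev_ids, images)
  test_set <- manifest_roi_set(manifest, test_ids, images)
  n_models <- length(design$subsets)
  model_ids <- sprintf("m%02d", seq_len(n_models))
  models <- vector("list", n_models)
  trained_on <- list()
  pred_dev <- matrix(NA_real_, length(dev_set$labels), n_models)
  pred_test <- matrix(NA_real_, length(test_set$labels), n_models)
  for (i in seq_len(n_models)) {
    sub <- design$subsets[[i]]
    tr_cases <- dev_ids[folds$fold_of[dev_ids] %in% sub$train_folds]
    va_cases <- dev_ids[folds$fold_of[dev_ids] %in% sub$val_folds]
    trained_on[[model_ids[i]]] <- tr_cases
    tr_ix <- dev_set$case_ids %in% tr_cases
    va_ix <- dev_set$case_ids %in% va_cases
    sub_train <- roi_set(dev_set$images[tr_ix], dev_set$labels[tr_ix],
                         dev_set$case_ids[tr_ix])
    sub_val <- roi_set(dev_set$images[va_ix], dev_set$labels[va_ix],
                       dev_set$case_ids[va_ix])
    cfg_i <- cfg
    cfg_i$seed <- mix_seed(cfg$seed, i)
    model <- build_model(spec, seed = mix_seed(cfg$seed, i, 1L))
    if (verbose) {
      message("training sub-model ", model_ids[i], " on folds ",
              paste(sub$train_folds, collapse = ","))
    }
    model <- train_cnn(model, sub_train, sub_val, cfg_i)
    models[[i]] <- model
    pred_dev[, i] <- predict(model, dev_set$images)$p_F
    pred_test[, i] <- predict(model, test_set$images)$p_F
  }
  names(models) <- model_ids
  grids <- list()
  long <- list()
  add_case <- function(cid, rset, preds, split) {
    ix <- which(rset$case_ids == cid)
    lab <- unname(rset$labels[ix[1]])
    cols <- if (split == "dev") {
      which(vapply(model_ids, function(mid) {
        !(cid %in% trained_on[[mid]])
      }, logical(1)))
    } else {
      seq_len(n_models)
    }
    g <- prediction_grid(cid, preds[ix, cols, drop = FALSE],
                         model_ids[cols], trained_on, lab)
    grids[[cid]] <<- g
    long[[cid]] <<- data.frame(case_id = cid,
                               roi_index = rep(seq_along(ix), length(cols)),
                               model_id = rep(model_ids[cols], each = length(ix)),
                               p_F = as.vector(preds[ix, cols]),
                               label = lab, split = split)
  }
  for (cid in dev_ids) add_case(cid, dev_set, pred_dev, "dev")
  for (cid in test_ids) add_case(cid, test_set, pred_test, "test")
  structure(list(models = models, grids = grids,
                 predictions = do.call(rbind, unname(long)),
                 design = design, folds = folds, partition = partition,
                 trained_on = trained_on),
            class = "emb_ensemble")
}

#' @export
print.emb_ensemble <- function(x, ...) {
  print(x$design)
  cat("  dev cases:", length(x$partition$dev_case_ids),
      "| test cases:", length(x$partition$test_case_ids), "\n")
  invisible(x)
}
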