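# ROI -> case aggregation and performance reporting: case risk scores,
# confusion matrices, ROC/AUC (trapezoid and rank forms), heat-grid figure.

#' Aggregate ROI probabilities into a case-level risk score
#'
#' The case score is the proportion of the case's ROIs whose predicted
#' failure probability exceeds the threshold.
#'
#' @param roi_probs non-empty vector of per-ROI failure probabilities
#' @param threshold ROI positivity threshold in (0, 1) (default 0.5)
#' @return fraction in \[0, 1\]
#' @examples
#' case_score(c(0.9, 0.2, 0.8), 0.5)  # 2/3
#' @export
case_score <- function(roi_probs, threshold = 0.5) {
  if (!length(roi_probs)) stop("empty ROI probability vector")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mean(roi_probs > threshold)
}

#' Two-class confusion matrix at a score threshold
#'
#' Predicts failure when `score > threshold`, then tallies truth (rows,
#' N then F) against prediction (columns).
#'
#' @param scores numeric scores (probabilities or case risk scores)
#' @param labels `"failure"` / `"non_failure"`, aligned with `scores`
#' @param threshold decision threshold (default 0.5)
#' @return 2 x 2 integer matrix, rows truth `N`,`F`, columns predicted
#' @export
confusion_matrix <- function(scores, labels, threshold = 0.5) {
  check_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  truth <- factor(ifelse(labels == "failure", "F", "N"), levels = c("N", "F"))
  pred <- factor(ifelse(scores > threshold, "F", "N"), levels = c("N", "F"))
  m <- table(truth = truth, predicted = pred)
  matrix(as.integer(m), 2, 2,
         dimnames = list(truth = c("N", "F"), predicted = c("N", "F")))
}

#' Empirical ROC curve and AUC
#'
#' Sweeps all distinct score thresholds, treating tied scores as a single
#' simultaneous threshold crossing (diagonal ROC segments), and integrates
#' by the trapezoidal rule. The same quantity is also computed as the
#' tie-corrected Mann-Whitney rank statistic and both are returned; they
#' agree to numerical precision.
#'
#' @param scores numeric scores (higher = more failure-like)
#' @param labels `"failure"` / `"non_failure"`, aligned with `scores`
#' @return list with `roc` (data frame `fpr`, `tpr`, `threshold`), `auc`
#'   (trapezoidal) and `auc_rank` (Mann-Whitney form)
#' @export
roc_auc <- function(scores, labels) {
  check_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pos <- labels == "failure"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  r <- rank(scores)
  auc_rank <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, auc = auc, auc_rank = auc_rank)
}

#' Build an evaluation report at ROI or case level
#'
#' Bundles the confusion matrix at the given threshold with the ROC curve
#' and AUC.
#'
#' @param scores numeric scores
#' @param labels aligned labels
#' @param level `"roi"` or `"case"` (descriptive)
#' @param threshold confusion-matrix threshold (default 0.5)
#' @return an `"emb_eval"` list: `level`, `confusion`, `roc`, `auc`,
#'   `threshold`
#' @export
eval_report <- function(scores, labels, level = c("roi", "case"),
                        threshold = 0.5) {
  level <- match.arg(level)
  ra <- roc_auc(scores, labels)
  structure(list(level = level,
                 confusion = confusion_matrix(scores, labels, threshold),
                 roc = ra$roc, auc = ra$auc, threshold = threshold),
            class = "emb_eval")
}

#' @export
print.emb_eval <- function(x, ...) {
  cat(toupper(x$level), "-level evaluation (threshold ", x$threshold, ")\n",
      sep = "")
  print(x$confusion)
  cat("AUC:", format(x$auc, digits = 4), "\n")
  invisible(x)
}

# green -> red colormap over [0, 1]
risk_palette <- function(v) grDevices::rgb(v, 1 - v, 0)

#' Render per-case prediction grids as a heat figure
#'
#' One block per case (rows = ROIs, columns = sub-models), failure
#' probability mapped green (low) to red (high), cases grouped by true
#' label.
#'
#' @param grids list of [prediction_grid()]s
#' @param file optional PNG path
#' @param ncol_cases cases per figure row
#' @return (invisibly) the list of per-case probability matrices in plotted
#'   order
#' @export
render_heat_grid <- function(grids, file = NULL, ncol_cases = 10L) {
  if (!length(grids)) stop("no prediction grids to render")
  labs <- vapply(grids, function(g) attr(g, "label"), "")
  ordv <- order(labs != "failure")
  grids <- grids[ordv]
  labs <- labs[ordv]
  if (!is.null(file)) {
    grDevices::png(file, width = 160 * ncol_cases,
                   height = 160 * ceiling(length(grids) / ncol_cases))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  nrow_fig <- ceiling(length(grids) / ncol_cases)
  op <- graphics::par(mfrow = c(nrow_fig, ncol_cases),
                      mar = c(0.4, 0.4, 1.2, 0.4))
  on.exit(graphics::par(op), add = TRUE)
  blocks <- lapply(grids, function(g) {
    m <- unclass(g)
    graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                    col = risk_palette(seq(0, 1, length.out = 64)),
                    zlim = c(0, 1), axes = FALSE,
                    main = paste0(attr(g, "case_id"), " (",
                                  substr(attr(g, "label"), 1, 1), ")"),
                    cex.main = 0.7)
    m
  })
  invisible(blocks)
}
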