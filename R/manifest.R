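# Case/ROI bookkeeping: manifest reading, case-level dev/test partitioning,
# stratified fold assignment, ROI counting. Everything here operates on case
# ids, never on individual ROIs, which is what guarantees that no case ever
# straddles a training/evaluation boundary.

new_manifest <- function(cases, dir = ".") {
  structure(list(cases = cases, dir = dir), class = "emb_manifest")
}

#' Read a case manifest CSV
#'
#' The manifest has one row per ROI with columns `case_id`, `label`
#' (`failure` / `non_failure`) and `roi_path` (relative to the manifest's
#' directory); an optional `subtype` column (`ischemic`,
#' `idiopathic_dilated`, `donor`) is carried through. Rows are grouped by
#' `case_id` into case records, preserving ROI order. Each case nominally
#' contributes 11 ROIs; other counts are accepted with a warning.
#'
#' @param path path to the CSV file
#' @return an object of class `"emb_manifest"`: a list of case records
#'   (`case_id`, `label`, `roi_paths`, `subtype`) plus the manifest directory
#' @export
load_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("case_id", "label", "roi_path")
  if (!all(req %in% names(df))) {
    stop("manifest must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no cases in manifest ", path)
  check_labels(df$label)
  dup <- df$roi_path[duplicated(df$roi_path)]
  if (length(dup)) {
    stop("duplicate roi_path(s): ", paste(utils::head(dup, 3), collapse = ", "))
  }
  ids <- unique(df$case_id)
  cases <- lapply(ids, function(id) {
    rows <- df[df$case_id == id, , drop = FALSE]
    lab <- unique(rows$label)
    if (length(lab) != 1) stop("case ", id, " has conflicting labels")
    list(case_id = as.character(id), label = lab, roi_paths = rows$roi_path,
         subtype = if ("subtype" %in% names(rows)) rows$subtype[1] else NA_character_)
  })
  names(cases) <- ids
  nroi <- vapply(cases, function(cs) length(cs$roi_paths), 0L)
  if (any(nroi != 11L)) {
    warning(sum(nroi != 11L), " case(s) do not have 11 ROIs; ",
            "aggregation will use the actual counts")
  }
  new_manifest(cases, dir = dirname(path))
}

#' @export
print.emb_manifest <- function(x, ...) {
  labs <- vapply(x$cases, `[[`, "", "label")
  cat("EMB manifest:", length(x$cases), "cases (",
      sum(labs == "failure"), "failure /", sum(labs == "non_failure"),
      "non-failure ),", sum(count_rois(x, names(x$cases))), "ROIs\n")
  invisible(x)
}

#' @export
as.data.frame.emb_manifest <- function(x, ...) {
  do.call(rbind, lapply(x$cases, function(cs) {
    data.frame(case_id = cs$case_id, label = cs$label, roi_path = cs$roi_paths,
               subtype = cs$subtype, row.names = NULL)
  }))
}

manifest_labels <- function(manifest, case_ids = names(manifest$cases)) {
  vapply(manifest$cases[case_ids], `[[`, "", "label")
}

# Absolute ROI paths for the given cases, in manifest order.
manifest_paths <- function(manifest, case_ids = names(manifest$cases)) {
  unlist(lapply(manifest$cases[case_ids], function(cs) {
    file.path(manifest$dir, cs$roi_paths)
  }), use.names = FALSE)
}

check_case_ids <- function(manifest, case_ids) {
  unknown <- setdiff(case_ids, names(manifest$cases))
  if (length(unknown)) {
    stop("unknown case id(s): ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  invisible(case_ids)
}

#' Count ROIs over a set of cases
#'
#' @param manifest an `"emb_manifest"`
#' @param case_ids case ids to count over (must all exist in the manifest)
#' @return integer total ROI count
#' @examples
#' # a 104-case development set of 11-ROI cases counts 1144 ROIs
#' @export
count_rois <- function(manifest, case_ids) {
  if (!length(case_ids)) return(0L)
  check_case_ids(manifest, case_ids)
  sum(vapply(manifest$cases[case_ids], function(cs) length(cs$roi_paths), 0L))
}

#' Split cases into development and held-out test sets
#'
#' Case-level partition: exactly `n_dev` cases are drawn into the
#' development set (training/validation or ensemble folds) and the rest form
#' the held-out test set. ROIs never cross the boundary because the draw is
#' over case ids. Deterministic given `seed`.
#'
#' @param manifest an `"emb_manifest"`
#' @param n_dev number of development cases, `0 < n_dev < n_cases`
#' @param seed integer seed
#' @return an `"emb_partition"`: `dev_case_ids`, `test_case_ids`, `seed`
#' @export
split_dev_test <- function(manifest, n_dev, seed = 0L) {
  ids <- names(manifest$cases)
  if (n_dev <= 0 || n_dev >= length(ids)) {
    stop("n_dev must satisfy 0 < n_dev < ", length(ids))
  }
  set.seed(seed)
  dev <- sort(sample(ids, n_dev))
  structure(list(dev_case_ids = dev, test_case_ids = sort(setdiff(ids, dev)),
                 seed = as.integer(seed)),
            class = "emb_partition")
}

#' @export
print.emb_partition <- function(x, ...) {
  cat("Case partition: dev", length(x$dev_case_ids), "/ test",
      length(x$test_case_ids), "(seed", x$seed, ")\n")
  invisible(x)
}

#' Assign development cases to cross-validation folds
#'
#' Stratified case-level fold assignment: within each label the cases are
#' shuffled (by `seed`) and dealt round-robin over the `K` folds, so per-label
#' fold sizes differ by at most one. With 57 non-failure and 47 failure
#' development cases and `K = 5` this reproduces the
#' (12,12,11,11,11) / (10,10,9,9,9) fold pattern up to fold relabelling.
#'
#' @param partition an `"emb_partition"`
#' @param manifest an `"emb_manifest"`
#' @param K number of folds (>= 2, and at most the number of dev cases of the
#'   rarer label)
#' @param seed integer seed
#' @param stratified shuffle-within-label round-robin when `TRUE` (default);
#'   plain shuffled deal otherwise
#' @return an `"emb_folds"`: `K`, named integer vector `fold_of`, `stratified`
#' @export
assign_folds <- function(partition, manifest, K = 5L, seed = 0L,
                         stratified = TRUE) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2 (no held-out fold is possible otherwise)")
  dev <- partition$dev_case_ids
  check_case_ids(manifest, dev)
  labs <- manifest_labels(manifest, dev)
  set.seed(seed)
  fold_of <- integer(0)
  groups <- if (stratified) split(dev, labs) else list(all = dev)
  for (g in groups) {
    if (length(g) < K) {
      stop("K = ", K, " exceeds the ", length(g), " dev case(s) of some label")
    }
    g <- sample(g)
    f <- ((seq_along(g) - 1L) %% K) + 1L
    fold_of[g] <- f
  }
  structure(list(K = K, fold_of = fold_of[dev], stratified = stratified),
            class = "emb_folds")
}

#' @export
print.emb_folds <- function(x, ...) {
  cat("Fold assignment: K =", x$K,
      if (x$stratified) "(stratified)" else "(unstratified)", "\n")
  print(table(fold = x$fold_of))
  invisible(x)
}

#' Serialize / read partition and fold files
#'
#' Partitions are stored as `{"dev": [...], "test": [...], "seed": s}` and
#' fold assignments as `{"K": k, "fold_of": {...}, "stratified": b}`.
#'
#' @param x an `"emb_partition"` or `"emb_folds"`
#' @param path JSON file path
#' @name partition-io
#' @export
write_partition <- function(x, path) {
  jsonlite::write_json(list(dev = x$dev_case_ids, test = x$test_case_ids,
                            seed = x$seed),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname partition-io
#' @export
read_partition <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(dev_case_ids = j$dev, test_case_ids = j$test,
                 seed = as.integer(j$seed)),
            class = "emb_partition")
}

#' @rdname partition-io
#' @export
write_folds <- function(x, path) {
  jsonlite::write_json(list(K = x$K, fold_of = as.list(x$fold_of),
                            stratified = x$stratified),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname partition-io
#' @export
read_folds <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(K = as.integer(j$K), fold_of = unlist(j$fold_of),
                 stratified = isTRUE(j$stratified)),
            class = "emb_folds")
}
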