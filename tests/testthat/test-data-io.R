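test_that("manifest loading groups ROIs by case and validates input", {
  man <- fx_cohort_manifest()
  expect_s3_class(man, "emb_manifest")
  expect_length(man$cases, 209)
  expect_identical(count_rois(man, names(man$cases)), 2299L)
  labs <- manifest_labels_of(man, names(man$cases))
  expect_identical(sum(labs == "failure"), 94L)
  expect_identical(sum(labs == "non_failure"), 115L)
  expect_identical(man$cases[[1]]$roi_paths,
                   sprintf("images/case_001_roi%02d.png", 1:11))

  # degenerate and malformed inputs
  empty <- file.path(tempdir(), "empty.csv")
  utils::write.csv(data.frame(case_id = character(), label = character(),
                              roi_path = character()),
                   empty, row.names = FALSE)
  expect_error(load_manifest(empty), "no cases")

  dup <- file.path(tempdir(), "dup.csv")
  utils::write.csv(data.frame(case_id = c("a", "a"), label = "failure",
                              roi_path = "x.png"),
                   dup, row.names = FALSE)
  expect_error(load_manifest(dup), "duplicate")

  badlab <- file.path(tempdir(), "badlab.csv")
  utils::write.csv(data.frame(case_id = "a", label = "sick",
                              roi_path = "x.png"),
                   badlab, row.names = FALSE)
  expect_error(load_manifest(badlab), "unknown label")

  single <- file.path(tempdir(), "single.csv")
  utils::write.csv(data.frame(case_id = "a", label = "failure",
                              roi_path = "x.png"),
                   single, row.names = FALSE)
  expect_warning(m1 <- load_manifest(single), "11 ROIs")
  expect_length(m1$cases, 1)
})

test_that("dev/test split is case-level, exact and seed-deterministic", {
  man <- fx_cohort_manifest()
  part <- split_dev_test(man, 104, seed = 0)
  expect_length(part$dev_case_ids, 104)
  expect_length(part$test_case_ids, 105)
  expect_identical(part, split_dev_test(man, 104, seed = 0))
  expect_false(identical(part$dev_case_ids,
                         split_dev_test(man, 104, seed = 1)$dev_case_ids))
  expect_error(split_dev_test(man, 209, seed = 0), "n_dev")
  expect_error(split_dev_test(man, 0, seed = 0), "n_dev")

  # disjointness and coverage over many seeds
  all_ids <- sort(names(man$cases))
  for (s in 1:100) {
    p <- split_dev_test(man, 104, seed = s)
    expect_length(intersect(p$dev_case_ids, p$test_case_ids), 0)
    expect_identical(sort(c(p$dev_case_ids, p$test_case_ids)), all_ids)
  }
})

test_that("ROI counts are conserved across partitions and sub-splits", {
  man <- fx_cohort_manifest()
  part <- split_dev_test(man, 104, seed = 0)
  expect_identical(count_rois(man, part$dev_case_ids), 1144L)
  expect_identical(count_rois(man, part$test_case_ids), 1155L)
  expect_identical(count_rois(man, part$dev_case_ids) +
                     count_rois(man, part$test_case_ids), 2299L)
  # 70/34 training/validation sub-split of the development set
  trn <- part$dev_case_ids[1:70]
  val <- part$dev_case_ids[71:104]
  expect_identical(count_rois(man, trn), 770L)
  expect_identical(count_rois(man, val), 374L)
  expect_identical(count_rois(man, character(0)), 0L)
  expect_error(count_rois(man, "nope"), "unknown case")
})

test_that("stratified fold assignment reproduces the reference fold pattern", {
  man <- fx_cohort_manifest()
  # engineer a 57 non-failure + 47 failure development set
  labs <- manifest_labels_of(man, names(man$cases))
  dev <- c(names(man$cases)[labs == "non_failure"][1:57],
           names(man$cases)[labs == "failure"][1:47])
  part <- structure(list(dev_case_ids = dev,
                         test_case_ids = setdiff(names(man$cases), dev),
                         seed = 0L),
                    class = "emb_partition")
  folds <- assign_folds(part, man, K = 5, seed = 0)
  expect_setequal(unique(folds$fold_of), 1:5)
  per_label <- table(manifest_labels_of(man, names(folds$fold_of)),
                     folds$fold_of)
  expect_identical(sort(as.integer(per_label["non_failure", ])),
                   c(11L, 11L, 11L, 12L, 12L))
  expect_identical(sort(as.integer(per_label["failure", ])),
                   c(9L, 9L, 9L, 10L, 10L))
  expect_identical(sort(as.integer(table(folds$fold_of))),
                   c(20L, 20L, 20L, 22L, 22L))

  expect_error(assign_folds(part, man, K = 1), "K must be")
  expect_error(assign_folds(part, man, K = 48), "exceeds")
})

test_that("fold sizes per label never differ by more than one", {
  man <- fx_cohort_manifest()
  for (s in 1:20) {
    set.seed(s)
    n_dev <- sample(30:150, 1)
    K <- sample(2:6, 1)
    part <- split_dev_test(man, n_dev, seed = s)
    labs <- manifest_labels_of(man, part$dev_case_ids)
    if (min(table(labs)) < K) next
    folds <- assign_folds(part, man, K = K, seed = s)
    per_label <- table(manifest_labels_of(man, names(folds$fold_of)),
                       folds$fold_of)
    expect_true(all(apply(per_label, 1, function(x) max(x) - min(x) <= 1)))
  }
  # exact divisibility: 5 + 5 cases over K = 5 gives one of each per fold
  labs <- manifest_labels_of(man, names(man$cases))
  dev10 <- c(names(man$cases)[labs == "failure"][1:5],
             names(man$cases)[labs == "non_failure"][1:5])
  p10 <- structure(list(dev_case_ids = dev10,
                        test_case_ids = setdiff(names(man$cases), dev10),
                        seed = 0L),
                   class = "emb_partition")
  f10 <- assign_folds(p10, man, K = 5, seed = 1)
  per_label <- table(manifest_labels_of(man, names(f10$fold_of)), f10$fold_of)
  expect_true(all(per_label == 1))
})

test_that("partition and fold files round-trip through JSON", {
  man <- fx_cohort_manifest()
  part <- split_dev_test(man, 104, seed = 3)
  pf <- file.path(tempdir(), "partition.json")
  write_partition(part, pf)
  expect_equal(read_partition(pf), part)
  folds <- assign_folds(part, man, K = 5, seed = 3)
  ff <- file.path(tempdir(), "folds.json")
  write_folds(folds, ff)
  back <- read_folds(ff)
  expect_identical(back$K, folds$K)
  expect_identical(back$fold_of[names(folds$fold_of)],
                   stats::setNames(as.integer(folds$fold_of),
                                   names(folds$fold_of)))
})
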