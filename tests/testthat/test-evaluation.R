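test_that("exact metrics follow N_P/N_A and N_P/N_R", {
  perfect <- exact_metrics(c("a", "b"), c("a", "b"))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_value),
               c(1, 1, 1))
  disjoint <- exact_metrics(c("a", "b"), "c")
  expect_equal(c(disjoint$precision, disjoint$recall, disjoint$f_value),
               c(0, 0, 0))
  mixed <- exact_metrics(c("a", "b", "c", "d"), c("a", "b", "e"))
  expect_equal(mixed$precision, 2 / 3)
  expect_equal(mixed$recall, 1 / 2)
  expect_equal(mixed$f_value, 4 / 7)
  empty_pred <- exact_metrics(c("a", "b"), character())
  expect_equal(empty_pred$precision, 0)
  expect_error(exact_metrics(character(), "a"), "empty")
})

test_that("semantic metrics credit ancestor-level near misses", {
  ont <- toy_ontology()
  perfect <- semantic_metrics(toy_ids[4:5], toy_ids[4:5], ont)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_value),
               c(1, 1, 1))

  # the worked example: predicting term5 for real term4 scores 2/3 in
  # parents_only mode
  near <- semantic_metrics(toy_ids[4], toy_ids[5], ont,
                           closure_mode = "parents_only")
  expect_equal(near$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(near$recall, 2 / 3, tolerance = 1e-12)

  none <- semantic_metrics(toy_ids[4], character(), ont)
  expect_equal(c(none$precision, none$recall), c(0, 0))
})

test_that("semantic metrics match the nested-max oracle and dominate exact ones", {
  for (seed in 1:15) {
    inst <- random_instance(seed)
    ids <- inst$ontology$ids
    real <- sort(sample(ids, sample.int(4, 1)))
    predicted <- sort(sample(ids, sample.int(4, 1)))
    got <- semantic_metrics(real, predicted, inst$ontology)
    want <- oracle_semantic(real, predicted, inst$parents)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f_value, want$f_value, tolerance = 1e-12)

    ex <- exact_metrics(real, predicted)
    expect_gte(got$precision + 1e-12, ex$precision)
    expect_gte(got$recall + 1e-12, ex$recall)

    # harmonic-mean identity, exactly
    for (rep in list(got, ex)) {
      if (rep$precision + rep$recall > 0)
        expect_equal(rep$f_value,
                     2 * rep$precision * rep$recall /
                       (rep$precision + rep$recall))
      else expect_identical(rep$f_value, 0)
    }
  }
})

test_that("cross-validation hides annotations, touches every protein once, and honours stubs", {
  inst <- random_instance(11)
  ann <- inst$annotations

  # perfect stub: always returns the true annotations
  truth <- ann
  perfect_stub <- function(p, network, annotations, k) truth[[p]]
  cv <- cross_validate(inst$network, ann, inst$ontology,
                       algorithm = perfect_stub, folds = 3, seed = 5)
  expect_equal(cv$exact$precision, 1)
  expect_equal(cv$exact$recall, 1)
  expect_equal(cv$semantic$f_value, 1)
  # every annotated network protein appears exactly once as a target
  evaluated <- cv$exact$per_target$protein
  expect_equal(length(evaluated) + cv$exact$n_skipped,
               length(intersect(proteins(inst$network), names(ann))))
  expect_false(anyDuplicated(evaluated) > 0)

  # empty stub: all metrics 0
  empty_stub <- function(p, network, annotations, k) character()
  cv0 <- cross_validate(inst$network, ann, inst$ontology,
                        algorithm = empty_stub, folds = 3, seed = 5)
  expect_equal(cv0$exact$f_value, 0)
  expect_equal(cv0$semantic$f_value, 0)

  # hiding: the predictor never sees a test protein's own annotations
  leak_check <- function(p, network, annotations, k) {
    if (p %in% names(annotations))
      stop("annotation leak for ", p)
    character()
  }
  expect_no_error(cross_validate(inst$network, ann, inst$ontology,
                                 algorithm = leak_check, folds = 3,
                                 seed = 5))

  expect_error(cross_validate(inst$network, ann, inst$ontology,
                              folds = 1, seed = 1), "folds")
  expect_error(cross_validate(inst$network, ann, inst$ontology,
                              folds = 10000, seed = 1), "folds")
})

test_that("a 2-fold split on a tiny symmetric instance reproduces a hand execution", {
  # 4 proteins on a cycle, every protein annotated with one term
  ont <- build_ontology(list(f = character(), g = character()))
  net <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                           c("D", "A")))
  ann <- list(A = "f", B = "g", C = "f", D = "g")
  cv <- cross_validate(net, ann, ont, algorithm = "nc", folds = 2,
                       seed = 3, k = 1)
  # reproduce the partition with the same seed
  set.seed(3)
  assignment <- sample(rep_len(1:2, 4))
  targets_all <- sort(names(ann))
  per_fold <- lapply(1:2, function(i) {
    test <- targets_all[assignment == i]
    train <- ann[setdiff(names(ann), test)]
    vals <- vapply(test, function(p) {
      nb <- intersect(protein_neighbors(net, p), names(train))
      if (!length(nb)) return(NA_real_)
      freq <- oracle_nc_scores(p, setNames(list(nb), p), train)
      pred <- names(freq)[order(-freq, names(freq))][1]
      as.numeric(pred %in% ann[[p]])
    }, numeric(1))
    mean(vals[!is.na(vals)])
  })
  expect_equal(cv$exact$precision, mean(unlist(per_fold)),
               tolerance = 1e-12)
})

test_that("holdout evaluation draws the requested sizes deterministically", {
  inst <- random_instance(12)
  ho <- holdout_evaluate(inst$network, inst$annotations, inst$ontology,
                         algorithm = "nc", sample_sizes = 2, seed = 9)
  expect_equal(length(ho), 1L)
  expect_equal(ho[[1]]$size, 2)
  expect_lte(ho[[1]]$exact$n_targets + ho[[1]]$exact$n_skipped, 2)

  ho2 <- holdout_evaluate(inst$network, inst$annotations, inst$ontology,
                          algorithm = "nc", sample_sizes = 2, seed = 9)
  expect_identical(ho[[1]]$exact$precision, ho2[[1]]$exact$precision)
  expect_identical(ho[[1]]$semantic$f_value, ho2[[1]]$semantic$f_value)

  expect_error(holdout_evaluate(inst$network, inst$annotations,
                                inst$ontology, sample_sizes = 10000),
               "sample size")
})

test_that("metrics are invariant under protein relabeling", {
  inst <- random_instance(4)
  # zero-padded labels keep the lexicographic order, hence the partition
  relabel <- setNames(sprintf("X%02d", seq_along(inst$proteins)),
                      inst$proteins)
  em <- interactions(inst$network)
  net2 <- ppi_network(cbind(relabel[em[, 1]], relabel[em[, 2]]),
                      proteins = unname(relabel))
  ann2 <- setNames(inst$annotations, relabel[names(inst$annotations)])
  cv1 <- cross_validate(inst$network, inst$annotations, inst$ontology,
                        algorithm = "nc", folds = 2, seed = 7)
  cv2 <- cross_validate(net2, ann2, inst$ontology, algorithm = "nc",
                        folds = 2, seed = 7)
  # same partition sizes and same pooled multiset of per-target metrics
  expect_equal(sort(cv1$exact$per_target$exact_f),
               sort(cv2$exact$per_target$exact_f), tolerance = 1e-12)
})

test_that("precision-recall curves sweep k", {
  inst <- random_instance(13)
  curve <- pr_curve(inst$network, inst$annotations, inst$ontology,
                    algorithm = "nc", k_max = 3, size = 3, seed = 2)
  expect_equal(nrow(curve), 6L)
  expect_setequal(unique(curve$mode), c("exact", "semantic"))
  expect_true(all(curve$precision >= 0 & curve$precision <= 1))
})
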