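test_that("splits realize 60/20/20 within every sample", {
  d <- cohort_design(samples_per_taxon = 3, phytoliths_per_sample = 20,
                     seed = 1)
  coh <- simulate_cohort(d)
  sp <- prepare_splits(coh, "lineage", seed = 2)
  # every retained sample contributes 12/4/4
  per_sample <- table(sp$sample_id, sp$partition)
  expect_true(all(per_sample[, "train"] == 12))
  expect_true(all(per_sample[, "validation"] == 4))
  expect_true(all(per_sample[, "test"] == 4))
  # partitions are disjoint and exhaustive
  expect_false(any(is.na(sp$partition)))
  expect_equal(nrow(sp), nrow(coh))
  expect_equal(anyDuplicated(sp$phytolith_id), 0)
})

test_that("largest-remainder rounding holds for awkward sample sizes", {
  for (seed in 1:5) {
    for (n in c(7, 11, 19, 23)) {
      counts <- dendriform:::largest_remainder_split(n)
      expect_equal(sum(counts), n)
      expect_equal(unname(counts["train"]), round(0.6 * n))
      expect_lte(abs(counts["validation"] - 0.2 * n), 1)
    }
  }
})

test_that("small classes are dropped and logged", {
  d <- cohort_design(samples_per_taxon = 1, phytoliths_per_sample = 19,
                     seed = 3)
  coh <- simulate_cohort(d)
  # subspecies classes have 19 phytoliths each -> everything dropped
  expect_error(prepare_splits(coh, "subspecies", seed = 1), "no class left")
  # at species level classes have 38 -> retained
  sp <- prepare_splits(coh, "species", seed = 1)
  expect_equal(sort(unique(sp$class)), sort(unique(coh$species)))
  # single small class among normal ones
  d4 <- cohort_design(samples_per_taxon = 1, phytoliths_per_sample = 20,
                      seed = 3)
  coh4 <- simulate_cohort(d4)
  small_cls <- coh4$subspecies[1]
  keep <- coh4$subspecies != small_cls |
    coh4$phytolith_id %in% head(coh4$phytolith_id[coh4$subspecies == small_cls], 10)
  coh4 <- coh4[keep, ]
  sp3 <- prepare_splits(coh4, "subspecies", seed = 1, min_class = 20)
  expect_false(small_cls %in% sp3$class)
  expect_true(any(grepl("dropped class", attr(sp3, "log"))))
})

test_that("trimming moves whole samples to test_other", {
  d <- cohort_design(samples_per_taxon = 4, phytoliths_per_sample = 20,
                     seed = 4)
  coh <- simulate_cohort(d)
  sp <- prepare_splits(coh, "lineage", seed = 9, trim_cap = 2)
  to <- sp[sp$partition == "test_other", ]
  # every class keeps exactly 2 samples; the rest are whole samples in
  # test_other
  for (cl in unique(sp$class)) {
    kept <- unique(sp$sample_id[sp$class == cl & sp$partition != "test_other"])
    expect_equal(length(kept), 2)
    dropped <- unique(to$sample_id[to$class == cl])
    expect_equal(length(dropped),
                 length(unique(coh$sample_id[coh$lineage == cl])) - 2)
    # no phytolith of a dropped sample appears in train/val/test
    expect_false(any(sp$sample_id %in% dropped &
                       sp$partition != "test_other"))
  }
})

test_that("genus labels map onto the six lineage classes", {
  expect_equal(lineage_class(c("Avena", "Lolium", "Bromus", "Triticum")),
               c("Avena", "Poeae", "Triticodae", "Triticum"))
  expect_true(is.na(lineage_class("Zea")))
  rec <- data.frame(phytolith_id = 1:60, sample_id = rep(c("a", "b", "c"), 20),
                    genus = rep(c("Lolium", "Elymus", "Avena"), 20))
  rec <- rec[order(rec$sample_id), ]
  rec$sample_id <- rep(c("a", "b", "c"), each = 20)
  rec$genus <- rep(c("Lolium", "Elymus", "Avena"), each = 20)
  sp <- prepare_splits(rec, "lineage", seed = 1)
  expect_equal(sort(unique(sp$class)), c("Avena", "Poeae", "Triticodae"))
})

test_that("kappa and NIR match closed forms", {
  conf <- matrix(c(40, 20, 10, 30), 2, 2) # truth in rows: [[40,10],[20,30]]
  conf <- rbind(c(40, 10), c(20, 30))
  expect_equal(sum(diag(conf)) / sum(conf), 0.70)
  expect_equal(cohen_kappa(conf), 0.40, tolerance = 1e-12)
  expect_equal(nir_from_counts(rowSums(conf)), 0.5)

  # brute-force definition on random matrices
  set.seed(6)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 8), k, k)
    n <- sum(m)
    po <- sum(diag(m)) / n
    pe <- 0
    for (j in seq_len(k)) pe <- pe + sum(m[j, ]) * sum(m[, j])
    pe <- pe / n^2
    expect_equal(cohen_kappa(m), (po - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("perfect and degenerate forests behave as documented", {
  d <- cohort_design(taxon_sd = 10, between_sample_sd = 0,
                     within_sample_sd = 0.3, seed = 7)
  coh <- simulate_cohort(d)
  sp <- prepare_splits(coh, "lineage", seed = 3)
  mod <- train_random_forest(coh, sp, ntree = 100, seed = 3)
  trainrep <- evaluate(mod, coh, sp, "train")
  expect_equal(trainrep$accuracy, 1.0)
  expect_equal(trainrep$kappa, 1.0)
  expect_lt(evaluate(mod, coh, sp, "test")$binom_p, 1e-6)

  # determinism under a fixed seed
  mod2 <- train_random_forest(coh, sp, ntree = 100, seed = 3)
  expect_identical(predict(mod), predict(mod2))

  # degenerate single-class input
  one <- coh[coh$lineage == "Avena", ]
  spo <- sp[sp$phytolith_id %in% one$phytolith_id, ]
  expect_error(train_random_forest(one, spo, seed = 1), ">=2 classes")

  # NaN predictors are reported by column
  bad <- coh; bad$Volume[3] <- NaN
  expect_error(train_random_forest(bad, sp, seed = 1), "Volume")
})

test_that("importances single out a planted discriminative trait", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    tc <- trait_columns("branching")
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(X) <- tc
    X$AverageDendriticLength <- X$AverageDendriticLength +
      rep(c(0, 4), each = n / 2)
    rec <- cbind(phytolith_id = seq_len(n),
                 sample_id = rep(c("s1", "s2", "s3", "s4"), n / 4),
                 lineage = rep(c("A", "B"), each = n / 2), X)
    sp <- data.frame(phytolith_id = rec$phytolith_id,
                     sample_id = rec$sample_id, class = rec$lineage,
                     partition = "train")
    mod <- train_random_forest(rec, sp, traits = "branching", ntree = 200,
                               seed = seed)
    imp <- importance_report(mod)
    expect_true(all(imp$gini >= 0), label = "non-negative importances")
    hits <- hits + (imp$trait[1] == "AverageDendriticLength")
  }
  expect_gte(hits, 9)
})

test_that("pure-noise predictors spread importance evenly", {
  ok <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 80
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(X) <- trait_columns("branching")
    rec <- cbind(phytolith_id = seq_len(n), sample_id = "s1",
                 lineage = rep(c("A", "B"), each = n / 2), X)
    sp <- data.frame(phytolith_id = rec$phytolith_id, sample_id = "s1",
                     class = rec$lineage, partition = "train")
    mod <- train_random_forest(rec, sp, traits = "branching", ntree = 200,
                               seed = seed)
    imp <- importance_report(mod)
    ok <- ok + (max(imp$gini) <= 3 * stats::median(imp$gini))
  }
  expect_gte(ok, 8)
})

test_that("generalization to unseen specimens is harder than to seen ones", {
  worse <- 0
  n_cohorts <- 20
  for (seed in seq_len(n_cohorts)) {
    d <- cohort_design(samples_per_taxon = 4, phytoliths_per_sample = 20,
                       taxon_sd = 2, between_sample_sd = 1.5,
                       within_sample_sd = 1, seed = 300 + seed)
    coh <- simulate_cohort(d)
    sp <- prepare_splits(coh, "lineage", seed = seed, trim_cap = 3)
    mod <- train_random_forest(coh, sp, ntree = 120, seed = seed)
    acc_test <- evaluate(mod, coh, sp, "test")$accuracy
    acc_other <- evaluate(mod, coh, sp, "test_other")$accuracy
    worse <- worse + (acc_other <= acc_test)
  }
  expect_gte(worse, ceiling(0.8 * n_cohorts))
})
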