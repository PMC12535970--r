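# Genus -> lineage grouping used for six-class classification: the four
# cereal genera stay, other Pooideae genera are merged into the Poeae
# subtribe or Triticodae supertribe group.
poeae_genera <- c("Alopecurus", "Arrhenatherum", "Helictochloa",
                  "Helictotrichon", "Lolium", "Parapholis")
triticodae_genera <- c("Aegilops", "Bromus", "Dasypyrum", "Elymus",
                       "Hordelymus", "Thinopyrum")

#' Map genera to the six lineage classes
#'
#' @param genus character vector of genus names.
#' @return character vector with values Avena, Hordeum, Secale, Triticum,
#'   Poeae or Triticodae (NA for unknown genera).
#' @export
lineage_class <- function(genus) {
  out <- ifelse(genus %in% c("Avena", "Hordeum", "Secale", "Triticum"), genus,
         ifelse(genus %in% poeae_genera, "Poeae",
         ifelse(genus %in% triticodae_genera, "Triticodae", NA_character_)))
  out
}

largest_remainder_split <- function(n, ratios = c(train = 0.6,
                                                  validation = 0.2,
                                                  test = 0.2)) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  base
}

#' Partition phytoliths into train/validation/test (+ test_other)
#'
#' Implements the classification protocol: classes with fewer than
#' `min_class` phytoliths are dropped; classes with more than `trim_cap`
#' inflorescence samples have whole samples removed (largest first, seeded
#' tie-break) and those phytoliths become the `test_other` set, so
#' `test_other` always comes from plant specimens unseen during training;
#' each retained sample is split 60/20/20 by a seeded draw with
#' largest-remainder rounding.
#'
#' @param records per-phytolith table with `phytolith_id`, `sample_id` and
#'   the label column for `level`.
#' @param level "lineage", "species" or "subspecies". For "lineage" a
#'   `genus` column, when present, is mapped through [lineage_class()].
#' @param seed split seed.
#' @param trim_cap maximum number of samples a class may keep.
#' @param min_class minimum phytoliths for a class to be retained.
#' @return `split_assignment`: data.frame (phytolith_id, sample_id, class,
#'   partition) with a `log` attribute describing trimming.
#' @export
prepare_splits <- function(records, level = c("lineage", "species", "subspecies"),
                           seed = 1L, trim_cap = Inf, min_class = 20L) {
  level <- match.arg(level)
  cls <- if (level == "lineage" && "genus" %in% names(records)) {
    lineage_class(records$genus)
  } else {
    records[[level]]
  }
  if (is.null(cls)) stop("records lack a '", level, "' column")
  df <- data.frame(phytolith_id = records$phytolith_id,
                   sample_id = records$sample_id,
                   class = as.character(cls), stringsAsFactors = FALSE)
  log_lines <- character(0)
  with_seed(seed, {
    # rule 1: drop classes with < min_class phytoliths
    csize <- table(df$class)
    small <- names(csize)[csize < min_class]
    if (length(small)) {
      log_lines <- c(log_lines,
                     sprintf("dropped class %s (%d phytoliths < %d)",
                             small, as.integer(csize[small]), min_class))
      df <- df[!df$class %in% small, , drop = FALSE]
    }
    if (!nrow(df)) stop("no class left after trimming")
    df$partition <- NA_character_
    # rule 2: trim whole samples from majority classes -> test_other
    for (cl in unique(df$class)) {
      sids <- unique(df$sample_id[df$class == cl])
      if (length(sids) > trim_cap) {
        ssize <- table(df$sample_id[df$class == cl])[sids]
        ord <- order(-as.integer(ssize), runif(length(sids)))
        drop_sids <- sids[ord[seq_len(length(sids) - trim_cap)]]
        df$partition[df$sample_id %in% drop_sids] <- "test_other"
        log_lines <- c(log_lines,
                       sprintf("class %s: %d sample(s) moved to test_other", cl,
                               length(drop_sids)))
      }
    }
    if (all(!is.na(df$partition))) stop("no class left after trimming")
    # rule 3: within-sample stratified 60/20/20
    for (sid in unique(df$sample_id[is.na(df$partition)])) {
      idx <- which(df$sample_id == sid & is.na(df$partition))
      n <- length(idx)
      if (n < 5)
        warning("sample ", sid, " has ", n,
                " phytoliths; rounding may starve a partition")
      counts <- largest_remainder_split(n)
      lab <- rep(names(counts), counts)
      df$partition[idx] <- sample(lab)
    }
  })
  attr(df, "log") <- log_lines
  attr(df, "seed") <- seed
  class(df) <- c("split_assignment", "data.frame")
  df
}

#' Train a Random Forest on a trait set
#'
#' CART forest with the Gini split criterion, 500 trees and
#' `floor(sqrt(p))` candidate features per split by default; deterministic
#' under a fixed seed. The default predictor set is the geometric +
#' branching + CC traits (the PH coordinates are excluded by default, the
#' configuration used for the published classification runs).
#'
#' @param records per-phytolith table (traits + labels).
#' @param split a `split_assignment`; rows with partition "train" are used.
#' @param traits trait sets to use as predictors.
#' @param ntree,mtry forest hyperparameters.
#' @param seed RNG seed.
#' @return a `randomForest` model with attribute `traits`.
#' @export
train_random_forest <- function(records, split,
                                traits = c("geometric", "branching", "cc"),
                                ntree = 500, mtry = NULL, seed = 1L) {
  cols <- unlist(lapply(traits, function(s) trait_columns(s)))
  cols <- intersect(cols, names(records))
  if (!length(cols)) stop("no predictor columns found")
  tr <- split[split$partition == "train", ]
  idx <- match(tr$phytolith_id, records$phytolith_id)
  X <- records[idx, cols, drop = FALSE]
  bad <- names(X)[vapply(X, function(v) any(!is.finite(v)), logical(1))]
  if (length(bad)) stop("NaN/Inf in predictor column(s): ",
                        paste(bad, collapse = ", "))
  y <- factor(tr$class)
  if (nlevels(y) < 2) stop("need >=2 classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  model <- with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = ntree, mtry = mtry,
                               importance = FALSE))
  attr(model, "trait_cols") <- cols
  model
}

#' Cohen's kappa from a confusion matrix
#' @param conf square confusion matrix (truth in rows).
#' @export
cohen_kappa <- function(conf) {
  conf <- as.matrix(conf)
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  (po - pe) / (1 - pe)
}

#' No-information rate from class counts
#' @param counts vector of per-class counts.
#' @return proportion of the most frequent class.
#' @export
nir_from_counts <- function(counts) max(counts) / sum(counts)

#' Evaluate a classifier on a partition
#'
#' Accuracy, Cohen's kappa, the no-information rate (share of the most
#' frequent true class), an exact one-sided binomial test of accuracy > NIR,
#' per-class recall, the confusion matrix and the model's Gini importances.
#' Labels unseen in training count as errors and are listed.
#'
#' @param model a trained forest from [train_random_forest()].
#' @param records full per-phytolith table.
#' @param split a `split_assignment`.
#' @param partition which partition to evaluate.
#' @return `class_report`.
#' @export
evaluate <- function(model, records, split, partition = "test") {
  ev <- split[split$partition == partition, ]
  if (!nrow(ev)) stop("partition ", partition, " is empty")
  idx <- match(ev$phytolith_id, records$phytolith_id)
  cols <- attr(model, "trait_cols")
  X <- records[idx, cols, drop = FALSE]
  truth <- ev$class
  pred <- as.character(predict(model, X))
  unseen <- setdiff(unique(truth), levels(model$y))
  lev <- sort(unique(c(truth, pred)))
  conf <- table(truth = factor(truth, lev), predicted = factor(pred, lev))
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  nir <- nir_from_counts(table(truth))
  bp <- binom.test(sum(diag(conf)), n, p = nir,
                   alternative = "greater")$p.value
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  imp <- importance_report(model)
  structure(list(confusion = conf, accuracy = acc,
                 kappa = cohen_kappa(conf), nir = nir, binom_p = bp,
                 per_class_recall = recall, importances = imp,
                 unseen_classes = unseen, n = n, partition = partition),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("%s set (n = %d): accuracy %.1f%%, kappa %.2f, NIR %.1f%%, binomial p = %.3g\n",
              x$partition, x$n, 100 * x$accuracy, x$kappa, 100 * x$nir,
              x$binom_p))
  if (length(x$unseen_classes))
    cat("classes unseen in training:",
        paste(x$unseen_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Trait importance ranking
#'
#' Traits sorted by mean decrease in Gini impurity.
#'
#' @param model trained forest.
#' @return data.frame (trait, gini) in decreasing order.
#' @export
importance_report <- function(model) {
  imp <- randomForest::importance(model, type = 2)
  out <- data.frame(trait = rownames(imp), gini = imp[, 1], row.names = NULL)
  out[order(-out$gini), , drop = FALSE]
}
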