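#' Average traits over inflorescence samples
#'
#' One row per sample: the arithmetic mean of every trait over the sample's
#' phytoliths. Metadata columns must be constant within a sample.
#'
#' @param records per-phytolith trait table (as from [simulate_cohort()] or
#'   [run_pipeline()]).
#' @param sample_col name of the sample id column.
#' @param trait_cols trait columns to average (default: all trait columns
#'   present).
#' @param meta_cols metadata columns carried along (default: the standard
#'   label columns present).
#' @return data.frame, one row per sample.
#' @export
average_by_sample <- function(records, sample_col = "sample_id",
                              trait_cols = NULL, meta_cols = NULL) {
  stopifnot(sample_col %in% names(records))
  if (is.null(trait_cols))
    trait_cols <- intersect(trait_columns(), names(records))
  if (is.null(meta_cols))
    meta_cols <- intersect(c("lineage", "species", "subspecies",
                             "domestication", "ploidy"), names(records))
  sid <- records[[sample_col]]
  for (mc in meta_cols) {
    nuniq <- tapply(records[[mc]], sid, function(x) length(unique(x)))
    if (any(nuniq > 1))
      stop("conflicting metadata within sample(s): ",
           paste(names(nuniq)[nuniq > 1], collapse = ", "))
  }
  ids <- sort(unique(sid))
  M <- vapply(trait_cols, function(tc) {
    as.vector(tapply(records[[tc]], sid, mean)[ids])
  }, numeric(length(ids)))
  meta <- records[match(ids, sid), meta_cols, drop = FALSE]
  out <- data.frame(sample_id = ids, meta, M, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[seq_along(meta_cols) + 1L] <- meta_cols
  out
}

#' Drop near-duplicate traits by correlation grouping
#'
#' Builds a graph on the trait columns with an edge wherever
#' `|Pearson r| > threshold`; each connected component is a redundancy group
#' from which one representative is kept: the member with the highest mean
#' absolute correlation to the rest of its group (ties broken
#' alphabetically). Zero-variance traits are dropped with a warning.
#'
#' @param tab sample table (or any table with trait columns).
#' @param threshold absolute-correlation threshold (study value 0.90).
#' @param trait_cols columns to consider.
#' @return list: `table` (input with dropped columns removed), `groups`
#'   (list of grouped trait names), `retained`, `dropped`.
#' @export
correlation_filter <- function(tab, threshold = 0.90, trait_cols = NULL) {
  if (is.null(trait_cols))
    trait_cols <- intersect(trait_columns(), names(tab))
  stopifnot(nrow(tab) >= 3)
  X <- as.matrix(tab[, trait_cols, drop = FALSE])
  const <- apply(X, 2, function(v) sd(v) == 0 || !is.finite(sd(v)))
  if (any(const)) {
    warning("dropping constant trait(s): ",
            paste(trait_cols[const], collapse = ", "))
    trait_cols <- trait_cols[!const]
    X <- X[, trait_cols, drop = FALSE]
  }
  R <- abs(cor(X))
  adj <- R > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  retained <- character(0)
  groups <- list()
  for (k in sort(unique(comp))) {
    members <- trait_cols[comp == k]
    if (length(members) == 1) {
      rep_trait <- members
    } else {
      score <- vapply(members, function(mv) {
        mean(R[mv, setdiff(members, mv)])
      }, numeric(1))
      best <- members[score == max(score)]
      rep_trait <- sort(best)[1]
      groups[[rep_trait]] <- members
    }
    retained <- c(retained, rep_trait)
  }
  retained <- trait_cols[trait_cols %in% retained]
  dropped <- setdiff(trait_cols, retained)
  keep_cols <- setdiff(names(tab), dropped)
  keep_cols <- setdiff(keep_cols, names(which(const)))
  list(table = tab[, keep_cols, drop = FALSE],
       groups = groups, retained = retained, dropped = dropped)
}

# elbow of the scree curve by maximum perpendicular distance from the chord
# joining its first and last points; when the maximizing point lies below the
# chord it is the first point that "contributes little additional variance",
# so retention stops just before it
scree_elbow <- function(ev) {
  n <- length(ev)
  if (n <= 2) return(1L)
  x <- seq_len(n)
  chord <- c(n - 1, ev[n] - ev[1])
  chord <- chord / sqrt(sum(chord^2))
  dx <- x - 1
  dy <- ev - ev[1]
  dist <- abs(dx * chord[2] - dy * chord[1])
  j <- which.max(dist)
  below <- ev[j] < ev[1] + (ev[n] - ev[1]) * (j - 1) / (n - 1)
  max(1L, if (below) j - 1L else j)
}

#' PCA with varimax rotation and elbow component selection
#'
#' Traits are standardized, decomposed by PCA and the retained components
#' rotated by (Kaiser-normalized) varimax. When `k` is not given it is set by
#' the elbow of the scree curve: the point with maximum perpendicular
#' distance from the chord joining the curve's first and last eigenvalues.
#' Scores use the regression method; components are reported in descending
#' order of post-rotation explained variance with a deterministic sign
#' (sum of cubed loadings non-negative).
#'
#' @param tab table whose trait columns are analysed.
#' @param k number of rotated components; `NULL` for automatic elbow choice.
#' @param trait_cols columns to use.
#' @return `rotated_components`: list with `loadings`, `scores`,
#'   `explained_variance` (post-rotation, per component), `eigenvalues`, `k`.
#' @export
pca_varimax <- function(tab, k = NULL, trait_cols = NULL) {
  if (is.null(trait_cols))
    trait_cols <- intersect(trait_columns(), names(tab))
  X <- as.matrix(tab[, trait_cols, drop = FALSE])
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  npos <- sum(ev > 1e-10)
  if (is.null(k)) k <- scree_elbow(ev)
  if (k > npos) stop("k exceeds the number of positive-variance components")
  if (nrow(Z) < k + 2) stop("need at least k + 2 rows")
  A <- pc$rotation[, seq_len(k), drop = FALSE] %*%
    diag(pc$sdev[seq_len(k)], k)
  if (k > 1) {
    vr <- varimax(A, normalize = TRUE, eps = 1e-6)
    L <- unclass(vr$loadings)
  } else {
    L <- A
  }
  # order by explained variance after rotation, fix signs
  expl <- colSums(L^2)
  ord <- order(expl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  expl <- expl[ord]
  for (j in seq_len(k)) {
    s <- sum(L[, j]^3)
    if (s == 0) s <- L[which.max(abs(L[, j])), j]
    if (s < 0) L[, j] <- -L[, j]
  }
  colnames(L) <- paste0("RC", seq_len(k))
  # regression scores: Z R^{-1} L  with R the trait correlation matrix
  Rcor <- cor(X)
  S <- Z %*% solve(Rcor, L)
  colnames(S) <- colnames(L)
  structure(list(loadings = L, scores = S,
                 explained_variance = expl / length(trait_cols),
                 eigenvalues = ev, k = k, trait_cols = trait_cols),
            class = "rotated_components")
}

#' @export
print.rotated_components <- function(x, ...) {
  cat(sprintf("<rotated_components: k = %d, cumulative variance %.1f%%>\n",
              x$k, 100 * sum(x$explained_variance)))
  invisible(x)
}

check_separation <- function(fit) {
  probs <- fitted(fit)
  eps <- 1e-8
  if (all(probs > 1 - eps | probs < eps) ||
      max(abs(coef(fit)), na.rm = TRUE) > 15)
    stop("separation detected: logistic ML estimates diverge")
}

#' Logistic regression of domestication status on rotated components
#'
#' Binary logistic model with "domesticated" as the reference category, so a
#' positive coefficient means higher odds of being wild. Reports Wald
#' SE/Z/p, odds ratios with profile-likelihood CIs by default (Wald
#' optional), and the likelihood-ratio chi-square against the intercept-only
#' model.
#'
#' @param scores matrix/data.frame of predictors (e.g. RC scores) or a
#'   `rotated_components`.
#' @param labels factor/character with values "wild"/"domesticated".
#' @param ci_method "profile" or "wald".
#' @return `logistic_summary`: list with `table` (B, SE, Z, OR, CI, p),
#'   `lr_chisq`, `df`, `lr_p`, `fit`.
#' @export
fit_logistic_domestication <- function(scores, labels,
                                       ci_method = c("profile", "wald")) {
  ci_method <- match.arg(ci_method)
  if (inherits(scores, "rotated_components")) scores <- scores$scores
  S <- as.data.frame(scores)
  y <- factor(labels, levels = c("domesticated", "wild"))
  if (any(is.na(y))) stop("labels must be 'wild' or 'domesticated'")
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  dat <- cbind(.y = as.integer(y) - 1L, S)
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  check_separation(fit)
  sm <- summary(fit)$coefficients
  B <- sm[, 1]; SE <- sm[, 2]; Z <- sm[, 3]; p <- sm[, 4]
  ci <- if (ci_method == "profile") {
    suppressMessages(suppressWarnings(confint(fit)))
  } else {
    cbind(B - qnorm(0.975) * SE, B + qnorm(0.975) * SE)
  }
  if (is.null(dim(ci))) ci <- matrix(ci, 1, 2)
  tab <- data.frame(term = rownames(sm), B = B, SE = SE, Z = Z,
                    OR = exp(B), CI_lo = exp(ci[, 1]), CI_hi = exp(ci[, 2]),
                    p = p, row.names = NULL)
  fit0 <- glm(.y ~ 1, data = dat, family = binomial())
  lr <- as.numeric(2 * (logLik(fit) - logLik(fit0)))
  df <- length(coef(fit)) - 1L
  structure(list(table = tab, lr_chisq = lr, df = df,
                 lr_p = pchisq(lr, df, lower.tail = FALSE),
                 ci_method = ci_method, fit = fit),
            class = "logistic_summary")
}

#' @export
print.logistic_summary <- function(x, ...) {
  cat(sprintf("Binary logistic model (reference: domesticated); LR chi2(%d) = %.2f, p = %.4g\n",
              x$df, x$lr_chisq, x$lr_p))
  print(x$table, digits = 3)
  invisible(x)
}

# closed-form log-likelihood of the intercept-only cumulative-logit model
null_ordinal_loglik <- function(y) {
  n <- table(y)
  sum(n * log(n / sum(n)))
}

#' Ordinal (proportional-odds) regression of ploidy level
#'
#' Cumulative-logit maximum-likelihood fit treating diploid < tetraploid <
#' hexaploid as ordered categories. Reports coefficients with SE/t/OR and
#' the latent-scale thresholds ("diploid|tetraploid",
#' "tetraploid|hexaploid"), plus the LR chi-square against the
#' intercept-only model (whose likelihood has a closed form).
#'
#' @param scores predictors (matrix/data.frame or `rotated_components`).
#' @param ploidy ordered factor or character vector of ploidy labels.
#' @param levels label order, lowest first.
#' @return `ordinal_summary`: list with `table`, `thresholds`, `lr_chisq`,
#'   `df`, `lr_p`, `fit`.
#' @export
fit_ordinal_ploidy <- function(scores, ploidy,
                               levels = c("diploid", "tetraploid", "hexaploid")) {
  if (inherits(scores, "rotated_components")) scores <- scores$scores
  S <- as.data.frame(scores)
  present <- levels[levels %in% unique(as.character(ploidy))]
  if (length(present) < length(levels))
    warning("ploidy level(s) with no rows dropped: ",
            paste(setdiff(levels, present), collapse = ", "))
  if (length(present) < 2) stop("need at least 2 ploidy levels present")
  y <- factor(as.character(ploidy), levels = present, ordered = TRUE)
  dat <- cbind(.y = y, S)
  if (length(present) == 2) {
    # two observed levels: the cumulative-logit model reduces to binary
    # logistic regression (threshold = -intercept)
    fitb <- suppressWarnings(glm(I(as.integer(.y) - 1L) ~ ., data = dat,
                                 family = binomial()))
    sm <- summary(fitb)$coefficients
    tab <- data.frame(term = rownames(sm)[-1], B = sm[-1, 1], SE = sm[-1, 2],
                      t = sm[-1, 3], OR = exp(sm[-1, 1]), row.names = NULL)
    thresholds <- data.frame(threshold = paste(present, collapse = "|"),
                             B = -sm[1, 1], SE = sm[1, 2], t = -sm[1, 3],
                             row.names = NULL)
    lr <- as.numeric(2 * (logLik(fitb) - null_ordinal_loglik(y)))
    df <- nrow(tab)
    return(structure(list(table = tab, thresholds = thresholds,
                          lr_chisq = lr, df = df,
                          lr_p = pchisq(lr, df, lower.tail = FALSE),
                          fit = fitb),
                     class = "ordinal_summary"))
  }
  fit <- suppressWarnings(MASS::polr(.y ~ ., data = dat, Hess = TRUE))
  if (!fit$convergence == 0 && !is.null(fit$convergence))
    stop("ordinal fit did not converge")
  sm <- summary(fit)$coefficients
  nco <- length(coef(fit))
  co <- sm[seq_len(nco), , drop = FALSE]
  tab <- data.frame(term = rownames(co), B = co[, 1], SE = co[, 2],
                    t = co[, 3], OR = exp(co[, 1]), row.names = NULL)
  th <- sm[nco + seq_len(nrow(sm) - nco), , drop = FALSE]
  thresholds <- data.frame(threshold = rownames(th), B = th[, 1],
                           SE = th[, 2], t = th[, 3], row.names = NULL)
  if (is.unsorted(thresholds$B)) stop("thresholds not increasing")
  lr <- as.numeric(2 * (logLik(fit) - null_ordinal_loglik(y)))
  df <- nco
  structure(list(table = tab, thresholds = thresholds, lr_chisq = lr,
                 df = df, lr_p = pchisq(lr, df, lower.tail = FALSE),
                 fit = fit),
            class = "ordinal_summary")
}

#' @export
print.ordinal_summary <- function(x, ...) {
  cat(sprintf("Proportional-odds model; LR chi2(%d) = %.2f, p = %.4g\n",
              x$df, x$lr_chisq, x$lr_p))
  print(x$table, digits = 3)
  print(x$thresholds, digits = 3)
  invisible(x)
}

#' Linear discriminant analysis with NIR binomial test
#'
#' Applies the same preprocessing as the regression stage (correlation
#' filter, then PCA + varimax) to individual phytolith traits and fits
#' Fisher LDA with proportional priors. Reports per-axis discriminative
#' power (eigenvalue share), resubstitution accuracy (or leave-one-out when
#' `cv = TRUE`), the no-information rate and a one-sided exact binomial test
#' of accuracy > NIR.
#'
#' @param records per-phytolith trait table.
#' @param labels class labels (character/factor), one per record.
#' @param corr_threshold correlation filter threshold.
#' @param k number of rotated components (`NULL` = elbow).
#' @param cv use leave-one-out accuracy instead of resubstitution.
#' @return `lda_result`: list with `power`, `accuracy`, `nir`, `binom_p`,
#'   `confusion`, `scores`, `fit`.
#' @export
fit_lda <- function(records, labels, corr_threshold = 0.90, k = NULL,
                    cv = FALSE) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  cf <- correlation_filter(records, corr_threshold)
  rc <- pca_varimax(cf$table, k = k,
                    trait_cols = intersect(cf$retained, names(cf$table)))
  S <- as.data.frame(rc$scores)
  fit <- tryCatch(MASS::lda(S, grouping = y),
                  error = function(e)
                    stop("singular pooled covariance; use a stronger correlation filter: ",
                         conditionMessage(e)))
  power <- fit$svd^2 / sum(fit$svd^2)
  pred <- if (cv) MASS::lda(S, grouping = y, CV = TRUE)$class
          else predict(fit, S)$class
  conf <- table(truth = y, predicted = pred)
  acc <- sum(diag(conf)) / sum(conf)
  nir <- max(table(y)) / length(y)
  bp <- binom.test(sum(diag(conf)), sum(conf), p = nir,
                   alternative = "greater")$p.value
  structure(list(power = power, accuracy = acc, nir = nir, binom_p = bp,
                 confusion = conf, scores = predict(fit, S)$x,
                 components = rc, fit = fit),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  cat(sprintf("LDA: accuracy %.1f%% vs NIR %.1f%% (exact binomial p = %.3g)\n",
              100 * x$accuracy, 100 * x$nir, x$binom_p))
  cat("discriminative power:",
      paste(sprintf("LD%d %.0f%%", seq_along(x$power), 100 * x$power),
            collapse = ", "), "\n")
  invisible(x)
}
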