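test_that("sample averaging matches a brute-force group-by", {
  rec <- data.frame(phytolith_id = 1:10,
                    sample_id = rep(c("s1", "s2", "s3", "s4", "s5"), each = 2),
                    lineage = rep("Avena", 10),
                    Volume = c(100, 200, 1:8),
                    Solidity = runif(10))
  st <- average_by_sample(rec, trait_cols = c("Volume", "Solidity"),
                          meta_cols = "lineage")
  expect_equal(nrow(st), 5)
  expect_equal(st$Volume[st$sample_id == "s1"], 150)
  oracle <- tapply(rec$Solidity, rec$sample_id, mean)
  expect_equal(st$Solidity, as.vector(oracle[st$sample_id]))

  rec$lineage[1] <- "Secale"
  expect_error(average_by_sample(rec, trait_cols = "Volume",
                                 meta_cols = "lineage"),
               "conflicting metadata.*s1")
})

test_that("correlation filter groups near-duplicates and keeps one", {
  set.seed(2)
  A <- rnorm(40)
  tab <- data.frame(Volume = A, ConvexHullVolume = 2 * A,
                    Solidity = rnorm(40), Sphericity = rnorm(40))
  cf <- correlation_filter(tab, 0.90,
                           trait_cols = names(tab))
  expect_equal(length(cf$retained), 3)
  expect_equal(length(intersect(c("Volume", "ConvexHullVolume"),
                                cf$retained)), 1)

  # three mutually correlated traits -> exactly one survivor
  base <- rnorm(60)
  tab3 <- data.frame(a = base + rnorm(60, 0, 0.1),
                     b = base + rnorm(60, 0, 0.1),
                     c = base + rnorm(60, 0, 0.1),
                     d = rnorm(60))
  cf3 <- correlation_filter(tab3, 0.9, trait_cols = names(tab3))
  expect_equal(sum(c("a", "b", "c") %in% cf3$retained), 1)
  expect_true("d" %in% cf3$retained)

  # weakly correlated table passes unchanged
  set.seed(5)
  tabu <- as.data.frame(matrix(rnorm(200), 50, 4))
  cfu <- correlation_filter(tabu, 0.9, trait_cols = names(tabu))
  expect_identical(cfu$table, tabu)

  tabc <- cbind(tabu, konst = 1)
  expect_warning(correlation_filter(tabc, 0.9, trait_cols = names(tabc)),
                 "constant")
})

test_that("varimax rotation preserves communalities and finds the elbow", {
  set.seed(7)
  n <- 120
  F3 <- matrix(rnorm(n * 3), n, 3)
  load_true <- matrix(0, 9, 3)
  load_true[1:3, 1] <- c(0.9, 0.8, 0.85)
  load_true[4:6, 2] <- c(0.9, 0.85, 0.8)
  load_true[7:9, 3] <- c(0.85, 0.9, 0.8)
  X <- F3 %*% t(load_true) + matrix(rnorm(n * 9, 0, 0.25), n, 9)
  colnames(X) <- paste0("t", 1:9)
  tab <- as.data.frame(X)

  rc <- pca_varimax(tab, k = 3, trait_cols = colnames(X))
  # communalities: row sums of squared loadings equal those before rotation
  pc <- prcomp(scale(X))
  A <- pc$rotation[, 1:3] %*% diag(pc$sdev[1:3])
  expect_equal(rowSums(rc$loadings^2), rowSums(A^2), tolerance = 1e-8)
  # each variable loads on exactly one rotated component
  main <- apply(abs(rc$loadings), 1, max)
  second <- apply(abs(rc$loadings), 1, function(v) sort(v, TRUE)[2])
  expect_true(all(main > 2 * second))

  # automatic elbow finds 3 factors most of the time
  hits <- 0
  for (i in 1:50) {
    set.seed(1000 + i)
    Fz <- matrix(rnorm(n * 3), n, 3)
    Xz <- Fz %*% t(load_true) + matrix(rnorm(n * 9, 0, 0.2), n, 9)
    colnames(Xz) <- paste0("t", 1:9)
    rcz <- pca_varimax(as.data.frame(Xz), trait_cols = colnames(Xz))
    hits <- hits + (rcz$k == 3)
  }
  expect_gte(hits, 45)

  expect_error(pca_varimax(tab, k = 99, trait_cols = colnames(X)),
               "positive-variance")
})

test_that("already-simple loadings are left essentially unrotated", {
  # scores on orthogonal one-variable factors are already varimax-optimal
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3) %*% diag(c(3, 2, 1))
  colnames(X) <- c("a", "b", "c")
  rc <- pca_varimax(as.data.frame(X), k = 3, trait_cols = colnames(X))
  L <- abs(rc$loadings)
  # permutation/sign-invariant check for near-identity structure
  expect_true(all(apply(L, 1, max) > 0.95))
  expect_true(all(apply(L, 1, function(v) sort(v, TRUE)[2]) < 0.3))
})

test_that("logistic stage reports ORs consistent with log-odds", {
  set.seed(3)
  n <- 120
  S <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("RC", 1:3)))
  y <- ifelse(runif(n) < plogis(S[, 1]), "wild", "domesticated")
  fitsum <- fit_logistic_domestication(S, y, ci_method = "wald")
  expect_equal(fitsum$table$OR, exp(fitsum$table$B), tolerance = 1e-12)
  expect_gte(fitsum$lr_chisq, 0)
  expect_equal(fitsum$df, 3)
  # orientation: positive coefficient means higher odds of wild
  expect_gt(fitsum$table$B[fitsum$table$term == "RC1"], 0)

  # profile CIs differ from Wald but bracket the estimate
  fitp <- fit_logistic_domestication(S, y, ci_method = "profile")
  expect_true(all(fitp$table$CI_lo < fitp$table$OR &
                  fitp$table$OR < fitp$table$CI_hi))

  expect_error(fit_logistic_domestication(S, rep("wild", n)), "both classes")
  sep <- ifelse(S[, 1] > 0, "wild", "domesticated")
  expect_error(fit_logistic_domestication(S, sep), "separation")
})

test_that("ordinal stage recovers null thresholds and flags empty levels", {
  set.seed(8)
  n <- 240
  S <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("RC1", "RC2")))
  y <- rep(c("diploid", "tetraploid", "hexaploid"), each = n / 3)
  fit <- fit_ordinal_ploidy(S, y)
  expect_equal(fit$thresholds$B, c(log(1 / 2), log(2)), tolerance = 0.2)
  expect_true(all(diff(fit$thresholds$B) > 0))
  expect_equal(fit$table$OR, exp(fit$table$B), tolerance = 1e-12)

  y2 <- rep(c("diploid", "tetraploid"), each = 40)
  S2 <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("RC1", "RC2")))
  expect_warning(fit_ordinal_ploidy(S2, y2), "hexaploid")

  # a planted monotone effect is recovered within 2 SE
  eta <- 2 * S[, 1]
  u <- runif(n)
  p1 <- plogis(-1 - eta); p2 <- plogis(1 - eta)
  y3 <- ifelse(u < p1, "diploid", ifelse(u < p2, "tetraploid", "hexaploid"))
  fit3 <- fit_ordinal_ploidy(S, y3)
  b <- fit3$table$B[fit3$table$term == "RC1"]
  se <- fit3$table$SE[fit3$table$term == "RC1"]
  expect_lt(abs(b - 2), 2 * se)
})

test_that("LDA separates well-separated classes and reports NIR", {
  set.seed(4)
  n <- 100
  X <- data.frame(Volume = c(rnorm(n), rnorm(n, 6)),
                  Solidity = rnorm(2 * n),
                  Sphericity = rnorm(2 * n),
                  MaxLength = rnorm(2 * n))
  y <- rep(c("wild", "domesticated"), each = n)
  res <- fit_lda(X, y, k = 4)
  expect_gte(res$accuracy, 0.99)
  expect_equal(res$nir, 0.5)
  expect_equal(sum(res$power), 1, tolerance = 1e-12)
  expect_lt(res$binom_p, 1e-10)

  # labels independent of the traits stay within binomial noise of the NIR
  # (leave-one-out accuracy; resubstitution is optimistically biased under
  # the null)
  null_ok <- 0
  for (i in 1:10) {
    set.seed(100 + i)
    X0 <- as.data.frame(matrix(rnorm(2 * n * 4), 2 * n, 4))
    names(X0) <- names(X)
    r0 <- fit_lda(X0, sample(y), k = 4, cv = TRUE)
    null_ok <- null_ok + (r0$binom_p > 0.05)
  }
  expect_gte(null_ok, 9)
})
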