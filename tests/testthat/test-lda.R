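test_that("distance matrix entries equal brute-force nearest searches", {
  set.seed(601)
  origins <- random_intervals(200, genome_length = 1e6, max_len = 2000)
  origins$timing_category <- sample(1:6, 200, replace = TRUE)
  marks <- list(H2AZ = random_intervals(80, 1e6, 2000),
                H3K9me3 = random_intervals(80, 1e6, 2000))
  dm <- build_distance_matrix(origins, marks)
  expect_equal(dm$H2AZ, bf_nearest(origins, marks$H2AZ))
  expect_equal(dm$H3K9me3, bf_nearest(origins, marks$H3K9me3))
  expect_equal(dm$group, c("early", "mid", "late")[
    (origins$timing_category + 1) %/% 2])
  expect_error(build_distance_matrix(origins, list(x = marks$H2AZ[0, ])),
               "empty mark track")
})

test_that("a single separating variable dominates the first axis", {
  set.seed(607)
  n <- 80
  d <- tibble::tibble(
    group = rep(c("early", "late"), each = n),
    signal = c(rnorm(n, 0), rnorm(n, 8)),
    noise1 = rnorm(2 * n), noise2 = rnorm(2 * n))
  fit <- run_lda(d)
  expect_equal(ncol(fit$scalings), 1)
  cors <- fit$correlations
  expect_gt(abs(cors$DA1[cors$variable == "signal"]), 0.95)
  expect_lt(max(abs(cors$DA1[cors$variable != "signal"])), 0.3)
  # sign convention: the dominating correlation is negative
  expect_lt(cors$DA1[cors$variable == "signal"], 0)
})

test_that("reported correlations match direct recomputation", {
  set.seed(613)
  d <- planted_distances(60)
  fit <- run_lda(d)
  X <- as.matrix(d[fit$vars])
  sc <- as.matrix(fit$scores[colnames(fit$scalings)])
  direct <- cor(X, sc)
  expect_equal(as.matrix(fit$correlations[, -1]), direct,
               ignore_attr = TRUE, tolerance = 1e-10)
  # axes have unit pooled within-group variance
  g <- fit$scores$group
  pooled <- Reduce(`+`, lapply(unique(g), function(lv) {
    z <- sc[g == lv, , drop = FALSE]
    crossprod(sweep(z, 2, colMeans(z)))
  })) / (nrow(sc) - length(unique(g)))
  expect_equal(diag(pooled), rep(1, ncol(sc)), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("axis coordinates are invariant to shifting a distance column", {
  set.seed(617)
  d <- planted_distances(50)
  fit1 <- run_lda(d)
  d2 <- dplyr::mutate(d, H2AZ = .data$H2AZ + 5000)
  fit2 <- run_lda(d2)
  expect_equal(as.matrix(fit1$scores[, -(1:2)]),
               as.matrix(fit2$scores[, -(1:2)]), tolerance = 1e-8)
})

test_that("planted three-group structure is recovered by nearest centroid", {
  set.seed(619)
  d <- planted_distances(100)
  # distances are heavy-tailed (exponential); fit on the log scale
  fit <- run_lda(d, log1p = TRUE)
  acc <- mean(lda_classify(fit) == d$group)
  expect_gte(acc, 0.9)
  # agreement with the reference implementation on the same data
  skip_if_not_installed("MASS")
  d_log <- dplyr::mutate(d, dplyr::across(-"group", log1p))
  ref <- MASS::lda(group ~ ., data = d_log)
  ref_pred <- stats::predict(ref)$class
  expect_gte(mean(as.character(ref_pred) == lda_classify(fit)), 0.95)
})

test_that("permuted labels give chance-level separation", {
  set.seed(631)
  d <- planted_distances(60)
  sep_true <- glance(run_lda(d))$separation
  sep_perm <- vapply(1:100, function(i) {
    dp <- d
    dp$group <- sample(dp$group)
    glance(run_lda(dp))$separation
  }, numeric(1))
  expect_gt(sep_true, max(sep_perm))
  # permutation accuracy hovers at chance (1/3)
  dp <- d; dp$group <- sample(dp$group)
  acc_perm <- mean(lda_classify(run_lda(dp)) == dp$group)
  expect_lt(acc_perm, 0.55)
})

test_that("singular covariance errors with advice, regularization rescues", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                      x = rep(1:5, 2), y = rep(1:5, 2) * 2)  # collinear
  expect_error(run_lda(d), "regularize")
  fit <- run_lda(d, regularize = 0.1)
  expect_s3_class(fit, "origin_lda")
  td <- tidy(fit)
  expect_true(all(c("variable", "axis", "correlation", "scaling") %in%
                    names(td)))
})
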