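test_that("PCA handles rank-1, isotropic and self-projection cases", {
  set.seed(1)
  # rank-1: points on y = 2x with negligible jitter
  x <- rnorm(200)
  d1 <- data.frame(a = x, b = 2 * x + rnorm(200, 0, 1e-9))
  p1 <- fit_pca(d1, features = c("a", "b"), standardize = FALSE)
  expect_gte(p1$explained_variance[1], 0.999)

  # isotropic: both components explain half the variance
  d2 <- data.frame(a = rnorm(1e4), b = rnorm(1e4))
  p2 <- fit_pca(d2, features = c("a", "b"))
  expect_equal(p2$explained_variance[1], 0.5, tolerance = 0.02)
  expect_equal(p2$explained_variance[2], 0.5, tolerance = 0.02)

  # reference scores are uncorrelated and centered by construction
  recs <- two_cluster_records(n_per = 60, seed = 2)
  model <- fit_pca(recs)
  expect_true(all(abs(crossprod(model$loadings) - diag(12)) < 1e-8))
  expect_false(is.unsorted(rev(model$explained_variance)))
  scores <- pca_project(recs, model)
  S <- cov(as.matrix(scores[, 1:12]))
  expect_lt(max(abs(S - diag(diag(S)))), 1e-6)
  expect_lt(max(abs(colMeans(as.matrix(scores[, 1:12])))), 1e-10)
})

test_that("projection is linear algebra on the reference frame", {
  recs <- two_cluster_records(n_per = 30, seed = 4)
  model <- fit_pca(recs)
  # the reference center maps to the origin
  center_rec <- as.data.frame(as.list(model$center))
  expect_lt(max(abs(as.matrix(pca_project(center_rec, model)))), 1e-10)
  # longhand for three records
  three <- recs[1:3, ]
  X <- as.matrix(three[, model$feature_names])
  longhand <- sweep(sweep(X, 2, model$center), 2, model$scale, "/") %*% model$loadings
  expect_equal(unname(as.matrix(pca_project(three, model)[, 1:12])),
               unname(longhand), tolerance = 1e-12)
  # projecting the full table with the reference model equals projecting the
  # reference rows alone: the model is frozen, not refit
  other <- two_cluster_records(n_per = 30, seed = 5)
  other$condition <- "other"
  both <- rbind(recs, other)
  joint <- pca_project(both, model)
  expect_equal(as.matrix(joint[both$condition == "synthetic", 1:12]),
               as.matrix(pca_project(recs, model)[, 1:12]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_project(recs[, -3], model), "lack")
  expect_error(fit_pca(transform(recs, area = 1)), "constant feature")
})

test_that("Tukey HSD matches base R's implementation on unbalanced groups", {
  set.seed(9)
  groups <- list(a = rnorm(12, 10), b = rnorm(8, 10.5), c = rnorm(15, 9.8))
  ours <- tukey_hsd(groups)
  df <- data.frame(v = unlist(groups),
                   g = rep(names(groups), lengths(groups)))
  ref <- TukeyHSD(aov(v ~ g, df))$g
  for (i in seq_len(nrow(ours))) {
    key <- paste0(ours$group2[i], "-", ours$group1[i])
    expect_equal(ours$mean_diff[i], unname(ref[key, "diff"]), tolerance = 1e-10)
    expect_equal(ours$lower[i], unname(ref[key, "lwr"]), tolerance = 1e-10)
    expect_equal(ours$upper[i], unname(ref[key, "upr"]), tolerance = 1e-10)
  }
})

test_that("Tukey HSD basic behaviour and invariances", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  r <- tukey_hsd(same)
  expect_equal(r$mean_diff, 0)
  expect_true(r$accept)

  set.seed(3)
  apart <- list(a = rnorm(50, 0, 0.1), b = rnorm(50, 100, 0.1))
  expect_false(tukey_hsd(apart)$accept)

  # swapping the pair mirrors the interval, accept unchanged
  fwd <- tukey_hsd(list(a = apart$a, b = apart$b))
  rev <- tukey_hsd(list(b = apart$b, a = apart$a))
  expect_equal(fwd$mean_diff, -rev$mean_diff)
  expect_equal(fwd$lower, -rev$upper)
  expect_equal(fwd$upper, -rev$lower)
  expect_equal(fwd$accept, rev$accept)

  # adding a constant to every value changes no interval width or accept
  shifted <- lapply(apart, function(x) x + 1e3)
  expect_equal(tukey_hsd(shifted)$upper - tukey_hsd(shifted)$lower,
               fwd$upper - fwd$lower, tolerance = 1e-9)

  expect_error(tukey_hsd(list(a = 1, b = c(1, 2))), "at least 2 values")
  expect_error(tukey_hsd(list(a = c(1, 2))), "at least two samples")
})

test_that("the equivalence margin turns accept into a positive claim", {
  set.seed(11)
  # tiny true difference, large n: classic test rejects, equivalence accepts
  close <- list(a = rnorm(2000, 0, 1), b = rnorm(2000, 0.001, 1))
  r <- tukey_hsd(close, equivalence_margin = 0.5)
  expect_true(r$accept)
  # small n: wide interval fails to reject, but cannot claim equivalence
  vague <- list(a = rnorm(4, 0, 5), b = rnorm(4, 0, 5))
  expect_false(tukey_hsd(vague, equivalence_margin = 0.01)$accept)
  expect_error(tukey_hsd(close, equivalence_margin = -1), "positive")
})

test_that("a condition is maximally similar to itself", {
  recs <- two_cluster_records(n_per = 60, seed = 21)
  dup <- recs
  dup$condition <- "copy"
  both <- rbind(recs, dup)
  prof <- similarity_profile("copy", "synthetic", both)
  expect_equal(prof$total, 12)
  expect_true(all(prof$accept))

  model <- fit_pca(recs)
  pc <- pc_similarity("copy", "synthetic", both, model)
  expect_true(all(pc$accept))
  expect_equal(pc$mean_diff, c(0, 0))
})

test_that("a single strongly shifted feature costs exactly one similarity point", {
  spec <- population_spec(list(c(100, 0.7), c(300, 0.5)),
                          list(c(15, 0.05), c(20, 0.05)),
                          c(0.5, 0.5), n = 500, seed = 31)
  a <- sample_population(spec)
  b <- a
  b$condition <- "shifted"
  b$bmd <- b$bmd + 10 * sd(b$bmd)  # one feature far off, rest identical
  both <- rbind(a, b)
  prof <- similarity_profile("shifted", "synthetic", both)
  expect_false(prof$accept[["bmd"]])
  expect_equal(prof$total, 11)
  expect_error(similarity_profile("nope", "synthetic", both), "unknown condition")
})

test_that("a size shift is seen on PC1 but not PC2", {
  spec <- population_spec(list(c(100, 0.7), c(300, 0.5)),
                          list(c(15, 0.05), c(20, 0.05)),
                          c(0.5, 0.5), n = 500, seed = 41)
  ref <- sample_population(spec)
  model <- fit_pca(ref)
  shifted <- ref
  shifted$condition <- "bigger"
  # displace every record along the size axis (PC1) by 5 score sds: the
  # feature-space direction is loadings[, 1] scaled back to raw units
  scores <- pca_project(ref, model)
  delta <- 5 * sd(scores$PC1) * model$loadings[, 1] * model$scale
  for (f in model$feature_names) {
    shifted[[f]] <- shifted[[f]] + delta[[f]]
  }
  both <- rbind(ref, shifted)
  pc <- pc_similarity("bigger", "synthetic", both, model)
  expect_false(pc$accept[pc$component == "PC1"])
  expect_true(pc$accept[pc$component == "PC2"])
})
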