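test_that("EM recovers well-separated clusters against the known-label oracle", {
  recs <- two_cluster_records(n_per = 100, seed = 101)
  fit <- fit_bigaussian(recs, seed = 1)
  # oracle: per-component sample means from the ground-truth labels
  for (k in 1:2) {
    truth_f <- mean(recs$max_feret[recs$true_component == k])
    truth_c <- mean(recs$circularity[recs$true_component == k])
    expect_lt(abs(fit$mu[k, 1] - truth_f) / truth_f, 0.05)
    expect_lt(abs(fit$mu[k, 2] - truth_c), 0.05)
  }
  truth_pf <- 100 * mean(recs$true_component == 1)
  expect_lt(abs(fit$pf1 - truth_pf), 5)
  # responsibilities are proper probabilities
  expect_true(all(fit$assignments$resp_cluster1 >= 0 &
                    fit$assignments$resp_cluster1 <= 1))
  expect_true(fit$converged)
})

test_that("degenerate input engages the variance floor and is flagged", {
  recs <- data.frame(max_feret = rep(100, 20), circularity = rep(0.5, 20))
  expect_warning(fit <- fit_bigaussian(recs, seed = 1, restarts = 2),
                 "variance floored")
  expect_true(fit$degenerate)
})

test_that("too few records is an informative error", {
  recs <- two_cluster_records(n_per = 5)
  expect_error(fit_bigaussian(recs[1:9, ]), "at least 10 records")
})

test_that("log-likelihood never decreases across EM iterations", {
  recs <- two_cluster_records(n_per = 80, seed = 5)
  fit <- fit_bigaussian(recs, seed = 3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
})

test_that("cluster labels follow the smaller-mean-Feret rule across seeds", {
  recs <- two_cluster_records(n_per = 60, seed = 8)
  for (s in c(1, 2, 99)) {
    fit <- fit_bigaussian(recs, seed = s, restarts = 4)
    expect_lt(fit$mu[1, 1], fit$mu[2, 1])
  }
})

test_that("fits are invariant to record order given the same seed", {
  recs <- two_cluster_records(n_per = 60, seed = 12)
  fit1 <- fit_bigaussian(recs, seed = 7)
  perm <- sample(nrow(recs))
  fit2 <- fit_bigaussian(recs[perm, ], seed = 7)
  expect_equal(fit1$mu, fit2$mu, tolerance = 1e-6)
  expect_equal(fit1$pf1, fit2$pf1, tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit1$assignments$cluster[perm], fit2$assignments$cluster)
})

test_that("the confidence interval follows the 1.96 sd / sqrt(n) formula", {
  expect_equal(confidence_interval(rep(3.5, 10)),
               c(mean = 3.5, lower = 3.5, upper = 3.5))
  x <- rnorm(100)
  x <- (x - mean(x)) / sd(x) + 5  # sample sd exactly 1
  ci <- confidence_interval(x)
  expect_equal(unname(ci["upper"] - ci["mean"]), 0.196, tolerance = 1e-12)
  # round trip with the generator-side inversion
  y <- rnorm(255)
  y <- (y - mean(y)) / sd(y) * 69.25
  ci <- confidence_interval(y)
  hw <- unname(ci["upper"] - ci["mean"])
  expect_equal(derive_sd_from_ci(hw, 255), 69.25, tolerance = 1e-9)
  expect_warning(one <- confidence_interval(5), "degenerate")
  expect_equal(one, c(mean = 5, lower = 5, upper = 5))
  expect_error(confidence_interval(numeric(0)), "empty")
})

test_that("representative particles are the nearest to the cluster centroid", {
  recs <- two_cluster_records(n_per = 40, seed = 31)
  fit <- fit_bigaussian(recs, seed = 2)
  # brute-force oracle in z-scored space
  X <- as.matrix(recs[, fit$features])
  Z <- scale(X)
  for (cl in 1:2) {
    members <- which(fit$assignments$cluster == cl)
    centroid <- colMeans(Z[members, , drop = FALSE])
    d <- sqrt(rowSums(sweep(Z[members, , drop = FALSE], 2, centroid)^2))
    top3 <- representative_particles(fit, recs, cluster = cl, k = 3)
    expect_equal(top3$label, recs$label[members[order(d)[1:3]]])
    expect_false(is.unsorted(top3$centroid_distance))
    # k = cluster size returns the whole cluster, sorted
    all_m <- representative_particles(fit, recs, cluster = cl, k = length(members))
    expect_setequal(all_m$label, recs$label[members])
    expect_false(is.unsorted(all_m$centroid_distance))
  }
  expect_error(representative_particles(fit, recs, cluster = 1, k = 1e5),
               "has only")
})

test_that("the population table has the standard layout and rounding", {
  recs <- two_cluster_records(n_per = 60, seed = 3)
  fit <- fit_bigaussian(recs, seed = 1)
  tab <- population_table(list(flask = fit))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$feature, c("max_feret", "circularity"))
  expect_true(all(tab$ci1_lower <= tab$mu1 & tab$mu1 <= tab$ci1_upper))
  expect_true(all(tab$ci2_lower <= tab$mu2 & tab$mu2 <= tab$ci2_upper))

  fake <- data.frame(condition = "c1", feature = "max_feret",
                     mu1 = 87.4, ci1_lower = 78.2, ci1_upper = 95.3,
                     mu2 = 313.1, ci2_lower = 303.4, ci2_upper = 322.6,
                     pf1 = 51.4)
  fmt <- format_population_table(fake)
  expect_equal(fmt$pf1, "51")
  expect_equal(fmt$mu1, "87")
  expect_equal(fmt$ci_mu1, "78-95")
  expect_equal(fmt$feature, "Feret's diameter")
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  recs <- two_cluster_records(n_per = 100, seed = 55)
  fit <- fit_bigaussian(recs, seed = 4)
  mc <- mclust::Mclust(recs[, c("max_feret", "circularity")], G = 2,
                       modelNames = "VVV", verbose = FALSE)
  mc_means <- t(mc$parameters$mean)
  o <- order(mc_means[, 1])
  expect_equal(unname(fit$mu), unname(mc_means[o, ]), tolerance = 0.02)
  expect_equal(fit$pf1, 100 * mc$parameters$pro[o[1]], tolerance = 2)
})
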