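test_that("spectral clustering separates exactly disconnected blocks", {
  n <- 10
  w <- matrix(0, n, n, dimnames = list(sprintf("P%02d", 1:n),
                                       sprintf("P%02d", 1:n)))
  w[1:5, 1:5] <- 0.8
  w[6:10, 6:10] <- 0.6
  diag(w) <- 1
  a <- spectral_clusters(w, 2, seed = 1)
  truth <- rep(1:2, each = 5)
  skip_if_not_installed("mclust")
  expect_equal(ari(a$labels, truth), 1)
  ## scaled partition matrix is orthonormal
  expect_equal(crossprod(a$q), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("requesting as many clusters as patients yields singletons", {
  set.seed(2)
  n <- 5
  w <- matrix(runif(n * n, 0.1, 0.9), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  dimnames(w) <- list(paste0("P", 1:n), paste0("P", 1:n))
  a <- spectral_clusters(w, n, seed = 1)
  expect_identical(sort(unname(a$labels)), 1:n)
  expect_error(spectral_clusters(w, n + 1), "n_clusters")
})

test_that("cluster labels are canonical: largest cluster first", {
  co <- simulate_cohort(30, 2, effect_size = 2, seed = 4)
  a <- spectral_clusters(fuse_views(co$views, k = 5), 2, seed = 4)
  sizes <- table(a$labels)
  expect_true(sizes[1] >= sizes[2])
})

test_that("normalized Laplacian eigenvalues lie in [0, 2]", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    w <- matrix(runif(n * n, 0.01, 1), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 1
    dimnames(w) <- list(paste0("P", 1:n), paste0("P", 1:n))
    a <- spectral_clusters(w, 2, seed = 1)
    expect_true(all(a$eigenvalues > -1e-10 & a$eigenvalues < 2 + 1e-10))
  }
})

test_that("clustering is invariant to patient permutation up to label names", {
  co <- simulate_cohort(24, 2, effect_size = 2, seed = 7)
  f <- fuse_views(co$views, k = 4)
  a <- spectral_clusters(f, 2, seed = 3)
  set.seed(8)
  perm <- sample(rownames(f$w))
  ap <- spectral_clusters(f$w[perm, perm], 2, seed = 3)
  skip_if_not_installed("mclust")
  expect_equal(ari(a$labels[perm], ap$labels[perm]), 1)
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  clin <- data.frame(patient_id = paste0("P", 1:4),
                     os_time = 1:4, os_event = 1L)
  km <- km_estimate(clin)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  clin2 <- data.frame(patient_id = paste0("P", 1:4),
                      os_time = 1:4, os_event = c(1L, 0L, 1L, 0L))
  km2 <- km_estimate(clin2)
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$surv, c(3 / 4, 3 / 8))

  clin3 <- data.frame(patient_id = paste0("P", 1:3),
                      os_time = c(5, 6, 7), os_event = 0L)
  expect_identical(nrow(km_estimate(clin3)), 0L)

  clin_bad <- data.frame(patient_id = "P1", os_time = -1, os_event = 1L)
  expect_error(km_estimate(clin_bad), "os_time")
})

test_that("log-rank statistic matches a per-event-time hand computation", {
  ## identical event-time multisets: observed = expected everywhere
  clin_eq <- data.frame(patient_id = paste0("P", 1:6),
                        os_time = c(1, 2, 3, 1, 2, 3), os_event = 1L)
  labs_eq <- stats::setNames(rep(1:2, each = 3), clin_eq$patient_id)
  lr_eq <- logrank_test(clin_eq, labs_eq)
  expect_equal(lr_eq$chisq, 0, tolerance = 1e-12)
  expect_equal(lr_eq$p_value, 1)

  clin <- data.frame(patient_id = paste0("P", 1:6),
                     os_time = c(1, 3, 5, 2, 4, 6),
                     os_event = c(1L, 1L, 0L, 1L, 1L, 1L))
  labs <- stats::setNames(rep(1:2, each = 3), clin$patient_id)
  ## independent oracle: sum (O - E) and hypergeometric variance over the
  ## distinct event times
  oe <- 0
  vv <- 0
  for (t in sort(clin$os_time[clin$os_event == 1])) {
    at_risk <- clin$os_time >= t
    n1 <- sum(at_risk & labs == 1)
    nt <- sum(at_risk)
    d1 <- sum(clin$os_time == t & clin$os_event == 1 & labs == 1)
    dt <- sum(clin$os_time == t & clin$os_event == 1)
    oe <- oe + d1 - dt * n1 / nt
    if (nt > 1) {
      vv <- vv + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
    }
  }
  lr <- logrank_test(clin, labs)
  expect_equal(lr$chisq, oe^2 / vv, tolerance = 1e-10)
  expect_identical(lr$df, 1L)

  expect_error(logrank_test(clin, stats::setNames(rep(1, 6),
                                                  clin$patient_id)),
               "2 non-empty")
})

test_that("log-rank null p-values are uniform under equal hazards", {
  labs <- stats::setNames(rep(1:2, each = 100), sprintf("P%03d", 1:200))
  pvals <- vapply(1:500, function(s) {
    surv <- simulate_survival(labs, c(0.002, 0.002), 0.2, seed = s)
    logrank_test(surv, labs)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("survival-guided selection returns the candidate table and respects ties", {
  co <- simulate_cohort(40, 2, effect_size = 2, seed = 10)
  surv <- simulate_survival(co$truth$labels, c(0.004, 0.001), 0.2,
                            seed = 11)
  f <- fuse_views(co$views)
  sel1 <- select_cluster_number(f, surv, c_range = 2, seed = 1)
  expect_identical(sel1$best_c, 2L)
  sel <- select_cluster_number(f, surv, 2:4, seed = 1)
  expect_identical(sel$selection$n_clusters, 2:4)
  expect_identical(sel$best_c,
                   sel$selection$n_clusters[which.min(sel$selection$p_value)])
  expect_error(select_cluster_number(f, surv, integer(0)), "non-empty")
})

test_that("the fitted model object carries labels, selection and methods", {
  co <- simulate_cohort(40, 2, effect_size = 2, seed = 14)
  surv <- simulate_survival(co$truth$labels, c(0.004, 0.001), 0.2,
                            seed = 15)
  fit <- snf_subtype(co$views, surv, c_range = 2:3, seed = 14)
  expect_s3_class(fit, "snf_subtype")
  expect_identical(fit$assignment$n_clusters, fit$selection$n_clusters[
    which.min(fit$selection$p_value)])
  expect_length(subtype_labels(fit), 40L)
  expect_output(print(fit), "log-rank")
  expect_output(summary(fit), "Subtype sizes")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_error(snf_subtype(co$views), "clinical")
  fit2 <- snf_subtype(co$views, n_subtypes = 2, seed = 14)
  expect_null(fit2$selection)
  skip_if_not_installed("mclust")
  expect_gt(ari(subtype_labels(fit2), co$truth$labels), 0.9)
})
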