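test_that("marginalization is additive, orthogonal and exactly
          reconstructs the centered tensor", {
  tens <- make_tensor(U = 8, TT = 20, n_trials = 4, noise_sd = 0.5,
                      f = function(u, e, m, t) {
                        u * sin(5 * t) + (e == 1) * t + (m == 1) * cos(t)
                      }, seed = 2)
  ms <- marginalize(tens)
  Xc <- sweep(tens$avg, 1, apply(tens$avg, 1, mean))
  recon <- Reduce(`+`, ms$margs)
  expect_lt(max(abs(recon - Xc)) / max(abs(Xc)), 1e-12)
  tot <- sum(Xc^2)
  parts <- sum(vapply(ms$margs, function(a) sum(a^2), numeric(1)))
  expect_equal(parts, tot, tolerance = 1e-12)
})

test_that("condition-independent input yields zero condition
          marginalizations", {
  tens <- make_tensor(U = 6, TT = 15, n_trials = 3,
                      f = function(u, e, m, t) u + sin(10 * t))
  ms <- marginalize(tens)
  expect_equal(max(abs(ms$margs$emotion)), 0)
  expect_equal(max(abs(ms$margs$memory)), 0)
  expect_equal(max(abs(ms$margs$interaction)), 0)
})

test_that("a pure emotion plant concentrates variance in the emotion
          marginalization", {
  set.seed(33)
  g <- runif(10, 0.5, 2)
  tens <- make_tensor(U = 10, TT = 25, n_trials = 3,
                      f = function(u, e, m, t) {
                        g[u] * sin(8 * t) * ifelse(e == 1, 1, -1)
                      }, seed = 3)
  ms <- marginalize(tens)
  tot <- sum(vapply(ms$margs, function(a) sum(a^2), numeric(1)))
  expect_gt(sum(ms$margs$emotion^2) / tot, 1 - 1e-10)
  # fit recovers the planted axis: decoder ~ unit gain direction
  m <- fit_dpca(tens, n_components = 3, lambda = 0)
  expect_equal(m$marg[1], "emotion")
  enc <- m$encoder[, 1]
  cosine <- abs(sum(enc * g) / sqrt(sum(enc^2) * sum(g^2)))
  expect_gt(cosine, 0.99)
})

test_that("unregularized single-marginalization dPCA equals PCA (SVD
          oracle)", {
  tens <- make_tensor(U = 9, TT = 20, n_trials = 4, noise_sd = 0.3,
                      f = function(u, e, m, t) {
                        u * t + e * sin(6 * t) + m * cos(3 * t)
                      }, seed = 4)
  m <- fit_dpca(tens, n_components = 4, lambda = 0,
                marginalizations = "full")
  X <- matrix(sweep(tens$avg, 1, apply(tens$avg, 1, mean)), nrow = 9)
  sv <- svd(X)
  for (k in 1:4) {
    cosine <- abs(sum(m$encoder[, k] * sv$u[, k]))
    expect_gte(cosine, 1 - 1e-8)
    dcos <- abs(sum(m$decoder[k, ] * sv$u[, k])) /
      sqrt(sum(m$decoder[k, ]^2))
    expect_gte(dcos, 1 - 1e-8)
  }
  expect_equal(m$explained_var_pct,
               100 * sv$d[1:4]^2 / sum(sv$d^2), tolerance = 1e-8)
})

test_that("a zero tensor gives zero explained variance and no NaNs", {
  tens <- make_tensor(U = 5, TT = 10, n_trials = 2)
  m <- fit_dpca(tens, n_components = 3)
  expect_true(all(m$explained_var_pct == 0))
  expect_false(any(is.nan(m$scores)))
  expect_error(fit_dpca(tens, n_components = 6), "exceeds")
})

test_that("explained-variance report normalizes and is monotone", {
  tens <- make_tensor(U = 10, TT = 20, n_trials = 4, noise_sd = 0.4,
                      f = function(u, e, m, t) {
                        u * t + e * sin(6 * t) + (m + e * m) * cos(4 * t)
                      }, seed = 6)
  m <- fit_dpca(tens, n_components = 8)
  ev <- explained_variance(m, tens, first_k = 6)
  expect_equal(sum(ev$pie_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(ev$cumulative) >= -1e-12))
  expect_equal(sum(ev$marginalization_pct), 100, tolerance = 1e-9)
  # components are ranked by explained variance
  expect_true(all(diff(m$explained_var_pct) <= 1e-12))
})

test_that("signal-variance estimate: 1 for noiseless repeats, small for
          pure noise, and noisier with fewer trials", {
  noiseless <- make_tensor(U = 6, TT = 15, n_trials = 4,
                           f = function(u, e, m, t) u * sin(5 * t) + e)
  expect_equal(as.numeric(estimate_signal_variance(noiseless)), 1)
  pure_noise <- make_tensor(U = 15, TT = 20, n_trials = 20, noise_sd = 1,
                            seed = 7)
  expect_lte(as.numeric(estimate_signal_variance(pure_noise)), 0.1)
  # 1/n law: halving the trial count raises the estimated noise share
  big <- make_tensor(U = 10, TT = 15, n_trials = 20, noise_sd = 1,
                     f = function(u, e, m, t) 0.5 * e * sin(4 * t),
                     seed = 8)
  small <- big
  small$single <- big$single[, , , 1:10, , drop = FALSE]
  small$counts <- array(10L, dim(big$counts))
  small$avg <- apply(small$single, c(1, 2, 3, 5), mean)
  expect_gt(attr(estimate_signal_variance(small), "noise_ss") /
              attr(estimate_signal_variance(small), "total_ss"),
            attr(estimate_signal_variance(big), "noise_ss") /
              attr(estimate_signal_variance(big), "total_ss"))
})

test_that("perfectly separated constant conditions decode at accuracy 1", {
  tens <- make_tensor(U = 6, TT = 10, n_trials = 4, noise_sd = 0.01,
                      f = function(u, e, m, t) {
                        ifelse(e == 1, 2, -2) + 0.2 * m
                      }, seed = 9)
  m <- fit_dpca(tens, n_components = 4)
  sig <- decode_significance(m, tens, n_iter = 20, n_shuffles = 20,
                             seed = 1, margs = "emotion")
  expect_true(all(sig$emotion$accuracy > 0.99))
  expect_true(all(sig$emotion$significant))
  expect_equal(sig$emotion$chance, 0.5)
})

test_that("label-shuffled data produce few significant bins", {
  set.seed(10)
  fracs <- vapply(1:4, function(r) {
    tens <- make_tensor(U = 12, TT = 25, n_trials = 6, noise_sd = 1,
                        seed = 20 + r)
    m <- fit_dpca(tens, n_components = 12)
    sig <- decode_significance(m, tens, n_iter = 50, n_shuffles = 50,
                               seed = r, margs = "emotion")
    mean(sig$emotion$significant)
  }, numeric(1))
  expect_lte(mean(fracs), 0.07)
})

test_that("decoding significance localizes a planted separation window", {
  time <- seq(-0.495, 2.5, by = 0.01)
  inwin <- time >= 0.2 & time <= 0.8
  tens <- make_tensor(U = 20, TT = length(time), n_trials = 8,
                      noise_sd = 0.35, time = time,
                      f = function(u, e, m, t) {
                        ifelse(t >= 0.2 & t <= 0.8,
                               ifelse(e == 1, 1, -1), 0)
                      }, seed = 11)
  m <- fit_dpca(tens, n_components = 5)
  sig <- decode_significance(m, tens, n_iter = 100, n_shuffles = 100,
                             seed = 3, margs = "emotion")
  hit <- sig$emotion$significant
  expect_gte(mean(hit[inwin]), 0.8)        # covers the planted window
  expect_lte(mean(hit[!inwin]), 0.15)      # and little outside it
})

test_that("PCA baseline: orthonormal loadings, Eckart-Young dominance,
          rank-1 input", {
  tens <- make_tensor(U = 8, TT = 20, n_trials = 3, noise_sd = 0.5,
                      f = function(u, e, m, t) u * e * sin(3 * t),
                      seed = 12)
  pb <- pca_baseline(tens, n_components = 4)
  G <- crossprod(pb$loadings)
  expect_lt(max(abs(G - diag(4))), 1e-10)
  m <- fit_dpca(tens, n_components = 4)
  for (k in 1:4) {
    expect_gte(sum(pb$explained_var_pct[1:k]) + 1e-9,
               emospike:::dpca_joint_var(m, tens, k))
  }
  rank1 <- make_tensor(U = 6, TT = 10, n_trials = 2,
                       f = function(u, e, m, t) u * sin(7 * t))
  sv <- pca_baseline(rank1, n_components = 3)$singular_values
  expect_gt(sv[1], 1e-6)
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("cross-validated lambda returns a grid member and behaves at
          high noise", {
  tens <- make_tensor(U = 8, TT = 12, n_trials = 6, noise_sd = 1,
                      f = function(u, e, m, t) 0.3 * e * sin(4 * t),
                      seed = 13)
  lam <- cv_lambda(tens, grid = c(0, 1e-4, 1e-2), n_folds = 3,
                   n_components = 4, seed = 5)
  expect_true(as.numeric(lam) %in% c(0, 1e-4, 1e-2))
  expect_equal(length(attr(lam, "errors")), 3L)
})

test_that("leave-one-region-out: empty region is identity, planted AMY
          effect disappears only when AMY is removed", {
  time <- seq(-0.25, 1.25, by = 0.01)
  regions <- rep(c("AMY", "HIP"), each = 10)
  is_amy <- regions == "AMY"
  tens <- make_tensor(U = 20, TT = length(time), n_trials = 6,
                      noise_sd = 0.3, time = time, regions = regions,
                      f = function(u, e, m, t) {
                        if (u <= 10) ifelse(e == 1, 1, -1) *
                          (t > 0.1 & t < 0.9) else 0
                      }, seed = 14)
  expect_error(leave_one_region_out(tens, "XX"), "unknown region")
  base <- fit_dpca(tens, n_components = 5)
  base_sig <- decode_significance(base, tens, n_iter = 40,
                                  n_shuffles = 40, seed = 2)
  # removing EC (absent) reproduces the full model
  lo_ec <- leave_one_region_out(tens, "EC", full_model = base,
                                full_sig = base_sig, n_components = 5,
                                n_iter = 40, n_shuffles = 40, seed = 2)
  expect_equal(lo_ec$n_excluded, 0L)
  expect_equal(lo_ec$model$explained_var_pct, base$explained_var_pct)
  expect_equal(lo_ec$delta_sig_bins[["emotion"]], 0)
  # removing AMY abolishes the emotion decoding; removing HIP does not
  lo_amy <- leave_one_region_out(tens, "AMY", full_model = base,
                                 full_sig = base_sig, n_components = 5,
                                 n_iter = 40, n_shuffles = 40, seed = 2)
  lo_hip <- leave_one_region_out(tens, "HIP", full_model = base,
                                 full_sig = base_sig, n_components = 5,
                                 n_iter = 40, n_shuffles = 40, seed = 2)
  frac_amy <- mean(lo_amy$significance$emotion$significant)
  frac_hip <- mean(lo_hip$significance$emotion$significant)
  expect_lt(frac_amy, 0.15)
  expect_gt(frac_hip, 0.5)
})
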