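# Demixed principal component analysis, implemented from scratch.
#
# The trial-averaged population tensor X[unit, emotion, memory, time] is
# centered per unit and decomposed additively into marginalizations by
# sequential condition averaging:
#   time (condition-independent), emotion x time, memory x time,
#   emotion x memory x time (interaction).
# For each marginalization phi, dPCA finds decoder/encoder pairs (D, F)
# minimizing || X_phi - F D X ||^2 + ridge, solved in closed form as a
# reduced-rank ridge regression: A = X_phi X' (X X' + lambda_eff I)^{-1},
# with the rank-q projection taken from the SVD of A X. Components are
# pooled across marginalizations and ranked by explained variance.

MARGS <- c("time", "emotion", "memory", "interaction")

center_tensor <- function(tensor) {
  X <- tensor$avg
  sweep(X, 1, apply(X, 1, mean))
}

flatten <- function(A) matrix(A, nrow = dim(A)[1])

# pseudo-inverse of a symmetric PSD matrix (eigenvalue thresholding)
sym_pinv <- function(G, tol = 1e-10) {
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(G), ncol(G)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

#' Marginalize the population tensor by task factor
#'
#' Splits the unit-centered condition tensor into four additive parts:
#' condition-independent (time), emotion, memory and emotion-x-memory
#' interaction, via sequential condition averaging. The parts sum back to
#' the centered tensor exactly (machine precision) and are mutually
#' orthogonal, so their sums of squares add up to the total variance.
#'
#' @param tensor A `population_tensor` from [build_population_tensor()].
#' @return Object of class `marginalization_set`: list `margs` of four
#'   arrays with the tensor's dimensions, `grand_mean` (the per-unit mean
#'   that was removed), `dims`, and the condition labels.
#' @export
marginalize <- function(tensor) {
  d <- dim(tensor$avg)
  if (d[2] < 2L || d[3] < 2L) {
    stop("marginalization needs >= 2 levels on both condition axes",
         call. = FALSE)
  }
  Xc <- center_tensor(tensor)
  m_t <- apply(Xc, c(1, 4), mean)                       # unit x time
  t_full <- aperm(array(m_t, c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
  m_e <- apply(Xc, c(1, 2, 4), mean)                    # unit x E x time
  e_full <- aperm(array(m_e, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)) -
    t_full
  m_m <- apply(Xc, c(1, 3, 4), mean)                    # unit x M x time
  m_full <- aperm(array(m_m, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3)) -
    t_full
  x_full <- Xc - t_full - e_full - m_full
  structure(list(margs = list(time = t_full, emotion = e_full,
                              memory = m_full, interaction = x_full),
                 grand_mean = apply(tensor$avg, 1, mean), dims = d,
                 emotions = tensor$emotions, memories = tensor$memories,
                 time = tensor$time),
            class = "marginalization_set")
}

#' Fit demixed PCA
#'
#' Estimates, per marginalization, paired decoder (`D`) and encoder (`F`)
#' axes by ridge-regularized reduced-rank regression of the marginalized
#' tensor on the full centered tensor, pools the components and ranks them
#' by explained variance. The effective ridge is `lambda` times the total
#' sum of squares of the centered tensor, so `lambda` is scale-free and
#' `lambda = 0` reduces to an unregularized fit (plain PCA when fitted with
#' `marginalizations = "full"`). `lambda = "cv"` selects lambda on a log
#' grid by held-out-trial reconstruction error ([cv_lambda()]).
#'
#' @param tensor A `population_tensor`.
#' @param n_components Total components kept (default 20).
#' @param lambda Ridge fraction (scale-free), or `"cv"`.
#' @param seed Seed for the CV fold draws (used when `lambda = "cv"`).
#' @param q_per_marg Components extracted per marginalization before
#'   pooling (default `n_components`).
#' @param marginalizations Marginalizations to fit (default all four), or
#'   `"full"` to treat the whole centered tensor as a single
#'   marginalization (the PCA limit).
#' @return Object of class `dpca_model`: `decoder` (components x units),
#'   `encoder` (units x components, orthonormal within marginalization),
#'   `marg` (marginalization of each component), `scores` (components x
#'   conditions*time, conditions ordered emotion-fastest),
#'   `explained_var_pct`, `lambda`, `total_ss`, condition metadata.
#' @export
fit_dpca <- function(tensor, n_components = 20, lambda = 0, seed = 1,
                     q_per_marg = n_components,
                     marginalizations = MARGS) {
  d <- dim(tensor$avg)
  U <- d[1]
  if (n_components > U) {
    stop("n_components exceeds the number of units", call. = FALSE)
  }
  if (identical(lambda, "cv")) {
    lambda <- as.numeric(cv_lambda(tensor, n_components = n_components,
                                   seed = seed))
  }
  X <- flatten(center_tensor(tensor))          # U x N
  if (any(!is.finite(X))) stop("non-finite values in tensor", call. = FALSE)
  total_ss <- sum(X^2)
  marg_list <- if (identical(marginalizations, "full")) {
    list(full = X)
  } else {
    ms <- marginalize(tensor)
    lapply(ms$margs[marginalizations], flatten)
  }
  decoder <- NULL
  encoder <- NULL
  marg <- character()
  if (total_ss > 0) {
    lam_eff <- lambda * total_ss
    # Moore-Penrose fallback keeps the lambda = 0 limit well defined on
    # rank-deficient (e.g. noiseless synthetic) tensors
    Ginv <- sym_pinv(tcrossprod(X) + diag(lam_eff, U))
    for (phi in names(marg_list)) {
      Xphi <- marg_list[[phi]]
      if (sum(Xphi^2) / total_ss < 1e-14) next
      A <- Xphi %*% crossprod(X, Ginv)         # U x U
      AX <- A %*% X
      q <- min(q_per_marg, U, qr(AX)$rank)
      if (q < 1L) next
      sv <- svd(AX, nu = q, nv = 0)
      Fq <- sv$u[, seq_len(q), drop = FALSE]   # U x q, orthonormal
      Dq <- crossprod(Fq, A)                   # q x U
      decoder <- rbind(decoder, Dq)
      encoder <- cbind(encoder, Fq)
      marg <- c(marg, rep(phi, q))
    }
  }
  if (is.null(decoder)) {                      # degenerate zero tensor
    q <- min(n_components, U)
    decoder <- matrix(0, q, U)
    encoder <- matrix(0, U, q)
    marg <- rep(names(marg_list)[1], q)
  }
  ev <- component_explained_var(X, decoder, encoder, total_ss)
  ord <- order(ev, decreasing = TRUE)
  keep <- ord[seq_len(min(n_components, length(ord)))]
  structure(list(decoder = decoder[keep, , drop = FALSE],
                 encoder = encoder[, keep, drop = FALSE],
                 marg = marg[keep],
                 scores = decoder[keep, , drop = FALSE] %*% X,
                 explained_var_pct = ev[keep], lambda = lambda,
                 total_ss = total_ss, dims = d,
                 emotions = tensor$emotions, memories = tensor$memories,
                 time = tensor$time, units = tensor$units),
            class = "dpca_model")
}

# Joint explained variance (% of total) of the first k components used
# together: 1 - ||X - F_k D_k X||^2 / ||X||^2. Unlike the sum of
# per-component variances this never double-counts shared variance, so it
# is the quantity bounded above by the PCA optimum (Eckart-Young).
dpca_joint_var <- function(model, tensor, k = length(model$marg)) {
  X <- flatten(center_tensor(tensor))
  tot <- sum(X^2)
  if (tot == 0) return(0)
  idx <- seq_len(min(k, length(model$marg)))
  R <- X - model$encoder[, idx, drop = FALSE] %*%
    (model$decoder[idx, , drop = FALSE] %*% X)
  100 * (1 - sum(R^2) / tot)
}

# Per-component explained variance (% of total): reduction in residual sum
# of squares when the single component f (d X) reconstructs X.
component_explained_var <- function(X, decoder, encoder, total_ss) {
  if (total_ss == 0) return(rep(0, nrow(decoder)))
  vapply(seq_len(nrow(decoder)), function(i) {
    R <- X - encoder[, i, drop = FALSE] %*%
      (decoder[i, , drop = FALSE] %*% X)
    100 * (1 - sum(R^2) / total_ss)
  }, numeric(1))
}

#' @export
print.dpca_model <- function(x, ...) {
  cat(sprintf("<dpca_model> %d components (lambda = %g)\n",
              length(x$marg), x$lambda))
  tab <- data.frame(component = seq_along(x$marg), marg = x$marg,
                    explained_var_pct = round(x$explained_var_pct, 2))
  print(utils::head(tab, 10), row.names = FALSE)
  invisible(x)
}

#' Cross-validated ridge selection for dPCA
#'
#' For each fold, one single trial per (unit, condition) cell is held out;
#' training condition averages are recomputed from the remaining trials, a
#' dPCA model is fitted at each candidate lambda, and the error of
#' reconstructing the held-out responses from the training averages is
#' accumulated. Returns the lambda with the smallest mean error.
#'
#' @param tensor A `population_tensor` (with single trials).
#' @param grid Candidate lambdas (default 0 and `10^(-7..-1)`).
#' @param n_folds Number of held-out draws (default 10).
#' @param n_components Components used in the reconstruction.
#' @param seed Seed for the held-out draws.
#' @return The selected lambda; attribute `"errors"` holds the per-lambda
#'   mean reconstruction errors.
#' @export
cv_lambda <- function(tensor, grid = c(0, 10^seq(-7, -1)), n_folds = 10,
                      n_components = 20, seed = 1) {
  cnt <- tensor$counts
  if (min(cnt) < 2L) {
    stop("lambda CV needs >= 2 trials per condition cell", call. = FALSE)
  }
  d <- dim(tensor$avg)
  n_components <- min(n_components, d[1])
  errs <- matrix(0, n_folds, length(grid))
  for (k in seq_len(n_folds)) {
    hold <- with_seed(child_seed(seed, "cvfold", k), {
      array(vapply(seq_len(d[1] * d[2] * d[3]),
                   function(i) sample.int(cnt[[i]], 1L), integer(1)),
            dim(cnt))
    })
    train <- tensor$avg
    test <- tensor$avg
    for (u in seq_len(d[1])) for (e in seq_len(d[2])) for (m in seq_len(d[3])) {
      n <- cnt[u, e, m]
      held <- tensor$single[u, e, m, hold[u, e, m], ]
      train[u, e, m, ] <- (tensor$avg[u, e, m, ] * n - held) / (n - 1)
      test[u, e, m, ] <- held
    }
    tr_tensor <- tensor
    tr_tensor$avg <- train
    mu <- apply(train, 1, mean)
    Xte <- flatten(sweep(test, 1, mu))
    for (g in seq_along(grid)) {
      fit <- fit_dpca(tr_tensor, n_components = n_components,
                      lambda = grid[g])
      Xtr <- flatten(sweep(train, 1, mu))
      recon <- fit$encoder %*% (fit$decoder %*% Xtr)
      errs[k, g] <- sum((Xte - recon)^2)
    }
  }
  mean_err <- colMeans(errs)
  out <- grid[which.min(mean_err)]
  attr(out, "errors") <- stats::setNames(mean_err, grid)
  out
}

#' Explained-variance accounting
#'
#' Per-component explained variance, per-marginalization totals (as % of
#' total variance; the marginalizations are orthogonal so the totals sum
#' to 100), the cumulative curve over the top `first_k` components, and
#' pie-normalized marginalization shares of the first `first_k` components
#' (summing to 100).
#'
#' @param model A `dpca_model`.
#' @param tensor The `population_tensor` it was fitted on.
#' @param first_k Components entering the cumulative curve and pie shares
#'   (default 15).
#' @return List: `component` (data frame: component, marg, pct),
#'   `marginalization_pct` (named, sums to 100), `cumulative` (length
#'   `first_k`), `pie_pct` (named by marginalization, sums to 100).
#' @export
explained_variance <- function(model, tensor, first_k = 15) {
  ms <- marginalize(tensor)
  total <- sum(flatten(center_tensor(tensor))^2)
  marg_pct <- vapply(ms$margs, function(A) {
    if (total == 0) 0 else 100 * sum(A^2) / total
  }, numeric(1))
  k <- min(first_k, length(model$explained_var_pct))
  top <- seq_len(k)
  cum <- cumsum(model$explained_var_pct[top])
  pie <- vapply(MARGS, function(phi) {
    sum(model$explained_var_pct[top][model$marg[top] == phi])
  }, numeric(1))
  if (sum(pie) > 0) pie <- 100 * pie / sum(pie)
  list(component = data.frame(component = seq_along(model$marg),
                              marg = model$marg,
                              pct = model$explained_var_pct),
       marginalization_pct = marg_pct, cumulative = cum, pie_pct = pie)
}

#' Estimate the signal fraction of the population variance
#'
#' The trial-averaged tensor mixes condition/time structure (signal) with
#' residual sampling noise: the noise variance of an n-trial average is
#' the single-trial noise variance over n. The across-trial variance per
#' (unit, condition, time) cell estimates the single-trial noise, so the
#' summed `var / n` estimates the noise content of the averages and
#' `1 - noise/total` the potentially explainable (signal) fraction --- the
#' dashed ceiling against which the cumulative dPCA variance is compared.
#'
#' @param tensor A `population_tensor` with >= 2 trials per cell.
#' @return Signal fraction in `[0, 1]`; attributes `"total_ss"` and
#'   `"noise_ss"`.
#' @export
estimate_signal_variance <- function(tensor) {
  if (min(tensor$counts) < 2L) {
    stop("signal-variance estimate needs >= 2 trials per condition cell",
         call. = FALSE)
  }
  d <- dim(tensor$avg)
  total <- sum(flatten(center_tensor(tensor))^2)
  noise <- 0
  for (u in seq_len(d[1])) for (e in seq_len(d[2])) for (m in seq_len(d[3])) {
    n <- tensor$counts[u, e, m]
    tr <- matrix(tensor$single[u, e, m, seq_len(n), ], nrow = n)
    mu <- colMeans(tr)
    v <- colSums(sweep(tr, 2, mu)^2) / (n - 1)
    noise <- noise + sum(v) / n
  }
  out <- max(0, min(1, if (total > 0) 1 - noise / total else 0))
  attr(out, "total_ss") <- total
  attr(out, "noise_ss") <- noise
  out
}

# Class index of each flattened condition (emotion fastest) for a
# marginalization's decoding task: emotion components decode the emotion
# label, memory components the memory label, interaction components the
# full condition tuple.
decode_classes <- function(marg, n_e, n_m) {
  cond <- expand.grid(e = seq_len(n_e), m = seq_len(n_m))
  switch(marg,
         emotion = cond$e,
         memory = cond$m,
         interaction = seq_len(n_e * n_m),
         stop("no decoding task for marginalization: ", marg,
              call. = FALSE))
}

#' Cross-validated decoding significance of condition components
#'
#' For the leading component of each condition marginalization (emotion,
#' memory, interaction), measures the time course of classification
#' accuracy using the component's decoder axis as a 1-D linear readout: on
#' each of `n_iter` stratified Monte Carlo iterations, one held-out single
#' trial per (unit, condition) forms a pseudo-trial population response,
#' which is classified at every time bin to the nearest training-class
#' mean along the decoder axis (ties toward the first class label). A null
#' distribution is built by reshuffling each unit's trial-to-condition
#' assignment (per-condition trial counts preserved) `n_shuffles` times
#' and repeating the cross-validation at `n_iter / 10` iterations per
#' shuffle; a time bin is significant where the real accuracy exceeds the
#' 97.5% quantile of the shuffled accuracies. The 95% and 100% quantile
#' curves are also returned.
#'
#' @param model A `dpca_model`.
#' @param tensor The `population_tensor` (single trials required, >= 2 per
#'   cell).
#' @param n_iter Monte Carlo cross-validation iterations (default 1000).
#' @param n_shuffles Label shuffles for the null (default 1000).
#' @param seed Integer master seed (CV draws and shuffles use derived
#'   substreams).
#' @param margs Marginalizations to decode (default the three condition
#'   marginalizations).
#' @return Named list per marginalization, each of class
#'   `decoding_significance`: `component` (index in the model),
#'   `accuracy` (per time bin), `shuffle_q95`, `shuffle_q975`,
#'   `shuffle_max`, `significant` (logical mask), `chance`, `time`.
#' @export
decode_significance <- function(model, tensor, n_iter = 1000,
                                n_shuffles = 1000, seed = 1,
                                margs = c("emotion", "memory",
                                          "interaction")) {
  d <- dim(tensor$avg)
  U <- d[1]; n_e <- d[2]; n_m <- d[3]; TT <- d[4]
  C <- n_e * n_m
  if (min(tensor$counts) < 2L) {
    stop("decoding needs >= 2 trials per condition cell", call. = FALSE)
  }
  counts <- matrix(0L, U, C)
  for (mm in seq_len(n_m)) for (ee in seq_len(n_e)) {
    counts[, (mm - 1L) * n_e + ee] <- tensor$counts[, ee, mm]
  }
  out <- list()
  for (mg in margs) {
    comp <- which(model$marg == mg)[1]
    if (is.na(comp)) next
    dvec <- as.numeric(model$decoder[comp, ])
    cls <- decode_classes(mg, n_e, n_m)
    n_cls <- max(cls)
    # per-condition projected single trials: proj[[ci]] is U x Jmax x T
    proj <- vector("list", C)
    for (mm in seq_len(n_m)) for (ee in seq_len(n_e)) {
      ci <- (mm - 1L) * n_e + ee
      proj[[ci]] <- tensor$single[, ee, mm, , , drop = FALSE] * dvec
      dim(proj[[ci]]) <- c(U, dim(tensor$single)[4], TT)
    }
    real_acc <- with_seed(child_seed(seed, mg, "real"), {
      decoder_cv(proj, counts, cls, n_cls, n_iter, U, C, TT)
    })
    n_iter_sh <- max(10L, ceiling(n_iter / 10))
    sh_acc <- matrix(0, n_shuffles, TT)
    for (b in seq_len(n_shuffles)) {
      proj_b <- with_seed(child_seed(seed, mg, "shuffle", b), {
        shuffle_condition_labels(proj, counts, U, C, TT)
      })
      sh_acc[b, ] <- with_seed(child_seed(seed, mg, "shufcv", b), {
        decoder_cv(proj_b, counts, cls, n_cls, n_iter_sh, U, C, TT)
      })
    }
    out[[mg]] <- structure(
      list(component = comp, accuracy = real_acc,
           shuffle_q95 = apply(sh_acc, 2, stats::quantile, probs = 0.95),
           shuffle_q975 = apply(sh_acc, 2, stats::quantile, probs = 0.975),
           shuffle_max = apply(sh_acc, 2, max),
           significant = real_acc >
             apply(sh_acc, 2, stats::quantile, probs = 0.975),
           chance = 1 / n_cls, n_iter = n_iter, n_shuffles = n_shuffles,
           time = tensor$time, seed = seed),
      class = "decoding_significance")
  }
  out
}

# One cross-validation pass: mean per-time-bin classification accuracy
# over n_iter stratified held-one-out draws. proj is a list of C arrays
# (U x Jmax x T) of decoder-projected single trials.
decoder_cv <- function(proj, counts, cls, n_cls, n_iter, U, C, TT) {
  totals <- lapply(seq_len(C), function(ci) {
    apply(proj[[ci]], c(1, 3), sum, na.rm = TRUE)       # U x T
  })
  Jmax <- dim(proj[[1]])[2]
  t_off <- (seq_len(TT) - 1L) * U * Jmax
  cls_n <- as.vector(table(factor(cls, seq_len(n_cls))))
  acc <- numeric(TT)
  for (it in seq_len(n_iter)) {
    pop_test <- matrix(0, C, TT)
    pop_train <- matrix(0, C, TT)
    for (ci in seq_len(C)) {
      j <- ceiling(stats::runif(U) * counts[, ci])
      base <- seq_len(U) + U * (j - 1L)
      held <- matrix(proj[[ci]][outer(base, t_off, "+")], U, TT)
      pop_test[ci, ] <- colSums(held)
      pop_train[ci, ] <- colSums((totals[[ci]] - held) / (counts[, ci] - 1L))
    }
    mu_cls <- rowsum(pop_train, cls) / cls_n              # n_cls x T
    best <- matrix(1L, C, TT)
    bestd <- abs(sweep(pop_test, 2, mu_cls[1, ], "-"))
    if (n_cls > 1L) for (k in 2:n_cls) {
      dk <- abs(sweep(pop_test, 2, mu_cls[k, ], "-"))
      upd <- dk < bestd                                   # strict: ties
      best[upd] <- k                                      # keep 1st class
      bestd[upd] <- dk[upd]
    }
    acc <- acc + colMeans(best == cls)
  }
  acc / n_iter
}

# Reassign each unit's trials to conditions uniformly at random while
# preserving the per-condition trial counts.
shuffle_condition_labels <- function(proj, counts, U, C, TT) {
  Jmax <- dim(proj[[1]])[2]
  out <- lapply(proj, function(a) array(NA_real_, c(U, Jmax, TT)))
  for (u in seq_len(U)) {
    nu <- counts[u, ]
    pool <- matrix(NA_real_, sum(nu), TT)
    pos <- 0L
    for (ci in seq_len(C)) {
      pool[pos + seq_len(nu[ci]), ] <-
        matrix(proj[[ci]][u, seq_len(nu[ci]), ], nu[ci], TT)
      pos <- pos + nu[ci]
    }
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    pos <- 0L
    for (ci in seq_len(C)) {
      out[[ci]][u, seq_len(nu[ci]), ] <- pool[pos + seq_len(nu[ci]), ]
      pos <- pos + nu[ci]
    }
  }
  out
}

#' Plain PCA baseline on the population matrix
#'
#' Singular value decomposition of the unit-centered `unit x
#' (condition * time)` matrix; the comparison baseline for dPCA.
#'
#' @param tensor A `population_tensor`.
#' @param n_components Number of components (default 5).
#' @return List: `loadings` (units x components, orthonormal), `scores`
#'   (components x conditions*time), `explained_var_pct`,
#'   `singular_values`.
#' @export
pca_baseline <- function(tensor, n_components = 5) {
  X <- flatten(center_tensor(tensor))
  k <- min(n_components, nrow(X), ncol(X))
  sv <- svd(X, nu = k, nv = 0)
  total <- sum(X^2)
  ev <- if (total > 0) 100 * sv$d[seq_len(k)]^2 / total else numeric(k)
  list(loadings = sv$u, scores = crossprod(sv$u, X),
       explained_var_pct = ev, singular_values = sv$d)
}

#' Leave-one-region-out dPCA rerun
#'
#' Refits the dPCA pipeline (fit, explained variance, decoding
#' significance) after excluding all units of one brain region, and
#' reports deltas against the full model: change in per-marginalization
#' variance shares and in the extent of significant decoding windows.
#'
#' @param tensor A `population_tensor`.
#' @param region Region to exclude (`"HIP"`, `"AMY"`, `"EC"`).
#' @param full_model,full_sig Optional precomputed full-population model
#'   and decoding significance (recomputed if missing).
#' @param n_components,lambda,n_iter,n_shuffles,seed As in [fit_dpca()]
#'   and [decode_significance()].
#' @return List: `model`, `significance`, `excluded_region`, `n_excluded`,
#'   `delta_marg_pct`, `delta_sig_bins` (per marginalization).
#' @export
leave_one_region_out <- function(tensor, region, full_model = NULL,
                                 full_sig = NULL, n_components = 20,
                                 lambda = 0, n_iter = 100,
                                 n_shuffles = 100, seed = 1) {
  if (!region %in% REGIONS) stop("unknown region: ", region, call. = FALSE)
  if (length(unique(tensor$units$region)) < 2L) {
    stop("leave-one-region-out needs >= 2 regions present", call. = FALSE)
  }
  keep <- tensor$units$region != region
  sub <- tensor
  sub$avg <- tensor$avg[keep, , , , drop = FALSE]
  sub$single <- tensor$single[keep, , , , , drop = FALSE]
  sub$counts <- tensor$counts[keep, , , drop = FALSE]
  sub$units <- tensor$units[keep, , drop = FALSE]
  if (is.null(full_model)) {
    full_model <- fit_dpca(tensor,
                           n_components = min(n_components,
                                              nrow(tensor$units)),
                           lambda = lambda, seed = seed)
  }
  if (is.null(full_sig)) {
    full_sig <- decode_significance(full_model, tensor, n_iter = n_iter,
                                    n_shuffles = n_shuffles, seed = seed)
  }
  model <- fit_dpca(sub, n_components = min(n_components, sum(keep)),
                    lambda = lambda, seed = seed)
  sig <- decode_significance(model, sub, n_iter = n_iter,
                             n_shuffles = n_shuffles, seed = seed)
  ev_full <- explained_variance(full_model, tensor)
  ev_sub <- explained_variance(model, sub)
  delta_marg <- ev_sub$marginalization_pct - ev_full$marginalization_pct
  delta_sig <- vapply(names(sig), function(mg) {
    sum(sig[[mg]]$significant) -
      if (mg %in% names(full_sig)) sum(full_sig[[mg]]$significant) else 0L
  }, numeric(1))
  list(model = model, significance = sig, excluded_region = region,
       n_excluded = sum(!keep), delta_marg_pct = delta_marg,
       delta_sig_bins = delta_sig)
}

#' Plot dPCA component time courses
#'
#' Base-graphics view of selected components: component score against
#' peri-stimulus time, one line per condition, with stimulus onset and
#' offset marked.
#'
#' @param model A `dpca_model`.
#' @param components Component indices to plot (default the top 4).
#' @export
plot_dpca <- function(model,
                      components = seq_len(min(4, length(model$marg)))) {
  C <- model$dims[2] * model$dims[3]
  conds <- as.vector(outer(model$emotions, model$memories, paste0))
  op <- graphics::par(mfrow = c(length(components), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (i in components) {
    S <- matrix(model$scores[i, ], nrow = C)
    graphics::matplot(model$time, t(S), type = "l", lty = 1,
                      xlab = "time (s)", ylab = "score",
                      main = sprintf("dPC %d (%s, %.1f%%)", i,
                                     model$marg[i],
                                     model$explained_var_pct[i]))
    graphics::abline(v = c(0, 0.5), col = "grey60", lty = 2)
    graphics::legend("topright", legend = conds, col = seq_len(C),
                     lty = 1, cex = 0.6, bty = "n")
  }
  invisible(model)
}
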