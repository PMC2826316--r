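#' Column scaling specification
#'
#' Mean-centering plus one of the standard chemometric column scalings:
#' `"pareto"` divides each centered column by the square root of its
#' standard deviation (suppressing, without silencing, peak-free spectral
#' regions — the convention for bucketed NMR data), `"unit_variance"`
#' divides by the standard deviation (the convention for peak tables and
#' expression blocks where every feature is a real, identified quantity),
#' `"none"` leaves the centered columns as they are.
#'
#' @param mode `"pareto"`, `"unit_variance"` or `"none"`.
#' @param center mean-center columns first.
#' @return object of class `scaling_spec`.
#' @export
scaling_spec <- function(mode = c("pareto", "unit_variance", "none"),
                         center = TRUE) {
  structure(list(mode = match.arg(mode), center = isTRUE(center)),
            class = "scaling_spec")
}

#' Center and scale a sample x feature matrix
#'
#' Zero-variance columns cannot be scaled and are dropped with a message
#' (never divided by zero); the returned centers/scales refer to the kept
#' columns.
#'
#' @param X samples x features numeric matrix, >= 2 rows.
#' @param spec a [scaling_spec()].
#' @return list with `X` (scaled matrix), `centers`, `scales`, `dropped`
#'   (names/indices of removed zero-variance columns).
#' @export
scale_matrix <- function(X, spec = scaling_spec()) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("scaling needs at least 2 samples")
  sds <- apply(X, 2, stats::sd)
  drop <- spec$mode != "none" & sds == 0
  if (spec$mode != "none" && all(drop)) stop("all columns have zero variance")
  kept <- which(!drop)
  dropped <- if (is.null(colnames(X))) which(drop) else colnames(X)[drop]
  if (any(drop)) {
    message("dropping ", sum(drop), " zero-variance column(s)")
    X <- X[, kept, drop = FALSE]
    sds <- sds[kept]
  }
  centers <- if (spec$center) colMeans(X) else rep(0, ncol(X))
  scales <- switch(spec$mode,
                   none = rep(1, ncol(X)),
                   pareto = sqrt(sds),
                   unit_variance = sds)
  Xs <- sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
  list(X = Xs, centers = centers, scales = scales,
       dropped = dropped, kept = kept)
}

apply_scaling <- function(X, centers, scales, kept = NULL) {
  X <- as.matrix(X)
  if (!is.null(kept)) X <- X[, kept, drop = FALSE]
  sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
}

#' Principal component analysis of a scaled matrix
#'
#' Computed by singular value decomposition of the (already centered and
#' scaled) matrix: loadings are the right singular vectors (orthonormal),
#' scores are `X %*% loadings`, and each component's R2X is its share of
#' the total variance, in decreasing order.
#'
#' @param X centered/scaled samples x features matrix.
#' @param n_components number of components; silently truncated to the
#'   matrix rank with a warning.
#' @return list with `scores`, `loadings`, `r2x` (per component).
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  sv <- svd(X)
  tot <- sum(sv$d^2)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components truncated from %d to rank %d",
                    n_components, rank))
    n_components <- rank
  }
  k <- seq_len(n_components)
  list(scores = sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components),
       loadings = sv$v[, k, drop = FALSE],
       r2x = sv$d[k]^2 / tot)
}

#' Fit a PLS regression model by NIPALS
#'
#' Partial least squares finds latent components maximizing the covariance
#' between the X block and the response, then regresses Y on the component
#' scores. Components are extracted by the NIPALS algorithm with deflation
#' of both blocks; for a single-column Y the weight vector is `X'y`
#' normalized, so the fit is deterministic and converges in one pass per
#' component. Inputs are expected already centered/scaled (see
#' [scale_matrix()]); the cross-validation and fusion wrappers handle
#' scaling internally.
#'
#' @param X centered/scaled samples x features matrix.
#' @param Y centered response vector or single/multi-column matrix.
#' @param n_components number of latent components (>= 1).
#' @param tol,max_iter NIPALS convergence control (multi-Y only).
#' @return object of class `pls_model`: weights `W`, X-loadings `P`,
#'   scores `T`, Y-loadings `Q` (components x Y-columns), regression
#'   coefficients `B` (for the full component count), per-component `r2x`,
#'   `r2y` and cumulative `r2y_cum`.
#' @export
fit_pls <- function(X, Y, n_components = 1, tol = 1e-12, max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned")
  if (n_components < 1) stop("n_components must be >= 1")
  if (all(apply(Y, 2, stats::sd) == 0))
    stop("Y is constant; a PLS response must vary")
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  ssx <- sum(X^2); ssy_tot <- sum(Y^2)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  Q <- matrix(0, n_components, m)
  r2x <- r2y <- numeric(n_components)
  Xd <- X; Yd <- Y
  for (a in seq_len(n_components)) {
    if (m == 1) {
      w <- crossprod(Xd, Yd)
      nw <- sqrt(sum(w^2))
      if (nw < sqrt(sum(Xd^2) * sum(Yd^2)) * 1e-14) {
        # Y carries no covariance with X: fall back to the dominant X
        # direction so the component is defined, with Y-loading ~ 0
        w <- svd(Xd, nu = 0, nv = 1)$v
      } else w <- w / nw
      t <- Xd %*% w
    } else {
      u <- Yd[, which.max(apply(Yd, 2, stats::var)), drop = FALSE]
      t_old <- NULL
      for (it in seq_len(max_iter)) {
        w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
        t <- Xd %*% w
        q <- crossprod(Yd, t) / sum(t^2)
        u <- Yd %*% q / sum(q^2)
        if (!is.null(t_old) && sqrt(sum((t - t_old)^2) / sum(t^2)) < tol) break
        t_old <- t
      }
    }
    tt <- sum(t^2)
    pl <- crossprod(Xd, t) / tt
    qa <- crossprod(Yd, t) / tt
    Xd <- Xd - t %*% t(pl)
    Yd <- Yd - t %*% t(qa)
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; Q[a, ] <- qa
    r2x[a] <- tt * sum(pl^2) / ssx
    r2y[a] <- tt * sum(qa^2) / ssy_tot
  }
  rownames(W) <- rownames(P) <- colnames(X)
  B <- W %*% solve(t(P) %*% W, Q)
  structure(list(W = W, P = P, T = Tm, Q = Q, B = B,
                 n_components = n_components,
                 r2x = r2x, r2y = r2y, r2y_cum = cumsum(r2y),
                 ssy = ssy_tot),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix on the same (centered/scaled) X scale as the
#'   training data.
#' @param n_components number of components to use (default: all fitted).
#' @param ... unused.
#' @return predicted Y matrix (centered scale).
#' @export
predict.pls_model <- function(object, newdata,
                              n_components = object$n_components, ...) {
  k <- seq_len(n_components)
  B <- object$W[, k, drop = FALSE] %*%
    solve(t(object$P[, k, drop = FALSE]) %*% object$W[, k, drop = FALSE],
          object$Q[k, , drop = FALSE])
  as.matrix(newdata) %*% B
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d component(s)\n", x$n_components))
  print(data.frame(component = seq_len(x$n_components),
                   R2X = round(x$r2x, 4), R2Y = round(x$r2y, 4),
                   R2Y_cum = round(x$r2y_cum, 4)))
  invisible(x)
}

cv_segments <- function(n, n_segments) {
  if (n_segments < 2) stop("n_segments must be >= 2")
  if (n < n_segments) stop("fewer samples than cross-validation segments")
  (seq_len(n) - 1) %% n_segments
}

# Fit scaling + PLS on a training subset, return held-out predictions on
# the original Y scale for each component count 1..ncomp.
fit_predict_fold <- function(X, Y, train, ncomp, x_scaling, y_center) {
  sc <- scale_matrix(X[train, , drop = FALSE], x_scaling)
  ytr <- Y[train]
  ym <- if (y_center) mean(ytr) else 0
  fit <- fit_pls(sc$X, ytr - ym, ncomp)
  Xte <- apply_scaling(X[!train, , drop = FALSE], sc$centers, sc$scales,
                       kept = sc$kept)
  preds <- vapply(seq_len(ncomp), function(a)
    as.numeric(predict(fit, Xte, n_components = a)) + ym,
    numeric(sum(!train)))
  matrix(preds, nrow = sum(!train))
}

#' Cross-validated Q2 of a PLS model
#'
#' Q2 measures how well held-out responses are predicted. Samples are split
#' into `n_segments` round-robin segments by input order (segment k holds
#' samples with index equal to k modulo `n_segments` — the "every 7th
#' sample" convention), the scaling and model are refit without each
#' segment, and the held-out responses are predicted. For component `a`,
#' `PRESS_a` is the prediction error sum of squares using `a` components
#' and `Q2_a = 1 - PRESS_a / SS_(a-1)` where `SS_(a-1)` is the residual sum
#' of squares of the previous component on the full-data fit (`SS_0` =
#' total sum of squares of the centered response). The cumulative Q2 is
#' `1 - prod_a(PRESS_a / SS_(a-1))`.
#'
#' @param X raw samples x features matrix (scaling is refit inside each
#'   training segment).
#' @param Y response vector.
#' @param n_components components to evaluate.
#' @param n_segments cross-validation segments (default 7).
#' @param x_scaling a [scaling_spec()] for the X block.
#' @param y_center center the response within each training set.
#' @return list with `q2` (per component), `q2_cum`, `press`, `ss_prev`.
#' @export
q2_cv <- function(X, Y, n_components = 1, n_segments = 7,
                  x_scaling = scaling_spec("pareto"), y_center = TRUE) {
  X <- as.matrix(X); Y <- as.numeric(Y)
  seg <- cv_segments(nrow(X), n_segments)
  pred <- matrix(NA_real_, nrow(X), n_components)
  for (k in unique(seg)) {
    train <- seg != k
    pred[!train, ] <- fit_predict_fold(X, Y, train, n_components,
                                       x_scaling, y_center)
  }
  press <- colSums((Y - pred)^2)
  # residual SS of the full-data fit after a-1 components
  sc <- scale_matrix(X, x_scaling)
  ym <- if (y_center) mean(Y) else 0
  fit <- fit_pls(sc$X, Y - ym, n_components)
  ss0 <- sum((Y - ym)^2)
  ss <- ss0 * (1 - c(0, fit$r2y_cum))  # SS_0 .. SS_ncomp
  ss_prev <- ss[seq_len(n_components)]
  q2 <- 1 - press / ss_prev
  list(q2 = q2, q2_cum = 1 - prod(press / ss_prev),
       press = press, ss_prev = ss_prev)
}

#' Select the number of PLS components by the Q2 rule
#'
#' Adds components while the per-component Q2 exceeds `threshold` (default
#' 0.05), up to `max_components`; always keeps at least one.
#'
#' @inheritParams q2_cv
#' @param max_components upper bound on components.
#' @param threshold minimum per-component Q2 to keep adding.
#' @return number of components selected.
#' @export
select_components <- function(X, Y, max_components = 5, threshold = 0.05,
                              n_segments = 7,
                              x_scaling = scaling_spec("pareto"),
                              y_center = TRUE) {
  cv <- q2_cv(X, Y, max_components, n_segments, x_scaling, y_center)
  ok <- cv$q2 > threshold
  if (!ok[1]) return(1L)
  a <- which(!ok)
  if (length(a) == 0) max_components else as.integer(a[1] - 1)
}

#' Permutation validation of a PLS model
#'
#' Refits the model after randomly permuting the response and records, for
#' each permutation, the absolute correlation of the permuted response with
#' the original, the model R2Y and the cross-validated Q2. A fitted model
#' is credible only if its real R2/Q2 clearly exceed the permuted
#' distributions; the real model is recorded at correlation 1.
#'
#' @inheritParams q2_cv
#' @param n_permutations number of random permutations.
#' @param seed integer seed making the permutations reproducible.
#' @return object of class `validation_result`: `real_R2`, `real_Q2`,
#'   data.frame `permuted` (`correlation`, `R2`, `Q2`), `n_permutations`,
#'   `seed`.
#' @export
permutation_validate <- function(X, Y, n_components = 1,
                                 n_permutations = 200, seed = 1L,
                                 n_segments = 7,
                                 x_scaling = scaling_spec("pareto"),
                                 y_center = TRUE) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  X <- as.matrix(X); Y <- as.numeric(Y)
  fit_r2 <- function(y) {
    sc <- scale_matrix(X, x_scaling)
    ym <- if (y_center) mean(y) else 0
    fit <- fit_pls(sc$X, y - ym, n_components)
    fit$r2y_cum[n_components]
  }
  real_R2 <- fit_r2(Y)
  real_Q2 <- q2_cv(X, Y, n_components, n_segments, x_scaling, y_center)$q2_cum
  perms <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_permutations), function(i) {
      yp <- sample(Y)
      c(correlation = abs(stats::cor(yp, Y)),
        R2 = fit_r2(yp),
        Q2 = q2_cv(X, yp, n_components, n_segments, x_scaling, y_center)$q2_cum)
    })
  })
  permuted <- as.data.frame(do.call(rbind, perms))
  structure(list(real_R2 = real_R2, real_Q2 = real_Q2, permuted = permuted,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("permutation validation: real R2 = %.3f, real Q2 = %.3f\n",
              x$real_R2, x$real_Q2))
  cat(sprintf("%d permutations: max permuted Q2 = %.3f (real beats %d/%d)\n",
              x$n_permutations, max(x$permuted$Q2),
              sum(x$real_Q2 > x$permuted$Q2), x$n_permutations))
  invisible(x)
}

#' Leave-out dose prediction
#'
#' Randomly partitions samples into `n_folds` folds, predicts each sample's
#' response from a model fitted without it, and repeats the whole partition
#' `n_repeats` times. The summary gives the mean and standard deviation of
#' the held-out predictions within each true response group — the standard
#' display for dose-prediction validation of a dose-regression model.
#'
#' @inheritParams q2_cv
#' @param n_folds folds per repetition (>= 2).
#' @param n_repeats number of random repartitions.
#' @param seed integer seed.
#' @return list with `predictions` (data.frame: sample, repeat, fold,
#'   y_true, y_pred) and `summary` (mean +/- SD of predictions per true
#'   response value).
#' @export
predict_left_out <- function(X, Y, n_components = 1, n_folds = 7,
                             n_repeats = 5, seed = 1L,
                             x_scaling = scaling_spec("pareto"),
                             y_center = TRUE) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  X <- as.matrix(X); Y <- as.numeric(Y)
  n <- nrow(X)
  res <- withr::with_seed(as.integer(seed), {
    out <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      fold <- sample(rep_len(seq_len(n_folds), n))
      pred <- numeric(n)
      for (k in seq_len(n_folds)) {
        train <- fold != k
        if (stats::sd(Y[train]) == 0)
          stop("a training fold has constant Y; reduce n_folds")
        pred[!train] <- fit_predict_fold(X, Y, train, n_components,
                                         x_scaling, y_center)[, n_components]
      }
      out[[r]] <- data.frame(sample = seq_len(n), rep = r, fold = fold,
                             y_true = Y, y_pred = pred)
    }
    do.call(rbind, out)
  })
  agg <- stats::aggregate(y_pred ~ y_true, data = res,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(y_true = agg$y_true,
                        mean_pred = agg$y_pred[, "mean"],
                        sd_pred = agg$y_pred[, "sd"])
  list(predictions = res, summary = summary)
}
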