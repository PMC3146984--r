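#' Fit a Gaussian discriminant classifier on seed samples
#'
#' Fits class-conditional multivariate normal densities to the skin and lesion
#' training samples in L*u*v* space. In `"lda"` mode a single pooled
#' within-class covariance is estimated (weighted by class sizes, maximum
#' likelihood); in `"qda"` mode each class keeps its own covariance. When an
#' estimated covariance is numerically singular (condition number above
#' `1e12`) a ridge `eps * trace/3 * I` is added and recorded, so degenerate
#' seed regions (e.g. a constant channel on very homogeneous skin) never abort
#' the fit.
#'
#' @param samples List with numeric matrices `skin` and `lesion` (columns
#'   L*, u*, v*), at least 4 rows each.
#' @param mode `"lda"` or `"qda"`.
#' @param priors Class prior probabilities `c(skin, lesion)`; default equal.
#' @param ridge_eps Relative ridge size used on singular covariances.
#' @return An object of class `"ics_gauss"`: `mode`, `means` (2 x 3 matrix,
#'   rows skin/lesion), `cov` (pooled, lda) or `covs` (per class, qda),
#'   `priors`, and `ridge` (per-class ridge actually added).
#' @export
fit_gaussian_classifier <- function(samples, mode = c("lda", "qda"),
                                    priors = c(skin = 0.5, lesion = 0.5),
                                    ridge_eps = 1e-6) {
  mode <- match.arg(mode)
  X <- lapply(samples[c("skin", "lesion")], function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- vapply(X, nrow, 0L)
  if (any(n < 4))
    stop("each class needs at least 4 training samples", call. = FALSE)
  if (abs(sum(priors) - 1) > 1e-9 || any(priors < 0))
    stop("'priors' must be nonnegative and sum to 1", call. = FALSE)
  mu <- t(vapply(X, colMeans, numeric(ncol(X[[1]]))))
  scat <- lapply(1:2, function(k) crossprod(sweep(X[[k]], 2, mu[k, ])))
  regularize <- function(S) {
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    singular <- min(ev) <= 0 || max(ev) / min(ev) > 1e12
    ridge <- 0
    if (singular) {
      ridge <- ridge_eps * max(sum(diag(S)) / nrow(S), 1e-6)
      S <- S + diag(ridge, nrow(S))
    }
    list(S = S, ridge = ridge)
  }
  out <- list(mode = mode, means = mu, priors = priors, n = n)
  if (mode == "lda") {
    r <- regularize((scat[[1]] + scat[[2]]) / sum(n))
    out$cov <- r$S
    out$ridge <- c(pooled = r$ridge)
  } else {
    r <- lapply(1:2, function(k) regularize(scat[[k]] / n[k]))
    out$covs <- list(skin = r[[1]]$S, lesion = r[[2]]$S)
    out$ridge <- c(skin = r[[1]]$ridge, lesion = r[[2]]$ridge)
  }
  class(out) <- "ics_gauss"
  out
}

#' @export
print.ics_gauss <- function(x, ...) {
  cat(sprintf("%s classifier: %d skin / %d lesion samples, priors %.2f/%.2f",
              toupper(x$mode), x$n[1], x$n[2], x$priors[1], x$priors[2]))
  if (any(x$ridge > 0)) cat(sprintf(", ridge %.3g", max(x$ridge)))
  cat("\n")
  invisible(x)
}

# Per-class Gaussian log densities (+ log priors) for an n x 3 feature matrix.
gauss_log_post_terms <- function(params, X) {
  covk <- function(k) if (params$mode == "lda") params$cov else params$covs[[k]]
  out <- vapply(1:2, function(k) {
    S <- covk(k)
    ch <- chol(S)
    z <- forwardsolve(t(ch), t(X) - params$means[k, ])
    -0.5 * colSums(z^2) - sum(log(diag(ch))) + log(params$priors[k])
  }, numeric(nrow(X)))
  matrix(out, nrow(X), 2)
}

# Posterior p(skin | x) for a feature matrix; stable logistic of the log-odds.
posterior_skin <- function(params, X) {
  lp <- gauss_log_post_terms(params, X)
  plogis(lp[, 1] - lp[, 2])
}

#' Per-pixel class posterior maps
#'
#' Evaluates the fitted Gaussian class-conditional densities at every pixel
#' inside the circular field and returns Bayes posteriors for skin and lesion.
#' Computation is done in log space for numerical stability; pixels outside
#' the field mask are `NA`.
#'
#' @param params An `"ics_gauss"` fit.
#' @param luv A `"luv_image"`.
#' @param lambda Mixing weight recorded on the map (set by [hybrid_posterior()];
#'   `NA` for a single-classifier map).
#' @return An object of class `"posterior_map"`: matrices `p_skin`,
#'   `p_lesion` (summing to 1 inside the field) and `lambda_used`.
#' @export
gaussian_posterior <- function(params, luv, lambda = NA_real_) {
  idx <- which(luv$field_mask)
  X <- cbind(luv$L[idx], luv$u[idx], luv$v[idx])
  p <- posterior_skin(params, X)
  p_skin <- matrix(NA_real_, nrow(luv$L), ncol(luv$L))
  p_skin[idx] <- p
  structure(list(p_skin = p_skin, p_lesion = 1 - p_skin, lambda_used = lambda),
            class = "posterior_map")
}

#' Hybrid posterior: convex combination of QDA and LDA maps
#'
#' The working posterior of the segmenter is
#' `p = lambda * p_QDA + (1 - lambda) * p_LDA`, evaluated per pixel and class.
#' `lambda = 0` reduces to pure LDA, `lambda = 1` to pure QDA.
#'
#' @param p_qda,p_lda `"posterior_map"` objects on the same grid.
#' @param lam Mixing weight in `[0, 1]`.
#' @return A `"posterior_map"` with `lambda_used = lam`.
#' @export
hybrid_posterior <- function(p_qda, p_lda, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0 || lam > 1)
    stop("'lam' must be a scalar in [0, 1]", call. = FALSE)
  if (!identical(dim(p_qda$p_skin), dim(p_lda$p_skin)))
    stop("posterior maps are not aligned", call. = FALSE)
  ps <- lam * p_qda$p_skin + (1 - lam) * p_lda$p_skin
  structure(list(p_skin = ps, p_lesion = 1 - ps, lambda_used = lam),
            class = "posterior_map")
}

#' @export
print.posterior_map <- function(x, ...) {
  cat(sprintf("posterior map %d x %d (lambda = %s), mean p(lesion) = %.3f\n",
              nrow(x$p_skin), ncol(x$p_skin), format(x$lambda_used),
              mean(x$p_lesion, na.rm = TRUE)))
  invisible(x)
}

# min(class accuracies) of the hybrid rule on labeled skin/lesion posteriors;
# exact 0.5 labels as skin (lesion membership requires evidence).
hybrid_min_accuracy <- function(ps_skin_lda, ps_skin_qda,
                                pl_skin_lda, pl_skin_qda, lam) {
  acc_skin   <- mean(lam * ps_skin_qda + (1 - lam) * ps_skin_lda >= 0.5)
  acc_lesion <- mean(lam * pl_skin_qda + (1 - lam) * pl_skin_lda < 0.5)
  min(acc_skin, acc_lesion)
}

#' Select the LDA/QDA mixing weight
#'
#' Scans a fine grid of mixing weights, classifies the pooled seed training
#' samples of both halves with the hybrid rule, scores each weight by the
#' minimum of the per-class accuracies (so neither class may be sacrificed),
#' and returns the smallest weight attaining the best score. The tie rule
#' deliberately privileges the simpler linear classifier: perfectly separable
#' seeds yield `lambda = 0`. Because each classifier was fit on its own half,
#' at least half of the pooled evaluation samples are unseen by each.
#'
#' @param split An `"ics_training"` split.
#' @param lda,qda `"ics_gauss"` fits of the two halves.
#' @param grid_step Grid resolution in `[0, 1]`; default 0.01.
#' @return The selected weight (a grid point in `[0, 1]`).
#' @export
select_lambda <- function(split, lda, qda, grid_step = 0.01) {
  skin   <- rbind(split$lda$skin, split$qda$skin)
  lesion <- rbind(split$lda$lesion, split$qda$lesion)
  if (nrow(skin) == 0 || nrow(lesion) == 0)
    stop("empty evaluation set", call. = FALSE)
  ps_l <- posterior_skin(lda, skin);   ps_q <- posterior_skin(qda, skin)
  pl_l <- posterior_skin(lda, lesion); pl_q <- posterior_skin(qda, lesion)
  grid <- seq(0, 1, by = grid_step)
  score <- vapply(grid, function(lam)
    hybrid_min_accuracy(ps_l, ps_q, pl_l, pl_q, lam), 0)
  grid[which.max(score)]   # which.max returns the first, i.e. smallest lambda
}
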