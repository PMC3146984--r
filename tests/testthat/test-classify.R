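# Stage 2: Gaussian discriminants, hybrid posterior, mixing-weight selection.

test_that("pooled covariance equals the weighted within-class formula", {
  set.seed(2)
  A <- matrix(rnorm(60, 0, 1), 20, 3)
  B <- matrix(rnorm(90, 5, 1), 30, 3)
  fit <- fit_gaussian_classifier(list(skin = A, lesion = B), "lda")
  hand <- (crossprod(sweep(A, 2, colMeans(A))) +
           crossprod(sweep(B, 2, colMeans(B)))) / (20 + 30)
  expect_equal(fit$cov, hand, ignore_attr = TRUE)
  expect_equal(fit$means[1, ], colMeans(A), ignore_attr = TRUE)
  fitq <- fit_gaussian_classifier(list(skin = A, lesion = B), "qda")
  expect_equal(fitq$covs$lesion,
               crossprod(sweep(B, 2, colMeans(B))) / 30, ignore_attr = TRUE)
  expect_error(fit_gaussian_classifier(list(skin = A[1:3, ], lesion = B)),
               "at least 4")
})

test_that("identical class distributions give posterior one half everywhere", {
  set.seed(3)
  X <- matrix(rnorm(150), 50, 3)
  fit <- fit_gaussian_classifier(list(skin = X, lesion = X), "lda")
  L <- matrix(rnorm(36), 6, 6)
  post <- gaussian_posterior(fit, make_luv(L, matrix(rnorm(36), 6),
                                           matrix(rnorm(36), 6)))
  expect_equal(post$p_skin, matrix(0.5, 6, 6), tolerance = 1e-9)
})

test_that("a zero-variance feature is handled by a recorded ridge", {
  set.seed(4)
  A <- cbind(rnorm(20), 1, rnorm(20))       # constant second channel
  B <- cbind(rnorm(20, 4), 1, rnorm(20, 4))
  expect_silent(fit <- fit_gaussian_classifier(list(skin = A, lesion = B), "qda"))
  expect_true(any(fit$ridge > 0))
  p <- icseg:::posterior_skin(fit, rbind(c(0, 1, 0), c(4, 1, 4)))
  expect_true(all(is.finite(p)))
})

test_that("posteriors reproduce the closed-form Gaussian Bayes rule", {
  # 1-D problem embedded in 3-D: means 0 and 2 on the first axis, unit
  # covariance, equal priors; at x = 0 the posterior of class 1 is e^2/(1+e^2)
  par <- make_gauss(rbind(skin = c(0, 5, 5), lesion = c(2, 5, 5)))
  luv <- make_luv(matrix(0, 1, 1), matrix(5, 1, 1), matrix(5, 1, 1))
  post <- gaussian_posterior(par, luv)
  expect_equal(post$p_skin[1, 1], exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # Mahalanobis-equidistant point: exactly one half
  luv_mid <- make_luv(matrix(1, 1, 1), matrix(5, 1, 1), matrix(5, 1, 1))
  expect_equal(gaussian_posterior(par, luv_mid)$p_skin[1, 1], 0.5,
               tolerance = 1e-12)
})

test_that("posterior maps normalize per pixel and respect the field mask", {
  set.seed(5)
  A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(60, 2), 20, 3)
  fit <- fit_gaussian_classifier(list(skin = A, lesion = B), "lda")
  mask <- matrix(c(TRUE, FALSE), 8, 8)
  luv <- make_luv(matrix(rnorm(64), 8), matrix(rnorm(64), 8),
                  matrix(rnorm(64), 8), mask)
  post <- gaussian_posterior(fit, luv)
  expect_true(all(abs(post$p_skin[mask] + post$p_lesion[mask] - 1) < 1e-9))
  expect_true(all(is.na(post$p_skin[!mask])))
})

test_that("posteriors agree with MASS discriminant analysis", {
  skip_if_not_installed("MASS")
  set.seed(6)
  A <- matrix(rnorm(900, 0, 1), 300, 3)
  B <- matrix(rnorm(900, 1.5, 1.3), 300, 3)
  fit <- fit_gaussian_classifier(list(skin = A, lesion = B), "qda")
  Xt <- matrix(rnorm(60, 0.7), 20, 3)
  mine <- icseg:::posterior_skin(fit, Xt)
  mq <- MASS::qda(rbind(A, B), grouping = rep(c("s", "l"), each = 300))
  ref <- predict(mq, Xt)$posterior[, "s"]
  expect_equal(mine, ref, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("hybrid posterior interpolates the two maps", {
  set.seed(7)
  pq <- make_posterior(matrix(runif(16), 4, 4))
  pl <- make_posterior(matrix(runif(16), 4, 4))
  expect_equal(hybrid_posterior(pq, pl, 0)$p_lesion, pl$p_lesion)
  expect_equal(hybrid_posterior(pq, pl, 1)$p_lesion, pq$p_lesion)
  pq1 <- make_posterior(matrix(0.9, 1, 1)); pl1 <- make_posterior(matrix(0.7, 1, 1))
  expect_equal(hybrid_posterior(pq1, pl1, 0.5)$p_lesion[1, 1], 0.8)
  expect_error(hybrid_posterior(pq, pl, 1.2), "0, 1")
  # monotone in lambda wherever the QDA posterior exceeds the LDA posterior
  lams <- seq(0, 1, 0.1)
  vals <- sapply(lams, function(l) hybrid_posterior(pq, pl, l)$p_lesion)
  up <- pq$p_lesion > pl$p_lesion
  expect_true(all(apply(vals[as.vector(up), , drop = FALSE], 1,
                        function(r) all(diff(r) >= -1e-12))))
})

test_that("lambda selection privileges LDA on separable seeds", {
  set.seed(8)
  mk_split <- function(skin_l, lesion_l, skin_q, lesion_q) {
    s <- list(lda = list(skin = skin_l, lesion = lesion_l),
              qda = list(skin = skin_q, lesion = lesion_q))
    s$origin <- s[c("lda", "qda")]
    s$origin_counts <- c(skin = nrow(skin_l) + nrow(skin_q),
                         lesion = nrow(lesion_l) + nrow(lesion_q))
    structure(s, class = "ics_training")
  }
  A1 <- matrix(rnorm(60, 0, 0.3), 20, 3); A2 <- matrix(rnorm(60, 0, 0.3), 20, 3)
  B1 <- matrix(rnorm(60, 6, 0.3), 20, 3); B2 <- matrix(rnorm(60, 6, 0.3), 20, 3)
  split <- mk_split(A1, B1, A2, B2)
  lda <- fit_gaussian_classifier(split$lda, "lda")
  qda <- fit_gaussian_classifier(split$qda, "qda")
  expect_equal(select_lambda(split, lda, qda), 0)
})

test_that("lambda selection matches an exhaustive grid oracle when QDA wins", {
  set.seed(9)
  # skin tightly at the origin, lesion a two-sided mixture: only a curved
  # boundary separates them, so the best mixing weight is far from 0
  mk <- function(n, f) t(vapply(seq_len(n), function(i) f(), numeric(3)))
  skin1 <- mk(40, function() rnorm(3, 0, 0.2))
  skin2 <- mk(40, function() rnorm(3, 0, 0.2))
  les <- function() c(sample(c(-4, 4), 1), rnorm(2, 0, 0.2))
  les1 <- mk(40, les); les2 <- mk(40, les)
  split <- structure(list(
    lda = list(skin = skin1, lesion = les1),
    qda = list(skin = skin2, lesion = les2),
    origin = NULL, origin_counts = c(skin = 80, lesion = 80)),
    class = "ics_training")
  lda <- fit_gaussian_classifier(split$lda, "lda")
  qda <- fit_gaussian_classifier(split$qda, "qda")
  lam <- select_lambda(split, lda, qda)
  expect_gt(lam, 0)

  # independent oracle: explicit density evaluation over the same grid
  dens <- function(x, mu, S) exp(-0.5 * mahalanobis(x, mu, S)) / sqrt(det(S))
  post_skin <- function(fit, X) {
    Ss <- if (fit$mode == "lda") list(fit$cov, fit$cov)
          else list(fit$covs$skin, fit$covs$lesion)
    ds <- dens(X, fit$means[1, ], Ss[[1]])
    dl <- dens(X, fit$means[2, ], Ss[[2]])
    ds / (ds + dl)
  }
  skin_all <- rbind(skin1, skin2); les_all <- rbind(les1, les2)
  grid <- seq(0, 1, 0.01)
  score <- vapply(grid, function(l) {
    ps <- l * post_skin(qda, skin_all) + (1 - l) * post_skin(lda, skin_all)
    pl <- l * post_skin(qda, les_all) + (1 - l) * post_skin(lda, les_all)
    min(mean(ps >= 0.5), mean(pl < 0.5))
  }, 0)
  expect_equal(lam, grid[which.max(score)])
  # the curved boundary really is better: pure QDA beats pure LDA
  expect_gt(score[length(score)], score[1])
  # deterministic: same inputs, same grid point
  expect_identical(lam, select_lambda(split, lda, qda))
  expect_true(lam %in% grid)
})
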