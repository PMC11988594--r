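test_that("masking value function recovers prediction, base, and averages", {
  model <- build_cnn(cnn_config(seed = 21))
  x <- rnorm(107)
  bg2 <- matrix(rnorm(2 * 107), 2)

  v_full <- shap_value_function(model, x, seq_len(107), bg2)
  expect_equal(v_full, drop(predict(model, matrix(x, 1), type = "matrix")),
               tolerance = 1e-12)

  v_empty <- shap_value_function(model, x, integer(0), bg2, mode = "mean-vector")
  expect_equal(v_empty,
               drop(predict(model, matrix(colMeans(bg2), 1), type = "matrix")),
               tolerance = 1e-12)

  # sample-average over 2 rows = explicit two-term average
  S <- c(3L, 50L, 101L)
  v <- shap_value_function(model, x, S, bg2)
  manual <- sapply(1:2, function(r) {
    z <- bg2[r, ]; z[S] <- x[S]
    drop(predict(model, matrix(z, 1), type = "matrix"))
  })
  expect_equal(v, rowMeans(manual), tolerance = 1e-12)

  expect_error(shap_value_function(model, x, 200L, bg2),
               class = "kelptrace_argument_error")
})

test_that("exact Shapley satisfies the dummy, symmetry, efficiency axioms", {
  set.seed(42)
  for (trial in 1:200) {
    m <- sample(3:6, 1)
    w <- rnorm(m); w[1] <- 0                    # feature 1 is a dummy
    w2 <- rnorm(m); w2[1] <- 0
    f <- function(X) cbind(X %*% w + 0.5 * (X %*% w2)^2)
    x <- rnorm(m)
    bg <- matrix(rnorm(4 * m), 4)
    ex <- shap_exact(f, x, bg)
    # dummy
    expect_lt(abs(ex$phi[1, 1, 1]), 1e-10)
    # efficiency: base + sum(phi) = v(full) = f(x)
    expect_lt(max(ex$residual_raw), 1e-9)
    expect_equal(ex$base_values[1] + sum(ex$phi[1, , 1]), drop(f(matrix(x, 1))),
                 tolerance = 1e-9)
  }

  # symmetry: interchangeable features (equal weights, values, and
  # background) get identical phi
  w <- c(1.3, 1.3, -0.7)
  f <- function(X) cbind(exp(X %*% w / 3))
  x <- c(0.8, 0.8, -0.2)
  ex <- shap_exact(f, x, c(0.1, 0.1, 0.4), mode = "mean-vector")
  expect_equal(ex$phi[1, 1, 1], ex$phi[1, 2, 1], tolerance = 1e-10)
})

test_that("exact Shapley on a linear model has the closed form w_i (x_i - m_i)", {
  set.seed(8)
  for (trial in 1:20) {
    m <- sample(2:9, 1)
    w <- rnorm(m); b <- rnorm(1)
    x <- rnorm(m); bgm <- rnorm(m)
    ex <- shap_exact(toy_linear(w, b), x, bgm, mode = "mean-vector")
    expect_equal(ex$phi[1, , 1], w * (x - bgm), tolerance = 1e-9)
    expect_equal(unname(ex$base_values[1]), sum(w * bgm) + b, tolerance = 1e-9)
  }
})

test_that("exact Shapley is linear in the game", {
  set.seed(12)
  m <- 5
  f1 <- function(X) cbind(sin(X[, 1]) + X[, 2] * X[, 3])
  f2 <- function(X) cbind(X[, 4]^2 - X[, 5] + X[, 1] * X[, 5])
  fsum <- function(X) f1(X) + f2(X)
  x <- rnorm(m); bg <- matrix(rnorm(6 * m), 6)
  ex1 <- shap_exact(f1, x, bg)
  ex2 <- shap_exact(f2, x, bg)
  exs <- shap_exact(fsum, x, bg)
  expect_equal(exs$phi, ex1$phi + ex2$phi, tolerance = 1e-9)
})

test_that("exact enumeration refuses wide active sets with guidance", {
  model <- build_cnn(cnn_config(seed = 1))
  expect_error(
    shap_exact(model, rnorm(107), matrix(rnorm(107), 1)),
    "shap_permutation",
    class = "kelptrace_argument_error"
  )
})

test_that("exact works on the CNN itself over a restricted active set", {
  model <- build_cnn(cnn_config(seed = 33))
  x <- matrix(rnorm(107), 1, dimnames = list(NULL, paste0("A", 1:107)))
  bg <- matrix(rnorm(10 * 107), 10)
  active <- c(5L, 20L, 21L, 60L, 100L)
  ex <- shap_exact(model, x, bg, features = active)
  expect_equal(dim(ex$phi), c(1L, 5L, 3L))
  expect_lt(max(ex$residual_raw), 1e-9)
  # base + contributions recover v(active set), all classes summing to 0 change
  expect_equal(sum(ex$phi[1, , ]), 0, tolerance = 1e-9)
  expect_equal(ex$feature_ids, paste0("A", active))
})

nonsep <- function(X) {
  cbind(X[, 1] * X[, 2] * X[, 3] + 0.5 * X[, 4] * X[, 5] * X[, 6] * X[, 7] +
          X[, 1] - X[, 6])
}

test_that("permutation estimate converges to the exact values", {
  set.seed(1)
  x <- rnorm(7)
  bg <- matrix(rnorm(20 * 7), 20)
  ex <- shap_exact(nonsep, x, bg)

  run1 <- shap_permutation(nonsep, x, bg, n_perm = 2000, seed = 1)
  # Monte-Carlo SE estimated from independent replicate runs
  reps <- sapply(2:11, function(s) {
    shap_permutation(nonsep, x, bg, n_perm = 2000, seed = s)$phi - ex$phi
  })
  se_max <- max(apply(reps, 1, sd))
  expect_lt(max(abs(run1$phi - ex$phi)), 3 * se_max)
  expect_lt(max(run1$residual_raw), 1e-9)
})

test_that("exhaustive permutation enumeration equals exact", {
  set.seed(3)
  x <- rnorm(3)
  bg <- matrix(rnorm(5 * 3), 5)
  f <- function(X) cbind(X[, 1] * X[, 2] + exp(X[, 3] / 2))
  ex <- shap_exact(f, x, bg)
  pm <- shap_permutation(f, x, bg, n_perm = 6, seed = 1)  # 3! orderings
  expect_equal(pm$method, "permutation-exhaustive")
  expect_equal(pm$phi, ex$phi, tolerance = 1e-10)
})

test_that("permutation sampling is seed-deterministic", {
  x <- rnorm(7); bg <- matrix(rnorm(8 * 7), 8)
  a <- shap_permutation(nonsep, x, bg, n_perm = 50, seed = 9)
  b <- shap_permutation(nonsep, x, bg, n_perm = 50, seed = 9)
  c3 <- shap_permutation(nonsep, x, bg, n_perm = 50, seed = 10)
  expect_identical(a$phi, b$phi)
  expect_false(isTRUE(all.equal(a$phi, c3$phi)))
})

test_that("permutation error decays like one over root n_perm", {
  set.seed(2)
  x <- rnorm(7)
  bg <- matrix(rnorm(20 * 7), 20)
  ex <- shap_exact(nonsep, x, bg)
  n_perms <- c(100, 400, 1600, 6400)
  errs <- vapply(n_perms, function(np) {
    mean(vapply(1:5, function(s) {
      mean(abs(shap_permutation(nonsep, x, bg, n_perm = np,
                                seed = 1000 + s)$phi - ex$phi))
    }, numeric(1)))
  }, numeric(1))
  slope <- unname(coef(lm(log(errs) ~ log(n_perms)))[2])
  expect_gte(slope, -0.65)
  expect_lte(slope, -0.35)
})

test_that("global importance ranks mean absolute contributions", {
  # hand-built explanation with known means
  phi <- array(0, dim = c(2, 3, 2))
  phi[, 1, 1] <- c(1, -1)     # mean |phi| = 1
  phi[, 2, 1] <- c(0.5, 0.5)  # 0.5
  phi[, 3, 2] <- c(2, 2)      # 2 on class 2
  expl <- kelptrace:::shap_new(
    phi, base_values = c(0.5, 0.5), residual_raw = matrix(0, 2, 2),
    method = "exact", mode = "mean-vector",
    feature_ids = c("f1", "f2", "f3"), sample_ids = c("s1", "s2"),
    feature_values = matrix(0, 2, 3), class_names = c("c1", "c2")
  )
  imp <- shap_importance(expl)
  expect_equal(imp$feature_id, c("f3", "f1", "f2"))
  expect_equal(imp$stacked, c(2, 1, 0.5))
  expect_equal(imp$mean_abs_c1, c(0, 1, 0.5))
  expect_equal(imp$rank, 1:3)

  zero <- expl
  zero$phi[] <- 0
  imp0 <- shap_importance(zero)
  expect_equal(imp0$stacked, c(0, 0, 0))
  expect_equal(imp0$feature_id, c("f1", "f2", "f3"))  # stable order

  td <- tidy(expl)
  expect_equal(nrow(td), 2 * 3 * 2)
  expect_equal(td$phi[td$sample_id == "s1" & td$class == "c2" &
                        td$feature_id == "f3"], 2)
})

test_that("local force records satisfy the sign identity and base value", {
  # symmetric zero-weight model: every output 1/3, base exactly 1/3
  model <- build_cnn(cnn_config(seed = 2))
  model$weights <- lapply(model$weights, function(p) p * 0)
  bg <- matrix(rnorm(6 * 107), 6)
  ex <- shap_exact(model, rnorm(107), bg, features = c(1L, 2L, 3L))
  expect_equal(unname(ex$base_values), rep(1 / 3, 3), tolerance = 1e-12)

  # trained-looking random model: output sits right of base iff sum(phi) > 0
  model2 <- build_cnn(cnn_config(seed = 14))
  x <- matrix(rnorm(107), 1)
  bg2 <- matrix(rnorm(12 * 107), 12)
  ex2 <- shap_exact(model2, x, bg2, features = c(4L, 9L, 55L, 80L))
  for (cl in 1:3) {
    rec <- shap_local(ex2, 1, cl)
    expect_equal(rec$output - rec$base_value, sum(ex2$phi[1, , cl]),
                 tolerance = 1e-12)
    expect_equal(rec$output >= rec$base_value, sum(ex2$phi[1, , cl]) >= 0)
    expect_equal(rec$contributions$phi,
                 rec$contributions$phi[order(-abs(rec$contributions$phi))])
  }
  expect_error(shap_local(ex2, 5, 1), class = "kelptrace_argument_error")
})

test_that("logit-scale attribution satisfies efficiency on the logit scale", {
  model <- build_cnn(cnn_config(seed = 44))
  x <- rnorm(107)
  bg <- matrix(rnorm(8 * 107), 8)
  ex <- shap_exact(logit_predictor(model), x, bg, features = c(2L, 30L, 77L))
  expect_lt(max(ex$residual_raw), 1e-9)
  # base values are mean background logits, not probabilities
  expect_false(isTRUE(all.equal(sum(ex$base_values), 1)))
})
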