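test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(3), 3)
  x <- random_fmap(4, 5, 3, seed = 1)
  expect_identical(relu(relu(x)), relu(x))
})

test_that("batch normalization follows the affine standardization form", {
  x <- array(2, c(3, 4, 2))
  # x identically equal to its mean, gamma = 1, beta = 0 -> zeros
  expect_equal(batch_norm(x, mu = 2, sigma2 = 1), array(0, dim(x)))

  # constant batch (sigma2 = 0): eps keeps the output finite, equal beta
  out <- batch_norm(x, gamma = 1, beta = 5, eps = 1e-5)
  expect_true(all(is.finite(out)))
  expect_equal(out, array(5, dim(x)), tolerance = 1e-6)

  # standardized input with gamma = 2, beta = 1 -> 2x + 1
  z <- random_fmap(6, 6, 1, seed = 2)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  out2 <- batch_norm(z, gamma = 2, beta = 1, mu = 0, sigma2 = 1,
                     eps = 1e-12)
  expect_equal(out2, 2 * z + 1, tolerance = 1e-9)

  # inverse affine recovers the standardized map
  g <- 1.7; b <- -0.4
  y <- batch_norm(z, gamma = g, beta = b, mu = 0, sigma2 = 1, eps = 1e-12)
  expect_equal((y - b) / g, z, tolerance = 1e-6)
})

test_that("residual blocks add the skip path and project when widening", {
  x <- random_fmap(6, 8, 4, seed = 3)
  # zero residual branch + identity skip -> relu(x)
  p0 <- residual_block_params(4, 4, 4, seed = 1, zero_branch = TRUE)
  expect_equal(residual_block(x, p0), relu(x), tolerance = 1e-12)

  # widening block uses a 1x1 projection skip with the new width
  p1 <- residual_block_params(4, 4, 16, seed = 2)
  out <- residual_block(x, p1)
  expect_equal(dim(out), c(6, 8, 16))
  expect_false(is.null(p1$ws))

  # gradient has an identity component when the skip is the identity:
  # with a tiny residual branch, d out / d x_i stays close to 1
  xp <- abs(random_fmap(3, 3, 1, seed = 4)) + 0.5
  p2 <- residual_block_params(1, 1, 1, seed = 5, zero_branch = TRUE)
  p2$w1 <- p2$w1 * 1e-3; p2$w2 <- p2$w2 * 1e-3
  eps <- 1e-5
  xp2 <- xp; xp2[2, 2, 1] <- xp2[2, 2, 1] + eps
  jac_diag <- (residual_block(xp2, p2)[2, 2, 1] -
                 residual_block(xp, p2)[2, 2, 1]) / eps
  expect_equal(jac_diag, 1, tolerance = 1e-3)
})

test_that("SE attention pools, excites and rescales channels", {
  # constant channel pools to its value
  x <- array(0, c(4, 6, 2))
  x[, , 1] <- 3.5; x[, , 2] <- -1.25
  out <- se_attention(x, se_params(2, zero = TRUE), return_gates = TRUE)
  expect_equal(attr(out, "gates"), c(0.5, 0.5))
  expect_equal(out, 0.5 * x, ignore_attr = TRUE, tolerance = 1e-12)

  # hidden width max(1, C/r): C = 32, r = 16 -> 2
  p <- se_params(32, r = 16)
  expect_equal(dim(p$w1), c(32L, 2L))

  # shape preserved, multiplicative bound for nonnegative inputs
  xn <- random_fmap(5, 7, 8, seed = 6, positive = TRUE)
  o <- se_attention(xn, se_params(8, seed = 2))
  expect_equal(dim(o), dim(xn))
  expect_true(all(o <= xn + 1e-12) && all(o >= 0))
})

test_that("GCA pools with a per-channel spatial softmax", {
  # spatially uniform channel: p uniform, g_c = v
  x <- array(0, c(3, 5, 2))
  x[, , 1] <- 2; x[, , 2] <- -1
  g <- foalwatch:::gca_context(x)
  expect_equal(g, c(2, -1), tolerance = 1e-12)

  # softmax weights sum to 1: context of exp-weighted sum lies within range
  xr <- random_fmap(6, 6, 3, seed = 7)
  gr <- foalwatch:::gca_context(xr)
  for (c in 1:3) {
    v <- as.vector(xr[, , c])
    w <- exp(v - max(v)); w <- w / sum(w)
    expect_equal(gr[c], sum(w * v), tolerance = 1e-12)  # brute force
  }

  # a large spatial spike dominates the context
  xs <- array(0, c(4, 4, 1)); xs[2, 3, 1] <- 50
  expect_equal(foalwatch:::gca_context(xs)[1], 50, tolerance = 1e-6)

  # zero weights gate by exactly 0.5
  o <- gca_attention(xr, gca_params(3, zero = TRUE))
  expect_equal(o, 0.5 * xr, tolerance = 1e-12)

  # shared-context variant also preserves shape and bounds
  o2 <- gca_attention(abs(xr), gca_params(3, seed = 3, variant = "shared"))
  expect_equal(dim(o2), dim(xr))
  expect_true(all(o2 <= abs(xr) + 1e-12))
})

test_that("CBAM gates channel-then-spatial and has an identity limit", {
  x <- random_fmap(6, 9, 4, seed = 8, positive = TRUE) + 0.1
  # saturated gates (huge MLP and spatial bias) -> output equals input
  p <- cbam_params(4, zero = TRUE)
  p$w1 <- matrix(1, 4, 1); p$w2 <- matrix(1e6, 1, 4)
  p$b_spatial <- 1e6
  expect_equal(cbam_attention(x, p), x, tolerance = 1e-9)

  # zeroed weights: both gates are exactly 0.5
  z <- cbam_attention(x, cbam_params(4, zero = TRUE), return_gates = TRUE)
  expect_equal(attr(z, "gates"), rep(0.5, 4))
  expect_equal(unique(as.vector(attr(z, "spatial_gates"))), 0.5)
  expect_equal(z, 0.25 * x, ignore_attr = TRUE, tolerance = 1e-12)

  # shape preservation and multiplicative bound on random nonnegative input
  o <- cbam_attention(x, cbam_params(4, seed = 9))
  expect_equal(dim(o), dim(x))
  expect_true(all(o <= x + 1e-12) && all(o >= 0))
})

test_that("backbones place attention only in stages 3 and 4", {
  plain <- build_backbone(depth = c(1, 1, 2, 1), attention = NULL, seed = 1)
  expect_equal(foalwatch:::backbone_attention_counts(plain), rep(0L, 4))

  gated <- build_backbone(depth = c(1, 1, 2, 1),
                          attention = attention_config("cbam"), seed = 1)
  expect_equal(foalwatch:::backbone_attention_counts(gated),
               c(0L, 0L, 2L, 1L))

  expect_error(build_backbone(depth = c(1, 1)), "4 stages")
})

test_that("stage strides give the documented C2..C5 geometry", {
  bb <- build_backbone(depth = c(1, 1, 1, 1), widths = c(4, 4, 8, 8),
                       seed = 2)
  maps <- backbone_forward(bb, random_fmap(64, 64, 3, seed = 10))
  expect_equal(sapply(maps, function(m) dim(m)[1]),
               c(C2 = 16, C3 = 8, C4 = 4, C5 = 2))
  expect_equal(sapply(maps, function(m) dim(m)[2]),
               c(C2 = 16, C3 = 8, C4 = 4, C5 = 2))
})
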