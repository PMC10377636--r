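test_that("spatial cosine matches a per-position loop oracle", {
  withr::with_seed(42, {
    a <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
    b <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  })
  loop <- 0
  for (i in 1:3) for (j in 1:3) {
    va <- a[i, j, ]; vb <- b[i, j, ]
    loop <- loop + sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  }
  expect_equal(cosine_similarity_spatial(a, b), loop / 9, tolerance = 1e-10)
})

test_that("spatial cosine handles identical, orthogonal and zero positions", {
  a <- array(abs(rnorm(2 * 2 * 3)) + 0.1, c(2, 2, 3))
  expect_equal(cosine_similarity_spatial(a, a), 1)
  # orthogonal channel vectors at every position
  o1 <- array(0, c(2, 2, 2)); o1[, , 1] <- 1
  o2 <- array(0, c(2, 2, 2)); o2[, , 2] <- 1
  expect_equal(cosine_similarity_spatial(o1, o2), 0)
  # both zero -> 1, one zero -> 0
  z <- array(0, c(1, 1, 3))
  expect_equal(cosine_similarity_spatial(z, z), 1)
  expect_equal(cosine_similarity_spatial(z, array(1, c(1, 1, 3))), 0)
  expect_error(cosine_similarity_spatial(a, o1), class = "percsim_usage_error")
})

test_that("vector cosine matches arithmetic and rejects double zeros", {
  v <- c(0.3, -0.2, 0.9)
  expect_equal(cosine_similarity_vector(v, v), 1)
  expect_equal(cosine_similarity_vector(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity_vector(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
  expect_error(cosine_similarity_vector(c(0, 0), c(0, 0)),
               class = "percsim_degenerate_error")
})

test_that("cosines are scale-invariant and spatial reduces to vector at 1x1", {
  withr::with_seed(5, {
    a <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    b <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    expect_equal(cosine_similarity_spatial(2.5 * a, 0.3 * b),
                 cosine_similarity_spatial(a, b), tolerance = 1e-12)
    v1 <- rnorm(6); v2 <- rnorm(6)
    expect_equal(cosine_similarity_vector(7 * v1, 0.01 * v2),
                 cosine_similarity_vector(v1, v2), tolerance = 1e-12)
    a1 <- array(rnorm(5), c(1, 1, 5)); b1 <- array(rnorm(5), c(1, 1, 5))
    expect_equal(cosine_similarity_spatial(a1, b1),
                 cosine_similarity_vector(as.vector(a1), as.vector(b1)),
                 tolerance = 1e-14)
  })
})

test_that("the forward pass equals a hand-rolled convolution oracle", {
  bb <- toy_backbone(seed = 7, input_size = 8)
  p <- random_patch(13, h = 8, w = 8)
  acts <- extract_activations(p, bb)
  # layer-by-layer oracle on the preprocessed input
  x <- p$pixels
  conv1 <- conv_loop_oracle(x, bb$layers[[1]]$w, bb$layers[[1]]$b)
  expect_equal(acts$conv1$data, conv1, tolerance = 1e-10)
  relu1 <- pmax(conv1, 0)
  pool1 <- array(0, c(4, 4, 2))
  for (i in 1:4) for (j in 1:4) for (ch in 1:2) {
    pool1[i, j, ch] <- max(relu1[2 * i - 1:0, 2 * j - 1:0, ch])
  }
  conv2 <- conv_loop_oracle(pool1, bb$layers[[4]]$w, bb$layers[[4]]$b)
  expect_equal(acts$conv2$data, conv2, tolerance = 1e-10)
  fc <- as.numeric(as.vector(conv2) %*% bb$layers[[5]]$w + bb$layers[[5]]$b)
  expect_equal(acts$fc6$data, fc, tolerance = 1e-10)
  expect_equal(acts$relu6$data, pmax(fc, 0), tolerance = 1e-10)
})

test_that("a constant-zero input through a bias-free backbone is all zeros", {
  bb <- toy_backbone(seed = 3, input_size = 8, bias_free = TRUE)
  acts <- extract_activations(const_patch(0), bb)
  for (a in acts) expect_equal(max(abs(a$data)), 0)
})

test_that("extract_activations respects order, kinds and unknown layers", {
  bb <- stub_backbone(seed = 1)
  p <- random_patch(2)
  acts <- extract_activations(p, bb, c("relu6", "conv1"))
  expect_equal(names(acts), c("relu6", "conv1"))
  expect_equal(acts$conv1$kind, "spatial")
  expect_equal(acts$relu6$kind, "vector")
  err <- tryCatch(extract_activations(p, bb, "conv9"), error = function(e) e)
  expect_s3_class(err, "percsim_usage_error")
  expect_match(conditionMessage(err), "relu6") # lists available names
})

test_that("identical patches give texture similarity 1 at every layer", {
  bb <- stub_backbone(seed = 4)
  p <- random_patch(8, h = 24, w = 24)
  tri <- patch_triplet(p, p, p)
  for (layer in backbone_layer_names(bb)) {
    expect_equal(texture_similarity(tri, bb, layer)$similarity, 1,
                 tolerance = 1e-9)
  }
})

test_that("triplet texture similarity is the average of the two pair cosines", {
  bb <- stub_backbone(seed = 6)
  pS <- random_patch(21, h = 24, w = 24)
  p2 <- random_patch(22, h = 24, w = 24)
  tri <- patch_triplet(pS, pS, p2)
  got <- texture_similarity(tri, bb, "relu6")$similarity
  c2 <- cosine_similarity_vector(
    extract_activations(pS, bb, "relu6")$relu6$data,
    extract_activations(p2, bb, "relu6")$relu6$data
  )
  expect_equal(got, (1 + c2) / 2, tolerance = 1e-12)
})

test_that("layer_sweep reuses one forward pass and matches per-layer calls", {
  bb <- stub_backbone(seed = 10)
  tris <- list(generate_triplet(lesion_scenario(2, seed = 31)),
               generate_triplet(lesion_scenario(4, seed = 32)))
  layers <- c("relu1", "pool2", "relu6")
  sw <- layer_sweep(tris, bb, layers)
  expect_equal(nrow(sw), 6L)
  for (i in seq_along(tris)) {
    for (ly in layers) {
      expect_equal(
        sw$similarity[sw$source_id == tris[[i]]$source_id & sw$layer == ly],
        texture_similarity(tris[[i]], bb, ly)$similarity,
        tolerance = 1e-12
      )
    }
  }
  same <- patch_triplet(const_patch(0.5, 16, 16), const_patch(0.5, 16, 16),
                        const_patch(0.5, 16, 16))
  row <- layer_sweep(list(same), bb, layers)
  expect_true(all(abs(row$similarity - 1) < 1e-9))
})

test_that("texture similarity degrades as injected noise amplitude grows", {
  bb <- stub_backbone()
  amps <- c(0, 0.04, 0.09)
  means <- vapply(amps, function(amp) {
    mean(vapply(1:20, function(s) {
      tri <- generate_triplet(lesion_scenario(
        grade = if (amp == 0) 1L else 3L, color_offset = c(0, 0, 0),
        texture_amp = amp, seed = 500 + s))
      texture_similarity(tri, bb, "relu6")$similarity
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
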