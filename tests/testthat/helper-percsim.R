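# shared fixtures, all generated in code

const_patch <- function(value, h = 8L, w = 8L, source_id = "fix") {
  image_patch(array(value, c(h, w, 3L)), source_id = source_id)
}

random_patch <- function(seed, h = 16L, w = 16L, source_id = "fix") {
  withr::with_seed(seed, image_patch(array(runif(h * w * 3), c(h, w, 3L)),
                                     source_id = source_id))
}

# a tiny bias-free 2-conv + 1-fc backbone with seeded weights, small enough
# for loop-based oracles
toy_backbone <- function(seed = 7L, input_size = 8L, bias_free = TRUE) {
  withr::with_seed(seed, {
    w1 <- array(rnorm(3 * 3 * 3 * 2), dim = c(3, 3, 3, 2))
    w2 <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
    flat <- (input_size / 2)^2 * 3
    layers <- list(
      list(name = "conv1", type = "conv", w = w1,
           b = if (bias_free) rep(0, 2) else rnorm(2)),
      list(name = "relu1", type = "relu"),
      list(name = "pool1", type = "pool"),
      list(name = "conv2", type = "conv", w = w2,
           b = if (bias_free) rep(0, 3) else rnorm(3)),
      list(name = "fc6", type = "fc",
           w = matrix(rnorm(flat * 4), nrow = flat),
           b = if (bias_free) rep(0, 4) else rnorm(4)),
      list(name = "relu6", type = "relu")
    )
    backbone_spec("toy", input_size, layers,
                  channel_means = c(0, 0, 0), channel_scales = c(1, 1, 1))
  })
}

# quadruple-loop convolution oracle with edge-replicate padding
conv_loop_oracle <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
  k <- dim(w)[1]; cout <- dim(w)[4]; pad <- (k - 1) %/% 2
  out <- array(0, c(H, W, cout))
  for (o in seq_len(cout)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        acc <- b[o]
        for (ci in seq_len(cin)) {
          for (di in seq_len(k)) {
            for (dj in seq_len(k)) {
              ii <- min(max(i + di - 1 - pad, 1), H)
              jj <- min(max(j + dj - 1 - pad, 1), W)
              acc <- acc + x[ii, jj, ci] * w[di, dj, ci, o]
            }
          }
        }
        out[i, j, o] <- acc
      }
    }
  }
  out
}

# draw (x, y) from the proportional-odds model with known parameters
simulate_olreg <- function(n, theta = c(-1, 0, 1), beta = 2, seed = 1L) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    cum <- vapply(theta, function(t) plogis(t - beta * x), numeric(n))
    u <- runif(n)
    y <- 1L + (u > cum[, 1]) + (u > cum[, 2]) + (u > cum[, 3])
    list(x = x, y = as.integer(y))
  })
}

# second, literal transcription of the CIE94 color-difference formula,
# kept deliberately independent of the package implementation
cie94_reference <- function(lab1, lab2) {
  dL <- lab1[1] - lab2[1]
  da <- lab1[2] - lab2[2]
  db <- lab1[3] - lab2[3]
  C1 <- sqrt(lab1[2]^2 + lab1[3]^2)
  C2 <- sqrt(lab2[2]^2 + lab2[3]^2)
  dC <- C1 - C2
  dH2 <- da^2 + db^2 - dC^2
  if (dH2 < 0) dH2 <- 0
  SL <- 1
  SC <- 1 + 0.045 * C1
  SH <- 1 + 0.015 * C1
  sqrt((dL / SL)^2 + (dC / SC)^2 + dH2 / SH^2)
}
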