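# Feature-extraction backbones. The texture metrics only need named
# activations from a convolutional network; the backbone abstraction keeps
# the metric code independent of which network produced them. The bundled
# implementation is a seeded, randomly initialized 2-conv + 1-fc stub with
# the classic VGG-style layer naming; a pretrained network (e.g.
# VGG16/ImageNet) can be plugged in by supplying its weights through the
# same layer list.

#' Classic VGG16 layer names
#'
#' Naming scheme used for layer arguments: convolutional blocks
#' `conv1_1 ... conv5_3`, pooling `pool1 ... pool5`, fully connected `fc6`,
#' `fc7` and their rectified outputs `relu6`, `relu7`. The rectified
#' embedding `relu6` (post-ReLU `fc6`) is the default texture layer.
#'
#' @export
VGG16_LAYERS <- c(
  "conv1_1", "conv1_2", "pool1",
  "conv2_1", "conv2_2", "pool2",
  "conv3_1", "conv3_2", "conv3_3", "pool3",
  "conv4_1", "conv4_2", "conv4_3", "pool4",
  "conv5_1", "conv5_2", "conv5_3", "pool5",
  "fc6", "relu6", "fc7", "relu7"
)

#' Build a feature-extraction backbone
#'
#' A backbone is an ordered list of layers (`conv` 3x3 same-padding,
#' `relu`, `pool` 2x2 max, `fc` dense on the flattened input) plus a
#' preprocessing recipe (resize target, per-channel means and scales).
#' Patches are bilinearly resized to the input size and channel-normalized
#' before the forward pass, for every requested layer, because the fully
#' connected layers need a fixed input size.
#'
#' @param name backbone identifier.
#' @param input_size integer: patches are resized to
#'   `input_size x input_size`.
#' @param layers list of layer descriptors; each is a list with `name`,
#'   `type` (`"conv"`, `"relu"`, `"pool"`, `"fc"`) and, for `conv`/`fc`,
#'   `w` and `b` weight arrays (`conv`: k x k x Cin x Cout; `fc`:
#'   D x Dout on the column-major flattened input).
#' @param channel_means,channel_scales length-3 normalization applied as
#'   `(x - mean) / scale` per channel.
#' @return an object of class `"backbone_spec"`.
#' @export
backbone_spec <- function(name, input_size, layers,
                          channel_means = c(0.5, 0.5, 0.5),
                          channel_scales = c(0.5, 0.5, 0.5)) {
  if (!length(layers)) {
    abort_percsim("a backbone needs at least one layer.", "percsim_usage_error")
  }
  structure(
    list(name = name, input_size = as.integer(input_size), layers = layers,
         channel_means = channel_means, channel_scales = channel_scales),
    class = "backbone_spec"
  )
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec> '%s', input %dx%d, layers: %s\n",
              x$name, x$input_size, x$input_size,
              paste(backbone_layer_names(x), collapse = ", ")))
  invisible(x)
}

#' @rdname backbone_spec
#' @param backbone a `backbone_spec`.
#' @export
backbone_layer_names <- function(backbone) {
  vapply(backbone$layers, `[[`, character(1), "name")
}

#' Seeded random stub backbone
#'
#' A small convolutional network (two 3x3 convolution + ReLU + max-pool
#' blocks, then one fully connected embedding) with weights drawn from a
#' seeded Gaussian. Random convolutional features are a long-standing,
#' surprisingly effective texture descriptor: the stub responds to the
#' amplitude and scale of local structure, which is all the texture
#' similarity needs, while being fully reproducible and dependency-free.
#' Layer names follow the VGG convention (`conv1`, `relu1`, `pool1`,
#' `conv2`, `relu2`, `pool2`, `fc6`, `relu6`).
#'
#' @param seed integer seed for the weight draw.
#' @param input_size resize target (default 32).
#' @param channels channel widths of the two conv blocks.
#' @param embed_dim length of the `fc6` embedding.
#' @return a [backbone_spec()].
#' @export
stub_backbone <- function(seed = 2023L, input_size = 32L,
                          channels = c(8L, 16L), embed_dim = 64L) {
  withr::with_seed(seed, {
    he <- function(k, cin, cout) {
      w <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout))
      # mean-center every kernel slice: the filters respond to local
      # contrast, not to the absolute channel level, so a constant color
      # shift leaves all activations unchanged (texture is decoupled from
      # mean color by construction)
      for (ci in seq_len(cin)) {
        for (o in seq_len(cout)) {
          w[, , ci, o] <- w[, , ci, o] - mean(w[, , ci, o])
        }
      }
      w
    }
    layers <- list(
      list(name = "conv1", type = "conv", w = he(3, 3, channels[1]),
           b = rep(0, channels[1])),
      list(name = "relu1", type = "relu"),
      list(name = "pool1", type = "pool"),
      list(name = "conv2", type = "conv", w = he(3, channels[1], channels[2]),
           b = rep(0, channels[2])),
      list(name = "relu2", type = "relu"),
      list(name = "pool2", type = "pool"),
      # global average pooling: the embedding sees per-channel response
      # statistics (a texture signature), not pixel placement, so patches
      # with the same texture but independent noise realizations embed
      # nearly identically
      list(name = "gap", type = "gap"),
      # the fc bias anchors the embedding at a fixed point (as trained
      # networks' biases do), breaking the cosine's scale invariance so the
      # embedding distinguishes texture amplitudes, not just texture shapes;
      # its scale sits a few times above the baseline skin-texture response
      list(name = "fc6", type = "fc",
           w = matrix(rnorm(channels[2] * embed_dim, sd = sqrt(1 / channels[2])),
                      nrow = channels[2]),
           b = rnorm(embed_dim, 0, 0.1)),
      list(name = "relu6", type = "relu")
    )
    backbone_spec(sprintf("stub-%d", seed), input_size, layers)
  })
}

# same-size convolution with edge-replicate padding, via shift-and-add
# (vectorized over positions); replicate padding keeps constant inputs
# constant, so mean-centered kernels are exactly shift-invariant
conv2d_same <- function(x, w, b) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; cin <- d[3]
  k <- dim(w)[1]; cout <- dim(w)[4]
  pad <- (k - 1L) %/% 2L
  ri <- c(rep(1L, pad), seq_len(H), rep(H, pad))
  ci_idx <- c(rep(1L, pad), seq_len(W), rep(W, pad))
  xp <- x[ri, ci_idx, , drop = FALSE]
  out <- array(rep(b, each = H * W), c(H, W, cout))
  for (o in seq_len(cout)) {
    acc <- out[, , o]
    for (ci in seq_len(cin)) {
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          acc <- acc + w[i, j, ci, o] *
            xp[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W), ci]
        }
      }
    }
    out[, , o] <- acc
  }
  out
}

maxpool2 <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  i1 <- seq(1L, 2L * H2, by = 2L); j1 <- seq(1L, 2L * W2, by = 2L)
  pmax(x[i1, j1, , drop = FALSE], x[i1 + 1L, j1, , drop = FALSE],
       x[i1, j1 + 1L, , drop = FALSE], x[i1 + 1L, j1 + 1L, , drop = FALSE])
}

# bilinear resize of an H x W x 3 array to size x size
resize_bilinear <- function(px, size) {
  d <- dim(px)
  if (d[1] == size && d[2] == size) return(px)
  img <- EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  aperm(as.array(out), c(2L, 1L, 3L))
}

backbone_preprocess <- function(patch, backbone) {
  px <- if (inherits(patch, "image_patch")) patch$pixels else patch
  px <- resize_bilinear(px, backbone$input_size)
  for (ch in 1:3) {
    px[, , ch] <- (px[, , ch] - backbone$channel_means[ch]) /
      backbone$channel_scales[ch]
  }
  px
}

backbone_forward <- function(x, backbone) {
  acts <- vector("list", length(backbone$layers))
  names(acts) <- backbone_layer_names(backbone)
  for (idx in seq_along(backbone$layers)) {
    ly <- backbone$layers[[idx]]
    x <- switch(ly$type,
      conv = conv2d_same(x, ly$w, ly$b),
      relu = pmax(x, 0),
      pool = maxpool2(x),
      gap  = as.numeric(colMeans(matrix(x, ncol = dim(x)[3]))),
      fc   = as.numeric(as.vector(x) %*% ly$w + ly$b),
      abort_percsim(sprintf("unknown layer type '%s'.", ly$type),
                    "percsim_usage_error")
    )
    acts[[idx]] <- x
  }
  acts
}

#' Extract named activations for a patch
#'
#' Resizes and normalizes the patch per the backbone's preprocessing, runs
#' the forward pass once, and returns the requested layers in order.
#' Convolutional/pooling layers yield spatial H x W x C activation maps;
#' fully connected layers (and their rectified variants) yield vectors.
#'
#' @param patch an [image_patch()] or H x W x 3 array.
#' @param backbone a [backbone_spec()], e.g. [stub_backbone()].
#' @param layers character vector of layer names (subset of
#'   [backbone_layer_names()]).
#' @return named list of `activation_map` objects (fields `layer`, `kind`
#'   = `"spatial"` or `"vector"`, `data`).
#' @export
extract_activations <- function(patch, backbone,
                                layers = backbone_layer_names(backbone)) {
  known <- backbone_layer_names(backbone)
  bad <- setdiff(layers, known)
  if (length(bad)) {
    abort_percsim(
      sprintf("unknown layer(s) %s; available: %s.",
              paste0("'", bad, "'", collapse = ", "),
              paste(known, collapse = ", ")),
      "percsim_usage_error"
    )
  }
  acts <- backbone_forward(backbone_preprocess(patch, backbone), backbone)
  lapply(stats::setNames(layers, layers), function(nm) {
    activation_map(nm, acts[[nm]])
  })
}

#' @rdname extract_activations
#' @param layer layer name.
#' @param data H x W x C array (spatial) or numeric vector.
#' @export
activation_map <- function(layer, data) {
  kind <- if (is.array(data) && length(dim(data)) == 3L) "spatial" else "vector"
  if (kind == "vector") data <- as.numeric(data)
  if (any(!is.finite(data))) {
    abort_percsim("activations must be finite.", "percsim_format_error")
  }
  structure(list(layer = layer, kind = kind, data = data),
            class = "activation_map")
}
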