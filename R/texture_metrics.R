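#' Cosine similarity between activation maps
#'
#' For spatial activation maps the cosine similarity is computed position
#' by position between the two length-C channel vectors and averaged over
#' the H x W positions. Positions where both channel vectors are zero
#' contribute 1 (identical absence of response); positions where exactly
#' one is zero contribute 0. This keeps rectified, sparse maps from
#' producing NaNs. For fully connected embeddings the plain vector cosine
#' `dot(a, b) / (|a| |b|)` is used.
#'
#' @param a,b `activation_map`s of the same layer, kind and shape (see
#'   [extract_activations()]), or raw arrays/vectors of matching shape.
#' @return scalar in `[-1, 1]`.
#' @name activation_cosine
NULL

act_data <- function(x) if (inherits(x, "activation_map")) x$data else x

#' @rdname activation_cosine
#' @export
cosine_similarity_spatial <- function(a, b) {
  a <- act_data(a); b <- act_data(b)
  if (!identical(dim(a), dim(b)) || length(dim(a)) != 3L) {
    abort_percsim("spatial cosine needs two H x W x C arrays of equal shape.",
                  "percsim_usage_error")
  }
  nchan <- dim(a)[3]
  ma <- matrix(a, ncol = nchan) # rows = spatial positions
  mb <- matrix(b, ncol = nchan)
  na <- sqrt(rowSums(ma^2))
  nb <- sqrt(rowSums(mb^2))
  dots <- rowSums(ma * mb)
  cosv <- ifelse(na > 0 & nb > 0, dots / (na * nb),
                 ifelse(na == 0 & nb == 0, 1, 0))
  mean(cosv)
}

#' @rdname activation_cosine
#' @export
cosine_similarity_vector <- function(a, b) {
  a <- act_data(a); b <- act_data(b)
  if (length(a) != length(b)) {
    abort_percsim("vector cosine needs two vectors of equal length.",
                  "percsim_usage_error")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) {
    abort_percsim("both embeddings are zero; cosine similarity is undefined.",
                  "percsim_degenerate_error")
  }
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

activation_cosine <- function(a, b) {
  if (inherits(a, "activation_map") && a$kind == "spatial") {
    cosine_similarity_spatial(a, b)
  } else {
    cosine_similarity_vector(a, b)
  }
}

#' Triplet texture similarity
#'
#' Texture similarity of the target patch to its perilesional references at
#' one backbone layer:
#' `value = (cos(S, S1) + cos(S, S2)) / 2`
#' where `cos` is the layer-appropriate cosine similarity of
#' [extract_activations()] outputs. Higher values mean the target's texture
#' is closer to the surrounding skin. The default layer is the rectified
#' first fully connected embedding (`relu6`), the most predictive layer for
#' perceptual texture scores.
#'
#' @param triplet a [patch_triplet()].
#' @param backbone a [backbone_spec()].
#' @param layer layer name (default `"relu6"`).
#' @return one-row tibble: `source_id`, `layer`, `similarity`.
#' @export
texture_similarity <- function(triplet, backbone = stub_backbone(),
                               layer = "relu6") {
  if (!inherits(triplet, "patch_triplet")) {
    abort_percsim("`triplet` must be a patch_triplet.", "percsim_usage_error")
  }
  aS  <- extract_activations(triplet$target, backbone, layer)[[layer]]
  a1  <- extract_activations(triplet$peri1, backbone, layer)[[layer]]
  a2  <- extract_activations(triplet$peri2, backbone, layer)[[layer]]
  val <- (activation_cosine(aS, a1) + activation_cosine(aS, a2)) / 2
  tibble::tibble(source_id = triplet$source_id, layer = layer,
                 similarity = val)
}

#' Texture similarity across layers
#'
#' Evaluates [texture_similarity()] at several layers with a single forward
#' pass per patch, for comparing the expressive ability of different
#' backbone layers.
#'
#' @param triplets list of [patch_triplet()]s.
#' @param backbone a [backbone_spec()].
#' @param layers character vector of layer names.
#' @return tibble with columns `source_id`, `layer`, `similarity` (one row
#'   per triplet x layer).
#' @export
layer_sweep <- function(triplets, backbone = stub_backbone(),
                        layers = backbone_layer_names(backbone)) {
  if (!length(triplets) || !length(layers)) {
    abort_percsim("`triplets` and `layers` must be non-empty.",
                  "percsim_usage_error")
  }
  purrr::map_dfr(triplets, function(tr) {
    aS <- extract_activations(tr$target, backbone, layers)
    a1 <- extract_activations(tr$peri1, backbone, layers)
    a2 <- extract_activations(tr$peri2, backbone, layers)
    tibble::tibble(
      source_id = tr$source_id,
      layer = layers,
      similarity = vapply(layers, function(ly) {
        (activation_cosine(aS[[ly]], a1[[ly]]) +
         activation_cosine(aS[[ly]], a2[[ly]])) / 2
      }, numeric(1), USE.NAMES = FALSE)
    )
  })
}

#' Score the texture similarity of many triplets
#'
#' Tidy wrapper mapping [texture_similarity()] over a list of triplets.
#'
#' @inheritParams layer_sweep
#' @param layer single layer name.
#' @return tibble with one row per triplet.
#' @export
score_texture <- function(triplets, backbone = stub_backbone(),
                          layer = "relu6") {
  purrr::map_dfr(triplets, texture_similarity, backbone = backbone,
                 layer = layer)
}
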