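#' Color distance metrics between mean color vectors
#'
#' Distances between two patch mean-color vectors, the building blocks of
#' the triplet color similarity. `euclidean_distance()` in CIELAB equals the
#' classic DeltaE (1976). `bray_curtis_distance()` is the normalized
#' L1-type distance `sum(|c1 - c2|) / sum(c1 + c2)`, defined for
#' nonnegative coordinates and bounded in `[0, 1]` (0 means identical).
#' `delta_e94()` is the CIE94 color difference with graphic-arts constants
#' (`kL = kC = kH = 1`, `K1 = 0.045`, `K2 = 0.015`); the reference chroma
#' is taken from the first argument, so the target (lesional) patch should
#' always be passed first.
#'
#' @param c1,c2 [color_vector()]s in the same space (`delta_e94()` requires
#'   LAB).
#' @return a nonnegative scalar distance.
#' @name color_distances
NULL

check_same_space <- function(c1, c2) {
  if (!inherits(c1, "color_vector") || !inherits(c2, "color_vector")) {
    abort_percsim("inputs must be color_vector objects (see mean_color()).",
                  "percsim_usage_error")
  }
  if (!identical(color_space(c1), color_space(c2))) {
    abort_percsim(sprintf("color spaces differ: %s vs %s.",
                          color_space(c1), color_space(c2)),
                  "percsim_usage_error")
  }
}

#' @rdname color_distances
#' @export
euclidean_distance <- function(c1, c2) {
  check_same_space(c1, c2)
  sqrt(sum((as.numeric(c1) - as.numeric(c2))^2))
}

#' @rdname color_distances
#' @export
bray_curtis_distance <- function(c1, c2) {
  check_same_space(c1, c2)
  a <- as.numeric(c1); b <- as.numeric(c2)
  if (any(a < -1e-9) || any(b < -1e-9)) {
    abort_percsim(
      paste0("Bray-Curtis needs nonnegative coordinates (skin colors are ",
             "positive in YIQ/LAB); got a negative component."),
      "percsim_domain_error"
    )
  }
  # numerical zeros (e.g. chroma of a gray pixel) are clamped, true
  # negatives rejected above
  a <- pmax(a, 0); b <- pmax(b, 0)
  denom <- sum(a + b)
  if (denom == 0) return(0)
  sum(abs(a - b)) / denom
}

#' @rdname color_distances
#' @export
delta_e94 <- function(c1, c2) {
  check_same_space(c1, c2)
  if (color_space(c1) != "LAB") {
    abort_percsim("delta_e94 is defined on CIELAB vectors only.",
                  "percsim_usage_error")
  }
  a <- as.numeric(c1); b <- as.numeric(c2)
  dL <- a[1] - b[1]
  C1 <- sqrt(a[2]^2 + a[3]^2) # reference chroma: first argument (the target)
  C2 <- sqrt(b[2]^2 + b[3]^2)
  dC <- C1 - C2
  dE2 <- dL^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2
  dH2 <- max(dE2 - dL^2 - dC^2, 0)
  kL <- 1; kC <- 1; kH <- 1; K1 <- 0.045; K2 <- 0.015
  SL <- 1; SC <- 1 + K1 * C1; SH <- 1 + K2 * C1
  sqrt((dL / (kL * SL))^2 + (dC / (kC * SC))^2 + dH2 / (kH * SH)^2)
}

color_metric_fun <- function(metric) {
  switch(metric,
    euclidean = euclidean_distance,
    deltae    = euclidean_distance, # DeltaE-1976 is Euclidean in LAB
    bcd       = bray_curtis_distance,
    deltae94  = delta_e94,
    abort_percsim(sprintf("unknown color metric '%s'.", metric),
                  "percsim_usage_error")
  )
}

#' Triplet color similarity
#'
#' Aggregates a color distance over a patch triplet:
#' `value = (M(mean(S), mean(S1)) + M(mean(S), mean(S2))) / 2`, where the
#' means are per-patch mean color vectors in the requested space. The
#' result is a distance (0 = the target looks like perilesional skin).
#'
#' @param triplet a [patch_triplet()].
#' @param space `"RGB"`, `"YIQ"` or `"LAB"`.
#' @param metric `"euclidean"`, `"bcd"`, `"deltae"` or `"deltae94"`
#'   (`"deltae"`/`"deltae94"` require `space = "LAB"`).
#' @return a one-row tibble: `source_id`, `space`, `metric`, `distance`,
#'   and `similarity` (`1 - distance`, only for the `[0, 1]`-bounded
#'   `bcd`; `NA` otherwise).
#' @export
color_similarity <- function(triplet,
                             space = c("YIQ", "RGB", "LAB"),
                             metric = c("bcd", "euclidean", "deltae", "deltae94")) {
  space <- match.arg(space)
  metric <- match.arg(metric)
  if (metric %in% c("deltae", "deltae94") && space != "LAB") {
    abort_percsim(sprintf("metric '%s' requires space = \"LAB\".", metric),
                  "percsim_usage_error")
  }
  if (!inherits(triplet, "patch_triplet")) {
    abort_percsim("`triplet` must be a patch_triplet.", "percsim_usage_error")
  }
  f <- color_metric_fun(metric)
  cs <- mean_color(triplet$target, space)
  d <- (f(cs, mean_color(triplet$peri1, space)) +
        f(cs, mean_color(triplet$peri2, space))) / 2
  tibble::tibble(
    source_id = triplet$source_id,
    space = space, metric = metric,
    distance = d,
    similarity = if (metric == "bcd") 1 - d else NA_real_
  )
}

#' Convert a Bray-Curtis distance to a similarity
#'
#' Color similarity on the bounded Bray-Curtis scale is `1 - BCD`, so
#' higher values mean the target is closer to perilesional skin (the
#' orientation used for cluster plots).
#'
#' @param bcd_value numeric in `[0, 1]`.
#' @return `1 - bcd_value`.
#' @export
to_similarity <- function(bcd_value) {
  if (any(!is.finite(bcd_value)) || any(bcd_value < 0) || any(bcd_value > 1)) {
    abort_percsim("BCD values must lie in [0, 1].", "percsim_domain_error")
  }
  1 - bcd_value
}

#' Score the color similarity of many triplets
#'
#' Tidy wrapper mapping [color_similarity()] over a list of triplets.
#'
#' @param triplets list of [patch_triplet()]s.
#' @inheritParams color_similarity
#' @return tibble with one row per triplet.
#' @export
score_color <- function(triplets, space = "YIQ", metric = "bcd") {
  purrr::map_dfr(triplets, color_similarity, space = space, metric = metric)
}
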