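# Synthetic patch triplets and rater panels. The generator emulates the
# statistical structure of a clinical study: photographs of lesion sites in
# which the target patch deviates from the perilesional skin by a
# grade-controlled mean-color offset (a reddening typical of lesional or
# scarred skin) and a grade-controlled amplitude of band-passed structural
# noise, rated by a small panel of noisy but consistent experts on the
# 1-4 visibility scale.

# direction in sRGB along which lesion color departs from base skin:
# erythema-like reddening (green and blue drop faster than red), which
# darkens slightly, stays inside the sRGB gamut for realistic offsets, and
# moves the YIQ chroma coordinates further into the positive octant.
LESION_COLOR_DIRECTION <- c(-0.2, -0.8, -0.55)

#' Default grade-to-deviation map
#'
#' Mean-color offset magnitudes (sRGB units along the reddening direction)
#' and lesion-texture amplitudes per visibility grade. Grade 1
#' (indistinguishable) injects nothing; deviations increase strictly with
#' grade, and the per-item lognormal jitter (`jitter_sd` on the log scale)
#' makes adjacent grades overlap, so exact-grade recovery is hard while
#' within-one-level recovery is easy - the regime the ordinal validation is
#' designed for.
#'
#' @return list with numeric `color_delta[4]`, `texture_amp[4]`,
#'   `jitter_sd`.
#' @export
default_grade_map <- function() {
  list(
    color_delta = c(0, 0.04, 0.09, 0.16),
    texture_amp = c(0, 0.03, 0.07, 0.12),
    jitter_sd = 0.35
  )
}

#' Describe one synthetic lesion photograph
#'
#' @param grade visibility grade 1..4 of the simulated site.
#' @param color_offset length-3 sRGB offset added to the target patch's
#'   base color (must be zero for grade 1).
#' @param texture_amp amplitude multiplying the band-passed lesion texture
#'   (zero for grade 1).
#' @param base_color sRGB base skin color shared by the three patches.
#' @param patch_size `c(H, W)` of every generated patch.
#' @param seed integer seed; generation is bit-reproducible given the
#'   scenario.
#' @return an object of class `"lesion_scenario"`.
#' @export
lesion_scenario <- function(grade, color_offset = NULL, texture_amp = NULL,
                            base_color = c(0.80, 0.55, 0.45),
                            patch_size = c(48L, 48L), seed = 1L) {
  grade <- as.integer(grade)
  if (!grade %in% 1:4) {
    abort_percsim("`grade` must be in 1..4.", "percsim_usage_error")
  }
  gm <- default_grade_map()
  if (is.null(color_offset)) {
    color_offset <- gm$color_delta[grade] * LESION_COLOR_DIRECTION
  }
  if (is.null(texture_amp)) texture_amp <- gm$texture_amp[grade]
  if (grade == 1L && (any(color_offset != 0) || texture_amp != 0)) {
    abort_percsim("grade 1 means no injected deviation.", "percsim_usage_error")
  }
  if (texture_amp < 0) {
    abort_percsim("`texture_amp` must be nonnegative.", "percsim_usage_error")
  }
  structure(
    list(grade = grade, color_offset = as.numeric(color_offset),
         texture_amp = texture_amp, base_color = as.numeric(base_color),
         patch_size = as.integer(patch_size), seed = as.integer(seed)),
    class = "lesion_scenario"
  )
}

# smoothed unit-variance Gaussian field, H x W
smooth_field <- function(h, w, kernel_size) {
  noise <- array(rnorm((h + 2 * kernel_size) * (w + 2 * kernel_size)),
                 dim = c(h + 2 * kernel_size, w + 2 * kernel_size, 1))
  kern <- array(1 / kernel_size^2, dim = c(kernel_size, kernel_size, 1, 1))
  sm <- conv2d_same(noise, kern, 0)[kernel_size + seq_len(h),
                                    kernel_size + seq_len(w), 1]
  sm / sd(sm)
}

# skin-like base texture: low-amplitude smoothed luminance noise
BASE_TEXTURE_AMP <- 0.02

skin_patch <- function(base_color, h, w, seed) {
  withr::with_seed(seed, {
    field <- smooth_field(h, w, 5L)
    px <- array(rep(base_color, each = h * w), dim = c(h, w, 3L))
    for (ch in 1:3) px[, , ch] <- px[, , ch] + BASE_TEXTURE_AMP * field
    px
  })
}

# band-passed structural noise for the lesion component: fine smoothing
# minus coarse smoothing isolates mid-frequency structure
lesion_field <- function(h, w, seed) {
  withr::with_seed(seed, {
    noise <- rnorm(h * w) # single draw shared by both smoothing scales
    base <- matrix(noise, h, w)
    f <- smooth_field_from(base, 3L) - smooth_field_from(base, 9L)
    f / sd(f)
  })
}

smooth_field_from <- function(base, kernel_size) {
  h <- nrow(base); w <- ncol(base)
  pad <- kernel_size
  big <- matrix(0, h + 2 * pad, w + 2 * pad)
  big[pad + seq_len(h), pad + seq_len(w)] <- base
  # reflect edges so the band-pass has no border artifact
  big[seq_len(pad), ] <- big[pad + seq_len(pad), ][pad:1, ]
  big[pad + h + seq_len(pad), ] <- big[h + seq_len(pad), ][pad:1, ]
  big[, seq_len(pad)] <- big[, pad + seq_len(pad)][, pad:1]
  big[, pad + w + seq_len(pad)] <- big[, w + seq_len(pad)][, pad:1]
  kern <- array(1 / kernel_size^2, dim = c(kernel_size, kernel_size, 1, 1))
  conv2d_same(array(big, dim = c(dim(big), 1L)), kern, 0)[pad + seq_len(h),
                                                          pad + seq_len(w), 1]
}

#' Generate one synthetic patch triplet
#'
#' The two perilesional patches are the base skin color plus low-amplitude
#' smoothed luminance noise (independent seeds). The target patch uses the
#' same construction plus the scenario's mean-color offset and
#' `texture_amp`-scaled band-passed structural noise. All pixels are
#' clipped to `[0, 1]`; if more than 10% of pixels needed clipping the
#' scenario is flagged with a warning.
#'
#' @param scenario a [lesion_scenario()].
#' @param source_id identifier stamped on the three patches.
#' @return a [patch_triplet()].
#' @export
generate_triplet <- function(scenario, source_id = sprintf("sim-%d", scenario$seed)) {
  h <- scenario$patch_size[1]; w <- scenario$patch_size[2]
  s1 <- skin_patch(scenario$base_color, h, w, derive_seed(scenario$seed, 1L))
  s2 <- skin_patch(scenario$base_color, h, w, derive_seed(scenario$seed, 2L))
  s <- skin_patch(scenario$base_color, h, w, derive_seed(scenario$seed, 3L))
  for (ch in 1:3) s[, , ch] <- s[, , ch] + scenario$color_offset[ch]
  if (scenario$texture_amp > 0) {
    lf <- lesion_field(h, w, derive_seed(scenario$seed, 4L))
    for (ch in 1:3) s[, , ch] <- s[, , ch] + scenario$texture_amp * lf
  }
  clipped <- mean(s < 0 | s > 1)
  if (clipped > 0.10) {
    warning(sprintf("%.0f%% of target pixels clipped; scenario leaves gamut.",
                    100 * clipped), call. = FALSE)
  }
  clip01 <- function(px) pmin(pmax(px, 0), 1)
  patch_triplet(
    image_patch(clip01(s), source_id),
    image_patch(clip01(s1), source_id),
    image_patch(clip01(s2), source_id)
  )
}

# truncate jitter draws at two standard deviations: extreme outliers would
# leave the sRGB gamut rather than look like worse lesions
trunc2sd <- function(x, s) pmin(pmax(x, -2 * s), 2 * s)

#' Generate a graded synthetic dataset
#'
#' Draws `n_per_grade[g]` scenarios per grade `g` with lognormal jitter
#' around the grade map's offsets and amplitudes, small per-photo base
#' color variation, and per-item seeds derived from the master seed. The
#' default counts mirror a 176-photo study with grade marginals
#' 24/61/44/47.
#'
#' @param n_per_grade integer vector of length 4: items per grade.
#' @param grade_map list as returned by [default_grade_map()].
#' @param master_seed integer master seed.
#' @param patch_size `c(H, W)` for all patches.
#' @return list with `triplets` (list of [patch_triplet()]) and `truth`
#'   (tibble `item_id`, `grade`, `color_delta`, `texture_amp`).
#' @export
generate_dataset <- function(n_per_grade = c(24L, 61L, 44L, 47L),
                             grade_map = default_grade_map(),
                             master_seed = 1L,
                             patch_size = c(48L, 48L)) {
  if (length(n_per_grade) != 4L || any(n_per_grade < 0)) {
    abort_percsim("`n_per_grade` must be 4 nonnegative counts.",
                  "percsim_usage_error")
  }
  grades <- rep(1:4, times = n_per_grade)
  n <- length(grades)
  params <- withr::with_seed(derive_seed(master_seed, 0L), {
    tibble::tibble(
      grade = grades,
      jitter_c = exp(trunc2sd(rnorm(n, 0, grade_map$jitter_sd), grade_map$jitter_sd)),
      jitter_t = exp(trunc2sd(rnorm(n, 0, grade_map$jitter_sd), grade_map$jitter_sd)),
      base_shift = matrix(runif(n * 3, -0.01, 0.01), ncol = 3) |>
        asplit(1)
    )
  })
  triplets <- vector("list", n)
  truth <- tibble::tibble(
    item_id = sprintf("item-%03d", seq_len(n)),
    grade = grades,
    color_delta = ifelse(grades == 1L, 0,
                         grade_map$color_delta[grades] * params$jitter_c),
    texture_amp = ifelse(grades == 1L, 0,
                         grade_map$texture_amp[grades] * params$jitter_t)
  )
  for (i in seq_len(n)) {
    sc <- lesion_scenario(
      grade = grades[i],
      color_offset = truth$color_delta[i] * LESION_COLOR_DIRECTION,
      texture_amp = truth$texture_amp[i],
      base_color = c(0.80, 0.55, 0.45) + as.numeric(params$base_shift[[i]]),
      patch_size = patch_size,
      seed = derive_seed(master_seed, i)
    )
    triplets[[i]] <- generate_triplet(sc, source_id = truth$item_id[i])
  }
  list(triplets = triplets, truth = truth)
}

#' Simulate an expert rater panel
#'
#' Each rater's score is a noisy discretization of the latent grade:
#' `clamp(round(grade + Normal(0, noise_sd)), 1, 4)`, independent across
#' raters and items. At `noise_sd = 0.5` a 6-rater panel reproduces the
#' qualitative behavior of an expert panel: excellent internal consistency
#' (alpha > 0.9) with moderate pairwise kappa.
#'
#' @param grades integer vector of true grades 1..4.
#' @param n_raters panel size (default 6).
#' @param noise_sd latent rating noise (default 0.5).
#' @param seed RNG seed.
#' @param attribute label for the resulting [rating_table()].
#' @return a [rating_table()] (items x raters).
#' @export
simulate_raters <- function(grades, n_raters = 6L, noise_sd = 0.5, seed = 1L,
                            attribute = "color") {
  if (n_raters < 2L) {
    abort_percsim("a panel needs at least 2 raters.", "percsim_usage_error")
  }
  n <- length(grades)
  m <- withr::with_seed(seed, {
    raw <- matrix(rep(grades, n_raters) + rnorm(n * n_raters, 0, noise_sd),
                  nrow = n)
    pmin(pmax(round(raw), 1L), 4L)
  })
  rownames(m) <- sprintf("item-%03d", seq_len(n))
  colnames(m) <- sprintf("rater-%d", seq_len(n_raters))
  rating_table(m, attribute = attribute)
}
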