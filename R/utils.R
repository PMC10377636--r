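# internal helpers

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (2.5 -> 3,
#' -2.5 -> -3), unlike [round()]'s round-half-even. Used for gold-standard
#' rounded mean scores so that class counts do not depend on banker's
#' rounding.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(1.5, 2.5, -2.5)) # 2 3 -3
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# derive a per-repetition seed below 2^31 from a master seed
derive_seed <- function(master_seed, index) {
  (as.integer(master_seed) + as.integer(index)) %% .Machine$integer.max
}

abort_percsim <- function(msg, class) {
  rlang::abort(msg, class = c(class, "percsim_error"))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_percsim(sprintf("`%s` must be a single finite number.", name),
                  "percsim_usage_error")
  }
}
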