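# shared fixture builders; everything is generated in code at test time

random_image <- function(side = 64, bit_depth = 16L, seed = 1,
                         pitch_xy = 250) {
  set.seed(seed)
  intensity_image(matrix(sample(0:(2^bit_depth - 1), side * side,
                                replace = TRUE), side, side),
                  bit_depth = bit_depth, pitch_xy = pitch_xy)
}

# a single straight horizontal filament through the field centre
horizontal_scene <- function(field_nm = 16000, amplitude = 2000,
                             margin = 0.2) {
  sc <- generate_scene(0, field_nm = field_nm, seed = 1,
                       amplitude = amplitude)
  y <- field_nm / 2 + 1  # just off a pixel boundary
  sc$curves <- list(cbind(y, seq(margin * field_nm, (1 - margin) * field_nm,
                                 length.out = 50)))
  sc
}

gaussian_profile <- function(sigma_nm = 100, spacing_nm = 10,
                             halfwidth_nm = 500) {
  pos <- seq(0, 2 * halfwidth_nm, by = spacing_nm)
  line_profile(pos, exp(-(pos - halfwidth_nm)^2 / (2 * sigma_nm^2)))
}
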