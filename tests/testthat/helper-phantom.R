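# Small phantom configurations shared across tests.

small_config <- function(..., seed = 11L) {
  phantom_config(n_frames = 4L, image_size = c(48L, 48L), seed = seed, ...)
}

# Landmark table with a known EAR: horizontal extent 2a, vertical
# distances 2v for both landmark pairs -> EAR = v / a.
landmarks_with_ear <- function(a = 4, v = 2, frame = 0L) {
  data.frame(frame = frame,
             point = paste0("P", 1:6),
             x = c(0, 1, 3, 2 * a, 3, 1),
             y = c(0, v, v, 0, -v, -v),
             stringsAsFactors = FALSE)
}
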