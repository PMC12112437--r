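# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Round-half-up nearest integer; base round() would round half to even,
# which makes nearest-neighbour lookups depend on parity.
round_half_up <- function(x) floor(x + 0.5)

# Validate a long control-point table (frame, point_id, space, x, y);
# single-frame tables may omit the frame column.
check_cp_table <- function(cps, name = "cps", require_space = FALSE,
                           require_frame = TRUE) {
  if (!is.data.frame(cps)) stopf("%s must be a data.frame", name)
  need <- c(if (require_frame) "frame", "point_id", "x", "y")
  if (require_space) need <- c(need, "space")
  miss <- setdiff(need, names(cps))
  if (length(miss) > 0L) {
    stopf("%s is missing column(s): %s", name, paste(miss, collapse = ", "))
  }
  if (!all(is.finite(cps$x)) || !all(is.finite(cps$y))) {
    stopf("%s contains non-finite coordinates", name)
  }
  invisible(cps)
}

# Euclidean distances between row-matched n x 2 coordinate matrices.
point_distances <- function(a, b) sqrt(rowSums((a - b)^2))

fmt_num <- function(x, digits = 4L) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}
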