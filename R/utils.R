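# Shared internal helpers: the angle convention and seeded evaluation.
#
# All axis angles in the package are signed degrees measured from the image
# horizontal, increasing counter-clockwise on screen, folded to (-90, 90].
# Because image rows grow downward, the display direction of an angle a is
# (cos a, -sin a) in (x = column, y = row) coordinates.

deg2rad <- function(a) a * pi / 180

rad2deg <- function(a) a * 180 / pi

# unit direction (dx, dy) in image coordinates for a from-horizontal angle
unit_from_angle <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  c(cos(a), -sin(a))
}

# fold any angle in degrees to the half-open interval (-90, 90]
fold_angle <- function(a) {
  a <- ((a + 90) %% 180) - 90
  a[a == -90] <- 90
  a
}

# angle of the segment p1 -> p2, folded to (-90, 90]
segment_angle <- function(p1, p2) {
  dx <- p2[1] - p1[1]
  dy <- p2[2] - p1[2]
  fold_angle(rad2deg(atan2(-dy, dx)))
}

# evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# derive a reproducible child seed from a base seed and an index, kept
# inside the 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %%
               .Machine$integer.max)
}

stop_if_not_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric matrix", arg),
         call. = FALSE)
  invisible(image)
}
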