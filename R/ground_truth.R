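#' Paired landmark segments of one anatomical structure
#'
#' The trapezoid technique treats the femoral neck (or shaft, or stem) as a
#' quadrangle: its axis joins the midpoints of two transverse landmark
#' segments.
#'
#' @param segment_a,segment_b 2 x 2 matrices, one (x, y) point per row,
#'   with distinct endpoints.
#' @param structure one of `"femoral_neck"`, `"femoral_shaft"`, `"stem"`.
#' @return An object of class `landmark_pair`.
#' @export
landmark_pair <- function(segment_a, segment_b,
                          structure = c("femoral_neck", "femoral_shaft",
                                        "stem")) {
  structure_lab <- match.arg(structure)
  chk <- function(s, nm) {
    s <- as.matrix(s)
    if (!all(dim(s) == c(2L, 2L)) || !is.numeric(s))
      stop(sprintf("`%s` must be a 2x2 numeric matrix", nm), call. = FALSE)
    if (all(s[1, ] == s[2, ]))
      stop(sprintf("`%s` is degenerate (identical endpoints)", nm),
           call. = FALSE)
    s
  }
  segment_a <- chk(segment_a, "segment_a")
  segment_b <- chk(segment_b, "segment_b")
  base::structure(list(segment_a = segment_a, segment_b = segment_b,
                       structure = structure_lab),
                  class = "landmark_pair")
}

#' Axis of a structure by the trapezoid technique
#'
#' The axis passes through the midpoints of the two landmark segments. The
#' direction is a unit vector normalized to a non-negative vertical
#' component (row coordinate), with a non-negative horizontal component
#' breaking the horizontal tie.
#'
#' @param pair a [landmark_pair()].
#' @return A list of class `axis` with `point` (a midpoint) and
#'   `direction` (unit vector).
#' @export
trapezoid_axis <- function(pair) {
  stopifnot(inherits(pair, "landmark_pair"))
  m1 <- colMeans(pair$segment_a)
  m2 <- colMeans(pair$segment_b)
  v <- m2 - m1
  len <- sqrt(sum(v^2))
  if (len < 1e-12)
    stop("segment midpoints coincide: axis undefined", call. = FALSE)
  v <- v / len
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  structure(list(point = m1, direction = unname(v)), class = "axis")
}

#' Angle between two directed axes
#'
#' Uses the full signed direction vectors (not folded to `[0, 90]`), so the
#' result lies in `[0, 180]` degrees.
#'
#' @param axis_1,axis_2 objects of class `axis`, or plain direction
#'   vectors.
#' @return Angle in degrees in `[0, 180]`.
#' @export
axes_angle <- function(axis_1, axis_2) {
  dir_of <- function(a) {
    v <- if (inherits(a, "axis")) a$direction else as.numeric(a)
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("zero direction vector", call. = FALSE)
    v / n
  }
  d1 <- dir_of(axis_1)
  d2 <- dir_of(axis_2)
  rad2deg(acos(max(-1, min(1, sum(d1 * d2)))))
}

#' Clinician NSA by the trapezoid technique
#'
#' Builds the neck (or stem) axis and the shaft axis from their landmark
#' segment pairs and returns the clinical neck-shaft angle between them.
#' To obtain the clinical (obtuse, ~135 degree) angle rather than its
#' supplement, the shaft direction is oriented distally (downward in image
#' coordinates, i.e. non-negative row component) and the neck direction
#' proximally (upward) before measuring.
#'
#' @param neck_pair [landmark_pair()] of the femoral neck or stem.
#' @param shaft_pair [landmark_pair()] of the femoral shaft.
#' @return NSA in degrees.
#' @export
trapezoid_nsa <- function(neck_pair, shaft_pair) {
  neck <- trapezoid_axis(neck_pair)
  shaft <- trapezoid_axis(shaft_pair)
  d_shaft <- shaft$direction            # already non-negative row component
  d_neck <- -neck$direction             # flip to point proximally (upward)
  axes_angle(d_neck, d_shaft)
}

#' NSA ground truth of a synthetic scene's landmarks
#'
#' Applies the trapezoid technique to the neck quadrangle and shaft
#' segment pair emitted by [generate_scene()]; for every generated scene
#' this reproduces `true_nsa_ap` to floating precision.
#'
#' @param scene a [generate_scene()] object.
#' @return NSA in degrees.
#' @export
scene_trapezoid_nsa <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  q <- scene$neck_quadrangle
  neck <- landmark_pair(q[1:2, ], q[3:4, ], "stem")
  shaft <- landmark_pair(scene$shaft_segment_pair[[1]],
                         scene$shaft_segment_pair[[2]], "femoral_shaft")
  trapezoid_nsa(neck, shaft)
}

#' Read a landmark table and compute per-hip clinician NSAs
#'
#' The landmark CSV has one row per segment with columns
#' `hip_id,structure,x1,y1,x2,y2`; each hip needs exactly two
#' `femoral_shaft` segments and two segments of one neck-like structure
#' (`femoral_neck` or `stem`).
#'
#' @param path CSV file path.
#' @return `read_landmarks()` returns the raw data frame;
#'   `landmarks_nsa()` returns a data frame with `hip_id` and
#'   `nsa_clinician`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hip_id", "structure", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df
}

#' @param landmarks a data frame as returned by [read_landmarks()].
#' @rdname read_landmarks
#' @export
landmarks_nsa <- function(landmarks) {
  per_hip <- split(landmarks, landmarks$hip_id)
  res <- lapply(names(per_hip), function(id) {
    d <- per_hip[[id]]
    seg <- function(row) rbind(c(d$x1[row], d$y1[row]),
                               c(d$x2[row], d$y2[row]))
    shaft_rows <- which(d$structure == "femoral_shaft")
    neck_rows <- which(d$structure %in% c("femoral_neck", "stem"))
    if (length(shaft_rows) != 2L || length(neck_rows) != 2L)
      stop(sprintf("hip '%s': need 2 shaft and 2 neck/stem segments", id),
           call. = FALSE)
    shaft <- landmark_pair(seg(shaft_rows[1]), seg(shaft_rows[2]),
                           "femoral_shaft")
    neck <- landmark_pair(seg(neck_rows[1]), seg(neck_rows[2]),
                          d$structure[neck_rows[1]])
    data.frame(hip_id = id, nsa_clinician = trapezoid_nsa(neck, shaft),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
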