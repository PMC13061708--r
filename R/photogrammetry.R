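# Pinhole-geometry stature estimation from image keypoints.
#
# Model: a levelled camera at a fixed height, optical axis horizontal, with
# the subject standing against a fronto-parallel background wall at a known
# distance. Under these assumptions vertical extents at the wall plane scale
# by similar triangles: world_cm = pixel_separation * wall_distance / focal.
# Image coordinates have the origin at the top-left corner with y increasing
# downward. Lens distortion and subject-to-wall offset are ignored; both are
# known error sources of the single-plane model.

#' Camera setup
#'
#' Capture geometry for wall-calibrated photographs. Defaults follow a common
#' field protocol: camera 200 cm from the background wall, lens 100 cm above
#' the floor, levelled. Focal length must be supplied in pixels (no EXIF
#' parsing); the principal point defaults to the image centre.
#'
#' @param focal_px Focal length in pixels; positive.
#' @param wall_distance_cm Camera-to-wall distance, cm (default 200).
#' @param camera_height_cm Optical-centre height above the floor, cm
#'   (default 100).
#' @param image_size_px Integer pair (width, height) in pixels.
#' @param principal_point_px Numeric pair (x, y); defaults to image centre.
#' @return An object of class `camera_setup`.
#' @export
camera_setup <- function(focal_px,
                         wall_distance_cm = 200,
                         camera_height_cm = 100,
                         image_size_px = c(2448, 3264),
                         principal_point_px = image_size_px / 2) {
  if (!is.finite(focal_px) || focal_px <= 0) {
    stop("focal_px must be positive: camera is uncalibrated", call. = FALSE)
  }
  stopifnot(wall_distance_cm > 0, camera_height_cm > 0,
            length(image_size_px) == 2L, all(image_size_px > 0),
            length(principal_point_px) == 2L)
  if (principal_point_px[1] < 0 || principal_point_px[1] > image_size_px[1] ||
      principal_point_px[2] < 0 || principal_point_px[2] > image_size_px[2]) {
    stop("principal point lies outside the image", call. = FALSE)
  }
  structure(
    list(focal_px = focal_px,
         wall_distance_cm = wall_distance_cm,
         camera_height_cm = camera_height_cm,
         image_size_px = as.numeric(image_size_px),
         principal_point_px = as.numeric(principal_point_px)),
    class = "camera_setup"
  )
}

#' Keypoint set
#'
#' The two vertical landmarks consumed by the geometry: the head vertex
#' (`top_px`) and the floor-contact or seat reference (`bottom_px`), in image
#' coordinates (y downward). Keypoint detection itself is upstream of this
#' package.
#'
#' @param posture `"standing"` or `"sitting"`.
#' @param top_px,bottom_px Numeric (x, y) pixel pairs; the top keypoint must
#'   be above the bottom one (smaller y).
#' @return An object of class `keypoint_set`.
#' @export
keypoint_set <- function(posture, top_px, bottom_px) {
  posture <- match.arg(posture, c("standing", "sitting"))
  stopifnot(length(top_px) == 2L, length(bottom_px) == 2L)
  if (!(top_px[2] < bottom_px[2])) {
    stop("degenerate keypoints: head vertex must be above the lower ",
         "reference (top y < bottom y)", call. = FALSE)
  }
  structure(
    list(posture = posture, top_px = as.numeric(top_px),
         bottom_px = as.numeric(bottom_px)),
    class = "keypoint_set"
  )
}

#' Vertical extent at the wall plane
#'
#' Similar-triangles conversion of the pixel separation between the two
#' keypoints into centimetres at the wall plane:
#' `(bottom_y - top_y) * wall_distance_cm / focal_px`.
#' By construction the estimate is linear in pixel separation and in wall
#' distance, and independent of the keypoints' x-coordinates.
#'
#' @param kp A [keypoint_set()].
#' @param cam A [camera_setup()].
#' @return Length in cm (standing height for a standing posture; vertex-to-
#'   seat extent for a sitting posture).
#' @export
#' @examples
#' cam <- camera_setup(focal_px = 1000)
#' kp <- keypoint_set("standing", top_px = c(500, 200), bottom_px = c(500, 1000))
#' vertical_extent_cm(kp, cam)  # 160 cm
vertical_extent_cm <- function(kp, cam) {
  stopifnot(inherits(kp, "keypoint_set"), inherits(cam, "camera_setup"))
  dy <- kp$bottom_px[2] - kp$top_px[2]
  if (dy <= 0) stop("degenerate keypoints: zero or negative pixel extent",
                    call. = FALSE)
  dy * cam$wall_distance_cm / cam$focal_px
}

#' World height of an image row
#'
#' Height above the floor, at the wall plane, of the point imaged at pixel
#' row `y_px`: `camera_height + (principal_y - y_px) * wall_distance / focal`.
#' The on-axis row maps to the camera height; rows below the principal point
#' (larger y) map lower.
#'
#' @param y_px Pixel row(s).
#' @param cam A [camera_setup()].
#' @return Height(s) above the floor, cm.
#' @export
world_height_of_pixel <- function(y_px, cam) {
  stopifnot(inherits(cam, "camera_setup"))
  cam$camera_height_cm +
    (cam$principal_point_px[2] - y_px) * cam$wall_distance_cm / cam$focal_px
}

#' Calibration residual of a standing capture
#'
#' Quality gate: for a standing posture the bottom keypoint is a floor
#' contact, so its back-projected world height should be zero. Returns the
#' absolute residual in cm and flags the capture when it exceeds `tol_cm`.
#'
#' @param kp A standing [keypoint_set()].
#' @param cam A [camera_setup()].
#' @param tol_cm Tolerance in cm (default 2).
#' @return A list with `residual_cm` and logical `pass`.
#' @export
validate_calibration <- function(kp, cam, tol_cm = 2) {
  stopifnot(inherits(kp, "keypoint_set"))
  if (kp$posture != "standing") {
    stop("calibration check requires a standing capture (floor contact)",
         call. = FALSE)
  }
  residual <- abs(world_height_of_pixel(kp$bottom_px[2], cam))
  list(residual_cm = residual, pass = residual <= tol_cm)
}
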