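#' Ground-truth gait parameters for the treadmill simulator
#'
#' Describes one simulated horse trotting in place on a treadmill. The trunk
#' landmarks (eye, withers, croup; the back point is carried along but not
#' analysed) oscillate vertically with a dominant second-harmonic component at
#' twice the stride frequency plus a stride-frequency component that injects
#' left/right asymmetry:
#' \deqn{z_k(t) = z_{0k} - A_k \cos(4\pi f t + \phi_k) + a_k \sin(2\pi f t + \psi)}
#' With the default phases, one stride-frequency unit of asymmetry amplitude
#' \eqn{a} produces a ground-truth Maxdiff of \eqn{2a\cos\psi} and Mindiff of
#' \eqn{2a\sin\psi} (see [oracle_symmetry()]).
#'
#' @param stride_frequency Stride rate in Hz (trot, treadmill).
#' @param belt_speed Treadmill belt speed in m/s.
#' @param duty_factor Fraction of the stride a hoof spends in stance.
#' @param trunk_amp Second-harmonic vertical amplitude in mm; scalar or a
#'   length-3 vector named for eye, withers, croup.
#' @param asym_amp Stride-frequency (asymmetry) amplitude in mm; scalar or
#'   length-3 vector as for `trunk_amp`. Zero gives a perfectly symmetric trot.
#' @param asym_phase Phase of the asymmetry component in radians.
#' @param trunk_phase Per-keypoint phase offsets of the second harmonic in
#'   radians (eye, withers, croup); default all zero.
#' @param hoof_lift Swing-arc apex of the hooves in mm.
#' @param withers_height Withers height of the horse in cm (calibration truth).
#' @param duration Recording length in seconds.
#' @param fps Frame rate in frames per second.
#' @param noise_sigma Default keypoint detection noise (pixels) used by
#'   [simulate_recording()].
#' @param occlusion_rate Default per keypoint-frame occlusion probability.
#' @param seed Integer seed controlling noise and occlusion.
#'
#' @return An object of class `gait_params`.
#' @seealso [simulate_gait()], [default_cameras()]
#' @export
gait_params <- function(stride_frequency = 1.25,
                        belt_speed = 4.8,
                        duty_factor = 0.45,
                        trunk_amp = c(eye = 35, withers = 30, croup = 32),
                        asym_amp = c(eye = 0, withers = 0, croup = 0),
                        asym_phase = 0,
                        trunk_phase = c(eye = 0, withers = 0, croup = 0),
                        hoof_lift = 80,
                        withers_height = 160,
                        duration = 30,
                        fps = 30,
                        noise_sigma = 1,
                        occlusion_rate = 0,
                        seed = 1L) {
  check_number(stride_frequency, "stride_frequency", lower = 0, strict_lower = TRUE)
  check_number(belt_speed, "belt_speed", lower = 0, strict_lower = TRUE)
  check_number(duty_factor, "duty_factor", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(hoof_lift, "hoof_lift", lower = 0)
  check_number(withers_height, "withers_height", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(occlusion_rate, "occlusion_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(asym_phase, "asym_phase")
  trunk_amp <- expand_trunk(trunk_amp, "trunk_amp")
  asym_amp <- expand_trunk(asym_amp, "asym_amp")
  trunk_phase <- expand_trunk(trunk_phase, "trunk_phase")
  if (any(trunk_amp < 0)) stop("'trunk_amp' must be non-negative", call. = FALSE)
  if (any(asym_amp < 0)) stop("'asym_amp' must be non-negative", call. = FALSE)
  structure(list(
    stride_frequency = stride_frequency, belt_speed = belt_speed,
    duty_factor = duty_factor, trunk_amp = trunk_amp, asym_amp = asym_amp,
    asym_phase = asym_phase, trunk_phase = trunk_phase, hoof_lift = hoof_lift,
    withers_height = withers_height, duration = duration, fps = fps,
    noise_sigma = noise_sigma, occlusion_rate = occlusion_rate,
    seed = as.integer(seed)
  ), class = "gait_params")
}

expand_trunk <- function(x, name) {
  kp <- c("eye", "withers", "croup")
  if (length(x) == 1L) x <- rep(x, 3)
  if (length(x) != 3L || !is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite scalar or length-3 vector (eye, withers, croup)",
                 name), call. = FALSE)
  stats::setNames(as.numeric(x), kp)
}

#' @export
print.gait_params <- function(x, ...) {
  cat("Simulated trot parameters\n")
  cat(sprintf("  stride frequency: %.3g Hz   belt speed: %.3g m/s   duty factor: %.2f\n",
              x$stride_frequency, x$belt_speed, x$duty_factor))
  cat(sprintf("  trunk amplitude (mm): eye %.1f, withers %.1f, croup %.1f\n",
              x$trunk_amp[1], x$trunk_amp[2], x$trunk_amp[3]))
  cat(sprintf("  asymmetry amplitude (mm): eye %.1f, withers %.1f, croup %.1f (phase %.2f rad)\n",
              x$asym_amp[1], x$asym_amp[2], x$asym_amp[3], x$asym_phase))
  cat(sprintf("  withers height: %.0f cm   duration: %.3g s at %g fps\n",
              x$withers_height, x$duration, x$fps))
  cat(sprintf("  noise: %.2g px   occlusion: %.2g   seed: %d\n",
              x$noise_sigma, x$occlusion_rate, x$seed))
  invisible(x)
}

#' Pinhole camera description
#'
#' A camera observing the treadmill. The optical axis is horizontal and
#' crosses the treadmill midline; `view_angle` is the horizontal angle between
#' the axis and the direction of travel (90 deg = perpendicular side view,
#' smaller values give oblique views from the front or rear as set by
#' `facing`). Handheld cameras are displaced every frame by a smooth seeded
#' bounce (a sinusoid at `bounce_frequency` plus low-pass-filtered jitter)
#' emulating an operator stepping on the spot; orientation is held fixed.
#'
#' @param id Camera identifier (unique within a session).
#' @param distance_from_midline Perpendicular distance from the treadmill
#'   midline in cm.
#' @param view_angle Angle between optical axis and direction of travel,
#'   degrees in (0, 90].
#' @param height Camera height above the belt in cm.
#' @param facing `"side"`, `"front"` or `"rear"` placement for oblique views.
#' @param side `"right"` or `"left"` of the horse.
#' @param focal_length Focal length in pixels.
#' @param image_size Image width and height in pixels.
#' @param handheld Logical; if `FALSE` the pose is constant across frames.
#' @param bounce_amp Handheld bounce amplitude in mm.
#' @param bounce_frequency Handheld bounce frequency in Hz.
#' @param bounce_seed Seed for the handheld jitter component.
#' @param label Free-text description.
#'
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(id,
                         distance_from_midline = 300,
                         view_angle = 90,
                         height = 100,
                         facing = c("side", "front", "rear"),
                         side = c("right", "left"),
                         focal_length = 950,
                         image_size = c(1920, 1080),
                         handheld = FALSE,
                         bounce_amp = 20,
                         bounce_frequency = 1,
                         bounce_seed = 1L,
                         label = NULL) {
  facing <- match.arg(facing)
  side <- match.arg(side)
  check_number(distance_from_midline, "distance_from_midline",
               lower = 0, strict_lower = TRUE)
  check_number(view_angle, "view_angle", lower = 0, upper = 90,
               strict_lower = TRUE)
  check_number(height, "height", lower = 0, strict_lower = TRUE)
  check_number(focal_length, "focal_length", lower = 0, strict_lower = TRUE)
  check_number(bounce_amp, "bounce_amp", lower = 0)
  check_number(bounce_frequency, "bounce_frequency", lower = 0)
  if (length(image_size) != 2L || any(image_size <= 0))
    stop("'image_size' must be positive width x height in px", call. = FALSE)
  if (facing == "side" && view_angle != 90)
    stop("'view_angle' must be 90 for facing = \"side\"; use facing = \"front\"/\"rear\" for obliques",
         call. = FALSE)
  structure(list(
    id = id, distance_from_midline = distance_from_midline,
    view_angle = view_angle, height = height, facing = facing, side = side,
    focal_length = focal_length, image_size = as.numeric(image_size),
    handheld = isTRUE(handheld), bounce_amp = bounce_amp,
    bounce_frequency = bounce_frequency, bounce_seed = as.integer(bounce_seed),
    label = label %||% sprintf("%s %s %ddeg", facing, side, round(view_angle))
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera %s (%s)%s\n", x$id, x$label,
              if (x$handheld) " [handheld]" else ""))
  cat(sprintf("  midline distance %.0f cm, view angle %.0f deg, height %.0f cm\n",
              x$distance_from_midline, x$view_angle, x$height))
  cat(sprintf("  focal %.0f px, image %d x %d px\n", x$focal_length,
              x$image_size[1], x$image_size[2]))
  if (x$handheld)
    cat(sprintf("  bounce %.0f mm at %.2g Hz (seed %d)\n",
                x$bounce_amp, x$bounce_frequency, x$bounce_seed))
  invisible(x)
}

#' The seven-camera treadmill rig
#'
#' The default camera set used throughout: six stationary cameras around the
#' treadmill (a perpendicular side view at three heights, 50-degree oblique
#' front and rear views, and a left-side view at 250 cm) plus a handheld
#' right-side camera at head height with ~1 Hz operator bounce.
#'
#' @param bounce_amp Handheld bounce amplitude in mm.
#' @param bounce_seed Seed for the handheld jitter.
#' @return A named list of [camera_model()] objects, ids `"cam1"` to `"cam7"`.
#' @export
default_cameras <- function(bounce_amp = 20, bounce_seed = 7L) {
  cams <- list(
    camera_model("cam1", 300, 50, 100, facing = "front", side = "right",
                 label = "oblique front right"),
    camera_model("cam2", 300, 90, 50, side = "right", label = "right side low"),
    camera_model("cam3", 300, 90, 100, side = "right", label = "right side mid"),
    camera_model("cam4", 300, 90, 160, side = "right", label = "right side high"),
    camera_model("cam5", 300, 50, 100, facing = "rear", side = "right",
                 label = "oblique rear right"),
    camera_model("cam6", 250, 90, 100, side = "left", label = "left side"),
    camera_model("cam7", 300, 90, 160, side = "right", handheld = TRUE,
                 bounce_amp = bounce_amp, bounce_frequency = 1,
                 bounce_seed = bounce_seed, label = "handheld right side")
  )
  stats::setNames(cams, vapply(cams, `[[`, "", "id"))
}

# Keypoint schema: 4 trunk landmarks + 3 per leg.
trunk_keypoints <- function() c("eye", "withers", "back", "croup")
leg_ids <- function() c("lf", "rf", "lh", "rh")
hoof_keypoints <- function() paste0("hoof_", leg_ids())
upper_joint_keypoints <- function() {
  # carpus on the forelimbs, tarsus on the hindlimbs
  c("carpus_lf", "carpus_rf", "tarsus_lh", "tarsus_rh")
}
all_keypoints <- function() {
  c(trunk_keypoints(), hoof_keypoints(),
    paste0("fetlock_", leg_ids()), upper_joint_keypoints())
}
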