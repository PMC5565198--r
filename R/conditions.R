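## classed conditions so callers can distinguish configuration errors, bad
## inputs, undefined values, and estimation failures

sp_stop <- function(msg, class) {
  stop(structure(class = c(class, "sceneprobe_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

sp_config_error    <- function(msg) sp_stop(msg, "sceneprobe_config_error")
sp_input_error     <- function(msg) sp_stop(msg, "sceneprobe_input_error")
sp_undefined_value <- function(msg) sp_stop(msg, "sceneprobe_undefined_value")
sp_estimation_error <- function(msg) sp_stop(msg, "sceneprobe_estimation_error")

#' Scene-excluded signal
#'
#' Returned (not thrown) by [select_insertion_points()] when no labelled
#' quadruple of insertion points satisfies all constraints for a scene.
#'
#' @param reason character, why the scene was excluded.
#' @return An object of class \code{scene_excluded}.
#' @export
scene_excluded <- function(reason) {
  structure(list(reason = reason), class = "scene_excluded")
}

#' Test for the scene-excluded signal
#' @param x object to test.
#' @return logical.
#' @export
is_scene_excluded <- function(x) inherits(x, "scene_excluded")

#' @export
print.scene_excluded <- function(x, ...) {
  cat("<scene_excluded>", x$reason, "\n"); invisible(x)
}
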