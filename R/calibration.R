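#' Device-timing calibration offsets
#'
#' Response times logged by stimulus software lag the physical response: the
#' audio round trip (soundcard output to recorded input) adds
#' `audio_pipeline_ms` to both modalities, and the button box adds a further
#' `keypad_mechanical_ms` (electronic latency plus mechanical coupling) to
#' finger responses only. The defaults are bench measurements for the rig the
#' generator emulates: 67.43 ms audio pipeline and 8.4 ms keypad, i.e. a total
#' button-press correction of 75.83 ms.
#'
#' @param audio_pipeline_ms Audio pipeline delay (ms, >= 0).
#' @param keypad_mechanical_ms Extra keypad delay for finger responses (ms, >= 0).
#' @return A `calibration_offsets` object.
#' @export
calibration_offsets <- function(audio_pipeline_ms = 67.43,
                                keypad_mechanical_ms = 8.4) {
  stopifnot(audio_pipeline_ms >= 0, keypad_mechanical_ms >= 0)
  out <- list(audio_pipeline_ms = audio_pipeline_ms,
              keypad_mechanical_ms = keypad_mechanical_ms)
  class(out) <- "calibration_offsets"
  out
}

#' Total correction applied to button presses
#'
#' @param offsets A [calibration_offsets()].
#' @return `audio_pipeline_ms + keypad_mechanical_ms`.
#' @export
#' @examples
#' total_button_offset(calibration_offsets())  # 75.83
total_button_offset <- function(offsets = calibration_offsets()) {
  stopifnot(inherits(offsets, "calibration_offsets"))
  offsets$audio_pipeline_ms + offsets$keypad_mechanical_ms
}

#' Calibrate raw response times
#'
#' Subtracts the device delay for the response modality: vocal responses lose
#' the audio pipeline delay, finger responses additionally lose the keypad
#' delay. Missing responses (`NA`) pass through unchanged. Calibration is a
#' rigid shift within a modality, so same-modality differences (e.g. the
#' proactive-inhibition difference score) are calibration-invariant.
#'
#' @param raw_ms Raw response time(s) in ms (`NA` = miss).
#' @param modality `"finger"` or `"vocal"`; recycled against `raw_ms`.
#' @param offsets A [calibration_offsets()].
#' @return Corrected time(s) in ms.
#' @export
#' @examples
#' calibrate_response(500, "vocal")   # 432.57
#' calibrate_response(500, "finger")  # 424.17
calibrate_response <- function(raw_ms, modality, offsets = calibration_offsets()) {
  stopifnot(inherits(offsets, "calibration_offsets"))
  if (!all(modality %in% c("finger", "vocal"))) {
    stop("calibrate_response: modality must be 'finger' or 'vocal'", call. = FALSE)
  }
  shift <- ifelse(modality == "finger",
                  total_button_offset(offsets),
                  offsets$audio_pipeline_ms)
  raw_ms - shift
}
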