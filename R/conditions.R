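# Typed conditions so the pipeline (and its exit codes) can distinguish
# failure modes: input errors, overlap violations (re-shoot signal),
# calibration failures and measurement failures.

ds_stop <- function(msg, class) {
  stop(structure(class = c(class, "dronestereo_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_input <- function(...) ds_stop(paste0(...), "dronestereo_input_error")
stop_overlap <- function(...) ds_stop(paste0(...), "dronestereo_overlap_error")
stop_calibration <- function(...) ds_stop(paste0(...), "dronestereo_calibration_error")
stop_measurement <- function(...) ds_stop(paste0(...), "dronestereo_measurement_error")
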