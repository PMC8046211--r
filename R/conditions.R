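# Classed conditions so callers (and the CLI) can distinguish failure modes.

rc_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "rimcorrect_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

validation_error <- function(msg, ...) rc_abort(msg, "rimcorrect_validation_error", ...)
config_error <- function(msg, ...) rc_abort(msg, "rimcorrect_config_error", ...)
model_error <- function(msg, ...) rc_abort(msg, "rimcorrect_model_error", ...)
convergence_error <- function(msg, ...) rc_abort(msg, "rimcorrect_convergence_error", ...)
usage_error <- function(msg, ...) rc_abort(msg, "rimcorrect_usage_error", ...)
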