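# Structured error conditions.  Every error raised by the package carries the
# class "leafrect_error" plus a specific subclass so callers (and the batch
# driver) can react programmatically instead of matching message strings.

lf_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "leafrect_error"), call = call))
}

stop_invalid_input    <- function(msg) lf_stop(msg, "leafrect_invalid_input")
stop_invalid_param    <- function(msg) lf_stop(msg, "leafrect_invalid_parameter")
stop_degenerate_image <- function(msg) lf_stop(msg, "leafrect_degenerate_image")
stop_plate_not_found  <- function(msg) lf_stop(msg, "leafrect_plate_not_found")
stop_singular_system  <- function(msg) lf_stop(msg, "leafrect_singular_system")
stop_scene_invalid    <- function(msg) lf_stop(msg, "leafrect_scene_invalid")
stop_scale_unreadable <- function(msg) lf_stop(msg, "leafrect_scale_unreadable")
stop_out_of_range     <- function(msg) lf_stop(msg, "leafrect_out_of_range")
stop_invalid_stats    <- function(msg) lf_stop(msg, "leafrect_invalid_stats")
stop_invalid_spec     <- function(msg) lf_stop(msg, "leafrect_invalid_spec")
stop_usage            <- function(msg) lf_stop(msg, "leafrect_usage_error")

# Re-raise errors from a pipeline stage with the stage name prepended, keeping
# the original condition classes intact.
with_stage <- function(stage, expr) {
  tryCatch(
    expr,
    leafrect_error = function(e) {
      if (is.null(attr(e, "leafrect_stage"))) {
        e$message <- sprintf("[%s] %s", stage, conditionMessage(e))
        attr(e, "leafrect_stage") <- stage
      }
      stop(e)
    }
  )
}

# Run an expression with a temporary RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
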