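# internal error helpers: every user-facing failure carries a class so callers
# (and the CLI) can distinguish bad input from bad configuration
stop_input <- function(msg) abort(msg, class = "dyadsync_input_error")
stop_format <- function(msg) abort(msg, class = "dyadsync_format_error")
stop_domain <- function(msg) abort(msg, class = "dyadsync_domain_error")
stop_config <- function(msg) abort(msg, class = "dyadsync_config_error")
stop_degenerate <- function(msg) abort(msg, class = "dyadsync_degenerate_error")
stop_validation <- function(msg) abort(msg, class = "dyadsync_validation_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fps <- function(fps) {
  if (!is_scalar_number(fps) || fps <= 0) {
    stop_config("`fps` must be a single positive number (Hz)")
  }
  fps
}

# population standard deviation (divisor N), used by the cross-correlation
# normalisation so that c(0) is exactly the Pearson correlation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
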