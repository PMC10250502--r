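# Internal numeric helpers shared across modules.

# Round half away from zero (sample/onset quantization). base::round() rounds
# half to even, which would make onset placement depend on parity.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Population (1/N) standard deviation; stats::sd uses the 1/(N-1) divisor.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_amtrack <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "amtrack_error")))
}
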