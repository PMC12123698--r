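## Condition constructors shared across estimators.

no_support_error <- function(msg) {
  stop(errorCondition(msg, class = c("noSupportError", "tailoras_error")))
}

optimization_error <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("optimizationError", "tailoras_error")))
}

is_no_support <- function(e) inherits(e, "noSupportError")
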