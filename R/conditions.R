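# Classed error conditions used across the package.
#
# Every error raised by landsec inherits from "les_error" plus one of:
#   les_schema_error      - malformed input structure (missing/unknown columns,
#                           label mismatches, duplicate keys)
#   les_value_error       - values violating a domain precondition (non-positive
#                           raw indicator, x outside [0,1], empty input)
#   les_lookup_error      - a requested key (year, fixture, indicator) is absent
#   les_numeric_error     - a numeric routine failed (non-convergence)
#   les_consistency_error - a judgment matrix failed the CR test

les_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "les_error")))
}

les_stop_schema <- function(msg, ...) les_stop(msg, "les_schema_error", ...)
les_stop_value <- function(msg, ...) les_stop(msg, "les_value_error", ...)
les_stop_lookup <- function(msg, ...) les_stop(msg, "les_lookup_error", ...)
les_stop_numeric <- function(msg, ...) les_stop(msg, "les_numeric_error", ...)
les_stop_consistency <- function(msg, ...) les_stop(msg, "les_consistency_error", ...)
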