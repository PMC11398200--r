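# Classed conditions so callers (and the CLI exit-code mapping) can tell a
# misconfiguration from bad data from misuse of a fitted object.

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("radrehab_config_error", "radrehab_error")))
}

abort_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("radrehab_domain_error", "radrehab_error")))
}

abort_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("radrehab_parse_error", "radrehab_data_error",
                                "radrehab_error")))
}

abort_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("radrehab_data_error", "radrehab_error")))
}

abort_state <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("radrehab_state_error", "radrehab_error")))
}

abort_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("radrehab_schema_error", "radrehab_error")))
}
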