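# Structured error conditions. Each user-facing failure mode has its own
# condition class so callers (and the CLI exit-code mapping) can dispatch on
# it rather than on message text.

ligstab_error <- function(msg, class, call = sys.call(-1), ...) {
  structure(
    class = c(class, "ligstab_error", "error", "condition"),
    list(message = msg, call = call, ...)
  )
}

stop_io <- function(msg, ...) stop(ligstab_error(msg, "ligstab_io_error", ...))
stop_selection <- function(msg, ...) stop(ligstab_error(msg, "ligstab_selection_error", ...))
stop_no_contacts <- function(msg, ...) stop(ligstab_error(msg, "ligstab_no_contacts_error", ...))
stop_domain <- function(msg, ...) stop(ligstab_error(msg, "ligstab_domain_error", ...))
stop_topology <- function(msg, ...) stop(ligstab_error(msg, "ligstab_topology_error", ...))
stop_window <- function(msg, ...) stop(ligstab_error(msg, "ligstab_window_error", ...))
stop_superposition <- function(msg, ...) stop(ligstab_error(msg, "ligstab_superposition_error", ...))
stop_correspondence <- function(msg, ...) stop(ligstab_error(msg, "ligstab_correspondence_error", ...))
stop_classification <- function(msg, ...) stop(ligstab_error(msg, "ligstab_classification_error", ...))
stop_comparability <- function(msg, ...) stop(ligstab_error(msg, "ligstab_comparability_error", ...))
stop_correlation <- function(msg, ...) stop(ligstab_error(msg, "ligstab_correlation_error", ...))
stop_schema <- function(msg, ...) stop(ligstab_error(msg, "ligstab_schema_error", ...))
stop_generation <- function(msg, ...) stop(ligstab_error(msg, "ligstab_generation_error", ...))

# Exit codes used by the command-line interface.
exit_code_for <- function(cond) {
  if (inherits(cond, "ligstab_io_error")) return(2L)
  if (inherits(cond, "ligstab_selection_error")) return(3L)
  if (inherits(cond, "ligstab_no_contacts_error")) return(4L)
  if (inherits(cond, "ligstab_schema_error")) return(5L)
  1L
}
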