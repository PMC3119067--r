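# Classed error conditions. Every error the package raises carries the class
# "cytopop_error" plus one specific subclass, so callers (and the CLI) can
# distinguish failure modes without parsing messages.

cyto_abort <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cytopop_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
cyto_value_error <- function(message) cyto_abort("cytopop_value_error", message)
cyto_key_error <- function(message) cyto_abort("cytopop_key_error", message)

# fcs_io
cyto_version_error <- function(message) cyto_abort("cytopop_version_error", message)
cyto_mode_error <- function(message) cyto_abort("cytopop_unsupported_mode_error", message)
cyto_corrupt_error <- function(message) cyto_abort("cytopop_corrupt_file_error", message)
cyto_malformed_text_error <- function(message) cyto_abort("cytopop_malformed_text_error", message)
cyto_parse_error <- function(message) cyto_abort("cytopop_parse_error", message)
cyto_io_error <- function(message) cyto_abort("cytopop_io_error", message)

# datamodel / transforms / clustering
cyto_name_clash_error <- function(message) cyto_abort("cytopop_name_clash_error", message)
cyto_convergence_error <- function(message) cyto_abort("cytopop_convergence_error", message)

# session
cyto_bundle_error <- function(message) cyto_abort("cytopop_bundle_error", message)
cyto_corrupt_bundle_error <- function(message) cyto_abort("cytopop_corrupt_bundle_error", message)

# synthdata / plotting
cyto_generation_error <- function(message) cyto_abort("cytopop_generation_error", message)
cyto_applicability_error <- function(message) cyto_abort("cytopop_applicability_error", message)
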