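# Structured conditions so callers (and the CLI) can map failures to exit
# codes without parsing messages.

nsafde_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nsafde_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
format_error <- function(message) nsafde_error(message, "nsafde_format_error")

#' @noRd
design_error <- function(message) nsafde_error(message, "nsafde_design_error")

#' @noRd
config_error <- function(message) nsafde_error(message, "nsafde_config_error")

#' @noRd
contract_error <- function(message) nsafde_error(message, "nsafde_contract_error")

#' @noRd
io_error <- function(message) nsafde_error(message, "nsafde_io_error")
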