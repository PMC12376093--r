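## Structured error conditions.
##
## Every user-facing failure is signalled as a classed condition so callers
## (and the command-line wrapper) can map failures to exit codes without
## string-matching messages. Classes:
##   tds_usage_error       bad flags / missing arguments        (exit 2)
##   tds_parse_error       malformed input file                 (exit 3)
##   tds_size_error        too few points / empty input         (exit 3)
##   tds_range_error       out-of-range axis request            (exit 3)
##   tds_domain_error      value outside mathematical domain    (exit 3)
##   tds_parameter_error   invalid algorithm parameter          (exit 2)
##   tds_consistency_error mismatched replicate metadata        (exit 3)
##   tds_data_error        data-quality failure                 (exit 3)
##   tds_masked_error      readout at a masked point            (exit 3)
##   tds_io_error          unreadable/unwritable path           (exit 3)
##   tds_degeneracy_error  singular / degenerate numerics       (exit 4)

tdsStop <- function(class, message, call. = FALSE) {
  stop(structure(
    class = c(class, "tds_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

tdsWarn <- function(class, message) {
  warning(structure(
    class = c(class, "tds_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

## exit-code contract for the command-line wrapper
tdsExitCode <- function(cond) {
  cls <- class(cond)
  if (any(c("tds_usage_error", "tds_parameter_error") %in% cls)) return(2L)
  if ("tds_degeneracy_error" %in% cls) return(4L)
  3L
}
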