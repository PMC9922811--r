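#' @keywords internal
#' Signal a classed error so callers (and the CLI) can distinguish
#' input-format problems, unassessable cases, and numerical failures.
tsr_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tsr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# condition classes used throughout:
#   tsr_format_error      - malformed config/CSV/geometry file
#   tsr_validation_error  - values inconsistent with the tissue scheme
#   tsr_empty_roi_error   - ROI does not intersect the grid
#   tsr_unassessable_error- case cannot be scored (zero denominator,
#                           tumor area too narrow for the field of view)
#   tsr_empty_bulk_error  - no tumor-gland pixels at all (subclass of
#                           unassessable)
#   tsr_numerical_error   - FFT counts deviated from integers
#   tsr_input_error       - bad argument to a statistics routine
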