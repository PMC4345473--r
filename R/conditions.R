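# Classed error conditions used across the package.
#
# Classes:
#   gsn_invalid_error    - bad argument values (empty statement, scale <= 0, ...)
#   gsn_not_found_error  - a uid, label or file that does not exist
#   gsn_typing_error     - an illegal (parent kind, child kind) pairing
#   gsn_format_error     - unreadable or non-conforming file content
#   gsn_validation_error - an operation that requires a well-formed graph was
#                          handed a graph with validation errors

gsn_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gsn_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_invalid <- function(message) gsn_abort(message, "gsn_invalid_error")
abort_not_found <- function(message) gsn_abort(message, "gsn_not_found_error")
abort_typing <- function(message) gsn_abort(message, "gsn_typing_error")
abort_format <- function(message) gsn_abort(message, "gsn_format_error")

abort_validation <- function(issues) {
  errs <- issues[issues$severity == "error", , drop = FALSE]
  msg <- paste0(
    "graph is not well-formed (", nrow(errs), " error",
    if (nrow(errs) == 1) "" else "s", "): ",
    paste(unique(errs$code), collapse = ", ")
  )
  cond <- structure(
    class = c("gsn_validation_error", "gsn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), issues = issues)
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
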