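#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse sample labels of the form "t0_r1" into condition and replicate
#'
#' Sample columns of probe tables encode condition x replicate as
#' \code{t<min>_r<idx>}. Used by readers and the summarizer.
#'
#' @param labels character vector of sample labels
#' @return data.table with columns sample_label, condition, replicate
#' @noRd
parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^t([0-9]+)_r([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed sample label(s): ", paste(labels[bad], collapse = ", "),
         " (expected 't<minutes>_r<replicate>', e.g. 't0_r1')")
  }
  data.table(
    sample_label = labels,
    condition = paste0("t", vapply(m, `[`, "", 2L)),
    replicate = as.integer(vapply(m, `[`, "", 3L))
  )
}

#' @noRd
assert_file_exists <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  invisible(path)
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
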