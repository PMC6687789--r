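# internal helpers shared across modules

# error with a stable class so callers/tests can distinguish bad input
# (validation) from unreadable files (format)
stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "vmshapes_validation_error")
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "vmshapes_format_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# coerce dist / matrix / data.frame to a validated symmetric distance matrix
as_distance_object <- function(d) {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) {
    stop_validation("distance matrix must be square, got %d x %d", nrow(m), ncol(m))
  }
  if (any(is.na(m))) stop_validation("distance matrix contains missing values")
  if (any(m < 0)) stop_validation("distance matrix has negative entries")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop_validation("distance matrix is not symmetric")
  }
  stats::as.dist(m)
}

# labels of a dist object, synthesising indices when absent
dist_ids <- function(d) {
  lab <- attr(d, "Labels")
  if (is.null(lab)) as.character(seq_len(attr(d, "Size"))) else as.character(lab)
}
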