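# Condition helpers: validation errors exit 1 from the CLI, I/O errors exit 2.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("snpcore_validation_error", "snpcore_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("snpcore_io_error", "snpcore_error")))
}

# Distinct-count and Shannon index of a vector of group keys.
group_stats <- function(key) {
  f <- tabulate(match(key, unique(key)))
  p <- f / length(key)
  list(k = length(f), H = -sum(p * log(p)))
}

n_distinct_key <- function(key) length(unique(key))

# Upper-triangle pair index table for n samples (a < b), column-major order.
pair_index <- function(n) {
  a <- sequence(seq_len(n - 1L))
  b <- rep.int(2:n, 1:(n - 1L))
  cbind(a = a, b = b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
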