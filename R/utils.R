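# shared small helpers

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going away from zero (so 31.25 -> 31.3
#' at one decimal), as used for reported percentages. Base `round()` rounds
#' ties to even, which does not match how percentages are conventionally
#' printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic per-subject seed derived from a cohort seed; stays within
# the 32-bit integer range R's RNG accepts
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) * 69069 + 1000003 * as.numeric(index)) %% 2147483647
  as.integer(s) + 1L
}

# stop() with a collected list of validation messages
stop_if_violations <- function(violations) {
  if (length(violations) > 0) {
    stop(paste0("invalid configuration:\n", paste0("  - ", violations, collapse = "\n")),
         call. = FALSE)
  }
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

write_tsv_matrix <- function(mat, path) {
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(mat)))
  invisible(path)
}

read_tsv_matrix <- function(path, header = TRUE) {
  as.matrix(utils::read.delim(path, header = header, check.names = FALSE))
}
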