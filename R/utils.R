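#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Locale-independent (byte-order) sort, so outputs are identical across
# platforms and collation settings.
sort_c <- function(x) x[order(x, method = "radix")]

order_c <- function(...) order(..., method = "radix")

# Most frequent value; ties broken by the lexicographically smallest value.
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  sort_c(winners)[1L]
}

# Canonical single-string key for a (ncRNA, disease) pair.
pair_key <- function(ncrna, disease) paste(ncrna, disease, sep = "\r")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_prob <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  name, deparse(x)))
  }
  invisible(x)
}
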