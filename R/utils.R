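#' @keywords internal
"_PACKAGE"

# Round half away from zero (so 29.5 -> 30), the convention used for the
# printed percentage tables; base round() would go to even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Timestamped, leveled logging to stderr.
tb_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...)))
}

tb_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

# Jaccard index of two sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}
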