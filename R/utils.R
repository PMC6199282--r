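# Deterministic seed derivation. All arithmetic stays below 2^53 so the
# results are exact in doubles, and outputs lie in [1, 2^31 - 2].

child_seeds <- function(master, n) {
  m <- as.double(master) %% 2147483647
  vapply(seq_len(n),
         function(i) as.integer((m * 48271 + i * 9973) %% 2147483647),
         integer(1))
}

# Order-sensitive hash of the master seed plus arbitrary labels/values
# (axis names, parameter values, experiment names). Multiplier kept small
# (< 2^21) so h * mult + byte < 2^53 exactly.
mix_seed <- function(master, ...) {
  parts <- vapply(list(...), function(x) {
    if (is.numeric(x)) format(x, digits = 15, trim = TRUE) else as.character(x)
  }, character(1))
  key <- paste(c(format(as.integer(master)), parts), collapse = "|")
  h <- 216613626
  for (b in utf8ToInt(key)) {
    h <- (h * 1000003 + b) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

fmt6 <- function(x) {
  # fixed 6-significant-digit text form used in all CSV output
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}
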