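# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed derivation: one user seed fans out to
# per-stage / per-sample substreams so stages are individually rerunnable.
# Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(base, ...) {
  ix <- c(...)
  s <- as.double(base) %% 2147483629
  for (k in seq_along(ix)) {
    s <- (s * 48271 + as.double(ix[k]) * 9973 + k) %% 2147483629
  }
  as.integer(s)
}

require_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# dosage coding of genotype calls: count of parent-1 alleles
call_dosage <- c(HOM_P2 = 0, HET = 1, HOM_P1 = 2)

# expected parent-1 read fraction under each call, used for junction refinement
call_expected_ratio <- c(HOM_P2 = 0, HET = 0.5, HOM_P1 = 1)
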