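# shared internal helpers

# canonical abundance measure column names
MEASURE_COLS <- c("arrays", "spacers", "cas_genes", "cas_clusters", "rm_genes")

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-away-from-zero rounding; base round() is round-half-even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_ct <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ct <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# fixed-precision TSV writer: 6 significant digits, stable column order,
# so repeated runs are byte-identical
write_tsv_fixed <- function(df, path, digits = 6) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# derive a reproducible child seed (< 2^31) from a base seed and a tag;
# double arithmetic is exact here and avoids integer overflow
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9973) %% 2147483587)
}
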