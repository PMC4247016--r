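# Internal helpers shared across modules.

# Modal value of an integer/numeric vector; ties broken toward the
# smallest value so that downstream calls are deterministic.
modal_value <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes first tie = smallest
}

# 5' end position of stranded reads (start on +, end on -).
five_prime_pos <- function(gr) {
  ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
}

# Normalize a nucleotide string vector to uppercase RNA (T -> U).
as_rna <- function(x) {
  chartr("acgtuT", "ACGUUU", toupper(x))
}

# Normalize to uppercase DNA (U -> T).
as_dna <- function(x) {
  chartr("acgut", "ACGTT", chartr("U", "T", toupper(x)))
}

# Shannon entropy (bits per nt) of a nucleotide string.
seq_entropy <- function(seq) {
  chars <- strsplit(as_dna(seq), "")[[1]]
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# Maximum frequency of any single dinucleotide (overlapping) in a string.
max_dinuc_fraction <- function(seq) {
  s <- as_dna(seq)
  n <- nchar(s)
  if (n < 2L) return(1)
  di <- substring(s, 1:(n - 1L), 2:n)
  max(table(di)) / length(di)
}

stop_ctx <- function(...) stop(sprintf(...), call. = FALSE)
warn_ctx <- function(...) warning(sprintf(...), call. = FALSE)
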