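DNA_BASES <- c("A", "C", "G", "T")

# sample n bases from a composition vector named A/C/G/T, return one string
random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs[DNA_BASES]),
        collapse = "")
}

# split a string into a character vector of single bases
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

paste0_chars <- function(v) paste(v, collapse = "")

# substring by 0-based half-open [start, end)
substr0 <- function(s, start, end) substring(s, start + 1L, end)

`substr0<-` <- function(s, start, end, value) {
  substring(s, start + 1L, end) <- value
  s
}

# overlap length of two 0-based half-open intervals
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing columns: ", paste(miss, collapse = ", "))
  }
}
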