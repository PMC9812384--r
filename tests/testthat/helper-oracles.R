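# Independent brute-force oracle for natural-abundance correction matrices:
# enumerates every isotope placement over the atoms of a small formula
# (feasible for <= 6 atoms) instead of convolving per-element distributions.
brute_na_column <- function(counts, tracer, j, max_shift,
                            ab = isotope_abundances()) {
  atoms <- rep(names(counts), counts)
  stopifnot(sum(atoms == tracer) >= j)
  labeled <- which(atoms == tracer)[seq_len(j)]
  natural <- if (j > 0) atoms[-labeled] else atoms
  out <- numeric(max_shift + 1L)
  if (length(natural) == 0L) {
    if (j <= max_shift) out[j + 1L] <- 1
    return(out)
  }
  states <- expand.grid(lapply(natural, function(e) seq_along(ab[[e]]) - 1L))
  prob <- rep(1, nrow(states))
  for (k in seq_along(natural)) {
    prob <- prob * ab[[natural[k]]][states[[k]] + 1L]
  }
  shift <- rowSums(states) + j
  for (s in 0:max_shift) out[s + 1L] <- sum(prob[shift == s])
  out
}

brute_na_matrix <- function(counts, tracer, n_tracer, max_shift) {
  vapply(0:max_shift, function(j) {
    if (j <= counts[[tracer]]) brute_na_column(counts, tracer, j, max_shift)
    else numeric(max_shift + 1L)
  }, numeric(max_shift + 1L))
}

# small well-formed peak table written to a temp CSV
write_demo_peak_csv <- function(path, n_samples = 2L) {
  rows <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    data.frame(sample_id = sprintf("s%d", i), arm_label = "wt",
               compartment = "tissue", metabolite = "lactate",
               isotopolog_index = 0:3,
               area = c(1000, 120, 40, 5) * i)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
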