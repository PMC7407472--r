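# Fixtures built in code; nothing here touches the filesystem except via
# withr-free tempfile() usage inside individual tests.

# Noiseless two-phase OD trace sampled every `by` minutes.
make_exp_curve <- function(rate = 0.85, od0 = 0.01, hours = 10, by = 10) {
  times <- seq(0, hours * 60, by = by)
  list(times = times, od = od0 * exp(rate * times / 60))
}

# Plain-R Monte-Carlo scan oracle, independent of the compiled path:
# brute-force sort of every replicate.
r_scan_oracle <- function(G, N, w, k, reps) {
  succ <- 0L
  for (i in seq_len(reps)) {
    pos <- sort(sample.int(G, N, replace = TRUE))
    if (any(pos[k:N] - pos[seq_len(N - k + 1)] <= w - 1)) succ <- succ + 1L
  }
  succ / reps
}

# Small mutation-record data.frame helper.
mut_rec <- function(well, pos, mtype = "SNP", allele = "A>G", freq = 1,
                    day = 1, condition = "High", size = 1L) {
  data.frame(well = well, day = day, condition = condition, mtype = mtype,
             position = pos, size = size, allele = allele, frequency = freq,
             stringsAsFactors = FALSE)
}

sorted_keys <- function(table)
  sort(paste(table$well, table$day, table$mtype, table$position, table$allele))
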