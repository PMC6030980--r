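# Deterministic in-memory spectra used across the I/O tests.
make_test_spectra <- function(n = 3, seed = 101) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    m <- sort(round(runif(10 + k, 100, 1500), 6))
    spectrum(m, round(runif(length(m), 1, 500), 4),
             source = list(scan = as.character(k), index = k,
                           title = paste0("scan_title_", k)),
             precursor = list(mz = round(runif(1, 300, 900), 6),
                              charge = sample(2:4, 1)))
  })
}
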