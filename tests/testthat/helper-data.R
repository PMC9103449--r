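# Small fixtures built in code; every table follows the package schema
# (omega, eps_h, eps_nh, ts, provenance).

toy_table <- function(n = 6, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    omega = runif(n, 0, 30),
    eps_h = runif(n, 0.38, 5),
    eps_nh = runif(n, 0, 1),
    ts = runif(n, 5, 40),
    provenance = rep("original", n)
  ))
}

# deterministic 86-row benchmark draw used across tests
benchmark_table <- function(seed = 101, keep_blob = FALSE) {
  generate_dataset(seed = seed, keep_blob = keep_blob)
}

# adjusted Rand index between two labelings; independent of mclust for the
# cheap cases, but mclust::adjustedRandIndex is used as the oracle where the
# value matters
simple_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

write_csv_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
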