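# shared fixtures, built once per test run

table1 <- function() read_measurements(toadcall_example("table1_lushanensis.tsv"))

holotype_record <- function() {
  tab <- table1()
  tab[tab$specimen_id == "JXNU 21042803", ]
}

claims_fixture <- function() read_claims(toadcall_example("claims_lushanensis.json"))

trait_fixture <- function() {
  load_trait_matrix(toadcall_example("table2_boulenophrys.tsv"),
                    aliases = claims_fixture()$aliases)
}

# a small, fast holotype-like clip: 3 calls is enough for most detector tests
quick_call_spec <- function(seed = 42, ...) {
  call_sim_spec(n_calls = 3, snr_db = 30, lead_silence_ms = 100, seed = seed,
                ...)
}

# per-site brute-force p-distance oracle, deliberately scalar and loop-based
p_distance_oracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  ncomp <- 0L; ndiff <- 0L
  for (i in seq_along(va)) {
    if (va[i] %in% acgt && vb[i] %in% acgt) {
      ncomp <- ncomp + 1L
      if (va[i] != vb[i]) ndiff <- ndiff + 1L
    }
  }
  if (ncomp == 0) NA_real_ else ndiff / ncomp
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T", "N", "-")) {
  paste(sample(alphabet, n, replace = TRUE,
               prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = "")
}
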