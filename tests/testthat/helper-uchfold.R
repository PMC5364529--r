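# shared fixtures, all generated in code

# N-terminal stretch of a UCH-like catalytic domain, used wherever a real
# amino-acid sequence is needed
uch_test_sequence <- function() {
  "MTGNAGEWCLMESDPGVFTELIKGFGCRGAQVEEIWSLEPENFEKLKPVHGLIFLFKW"
}

# deterministic toy protein: n_res residues on a loose 3D random walk with
# 3 heavy atoms each; seed-fixed so contact lists are reproducible
toy_structure <- function(n_res = 20, seed = 42, step = 3.8) {
  set.seed(seed)
  ca <- apply(matrix(rnorm(3 * n_res), ncol = 3), 2L, cumsum) * step / sqrt(3)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    offs <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), ncol = 3, byrow = TRUE)
    data.frame(resno = i,
               x = ca[i, 1] + offs[, 1],
               y = ca[i, 2] + offs[, 2],
               z = ca[i, 3] + offs[, 3])
  }))
  atoms
}

# brute-force O(n^2) contact-order oracle, straight from the definition
rco_brute_force <- function(atoms, cutoff = 6, min_separation = 2) {
  idx <- match(atoms$resno, unique(atoms$resno))
  n <- nrow(atoms)
  seps <- c()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (abs(idx[b] - idx[a]) < min_separation) next
      d <- sqrt(sum((atoms[a, c("x", "y", "z")] - atoms[b, c("x", "y", "z")])^2))
      if (d <= cutoff) seps <- c(seps, abs(idx[b] - idx[a]))
    }
  }
  list(rco = sum(seps) / (length(unique(atoms$resno)) * length(seps)),
       n_contacts = length(seps))
}

# independent reading of the bundled exchange-rate table plus a literal
# transcription of the additive log-factor model, used as the k_int oracle
kint_oracle <- function(sequence, i, pd, temperature) {
  path <- system.file("extdata", "hdx_reference_rates.csv", package = "uchfold")
  tab <- read.csv(path, comment.char = "#")
  g <- function(res, col) tab[tab$residue == res, col]
  s <- strsplit(sequence, "")[[1]]
  al <- g(s[i], "acid_l") + g(s[i - 1], "acid_r")
  bl <- g(s[i], "base_l") + g(s[i - 1], "base_r")
  if (i == 2) { al <- al + g("NT", "acid_r"); bl <- bl + g("NT", "base_r") }
  if (i == length(s)) { al <- al + g("CT", "acid_l"); bl <- bl + g("CT", "base_l") }
  arr <- function(ea) exp(-(ea / 1.9872e-3) * (1 / temperature - 1 / 293))
  (10^(1.62 + al) * 10^(-pd) * arr(14) +
      10^(10.05 + bl) * 10^(pd - 15.05) * arr(17) +
      10^(-1.5 + bl) * arr(19)) / 60
}
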