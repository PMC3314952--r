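# brute-force double-loop oracle for the intrinsic R2 sum, kept deliberately
# naive and independent of the vectorised implementation
brute_force_r2 <- function(seq, scale = 1, properties = residue_properties()) {
  rg <- setNames(properties$rg_A, properties$residue)
  lam <- setNames(properties$lambda, properties$residue)
  n <- nrow(seq)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      rj <- seq$residue[j]
      acc <- acc + rg[[rj]]^3 * exp(-abs(i - j) / lam[[rj]])
    }
    out[i] <- scale * acc
  }
  out
}

random_sequence <- function(n) {
  protein_sequence(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                          n, replace = TRUE))
}

write_fasta <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}
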