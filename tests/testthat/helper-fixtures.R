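# Shared fixture builders; everything is generated in code.

make_aln <- function(...) {
  seqs <- c(...)
  mutsmith::new_alignment(names(seqs), unname(seqs))
}

random_alignment <- function(n_seq, n_col, seed, gap_prob = 0.05) {
  set.seed(seed)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n_seq), function(i) {
    paste(sample(c(letters20, "-"), n_col, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 20, 20), gap_prob)),
          collapse = "")
  }, character(1))
  mutsmith::new_alignment(sprintf("seq%03d", seq_len(n_seq)), seqs)
}

point_structure <- function(xyz, charge = 0, radius = 1.7, element = "C") {
  n <- nrow(xyz)
  s <- mutsmith::new_structure(tibble::tibble(
    chain = "A", resno = seq_len(n), resid = "ION", elety = "Q",
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
  s$charge <- rep_len(charge, n)
  s$radius <- rep_len(radius, n)
  s
}

structure_coord_key <- function(x) {
  # order-independent fingerprint of atom identities and coordinates
  df <- x[order(x$chain, x$resno, x$elety), c("chain", "resno", "resid", "elety", "x", "y", "z")]
  df
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
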