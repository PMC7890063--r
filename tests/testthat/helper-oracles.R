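# Independent oracles used to cross-check the package implementation.
# These are deliberately naive (loops, brute force) and share no code with R/.

# Gotoh affine-gap global alignment score: a gap of length L costs
# open + L * ext (open, ext given as positive costs).
oracle_align_score <- function(a, b, mat, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force pocket: residue in pocket iff any heavy-atom pair within cutoff.
oracle_pocket <- function(model, ligands, cutoff) {
  poly <- model$atoms[!(model$atoms$element %in% c("H", "D")), ]
  lig <- ligands$atoms
  res <- unique(poly[, c("chain", "resno", "insert")])
  hit <- logical(nrow(res))
  for (r in seq_len(nrow(res))) {
    ratoms <- poly[poly$chain == res$chain[r] & poly$resno == res$resno[r] &
                     poly$insert == res$insert[r], ]
    found <- FALSE
    for (i in seq_len(nrow(ratoms))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((ratoms$x[i] - lig$x[j])^2 + (ratoms$y[i] - lig$y[j])^2 +
                    (ratoms$z[i] - lig$z[j])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    hit[r] <- found
  }
  res[hit, , drop = FALSE]
}

# Naive sliding-window motif scanner (character-by-character, no regex).
oracle_motifs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- list()
  for (i in seq_len(max(0, n - 4))) {
    w <- ch[i:(i + 4)]
    if (w[1] == "D" && w[2] %in% c("D", "E") && w[5] == "D")
      hits[[length(hits) + 1]] <- data.frame(motif = "aspartate_rich",
                                             start = i)
  }
  for (i in seq_len(max(0, n - 8))) {
    w <- ch[i:(i + 8)]
    if (w[1] %in% c("N", "D") && w[2] == "D" && w[5] %in% c("S", "T") &&
        w[9] == "E")
      hits[[length(hits) + 1]] <- data.frame(motif = "nse_triad", start = i)
  }
  if (!length(hits)) return(data.frame(motif = character(0),
                                       start = integer(0)))
  do.call(rbind, hits)
}

random_seq <- function(n, alphabet = pocketprofile:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a tiny hand-written PDB: residues ALA, GLY, VAL + one 2-atom ligand
toy_pdb_text <- function() {
  paste(c(
    "HEADER    toy",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       5.200   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  VAL A   3       9.000   0.000   0.000  1.00  0.00           C",
    "HETATM    5  P1  LIG A 900       1.400   4.000   0.000  1.00  0.00           P",
    "HETATM    6  O1  LIG A 900       1.400   5.500   0.000  1.00  0.00           O",
    "TER",
    "END"), collapse = "\n")
}

mm_rates <- function(S, Km, vmax) vmax * S / (Km + S)
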