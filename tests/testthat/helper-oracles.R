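# Independent oracles used across the suite. These deliberately avoid the
# package's alignment/ORF code paths: a textbook Gotoh dynamic program, a
# full recursive enumeration of local alignment paths (tiny inputs only),
# and a positional six-frame ORF scan.

.oracle_env <- new.env()

blosum62_matrix <- function() {
  if (is.null(.oracle_env$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .oracle_env$B62 <- e$BLOSUM62
  }
  .oracle_env$B62
}

# best local alignment score, affine gaps costing open + k * ext
gotoh_local_score <- function(a, b, subst, open, ext) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, m + 1, n + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + subst[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# exhaustive enumeration of every local alignment path (exponential; keep
# sequences at <= 5 residues)
enum_local_score <- function(a, b, subst, open, ext) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  best <- 0
  go <- function(i, j, acc, state) {
    best <<- max(best, acc)
    if (i < m && j < n) {
      go(i + 1, j + 1, acc + subst[a[i + 1], b[j + 1]], "M")
    }
    if (j < n) go(i, j + 1, acc - if (state == "A") ext else open + ext, "A")
    if (i < m) go(i + 1, j, acc - if (state == "B") ext else open + ext, "B")
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      go(i, j, subst[a[i], b[j]], "M")
    }
  }
  best
}

dna_subst_matrix <- function(match = 1, mismatch = -2) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

# positional six-frame scan for the longest ATG-initiated ORF; stops at a
# stop codon or the end of the frame
brute_orf_peptides <- function(dna, min_aa) {
  gc <- Biostrings::GENETIC_CODE
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  translate1 <- function(codon) {
    if (grepl("N", codon)) "X" else unname(gc[codon])
  }
  peps <- character()
  for (s in c(dna, revcomp(dna))) {
    chars <- strsplit(s, "")[[1]]
    for (f in 1:3) {
      starts <- seq(f, length(chars) - 2, by = 3)
      codons <- vapply(starts, function(p) {
        paste(chars[p:(p + 2)], collapse = "")
      }, character(1))
      aas <- vapply(codons, translate1, character(1))
      i <- 1
      while (i <= length(aas)) {
        if (aas[i] == "M") {
          j <- i
          while (j <= length(aas) && aas[j] != "*") j <- j + 1
          peps <- c(peps, paste(aas[i:(j - 1)], collapse = ""))
          i <- j  # next ATG-initiated ORF starts after this stretch
        }
        i <- i + 1
      }
    }
  }
  peps <- peps[nchar(peps) >= min_aa]
  peps
}

# direct Monte-Carlo estimate of the probability that an expression vector
# with tissue means uniform on [0.1, 200] and multiplicative log-normal
# noise passes the default matching criteria against a model
mc_decoy_pass_rate <- function(model, sigma, n_draws, criteria) {
  passes <- vapply(seq_len(n_draws), function(i) {
    mu <- stats::runif(length(model), 0.1, 200)
    v <- mu * exp(stats::rnorm(length(model), 0, sigma))
    model_match(v, bait_model("mc", model), criteria)$passed
  }, logical(1))
  mean(passes)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}
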