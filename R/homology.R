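# Local-alignment homology search with Karlin-Altschul statistics,
# cytochrome P450 motif scanning and longest-ORF peptide prediction.
# Stands in for the BLASTP/BLASTN and ESTScan stages of the screen.

#' Default alignment parameters per alphabet
#'
#' Protein: BLOSUM62, affine gap open 11 / extend 1, Karlin-Altschul
#' K = 0.041, lambda = 0.267 (gapped BLOSUM62 values). DNA: match +1 /
#' mismatch -2, gap open 5 / extend 2, K = 0.46, lambda = 1.28.
#'
#' @param alphabet `"protein"` or `"dna"`.
#' @return list with `gap_open`, `gap_extend`, `K`, `lambda` and either
#'   `matrix` (protein) or `match`/`mismatch` (dna).
#' @export
alignment_params <- function(alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "protein") {
    list(alphabet = "protein", matrix = "BLOSUM62",
         gap_open = 11, gap_extend = 1, K = 0.041, lambda = 0.267)
  } else {
    list(alphabet = "dna", match = 1, mismatch = -2,
         gap_open = 5, gap_extend = 2, K = 0.46, lambda = 1.28)
  }
}

.subst_matrix <- function(params) {
  if (params$alphabet == "protein") {
    if (identical(params$matrix, "BLOSUM62")) .blosum62() else params$matrix
  } else {
    Biostrings::nucleotideSubstitutionMatrix(
      match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  }
}

.as_single_seq <- function(x, alphabet) {
  if (inherits(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  if (inherits(x, "XString")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(if (alphabet == "dna") Biostrings::DNAString(x)
           else Biostrings::AAString(x))
  }
  stop("expected a single sequence", call. = FALSE)
}

.seq_alphabet <- function(x) {
  if (inherits(x, c("DNAString", "DNAStringSet"))) return("dna")
  if (inherits(x, c("AAString", "AAStringSet"))) return("protein")
  guess_alphabet(as.character(x))
}

#' Karlin-Altschul E-value
#'
#' E = K * m * n * exp(-lambda * S) for a local alignment of raw score S
#' between sequences of lengths m and n. For stringent cutoffs the E-value
#' can underflow double precision; use [log10_evalue_of()] for comparisons.
#'
#' @param raw_score raw alignment score (>= 0).
#' @param m,n sequence lengths (>= 1).
#' @param K,lambda Karlin-Altschul parameters (> 0).
#' @return expectation value (may underflow to 0 for very large scores).
#' @export
evalue_of <- function(raw_score, m, n, K, lambda) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive",
                                  call. = FALSE)
  if (m < 1 || n < 1) stop("m and n must be >= 1", call. = FALSE)
  K * m * n * exp(-lambda * raw_score)
}

#' @rdname evalue_of
#' @export
log10_evalue_of <- function(raw_score, m, n, K, lambda) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive",
                                  call. = FALSE)
  if (m < 1 || n < 1) stop("m and n must be >= 1", call. = FALSE)
  (log(K) + log(m) + log(n) - lambda * raw_score) / log(10)
}

.bit_score <- function(raw_score, K, lambda) {
  (lambda * raw_score - log(K)) / log(2)
}

.empty_hit <- function(query_id, subject_id, m, n, params) {
  list(query_id = query_id, subject_id = subject_id, raw_score = 0,
       bit_score = .bit_score(0, params$K, params$lambda),
       evalue = evalue_of(0, m, n, params$K, params$lambda),
       log10_evalue = log10_evalue_of(0, m, n, params$K, params$lambda),
       query_span = c(0L, 0L), subject_span = c(0L, 0L))
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment under affine gap penalties (computed via
#' `Biostrings::pairwiseAlignment`), scored with BLOSUM62 for proteins or
#' +1/-2 for DNA by default, and annotated with the Karlin-Altschul bit
#' score and E-value. If no residue pair scores positively the hit has raw
#' score 0 and empty spans.
#'
#' @param a,b sequences (`XString`, length-1 `XStringSet`, or character);
#'   both must share one alphabet.
#' @param params alignment parameter list from [alignment_params()];
#'   defaults follow the alphabet of `a`.
#' @param query_id,subject_id labels used in the returned hit.
#' @return object of class `alignment_hit`: list with `query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `evalue`, `log10_evalue`,
#'   and 0-based half-open `query_span`/`subject_span`.
#' @export
#' @examples
#' local_align("ACDEFG", "ACDEFG")$raw_score  # 36 under BLOSUM62
local_align <- function(a, b, params = NULL,
                        query_id = "query", subject_id = "subject") {
  alpha_a <- .seq_alphabet(a)
  alpha_b <- .seq_alphabet(b)
  if (!identical(alpha_a, alpha_b)) {
    stop("alphabet mismatch between query (", alpha_a, ") and subject (",
         alpha_b, ")", call. = FALSE)
  }
  if (is.null(params)) params <- alignment_params(alpha_a)
  sa <- .as_single_seq(a, alpha_a)
  sb <- .as_single_seq(b, alpha_b)
  if (length(sa) == 0 || length(sb) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "local", substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  s <- Biostrings::score(pa)
  m <- length(sa); n <- length(sb)
  if (s <= 0) {
    hit <- .empty_hit(query_id, subject_id, m, n, params)
  } else {
    qr <- Biostrings::pattern(pa)
    sr <- Biostrings::subject(pa)
    hit <- list(
      query_id = query_id, subject_id = subject_id, raw_score = s,
      bit_score = .bit_score(s, params$K, params$lambda),
      evalue = evalue_of(s, m, n, params$K, params$lambda),
      log10_evalue = log10_evalue_of(s, m, n, params$K, params$lambda),
      query_span = c(BiocGenerics::start(qr) - 1L, BiocGenerics::end(qr)),
      subject_span = c(BiocGenerics::start(sr) - 1L, BiocGenerics::end(sr)))
  }
  class(hit) <- "alignment_hit"
  hit
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf(
    "alignment_hit %s vs %s: score %.0f, bits %.1f, E %.3g, q[%d,%d) s[%d,%d)\n",
    x$query_id, x$subject_id, x$raw_score, x$bit_score, x$evalue,
    x$query_span[1], x$query_span[2], x$subject_span[1], x$subject_span[2]))
  invisible(x)
}

.score_matrix <- function(queries, subjects, params) {
  # raw SW scores, queries in rows; vectorize over the larger side
  nq <- length(queries); ns <- length(subjects)
  sm <- .subst_matrix(params)
  scores <- matrix(0, nrow = nq, ncol = ns)
  if (nq >= ns) {
    for (j in seq_len(ns)) {
      scores[, j] <- Biostrings::pairwiseAlignment(
        queries, subjects[[j]], type = "local", substitutionMatrix = sm,
        gapOpening = params$gap_open, gapExtension = params$gap_extend,
        scoreOnly = TRUE)
    }
  } else {
    # SW score is symmetric for symmetric scoring schemes
    for (i in seq_len(nq)) {
      scores[i, ] <- Biostrings::pairwiseAlignment(
        subjects, queries[[i]], type = "local", substitutionMatrix = sm,
        gapOpening = params$gap_open, gapExtension = params$gap_extend,
        scoreOnly = TRUE)
    }
  }
  pmax(scores, 0)
}

#' Best homolog per query under an E-value cutoff
#'
#' All-vs-all local alignment of `queries` against `subjects`; for every
#' query the minimum-E subject passing the cutoff is reported. Ties are
#' broken by higher raw score, then lexicographically smaller subject id,
#' so results do not depend on subject order.
#'
#' @param queries,subjects `XStringSet`s of a common alphabet.
#' @param e_cutoff maximum E-value (default 1e-4, the protein screening
#'   cutoff).
#' @param params see [alignment_params()].
#' @return data.frame with one row per query that has a passing hit:
#'   `query_id`, `subject_id`, `raw_score`, `bit_score`, `evalue`,
#'   `log10_evalue`.
#' @export
find_homologs <- function(queries, subjects, e_cutoff = 1e-4,
                          params = NULL) {
  if (length(subjects) == 0 || length(queries) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), log10_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  alpha <- .seq_alphabet(queries)
  if (!identical(alpha, .seq_alphabet(subjects))) {
    stop("alphabet mismatch between queries and subjects", call. = FALSE)
  }
  if (is.null(params)) params <- alignment_params(alpha)
  qids <- seq_ids(queries); sids <- seq_ids(subjects)
  scores <- .score_matrix(queries, subjects, params)
  m <- Biostrings::width(queries); n <- Biostrings::width(subjects)
  log_e <- (log(params$K) + outer(log(m), log(n), `+`) -
              params$lambda * scores) / log(10)
  cutoff_log <- log10(e_cutoff)
  rows <- lapply(seq_along(qids), function(i) {
    ok <- which(log_e[i, ] <= cutoff_log)
    if (length(ok) == 0) return(NULL)
    # min E, then max raw score, then lexicographic subject id
    ord <- ok[order(log_e[i, ok], -scores[i, ok], sids[ok])]
    j <- ord[1L]
    data.frame(query_id = qids[i], subject_id = sids[j],
               raw_score = scores[i, j],
               bit_score = .bit_score(scores[i, j], params$K, params$lambda),
               evalue = 10^log_e[i, j], log10_evalue = log_e[i, j],
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), log10_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Cytochrome P450 consensus motifs. X is any residue. Positions are
# reported 0-based; the field's 1-based residue numbering (e.g. EXXR near
# 387, heme motif near 464-473) is position + 1.
.P450_MOTIFS <- c(
  EXXR            = "E..R",
  PXRX            = "P.R.",
  heme_FXXGXRXCXG = "F..G.R.C.G",
  oxygen_binding  = "[AG]G.[DE]TT"
)

#' Scan a peptide for cytochrome P450 consensus motifs
#'
#' Finds all non-overlapping matches of the four consensus motifs that
#' mark cytochrome P450 structural integrity and heme placement:
#' EXXR, the PERF-region PXRX, the heme-binding FXXGXRXCXG, and the
#' oxygen binding and activation motif (A/G)GX(D/E)TT.
#'
#' @param peptide a single protein sequence (`AAString`, length-1
#'   `AAStringSet`, or character). Nucleotide input is an error.
#' @return data.frame with columns `motif`, `start` (0-based) and `match`.
#' @export
#' @examples
#' scan_p450_motifs("AAEKLRAA")  # EXXR at 0-based position 2
scan_p450_motifs <- function(peptide) {
  if (identical(.seq_alphabet(peptide), "dna")) {
    stop("scan_p450_motifs expects a protein sequence", call. = FALSE)
  }
  pep <- as.character(.as_single_seq(peptide, "protein"))
  rows <- lapply(names(.P450_MOTIFS), function(nm) {
    m <- gregexpr(.P450_MOTIFS[[nm]], pep)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(motif = nm, start = as.integer(m) - 1L,
               match = substring(pep, m, m + attr(m, "match.length") - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(motif = character(), start = integer(),
                      match = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Classify a peptide as cytochrome P450 by homology
#'
#' A peptide is called a P450 when its best local-alignment hit against a
#' curated reference P450 set has E <= `e_cutoff` (the screening cutoff
#' 1e-4 by default). Consensus-motif hits are reported alongside as
#' advisory annotation; they do not gate the call.
#'
#' @param peptide protein sequence.
#' @param reference_p450s non-empty `AAStringSet` of reference P450s;
#'   default is the packaged synthetic reference set
#'   ([p450_references()]).
#' @param e_cutoff E-value cutoff (default 1e-4).
#' @return list with `is_p450`, `best_reference`, `evalue`,
#'   `log10_evalue`, `motifs` (data.frame from [scan_p450_motifs()]).
#' @export
classify_p450 <- function(peptide, reference_p450s = p450_references(),
                          e_cutoff = 1e-4) {
  if (length(reference_p450s) == 0) {
    stop("empty reference P450 set", call. = FALSE)
  }
  pep <- .as_single_seq(peptide, "protein")
  q <- Biostrings::AAStringSet(as.character(pep))
  names(q) <- "query"
  hits <- find_homologs(q, reference_p450s, e_cutoff = Inf)
  best <- hits[hits$log10_evalue <= log10(e_cutoff), , drop = FALSE]
  list(
    is_p450 = nrow(best) > 0,
    best_reference = if (nrow(best)) best$subject_id[1L] else NA_character_,
    evalue = if (nrow(hits)) hits$evalue[1L] else NA_real_,
    log10_evalue = if (nrow(hits)) hits$log10_evalue[1L] else NA_real_,
    motifs = scan_p450_motifs(pep)
  )
}

#' Longest ORF peptide of a transcript
#'
#' Scans all six reading frames for the longest ATG-initiated open reading
#' frame and returns its translation (stop codon excluded). An ORF may run
#' to the end of a frame without a stop codon, as expected for transcripts
#' with incomplete 3' ends. Ties are resolved deterministically: frames in
#' the order +1, +2, +3, -1, -2, -3, then leftmost start.
#'
#' @param transcript a single DNA sequence (ACGTN characters only).
#' @param min_aa minimum peptide length in residues (default 50).
#' @return an `AAString` peptide, or `NULL` when no ORF reaches `min_aa`.
#' @export
#' @examples
#' as.character(longest_orf_peptide("ATGAAATAA", min_aa = 1))  # "MK"
longest_orf_peptide <- function(transcript, min_aa = 50) {
  if (inherits(transcript, c("AAString", "AAStringSet"))) {
    stop("longest_orf_peptide expects a DNA sequence", call. = FALSE)
  }
  raw <- if (is.character(transcript)) transcript else
    as.character(.as_single_seq(transcript, "dna"))
  chars <- unique(strsplit(toupper(raw), "")[[1L]])
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("non-ACGTN characters in transcript", call. = FALSE)
  }
  dna <- Biostrings::DNAString(toupper(raw))
  strands <- list(fwd = dna, rev = Biostrings::reverseComplement(dna))
  best <- NULL
  best_len <- -1L
  for (s in seq_along(strands)) {
    for (f in 1:3) {
      len <- length(strands[[s]])
      w <- ((len - f + 1L) %/% 3L) * 3L
      if (w < 3L) next
      pep <- as.character(Biostrings::translate(
        Biostrings::subseq(strands[[s]], start = f, width = w),
        if.fuzzy.codon = "X"))
      m <- gregexpr("M[^*]*", pep)[[1L]]
      if (m[1L] == -1L) next
      lens <- attr(m, "match.length")
      k <- which.max(lens)  # leftmost maximal ORF within this frame
      if (lens[k] > best_len) {
        best_len <- lens[k]
        best <- substring(pep, m[k], m[k] + lens[k] - 1L)
      }
    }
  }
  if (is.null(best) || best_len < min_aa) return(NULL)
  Biostrings::AAString(best)
}

#' Packaged synthetic reference P450 peptides
#'
#' A small synthetic stand-in for a curated plant cytochrome P450 list:
#' divergent variants of the packaged P450 template peptide. Generated
#' once with a frozen seed; see the package vignette.
#'
#' @return an `AAStringSet`.
#' @export
p450_references <- function() {
  if (is.null(.cypscreen_cache$p450_refs)) {
    .cypscreen_cache$p450_refs <-
      read_fasta(.extdata("p450_references_synthetic.fasta"),
                 alphabet = "protein")
  }
  .cypscreen_cache$p450_refs
}

#' Packaged synthetic P450 template peptide
#'
#' A 500-residue synthetic peptide carrying the four P450 consensus motifs
#' at realistic positions (oxygen-binding near residue 321, EXXR near 387,
#' PERF/PXRX near 430, heme motif near 464). Used as the ancestor for
#' generated P450 decoys and planted orthogroups.
#'
#' @return a length-1 `AAStringSet`.
#' @export
p450_template <- function() {
  if (is.null(.cypscreen_cache$p450_template)) {
    .cypscreen_cache$p450_template <-
      read_fasta(.extdata("p450_template_synthetic.fasta"),
                 alphabet = "protein")
  }
  .cypscreen_cache$p450_template
}

#' Packaged synthetic bait reference protein
#'
#' Synthetic stand-in for the bait methyltransferase protein used to locate
#' each assembly's bait transcript by homology. Contains no P450 motifs.
#'
#' @return a length-1 `AAStringSet`.
#' @export
bait_reference <- function() {
  if (is.null(.cypscreen_cache$bait_ref)) {
    .cypscreen_cache$bait_ref <-
      read_fasta(.extdata("bait_reference_synthetic.fasta"),
                 alphabet = "protein")
  }
  .cypscreen_cache$bait_ref
}
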