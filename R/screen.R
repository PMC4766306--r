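# End-to-end candidate screen: per-assembly P450 + co-expression lists,
# bait selection by homology, cross-assembly homolog linking at a
# stringent nucleotide cutoff, and the all-assemblies intersection that
# defines top-priority candidates.

#' Screen configuration
#'
#' @param reference id of the reference assembly whose candidates are
#'   reported (its own co-expressing list counts toward the presence
#'   total).
#' @param criteria a [match_criteria()] for the expression screen.
#' @param protein_cutoff E-value cutoff for P450 classification and bait
#'   selection (default 1e-4).
#' @param dna_cutoff E-value cutoff for cross-assembly nucleotide linking
#'   (default 1e-50).
#' @param min_present number of assemblies (including the reference) a
#'   candidate must appear in to be flagged top priority; default all.
#' @param bait_ref reference bait protein (`AAStringSet`, default
#'   packaged).
#' @param reference_p450s reference P450 peptide set (default packaged).
#' @param exclude_assemblies assembly ids to drop before screening (e.g.
#'   an assembly abandoned for poor quality).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(reference, criteria = match_criteria(),
                          protein_cutoff = 1e-4, dna_cutoff = 1e-50,
                          min_present = NULL, bait_ref = bait_reference(),
                          reference_p450s = p450_references(),
                          exclude_assemblies = character()) {
  structure(list(reference = reference, criteria = criteria,
                 protein_cutoff = protein_cutoff, dna_cutoff = dna_cutoff,
                 min_present = min_present, bait_ref = bait_ref,
                 reference_p450s = reference_p450s,
                 exclude_assemblies = exclude_assemblies),
            class = "screen_config")
}

#' Select the bait transcript of an assembly
#'
#' The assembly transcript whose peptide is the best-scoring homolog of
#' the reference bait protein at the protein cutoff (ties resolved as in
#' [find_homologs()]).
#'
#' @param peptides the assembly's predicted peptides (`AAStringSet`,
#'   named by transcript id).
#' @param bait_ref reference bait protein (length-1 `AAStringSet`).
#' @param e_cutoff protein E-value cutoff (default 1e-4).
#' @return the bait transcript id.
#' @export
select_bait <- function(peptides, bait_ref = bait_reference(),
                        e_cutoff = 1e-4) {
  if (length(peptides) == 0) stop("empty assembly peptide set",
                                  call. = FALSE)
  hits <- find_homologs(bait_ref, peptides, e_cutoff = e_cutoff)
  if (nrow(hits) == 0) {
    stop("bait not found: no homolog of the bait reference passes E <= ",
         format(e_cutoff), call. = FALSE)
  }
  hits$subject_id[1L]
}

#' Co-expressing P450 transcripts of one assembly
#'
#' Intersection of the bait co-expression passing set and the transcripts
#' whose peptides classify as cytochrome P450. Returned in deterministic
#' id-sorted order.
#'
#' @param assembly list with `peptides` (`AAStringSet`), `expression`
#'   (an [expression_matrix()]) and `bait_model` (a [bait_model()] whose
#'   `bait_transcript_id` is set so the bait itself is excluded).
#' @param criteria a [match_criteria()].
#' @param reference_p450s reference P450 set.
#' @param e_cutoff protein classification cutoff (default 1e-4).
#' @return character vector of transcript ids.
#' @export
p450_coexpress_list <- function(assembly, criteria = match_criteria(),
                                reference_p450s = p450_references(),
                                e_cutoff = 1e-4) {
  passing <- screen_matrix(assembly$expression, assembly$bait_model,
                           criteria)$transcript_id
  if (length(passing) == 0) return(character())
  ids <- seq_ids(assembly$peptides)
  passing <- passing[passing %in% ids]  # only transcripts with a peptide
  is_p450 <- vapply(passing, function(id) {
    classify_p450(assembly$peptides[[match(id, ids)]],
                  reference_p450s, e_cutoff)$is_p450
  }, logical(1))
  sort(passing[is_p450])
}

#' Cross-assembly presence of a candidate
#'
#' For each other assembly, the candidate's nucleotide sequence is
#' aligned against that assembly's bait co-expressing transcripts only
#' (not the whole assembly); the best hit passing the stringent cutoff
#' constitutes a link.
#'
#' @param candidate_seq the candidate transcript (`DNAString` or length-1
#'   `DNAStringSet`).
#' @param coexpress_seqs named list (by assembly id) of `DNAStringSet`s
#'   holding each assembly's co-expressing transcripts.
#' @param dna_cutoff nucleotide E-value cutoff (default 1e-50).
#' @return named list; per assembly either a list with `transcript_id`,
#'   `evalue`, `log10_evalue` or `NULL` when no link passes.
#' @export
cross_assembly_presence <- function(candidate_seq, coexpress_seqs,
                                    dna_cutoff = 1e-50) {
  q <- Biostrings::DNAStringSet(as.character(
    .as_single_seq(candidate_seq, "dna")))
  names(q) <- "candidate"
  out <- lapply(coexpress_seqs, function(subjects) {
    if (length(subjects) == 0) return(NULL)
    hits <- find_homologs(q, subjects, e_cutoff = dna_cutoff)
    if (nrow(hits) == 0) return(NULL)
    list(transcript_id = hits$subject_id[1L], evalue = hits$evalue[1L],
         log10_evalue = hits$log10_evalue[1L])
  })
  out
}

#' Run the full candidate screen
#'
#' Orchestrates the whole workflow: per-assembly bait selection by
#' homology, expression-model matching, P450 classification of the
#' reference assembly's passing transcripts, cross-assembly nucleotide
#' linking of each reference candidate against the other assemblies'
#' co-expressing lists, and ranking by presence count. Candidates present
#' in all assemblies' co-expressing lists (the reference counts itself)
#' are flagged top priority. The screen itself is deterministic given its
#' inputs.
#'
#' @param dataset a `screen_dataset` from [generate_screen_dataset()], or
#'   any named list of assemblies, each a list with `transcripts`
#'   (`DNAStringSet`), `peptides` (`AAStringSet`), `expression`
#'   (an [expression_matrix()]) and `bait_model` (a [bait_model()]).
#' @param config a [screen_config()].
#' @param verbose log each stage's list sizes (default TRUE).
#' @return data.frame of class `candidate_report`, one row per reference
#'   candidate sorted by (`n_assemblies_present` desc, `r` desc, id):
#'   columns `candidate_id`, `r`, `fold`, `background`, `p`,
#'   `n_assemblies_present`, `top_priority`, plus a `links` list column
#'   of per-assembly link details and a `motifs` list column of
#'   consensus-motif hits.
#' @export
run_screen <- function(dataset, config, verbose = TRUE) {
  assemblies <- if (inherits(dataset, "screen_dataset"))
    dataset$assemblies else dataset
  assemblies <- assemblies[setdiff(names(assemblies),
                                   config$exclude_assemblies)]
  if (length(assemblies) < 2) stop("need at least 2 assemblies",
                                   call. = FALSE)
  if (!config$reference %in% names(assemblies)) {
    stop("reference assembly '", config$reference, "' not in dataset",
         call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))

  # stage 1: bait selection + expression screen per assembly
  coexpress <- list()
  results_all <- list()
  for (asm in names(assemblies)) {
    d <- assemblies[[asm]]
    bait_id <- tryCatch(
      select_bait(d$peptides, config$bait_ref, config$protein_cutoff),
      error = function(e) {
        stop("assembly '", asm, "': ", conditionMessage(e), call. = FALSE)
      })
    d$bait_model$bait_transcript_id <- bait_id
    assemblies[[asm]] <- d
    res <- screen_matrix(d$expression, d$bait_model, config$criteria,
                         all = TRUE)
    results_all[[asm]] <- res
    coexpress[[asm]] <- sort(res$transcript_id[res$passed])
    say("%s: bait %s; %d of %d transcripts co-express",
        asm, bait_id, length(coexpress[[asm]]), nrow(res))
  }

  # stage 2: P450 classification of the reference co-expressing list
  ref <- assemblies[[config$reference]]
  candidates <- p450_coexpress_list(ref, config$criteria,
                                    config$reference_p450s,
                                    config$protein_cutoff)
  say("%s (reference): %d co-expressing P450 candidates",
      config$reference, length(candidates))

  others <- setdiff(names(assemblies), config$reference)
  other_seqs <- lapply(others, function(asm) {
    d <- assemblies[[asm]]
    d$transcripts[match(coexpress[[asm]], seq_ids(d$transcripts))]
  })
  names(other_seqs) <- others

  n_total <- length(assemblies)
  min_present <- if (is.null(config$min_present)) n_total else
    config$min_present

  ref_ids <- seq_ids(ref$transcripts)
  ref_stats <- results_all[[config$reference]]
  rows <- lapply(candidates, function(id) {
    links <- cross_assembly_presence(
      ref$transcripts[[match(id, ref_ids)]], other_seqs, config$dna_cutoff)
    n_present <- 1L + sum(!vapply(links, is.null, logical(1)))
    st <- ref_stats[ref_stats$transcript_id == id, ]
    pep <- ref$peptides[[match(id, seq_ids(ref$peptides))]]
    data.frame(candidate_id = id, r = st$r, fold = st$fold,
               background = st$background, p = st$p,
               n_assemblies_present = n_present,
               top_priority = n_present >= min_present,
               links = I(list(links)), motifs = I(list(scan_p450_motifs(pep))),
               stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(report)) {
    report <- data.frame(candidate_id = character(), r = numeric(),
                         fold = numeric(), background = numeric(),
                         p = numeric(), n_assemblies_present = integer(),
                         top_priority = logical(),
                         links = I(list()), motifs = I(list()),
                         stringsAsFactors = FALSE)
  } else {
    report <- report[order(-report$n_assemblies_present, -report$r,
                           report$candidate_id), , drop = FALSE]
    rownames(report) <- NULL
  }
  say("top-priority candidates (present in %d/%d lists): %d",
      min_present, n_total, sum(report$top_priority))
  class(report) <- c("candidate_report", class(report))
  report
}

#' Write a candidate report as TSV
#'
#' Flat export of [run_screen()] output: list columns are serialized as
#' compact per-assembly `assembly:transcript:evalue` strings.
#'
#' @param report a `candidate_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  flat <- report[, c("candidate_id", "r", "fold", "background", "p",
                     "n_assemblies_present", "top_priority")]
  flat$links <- vapply(report$links, function(l) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (length(l) == 0) return("")
    paste(vapply(names(l), function(a) {
      sprintf("%s:%s:%.3g", a, l[[a]]$transcript_id, l[[a]]$evalue)
    }, character(1)), collapse = ";")
  }, character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
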