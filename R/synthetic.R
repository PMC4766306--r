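# Seeded synthetic-data generator: multi-assembly sequence + expression
# fixtures with one planted bait-correlated P450 orthogroup, and noisy
# substrate-inhibition rate curves. Every stochastic operation takes an
# explicit seed and is byte-reproducible.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codons per amino acid, flattened for vectorized reverse translation
.codon_pool <- function() {
  if (is.null(.cypscreen_cache$codon_pool)) {
    gc <- Biostrings::GENETIC_CODE
    by_aa <- split(names(gc), unname(gc))
    by_aa <- by_aa[names(by_aa) != "*"]
    pool <- unlist(by_aa, use.names = FALSE)
    sizes <- lengths(by_aa)
    offsets <- setNames(c(0L, cumsum(sizes))[seq_along(sizes)], names(sizes))
    .cypscreen_cache$codon_pool <-
      list(pool = pool, sizes = sizes, offsets = offsets,
           stops = names(gc)[gc == "*"])
  }
  .cypscreen_cache$codon_pool
}

.random_peptide <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

# remove EXXR and heme-motif matches so non-P450 decoys stay motif-free
.scrub_p450_motifs <- function(pep) {
  while (grepl("E..R", pep)) pep <- sub("E(..R)", "Q\\1", pep)
  while (grepl("F..G.R.C.G", pep)) {
    pep <- sub("F(..G.R.C.G)", "L\\1", pep)
  }
  pep
}

# reverse-translate a peptide string, sampling synonymous codons uniformly
.reverse_translate <- function(pep, add_stop = TRUE) {
  cp <- .codon_pool()
  aas <- strsplit(pep, "")[[1L]]
  pick <- cp$offsets[aas] + ceiling(stats::runif(length(aas)) * cp$sizes[aas])
  codons <- cp$pool[pick]
  if (add_stop) codons <- c(codons, sample(cp$stops, 1L))
  paste(codons, collapse = "")
}

# substitute exactly n_sub positions, never to the original character
.mutate_chars <- function(chars, n_sub, alphabet) {
  if (n_sub == 0L) return(chars)
  pos <- sample(length(chars), n_sub)
  repl <- alphabet[ceiling(stats::runif(n_sub) * length(alphabet))]
  clash <- repl == chars[pos]
  while (any(clash)) {
    repl[clash] <- alphabet[ceiling(stats::runif(sum(clash)) *
                                      length(alphabet))]
    clash <- repl == chars[pos]
  }
  chars[pos] <- repl
  chars
}

# substitution-only CDS mutation that never creates an in-frame stop codon
.mutate_cds <- function(dna, identity) {
  chars <- strsplit(dna, "")[[1L]]
  L <- length(chars)
  n_sub <- round((1 - identity) * L)
  if (n_sub == 0L) return(dna)
  stops <- .codon_pool()$stops
  coding <- seq_len(L - 3L)  # keep the terminal stop codon intact
  pos <- sample(coding, min(n_sub, length(coding)))
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    frame_start <- p - ((p - 1L) %% 3L)
    for (b in sample(setdiff(bases, chars[p]))) {
      codon <- chars[frame_start:(frame_start + 2L)]
      codon[p - frame_start + 1L] <- b
      if (!(paste(codon, collapse = "") %in% stops)) {
        chars[p] <- b
        break
      }
    }
  }
  paste(chars, collapse = "")
}

#' Mutate a sequence to a target identity
#'
#' Produces a homolog by random substitutions (no indels): exactly
#' `round((1 - target_identity) * length)` positions are replaced with a
#' different residue, so realized identity matches the target to within
#' rounding.
#'
#' @param seq a single DNA or protein sequence (`XString`, length-1
#'   `XStringSet`, or character).
#' @param target_identity fraction in (0, 1].
#' @param seed optional integer seed for reproducibility; `NULL` uses the
#'   current RNG stream.
#' @return mutated sequence of the same class as `seq` was coerced to
#'   (`DNAString` or `AAString`).
#' @export
mutate_homolog <- function(seq, target_identity, seed = NULL) {
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]", call. = FALSE)
  }
  alpha <- .seq_alphabet(seq)
  s <- as.character(.as_single_seq(seq, alpha))
  run <- function() {
    chars <- strsplit(s, "")[[1L]]
    n_sub <- round((1 - target_identity) * length(chars))
    alphabet <- if (alpha == "dna") c("A", "C", "G", "T") else .AA20
    paste(.mutate_chars(chars, n_sub, alphabet), collapse = "")
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (alpha == "dna") Biostrings::DNAString(out) else Biostrings::AAString(out)
}

#' Default bait expression models
#'
#' The packaged per-assembly bait models: tissue expression of the bait
#' methyltransferase in each of the five usable assemblies (three
#' ABySS/MIRA-style, two Trinity-style; relative units, RPM or TPM as
#' originally quantified). These are the models the screen's defaults
#' emulate.
#'
#' @return named list of [bait_model()] objects.
#' @export
default_bait_models <- function() {
  tab <- utils::read.delim(.extdata("bait_models.tsv"),
                           stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    bait_model(tab$assembly[i],
               c(tab$leaf[i], tab$inflorescence[i], tab$bulb[i]),
               unit = tab$unit[i])
  })
  setNames(out, tab$assembly)
}

#' Define a synthetic screen scenario
#'
#' Parameters of the generated multi-assembly dataset. Defaults mirror the
#' study conditions the screen assumes: five usable assemblies with the
#' packaged bait models, three tissues, one planted bait-correlated P450
#' orthogroup among 50 decoy P450s, mild multiplicative expression noise
#' and orthologs divergent but linkable at the stringent nucleotide
#' cutoff.
#'
#' @param n_assemblies number of assemblies (>= 2; default 5).
#' @param n_transcripts transcripts per assembly (default 250).
#' @param n_p450_decoys decoy P450 transcripts per assembly (default 50).
#' @param planted_orthogroup plant the true candidate orthogroup
#'   (default TRUE).
#' @param bait_models list of per-assembly [bait_model()]s; default the
#'   first `n_assemblies` packaged models.
#' @param expression_noise_sigma log-scale standard deviation of the
#'   multiplicative expression noise (default 0.05).
#' @param homolog_identity nucleotide identity of planted orthogroup
#'   members to their common ancestor (default 0.95).
#' @param tissues tissue labels.
#' @param seed integer seed; identical seed and parameters give
#'   byte-identical outputs.
#' @return object of class `screen_scenario`.
#' @export
screen_scenario <- function(n_assemblies = 5, n_transcripts = 250,
                            n_p450_decoys = 50, planted_orthogroup = TRUE,
                            bait_models = NULL,
                            expression_noise_sigma = 0.05,
                            homolog_identity = 0.95,
                            tissues = c("leaf", "inflorescence", "bulb"),
                            seed = 1) {
  if (n_assemblies < 2) stop("need at least 2 assemblies", call. = FALSE)
  if (homolog_identity <= 0 || homolog_identity > 1) {
    stop("homolog_identity must be in (0, 1]", call. = FALSE)
  }
  if (expression_noise_sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(bait_models)) {
    pool <- default_bait_models()
    if (n_assemblies > length(pool)) {
      # extend with jittered copies of the last packaged model
      extra <- lapply(seq_len(n_assemblies - length(pool)), function(i) {
        base <- pool[[length(pool)]]
        bait_model(paste0("assembly_", length(pool) + i),
                   base$values * (1 + 0.1 * i), unit = "relative")
      })
      pool <- c(pool, setNames(extra, vapply(extra, `[[`, "", "assembly_id")))
    }
    bait_models <- pool[seq_len(n_assemblies)]
  }
  if (length(bait_models) != n_assemblies) {
    stop("need one bait model per assembly", call. = FALSE)
  }
  min_needed <- n_p450_decoys + 1L + as.integer(planted_orthogroup)
  if (n_transcripts < min_needed) {
    stop("n_transcripts too small for requested composition", call. = FALSE)
  }
  structure(list(n_assemblies = n_assemblies, n_transcripts = n_transcripts,
                 n_p450_decoys = n_p450_decoys,
                 planted_orthogroup = isTRUE(planted_orthogroup),
                 bait_models = bait_models,
                 expression_noise_sigma = expression_noise_sigma,
                 homolog_identity = homolog_identity,
                 tissues = as.character(tissues), seed = as.integer(seed)),
            class = "screen_scenario")
}

# divergence of the planted orthogroup ancestor from the packaged P450
# template, and of per-assembly decoy P450s (identity drawn per decoy)
.PLANTED_TEMPLATE_IDENTITY <- 0.85
.DECOY_IDENTITY_RANGE <- c(0.65, 0.90)
.BAIT_IDENTITY <- 0.90
.PLANTED_EXPR_SCALE <- 2

#' Generate a synthetic multi-assembly screen dataset
#'
#' Builds, for each assembly: nucleotide transcripts, predicted peptides,
#' an expression matrix and the assembly's bait model. Exactly one planted
#' P450 orthogroup (when enabled) has noiseless expression proportional to
#' each assembly's bait model, degraded by multiplicative log-normal noise
#' of sd `expression_noise_sigma`; orthogroup members descend from one
#' ancestor CDS at `homolog_identity`. Decoy P450s carry the consensus
#' motifs but expression independent of the bait (log-normal around
#' tissue means drawn uniformly on [0.1, 200]); non-P450 transcripts lack
#' the EXXR and heme motifs. The bait transcript is present in every
#' assembly with expression equal to its model.
#'
#' @param scenario a [screen_scenario()].
#' @return object of class `screen_dataset`: list with `assemblies` (each
#'   a list of `transcripts`, `peptides`, `expression`, `bait_model`),
#'   `scenario`, and `truth` (`planted_ids`, `bait_ids` per assembly).
#' @export
generate_screen_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "screen_scenario"))
  withr::with_seed(scenario$seed, .generate_screen_dataset(scenario))
}

.generate_screen_dataset <- function(sc) {
  template <- as.character(p450_template()[[1L]])
  bait_pep0 <- as.character(bait_reference()[[1L]])
  sigma <- sc$expression_noise_sigma

  planted_anc_pep <- paste(
    .mutate_chars(strsplit(template, "")[[1L]],
                  round((1 - .PLANTED_TEMPLATE_IDENTITY) * nchar(template)),
                  .AA20),
    collapse = "")
  planted_anc_cds <- .reverse_translate(planted_anc_pep)

  assemblies <- list()
  planted_ids <- character()
  bait_ids <- character()

  for (a in seq_len(sc$n_assemblies)) {
    bm <- sc$bait_models[[a]]
    asm <- bm$assembly_id
    model <- unname(bm$values)

    peps <- character()
    cds <- character()
    expr <- list()
    kind <- character()

    # bait transcript: expression is the model itself
    bait_pep <- paste(
      .mutate_chars(strsplit(bait_pep0, "")[[1L]],
                    round((1 - .BAIT_IDENTITY) * nchar(bait_pep0)), .AA20),
      collapse = "")
    peps <- c(peps, bait_pep)
    cds <- c(cds, .reverse_translate(bait_pep))
    expr <- c(expr, list(model))
    kind <- c(kind, "bait")

    if (sc$planted_orthogroup) {
      p_cds <- .mutate_cds(planted_anc_cds, sc$homolog_identity)
      p_pep <- sub("\\*$", "", as.character(Biostrings::translate(
        Biostrings::DNAString(p_cds))))
      peps <- c(peps, p_pep)
      cds <- c(cds, p_cds)
      expr <- c(expr, list(.PLANTED_EXPR_SCALE * model *
                             exp(stats::rnorm(length(model), 0, sigma))))
      kind <- c(kind, "planted")
    }

    for (j in seq_len(sc$n_p450_decoys)) {
      ident <- stats::runif(1, .DECOY_IDENTITY_RANGE[1],
                            .DECOY_IDENTITY_RANGE[2])
      d_pep <- paste(
        .mutate_chars(strsplit(template, "")[[1L]],
                      round((1 - ident) * nchar(template)), .AA20),
        collapse = "")
      peps <- c(peps, d_pep)
      cds <- c(cds, .reverse_translate(d_pep))
      mu <- stats::runif(length(model), 0.1, 200)
      expr <- c(expr, list(mu * exp(stats::rnorm(length(model), 0, sigma))))
      kind <- c(kind, "decoy_p450")
    }

    n_other <- sc$n_transcripts - length(peps)
    for (j in seq_len(n_other)) {
      o_pep <- .scrub_p450_motifs(
        .random_peptide(round(stats::runif(1, 150, 450))))
      peps <- c(peps, o_pep)
      cds <- c(cds, .reverse_translate(o_pep))
      mu <- stats::runif(length(model), 0.1, 200)
      expr <- c(expr, list(mu * exp(stats::rnorm(length(model), 0, sigma))))
      kind <- c(kind, "other")
    }

    ord <- sample(length(peps))
    ids <- sprintf("%s_t%03d", asm, seq_along(peps))
    peps <- setNames(peps[ord], ids)
    cds <- setNames(cds[ord], ids)
    expr_mat <- do.call(rbind, expr[ord])
    dimnames(expr_mat) <- list(ids, sc$tissues)
    kind <- kind[ord]

    planted_ids[asm] <- if (sc$planted_orthogroup)
      ids[kind == "planted"] else NA_character_
    bait_ids[asm] <- ids[kind == "bait"]

    transcripts <- Biostrings::DNAStringSet(cds)
    peptides <- Biostrings::AAStringSet(peps)
    assemblies[[asm]] <- list(
      transcripts = transcripts,
      peptides = peptides,
      expression = expression_matrix(expr_mat, assembly_id = asm,
                                     unit = "relative"),
      bait_model = bm
    )
  }

  structure(list(assemblies = assemblies, scenario = sc,
                 truth = list(planted_ids = planted_ids,
                              bait_ids = bait_ids)),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(
    "screen_dataset: %d assemblies x %d transcripts (planted orthogroup: %s)\n",
    length(x$assemblies), x$scenario$n_transcripts,
    ifelse(x$scenario$planted_orthogroup, "yes", "no")))
  invisible(x)
}

#' Write a screen dataset to disk
#'
#' One FASTA of transcripts, one FASTA of peptides and one expression TSV
#' per assembly, in the same formats the readers consume.
#'
#' @param dataset a `screen_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "screen_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (asm in names(dataset$assemblies)) {
    d <- dataset$assemblies[[asm]]
    write_fasta(d$transcripts, file.path(dir, paste0(asm, "_transcripts.fasta")))
    write_fasta(d$peptides, file.path(dir, paste0(asm, "_peptides.fasta")))
    write_expression(d$expression, file.path(dir, paste0(asm, "_expression.tsv")))
  }
  invisible(dir)
}

#' Define a kinetic assay scenario
#'
#' Defaults are the enzymology conditions for the preferred substrate:
#' Km 1.13 uM, kcat 15.0 / min, substrate-inhibition Ki 64.3 uM, enzyme
#' 2.5 nM, 12 substrate concentrations log-spaced over 0.25-200 uM in
#' triplicate, 5% multiplicative Gaussian noise.
#'
#' @param km Michaelis constant, uM (> 0).
#' @param kcat turnover number, 1/min (> 0).
#' @param ki substrate-inhibition constant, uM (`Inf` disables
#'   inhibition).
#' @param enzyme_conc enzyme concentration, nM (> 0).
#' @param substrate_grid substrate concentrations, uM.
#' @param replicates technical replicates per concentration.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return object of class `kinetic_scenario`.
#' @export
kinetic_scenario <- function(km = 1.13, kcat = 15.0, ki = 64.3,
                             enzyme_conc = 2.5,
                             substrate_grid = exp(seq(log(0.25), log(200),
                                                      length.out = 12)),
                             replicates = 3, noise_cv = 0.05, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (length(substrate_grid) == 0) stop("empty substrate grid",
                                        call. = FALSE)
  if (any(substrate_grid <= 0)) stop("substrate concentrations must be > 0",
                                     call. = FALSE)
  params <- kinetic_params(km = km, kcat = kcat, ki = ki,
                           enzyme_conc = enzyme_conc)
  structure(list(params = params, substrate_grid = substrate_grid,
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "kinetic_scenario")
}

#' Simulate noisy rate measurements
#'
#' v = model rate times (1 + eps), eps ~ Normal(0, noise_cv), clipped at
#' zero.
#'
#' @param scenario a [kinetic_scenario()].
#' @return data.frame with columns `S_uM`, `replicate`, `v` (nM/min).
#' @export
simulate_rates <- function(scenario) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  withr::with_seed(scenario$seed, {
    grid <- expand.grid(S_uM = scenario$substrate_grid,
                        replicate = seq_len(scenario$replicates),
                        KEEP.OUT.ATTRS = FALSE)
    mu <- enzyme_rate(grid$S_uM, scenario$params)
    eps <- stats::rnorm(nrow(grid), 0, scenario$noise_cv)
    grid$v <- pmax(mu * (1 + eps), 0)
    grid
  })
}
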