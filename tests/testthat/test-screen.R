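make_assembly <- function(peps, cds, expr, model, asm = "demo") {
  list(transcripts = Biostrings::DNAStringSet(cds),
       peptides = Biostrings::AAStringSet(peps),
       expression = expression_matrix(expr, asm),
       bait_model = bait_model(asm, model))
}

test_that("bait selection finds the closest homolog or fails loudly", {
  withr::local_seed(71)
  bait0 <- as.character(bait_reference()[[1]])
  exact <- c(t1 = random_aa(300), t2 = bait0, t3 = random_aa(250))
  expect_equal(select_bait(Biostrings::AAStringSet(exact)), "t2")

  # a 90%-identity ortholog among unrelated decoys still wins
  ortho <- as.character(mutate_homolog(bait0, 0.9, seed = 4))
  set2 <- c(d1 = random_aa(300), ortho = ortho, d2 = random_aa(240))
  expect_equal(select_bait(Biostrings::AAStringSet(set2)), "ortho")

  none <- Biostrings::AAStringSet(c(x = random_aa(200), y = random_aa(220)))
  expect_error(select_bait(none), "bait not found")
})

test_that("the P450 co-expression list intersects both criteria", {
  withr::local_seed(72)
  model <- c(1, 30, 45)
  p450 <- as.character(mutate_homolog(as.character(p450_template()[[1]]),
                                      0.8, seed = 1))
  bait0 <- as.character(bait_reference()[[1]])
  corr_non_p450 <- random_aa(300)  # co-expressed but not a P450
  peps <- c(bait = bait0, cand = p450, red = corr_non_p450,
            dull = random_aa(280))
  cds <- vapply(peps, function(p) cypscreen:::.reverse_translate(p),
                character(1))
  expr <- rbind(bait = model, cand = 2 * model, red = 3 * model,
                dull = c(80, 90, 70))
  colnames(expr) <- c("leaf", "inflorescence", "bulb")
  asm <- make_assembly(peps, cds, expr, model)
  asm$bait_model$bait_transcript_id <- "bait"

  lst <- p450_coexpress_list(asm)
  expect_identical(lst, "cand")

  # an unreachable fold cutoff empties the list
  hard <- match_criteria(fold_cutoff = 1e9)
  expect_length(p450_coexpress_list(asm, hard), 0)

  # no P450s at all
  asm2 <- asm
  asm2$peptides <- Biostrings::AAStringSet(
    c(bait = bait0, cand = random_aa(300), red = corr_non_p450,
      dull = random_aa(280)))
  expect_length(p450_coexpress_list(asm2), 0)
})

test_that("cross-assembly linking respects the stringent cutoff", {
  withr::local_seed(73)
  anc <- random_dna(1500)
  close_hom <- as.character(mutate_homolog(anc, 0.95))
  far_hom <- as.character(mutate_homolog(anc, 0.60))
  lists <- list(
    asm_close = Biostrings::DNAStringSet(c(a = close_hom,
                                           b = random_dna(900))),
    asm_far = Biostrings::DNAStringSet(c(c = far_hom)),
    asm_none = Biostrings::DNAStringSet(c(d = random_dna(1200))))
  links <- cross_assembly_presence(Biostrings::DNAString(anc), lists)
  expect_equal(links$asm_close$transcript_id, "a")
  expect_lt(links$asm_close$log10_evalue, -50)
  expect_null(links$asm_far)
  expect_null(links$asm_none)
})

test_that("the full screen recovers exactly the planted candidate", {
  sc <- screen_scenario(n_transcripts = 100, n_p450_decoys = 20, seed = 42)
  ds <- generate_screen_dataset(sc)
  cfg <- screen_config(reference = "narcissus_abyssmira")
  rep <- run_screen(ds, cfg, verbose = FALSE)
  top <- rep$candidate_id[rep$top_priority]
  expect_identical(top, unname(ds$truth$planted_ids[["narcissus_abyssmira"]]))
  expect_equal(rep$n_assemblies_present[rep$top_priority], 5L)
  # deterministic given inputs
  rep2 <- run_screen(ds, cfg, verbose = FALSE)
  expect_identical(rep$candidate_id, rep2$candidate_id)
  expect_identical(rep$n_assemblies_present, rep2$n_assemblies_present)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_report(rep, out)
  flat <- read.delim(out)
  expect_true(all(c("candidate_id", "top_priority", "links") %in%
                    names(flat)))
})

test_that("ablating one assembly's signal demotes the candidate", {
  sc <- screen_scenario(n_transcripts = 60, n_p450_decoys = 10, seed = 19)
  ds <- generate_screen_dataset(sc)
  asm <- "galanthus_sp_trinity"
  pid <- ds$truth$planted_ids[[asm]]
  # overwrite the planted member's expression with a bait-independent one
  ds$assemblies[[asm]]$expression$values[pid, ] <- c(120, 2, 35)
  cfg <- screen_config(reference = "narcissus_abyssmira")
  rep <- run_screen(ds, cfg, verbose = FALSE)
  pref <- ds$truth$planted_ids[["narcissus_abyssmira"]]
  row <- rep[rep$candidate_id == pref, ]
  expect_equal(row$n_assemblies_present, 4L)
  expect_false(row$top_priority)
  expect_equal(sum(rep$top_priority), 0)

  # dropping that assembly makes the remaining four unanimous again
  cfg4 <- screen_config(reference = "narcissus_abyssmira",
                        exclude_assemblies = asm)
  rep4 <- run_screen(ds, cfg4, verbose = FALSE)
  row4 <- rep4[rep4$candidate_id == pref, ]
  expect_equal(row4$n_assemblies_present, 4L)
  expect_true(row4$top_priority)
})

test_that("null scenarios yield no top-priority candidates", {
  hits <- vapply(1:12, function(s) {
    sc <- screen_scenario(n_transcripts = 60, n_p450_decoys = 15,
                          planted_orthogroup = FALSE, seed = 1000 + s)
    ds <- generate_screen_dataset(sc)
    rep <- run_screen(ds, screen_config(reference = "narcissus_abyssmira"),
                      verbose = FALSE)
    sum(rep$top_priority)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})
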