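test_that("FPKM follows its defining formula and scaling law", {
  expect_equal(compute_fpkm(0, 500, 1e6), 0)
  expect_equal(compute_fpkm(10, 1000, 1e6), 10)
  expect_equal(compute_fpkm(10, 1000, 2e6), 5)  # doubling library halves
  expect_error(compute_fpkm(1, 0, 1e6))
})

test_that("FPKM validation is strict at the threshold", {
  th <- validation_thresholds()
  # two genes, one condition; library total = 1e6 by construction
  counts <- data.frame(
    gene = c("g1", "filler"), condition = "c1",
    count = c(1, 999999), gene_length = c(1000, 5000))
  # g1: fpkm = 1 * 1e9 / (1000 * 1e6) = 1.0 exactly -> not validated
  expect_false(fpkm_validate("g1", counts, th))
  counts$count <- c(2, 999998)  # g1 fpkm 2 > 1
  expect_true(fpkm_validate("g1", counts, th))
  expect_false(fpkm_validate("absent", counts, th))
  # one qualifying condition among several suffices
  dull <- within(counts, {condition <- "c2"; count <- c(0, 1000000)})
  expect_true(fpkm_validate("g1", rbind(counts, dull), th))
  expect_false(fpkm_validate("g1", dull, th))
})

test_that("transcript overlap validation is inclusive at 60% and unique-locus only", {
  th <- validation_thresholds()
  aln <- function(frac, loci) data.frame(
    gene = "g1", transcript = "t1", covered_fraction = frac,
    n_loci = loci)
  expect_true(transcript_overlap_validate("g1", aln(0.60, 1), th))
  expect_false(transcript_overlap_validate("g1", aln(0.59, 1), th))
  expect_false(transcript_overlap_validate("g1", aln(0.95, 2), th))
  expect_false(transcript_overlap_validate("g2", aln(0.95, 1), th))
})

test_that("peptide validation requires unique unambiguous matches below q", {
  th <- validation_thresholds()
  proteome <- Biostrings::AAStringSet(c(
    g1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
    g2 = "MSHFSRQLEERWWPLNNNQQKV"))
  pep <- function(p, q) data.frame(peptide = p, q_value = q)
  expect_true(peptide_validate("g1", pep("MKTAYIAKQR", 0.005),
                               proteome, th))
  expect_false(peptide_validate("g1", pep("MKTAYIAKQR", 0.02),
                                proteome, th))
  # SHFSRQLEER occurs in both proteins: ambiguous, validates neither
  expect_false(peptide_validate("g1", pep("SHFSRQLEER", 0.001),
                                proteome, th))
  expect_false(peptide_validate("g2", pep("SHFSRQLEER", 0.001),
                                proteome, th))
})

test_that("evidence flags are monotone in added evidence", {
  th <- validation_thresholds()
  aln <- data.frame(gene = "g1", transcript = "t1",
                    covered_fraction = 0.8, n_loci = 1L)
  more <- rbind(aln, data.frame(gene = "g1", transcript = "t2",
                                covered_fraction = 0.1, n_loci = 2L))
  expect_true(transcript_overlap_validate("g1", aln, th))
  expect_true(transcript_overlap_validate("g1", more, th))
})

test_that("Venn partition conserves the subset under every selector", {
  set.seed(707)
  n <- 40
  ev <- data.frame(
    gene_id = sprintf("g%02d", 1:n),
    transcriptome_flag = sample(c(TRUE, FALSE), n, TRUE),
    fpkm_flag = sample(c(TRUE, FALSE), n, TRUE),
    protein_flag = sample(c(TRUE, FALSE), n, TRUE),
    dubious_flag = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)),
    repeat_flag = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)),
    non_reference_flag = sample(c(TRUE, FALSE), n, TRUE))
  class(ev) <- c("evidence_set", "data.frame")
  for (sel in c("all", "nondubious", "non_reference",
                "non_reference_norepeat")) {
    vp <- venn_partition(ev, sel)
    expect_equal(sum(vp$counts), vp$total, info = sel)
    # set-algebra oracle for two cells
    sub <- switch(sel,
      all = ev,
      nondubious = ev[!ev$dubious_flag, ],
      non_reference = ev[ev$non_reference_flag, ],
      non_reference_norepeat = ev[ev$non_reference_flag & !ev$repeat_flag, ])
    expect_equal(vp$no_evidence,
                 sum(!sub$transcriptome_flag & !sub$fpkm_flag &
                       !sub$protein_flag), info = sel)
    expect_equal(unname(vp$counts["T+F+P"]),
                 sum(sub$transcriptome_flag & sub$fpkm_flag &
                       sub$protein_flag), info = sel)
  }
  # all flags false -> everything in no_evidence
  ev0 <- ev
  ev0$transcriptome_flag <- ev0$fpkm_flag <- ev0$protein_flag <- FALSE
  expect_equal(venn_partition(ev0, "all")$no_evidence, n)
  # one gene per combination -> all eight cells equal 1
  combos <- expand.grid(t = c(FALSE, TRUE), f = c(FALSE, TRUE),
                        p = c(FALSE, TRUE))
  ev8 <- data.frame(gene_id = sprintf("c%d", 1:8),
                    transcriptome_flag = combos$t, fpkm_flag = combos$f,
                    protein_flag = combos$p, dubious_flag = FALSE,
                    repeat_flag = FALSE, non_reference_flag = FALSE)
  expect_true(all(venn_partition(ev8, "all")$counts == 1L))
})

test_that("log-space Fisher matches enumeration and stays finite", {
  expect_equal(fisher_exact_log(matrix(c(1, 1, 1, 1), 2)), 0)
  # empty margin: p = 1 by convention
  expect_equal(fisher_exact_log(matrix(c(0, 0, 5, 7), 2,
                                       byrow = TRUE)), 0)
  # transposition symmetry
  m <- matrix(c(12, 3, 5, 20), 2)
  expect_equal(fisher_exact_log(m), fisher_exact_log(t(m)))
  set.seed(808)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = stats::runif(4)))
    tab <- matrix(cells, 2)
    expect_lt(abs(fisher_exact_log(tab) - fisher_enum_oracle(tab)),
              1e-6)
  }
  # agrees with stats::fisher.test where p does not underflow
  for (tab in list(matrix(c(10, 2, 3, 15), 2),
                   matrix(c(40, 1, 2, 35), 2))) {
    expect_equal(10^fisher_exact_log(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
})

test_that("the synthetic evidence pipeline recovers the expressed set", {
  sp <- mini_panel()
  tr <- sp$truth
  ev_in <- generate_expression_evidence(tr, seed = 9)
  pl <- tr$placements[tr$placements$strain == tr$focal_strain, ]
  coding <- pl[pl$class %in% c("core", "novel", "dubious"), ]
  es <- evidence_set(coding$gene_id, ev_in$alignments, ev_in$counts,
                     ev_in$peptides, ev_in$proteome,
                     dubious = coding$class == "dubious",
                     non_reference = coding$class == "novel")
  union_flag <- es$transcriptome_flag | es$fpkm_flag | es$protein_flag
  expect_identical(unname(union_flag), unname(coding$expressed))
})
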