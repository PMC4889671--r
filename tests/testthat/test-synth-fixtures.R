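test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(chromosome_length = 8000,
                                subtelomere_span = 5000),
               "twice")
  expect_error(synthetic_config(n_clusters = 4, cluster_size = 3,
                                n_novel_genes = 8), "cluster")
  expect_error(synthetic_config(expression_fraction = 1.5))
  # genes that cannot fit raise a sizing error
  too_many <- synthetic_config(n_core_genes = 200, n_chromosomes = 1,
                               chromosome_length = 10000,
                               subtelomere_span = 2500,
                               n_novel_genes = 0, n_clusters = 0,
                               cluster_size = 0)
  expect_error(generate_strain_panel(too_many), "infeasible")
})

test_that("generation is deterministic and respects gene content", {
  cfg <- mini_config()
  a <- generate_strain_panel(cfg)
  b <- generate_strain_panel(cfg)
  expect_identical(lapply(a$panel, as.character),
                   lapply(b$panel, as.character))
  expect_identical(a$truth$placements, b$truth$placements)
  # FASTA bytes are identical too
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  write_strain_panel(a, da); write_strain_panel(b, db)
  for (f in list.files(da))
    expect_identical(readBin(file.path(da, f), "raw", 1e6),
                     readBin(file.path(db, f), "raw", 1e6))

  # no novel/pseudo/dubious genes: every strain has reference content
  flat <- synthetic_config(seed = 3, n_novel_genes = 0, n_clusters = 0,
                           cluster_size = 0, n_pseudogenes = 0,
                           n_dubious = 0)
  sp0 <- generate_strain_panel(flat)
  pl <- sp0$truth$placements
  ref_genes <- sort(pl$gene_id[pl$strain == "ref"])
  for (st in sp0$truth$strains)
    expect_identical(sort(pl$gene_id[pl$strain == st]), ref_genes)
})

test_that("every placed gene appears once and clusters are adjacent", {
  sp <- default_panel()
  pl <- sp$truth$placements
  for (st in sp$truth$strains) {
    ids <- pl$gene_id[pl$strain == st]
    expect_equal(anyDuplicated(ids), 0L)
  }
  # cluster members are coordinate-adjacent on one chromosome
  info <- sp$truth$gene_info
  for (cl in unique(stats::na.omit(info$cluster_id))) {
    members <- info$gene_id[!is.na(info$cluster_id) &
                              info$cluster_id == cl]
    foc <- pl[pl$strain == sp$truth$focal_strain, ]
    rows <- foc[foc$gene_id %in% members, ]
    expect_equal(length(unique(rows$contig)), 1L)
    on_ctg <- foc[foc$contig == rows$contig[1], ]
    on_ctg <- on_ctg[order(on_ctg$start), ]
    idx <- which(on_ctg$gene_id %in% members)
    expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("fully subtelomeric placement passes a coordinate audit", {
  cfg <- synthetic_config(seed = 19, n_novel_genes = 10,
                          novel_subtelomeric_fraction = 1.0,
                          n_clusters = 0, cluster_size = 0)
  sp <- generate_strain_panel(cfg)
  pl <- sp$truth$placements
  novel <- pl[pl$class == "novel", ]
  expect_gt(nrow(novel), 0)
  # brute-force coordinate check against the chromosome ends
  for (i in seq_len(nrow(novel))) {
    L <- cfg$chromosome_length
    d <- min(novel$start[i] - 1, L - novel$end[i])
    expect_lte(d, cfg$subtelomere_span)
    expect_identical(novel$location_class[i], "subtelomeric")
  }
})

test_that("planted ORFs validate and planted pseudogenes do not", {
  sp <- mini_panel()
  tr <- sp$truth
  genome <- sp$panel[[tr$focal_strain]]
  pl <- tr$placements[tr$placements$strain == tr$focal_strain, ]
  for (i in seq_len(nrow(pl))) {
    v <- validate_orf(gene_models(pl$gene_id[i], pl$contig[i],
                                  pl$start[i], pl$end[i],
                                  pl$strand[i]), genome)
    if (pl$class[i] == "pseudogene") {
      expect_identical(v$status, "invalid")
      expect_true("internal_stop" %in% v$defects)
    } else {
      expect_identical(v$status, "valid_coding")
    }
  }
})

test_that("annotator tracks perturb at the requested rate", {
  sp <- default_panel()
  tr <- sp$truth
  # error_rate 0: both tracks equal truth
  clean <- generate_annotator_calls(tr, 0, seed = 2)
  truth_models <- placement_models(tr, tr$focal_strain)
  for (track in list(clean$track_a, clean$track_b)) {
    expect_equal(track$models[, c("id", "start", "end")],
                 truth_models[order(truth_models$contig,
                                    truth_models$start),
                              c("id", "start", "end")],
      ignore_attr = TRUE)
  }
  expect_equal(nrow(clean$perturbations), 0L)
  # drop-only at rate 1: empty tracks
  empty <- generate_annotator_calls(tr, 1, seed = 2, types = "drop")
  expect_equal(nrow(empty$track_a$models), 0L)
  expect_equal(nrow(empty$track_b$models), 0L)
  # rate 0.2: per-gene diff against truth within the binomial 99% CI
  calls <- generate_annotator_calls(tr, 0.2, seed = 14)
  n <- nrow(tr$placements[tr$placements$strain == tr$focal_strain, ])
  truth_key <- paste(truth_models$id, truth_models$start,
                     truth_models$end)
  for (track in list(calls$track_a, calls$track_b)) {
    mk <- paste(track$models$id, track$models$start, track$models$end)
    n_perturbed <- n - sum(truth_key %in% mk)
    ci <- stats::qbinom(c(0.005, 0.995), n, 0.2)
    expect_gte(n_perturbed, ci[1])
    expect_lte(n_perturbed, ci[2])
  }
  # the perturbation log matches the observed diffs
  pa <- calls$perturbations[calls$perturbations$track == "trackA", ]
  mk <- paste(calls$track_a$models$id, calls$track_a$models$start,
              calls$track_a$models$end)
  diffed <- truth_models$id[!(truth_key %in% mk)]
  expect_setequal(pa$gene_id, diffed)
})

test_that("evidence generation honors the expression fraction limits", {
  sp <- mini_panel()
  tr <- sp$truth
  # expression_fraction = 0: nothing validates
  cfg0 <- synthetic_config(seed = 31, expression_fraction = 0)
  sp0 <- generate_strain_panel(cfg0)
  ev0 <- generate_expression_evidence(sp0$truth, seed = 4)
  pl0 <- sp0$truth$placements
  coding0 <- pl0[pl0$strain == sp0$truth$focal_strain &
                   pl0$class %in% c("core", "novel", "dubious"), ]
  es0 <- evidence_set(coding0$gene_id, ev0$alignments, ev0$counts,
                      ev0$peptides, ev0$proteome)
  expect_false(any(es0$transcriptome_flag | es0$fpkm_flag |
                     es0$protein_flag))
  # expression_fraction = 1: no gene lacks evidence among nondubious
  cfg1 <- synthetic_config(seed = 32, expression_fraction = 1)
  sp1 <- generate_strain_panel(cfg1)
  ev1 <- generate_expression_evidence(sp1$truth, seed = 5)
  pl1 <- sp1$truth$placements
  coding1 <- pl1[pl1$strain == sp1$truth$focal_strain &
                   pl1$class %in% c("core", "novel"), ]
  es1 <- evidence_set(coding1$gene_id, ev1$alignments, ev1$counts,
                      ev1$peptides, ev1$proteome)
  vp <- venn_partition(es1, "all")
  expect_equal(vp$no_evidence, 0L)
})

test_that("emitted FASTA and GFF3 round-trip the planted coordinates", {
  sp <- mini_panel()
  tr <- sp$truth
  focal <- tr$focal_strain
  d <- withr::local_tempdir()
  write_strain_panel(sp, d)
  g <- read_genome_fasta(file.path(d, paste0(focal, ".fasta")))
  expect_identical(as.character(g), as.character(sp$panel[[focal]]))

  set <- annotation_set(focal, placement_models(tr, focal), "truth")
  gff <- file.path(d, "focal.gff3")
  write_annotation_gff3(set, gff)
  back <- read_annotation_gff3(gff, focal)
  cols <- c("id", "contig", "start", "end", "strand", "status")
  expect_equal(back$models[, cols], set$models[, cols],
               ignore_attr = TRUE)

  # evidence TSV round-trip
  ev <- generate_expression_evidence(tr, seed = 6)
  f <- file.path(d, "counts.tsv")
  write_evidence_tsv(ev$counts, f)
  expect_equal(read_evidence_tsv(f), ev$counts, ignore_attr = TRUE)
})
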