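test_that("N50 matches its definition and the scan oracle", {
  expect_equal(n50(c(10, 5, 3, 2)), 10)
  expect_equal(n50(c(7, 7, 7)), 7)
  set.seed(909)
  for (rep in 1:100) {
    lens <- sample(1:5000, sample(1:30, 1), replace = TRUE)
    expect_equal(n50(lens), n50_scan_oracle(lens))
    # permutation invariance and linear scaling
    expect_equal(n50(lens[sample.int(length(lens))]), n50(lens))
    expect_equal(n50(lens * 3), 3 * n50(lens))
  }
  expect_error(n50(numeric(0)))
})

test_that("subtelomeric classification is inclusive at the 50 kbp boundary", {
  params <- geography_params()   # 50 kbp span
  clen <- c(chrA = 500000)
  mk <- function(s, e) gene_models("g", "chrA", s, e, "+")
  expect_true(subtelomeric_classify(mk(30000, 31000), clen, params))
  expect_false(subtelomeric_classify(mk(249000, 251000), clen, params))
  # nearest-end distance exactly 50,000 (start = 50,001) counts
  expect_true(subtelomeric_classify(mk(50001, 51001), clen, params))
  expect_false(subtelomeric_classify(mk(50002, 51002), clen, params))
  # right end mirrors
  expect_true(subtelomeric_classify(mk(448000, 450000), clen, params))
  expect_error(subtelomeric_classify(mk(1, 10), c(other = 100), params))
})

test_that("cluster detection finds maximal adjacent runs", {
  params <- geography_params(cluster_max_gap = 20000)
  clen <- c(chr1 = 500000, chr2 = 500000)
  models <- gene_models(
    c("n1", "n2", "n3", "far", "lone", "x1"),
    c("chr1", "chr1", "chr1", "chr1", "chr2", "chr1"),
    c(10000, 12000, 14500, 200000, 40000, 13000),
    c(11000, 13000, 15500, 201000, 41000, 13400),
    "+")
  cl <- detect_gene_clusters(c("n1", "n2", "n3", "far", "lone"),
                             models, clen, params)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$members, "n1,n2,n3")
  expect_true(cl$subtelomeric)
  # two genes with a gap beyond the maximum never cluster
  none <- detect_gene_clusters(
    c("n1", "far"), models, clen, params)
  expect_equal(nrow(none), 0L)
  # singletons never cluster
  expect_equal(nrow(detect_gene_clusters("lone", models, clen, params)),
               0L)
  # planted clusters in the synthetic panel come out together
  sp <- default_panel()
  tr <- sp$truth
  focal_models <- placement_models(tr, tr$focal_strain)
  sc_params <- geography_params(
    subtelomere_span = tr$config$subtelomere_span,
    cluster_max_gap = 2000)
  clens <- stats::setNames(Biostrings::width(sp$panel[[tr$focal_strain]]),
                           names(sp$panel[[tr$focal_strain]]))
  novel <- tr$gene_info$gene_id[tr$gene_info$class == "novel"]
  calls <- detect_gene_clusters(novel, focal_models, clens, sc_params)
  planted <- tr$gene_info$gene_id[!is.na(tr$gene_info$cluster_id)]
  joint <- vapply(calls$members, function(s)
    all(planted %in% strsplit(s, ",")[[1]]), logical(1))
  expect_true(any(joint))
})

test_that("missing-gene detection replays planted absences", {
  sc <- scoring_scheme()
  sp <- mini_panel()
  tr <- sp$truth
  focal <- tr$focal_strain
  focal_set <- annotation_set(focal, placement_models(tr, focal))
  params <- geography_params(subtelomere_span = tr$config$subtelomere_span)
  # novel and dubious genes are planted on the focal strain only, so
  # they are absent from the reference genome; core genes are present
  # everywhere (planted pseudogenes are not searched)
  miss <- detect_missing_genes(focal_set, sp$panel[[focal]],
                               sp$panel[["ref"]], sc, params)
  absent <- tr$gene_info$gene_id[tr$gene_info$class %in%
                                   c("novel", "dubious")]
  expect_setequal(miss$gene_id, absent)
  # against itself nothing is missing
  self <- detect_missing_genes(focal_set, sp$panel[[focal]],
                               sp$panel[[focal]], sc, params)
  expect_equal(nrow(self), 0L)
  # raising the floor only grows the missing set
  higher <- geography_params(
    subtelomere_span = tr$config$subtelomere_span,
    missing_bit_floor = 60)
  miss_hi <- detect_missing_genes(focal_set, sp$panel[[focal]],
                                  sp$panel[["ref"]], sc, higher)
  expect_true(all(miss$gene_id %in% miss_hi$gene_id))
})

test_that("nonsyntenic homologs require reciprocity and broken flanks", {
  sc <- scoring_scheme()
  set.seed(111)
  orf <- function(n) strainpan:::.random_orf(n)
  genes <- replicate(5, orf(45))
  dup <- genes[3]  # gene relocated in genome B
  spacer <- function() random_dna_string(300)
  seq_a <- paste0(spacer(), genes[1], spacer(), genes[2], spacer(),
                  genes[3], spacer(), genes[4], spacer(), genes[5],
                  spacer())
  # genome B: same neighborhood for genes 1,2,4,5 but gene 3's copy
  # moved to a second contig with different neighbors
  extra <- replicate(2, orf(45))
  seq_b1 <- paste0(spacer(), genes[1], spacer(), genes[2], spacer(),
                   genes[4], spacer(), genes[5], spacer())
  seq_b2 <- paste0(spacer(), extra[1], spacer(), dup, spacer(),
                   extra[2], spacer())
  find <- function(seq, orfs, contig) {
    starts <- vapply(orfs, function(o) as.integer(regexpr(o, seq, fixed = TRUE)),
                     integer(1))
    gene_models(names(orfs), contig, starts,
                starts + nchar(orfs) - 1L, "+")
  }
  ga <- Biostrings::DNAStringSet(c(c1 = seq_a))
  gb <- Biostrings::DNAStringSet(c(c1 = seq_b1, c2 = seq_b2))
  # orthologs share ids across genomes, as a liftover would assign
  names(genes) <- paste0("g", 1:5)
  ma <- find(seq_a, genes, "c1")
  mb1 <- find(seq_b1, genes[c(1, 2, 4, 5)], "c1")
  mb2 <- find(seq_b2, stats::setNames(c(extra[1], dup, extra[2]),
                                      c("x1", "g3", "x2")), "c2")
  set_a <- annotation_set("A", ma)
  set_b <- annotation_set("B", rbind(mb1, mb2))
  pairs <- find_nonsyntenic_homologs(set_a, set_b, ga, gb, sc,
                                     geography_params())
  expect_true(any(pairs$gene_a == "g3" & pairs$gene_b == "g3"))
  # genes in conserved neighborhoods are not reported
  expect_false(any(pairs$gene_a %in% c("g1", "g2", "g4", "g5")))
})

test_that("reference-guided scaffolding restores a shredded chromosome", {
  sp <- mini_panel()
  chr <- sp$panel[["ref"]][["chr01"]]
  L <- length(chr)
  cuts <- floor(seq(1, L + 1, length.out = 5))
  parts <- lapply(1:4, function(i)
    Biostrings::subseq(chr, cuts[i], cuts[i + 1] - 1))
  parts[[2]] <- Biostrings::reverseComplement(parts[[2]])
  shuffled <- Biostrings::DNAStringSet(parts[c(4, 2, 1, 3)])
  names(shuffled) <- paste0("ctg", 1:4)
  ref <- Biostrings::DNAStringSet(c(chr01 = as.character(chr)))
  plc <- reference_guided_scaffold(shuffled, ref)
  expect_equal(plc$order[match(paste0("ctg", c(3, 2, 4, 1)),
                               plc$contig)], 1:4)
  expect_equal(plc$strand[plc$contig == "ctg2"], "-")
  expect_true(all(plc$strand[plc$contig != "ctg2"] == "+"))
  # the unshuffled genome is the identity placement
  whole <- reference_guided_scaffold(ref, ref)
  expect_equal(whole$chrom, "chr01")
  expect_equal(whole$order, 1L)
  expect_equal(whole$strand, "+")
  # a random-DNA contig stays unplaced, never dropped
  set.seed(222)
  noise <- Biostrings::DNAStringSet(c(junk = random_dna_string(3000)))
  mixed <- c(shuffled, noise)
  plc2 <- reference_guided_scaffold(mixed, ref)
  expect_true("junk" %in% plc2$contig)
  expect_true(is.na(plc2$chrom[plc2$contig == "junk"]))
})
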