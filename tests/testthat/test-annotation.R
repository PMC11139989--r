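# Evidence chain: motif overlap, perturbed-gene concordance, variants in
# enhancers, and their composition.

test_that("motif counts match the overlap oracle and keep zero-hit enhancers", {
  net <- tiny_network()
  sites <- data.frame(
    chrom = "chr1",
    start = c(150, 200, 450, 1500, 8000),
    end   = c(160, 260, 600, 1600, 8100),
    name = sprintf("m%d", 1:5), stringsAsFactors = FALSE)
  ann <- annotate_motifs(net, c("e1", "e2", "e3"), sites)
  expect_equal(ann$motif_count, c(3L, 1L, 0L))
  expect_equal(ann$motifs[[1]], c("m1", "m2", "m3"))
  expect_equal(ann$enhancer_id[ann$motif_count == 0], "e3")

  set.seed(13)
  enh <- random_intervals(40, chroms = "chr1")
  rnet <- regulatory_network(
    data.frame(enhancer_id = enh$name, chrom = enh$chrom, start = enh$start,
               end = enh$end, stringsAsFactors = FALSE),
    stats::setNames(replicate(40, "g", simplify = FALSE), enh$name))
  msites <- random_intervals(150, chroms = "chr1")
  ann2 <- annotate_motifs(rnet, enh$name, msites)
  oracle <- brute_force_overlap(enh, msites)
  counts <- table(factor(oracle$query_idx, levels = 1:40))
  expect_equal(ann2$motif_count, as.integer(counts))
})

test_that("concordant genes are plain set intersections", {
  net <- tiny_network()
  conc <- concordant_perturbed_genes(net, c("e1", "e2"), c("gB", "gD", "gZ"))
  expect_equal(conc$e1, "gB")
  expect_equal(conc$e2, c("gB", "gD"))
  expect_equal(concordant_perturbed_genes(net, "e3", c("gB"))$e3, character(0))
  # perturbed == E_G: everything concordant
  expect_equal(concordant_perturbed_genes(net, "e1", c("gA", "gB"))$e1,
               c("gA", "gB"))
  expect_error(concordant_perturbed_genes(net, "nope", "gA"), "not in network")
})

test_that("variant assignment is strict on q and inclusive on the printed range", {
  net <- regulatory_network(
    data.frame(enhancer_id = "enh_ada", chrom = "chr20",
               start = 44640671, end = 44653156, stringsAsFactors = FALSE),
    list(enh_ada = c("ADA", "OTHER")))
  variants <- data.frame(
    variant_id = c("v_in", "v_q", "v_out"),
    chrom = "chr20",
    pos = c(44642751, 44642751, 44653157),
    gene = "ADA",
    qvalue = c(0.01, 0.05, 0.01), stringsAsFactors = FALSE)
  vin <- variants_in_enhancers(net, "enh_ada", variants)
  expect_equal(vin$enh_ada$variant_id, "v_in")  # q = 0.05 exactly is filtered out

  # raising the q threshold never loses variants (monotonicity)
  for (q in c(0.01, 0.05, 0.2, 1)) {
    v1 <- variants_in_enhancers(net, "enh_ada", variants, q_threshold = q)
    v2 <- variants_in_enhancers(net, "enh_ada", variants, q_threshold = q + 0.2)
    expect_true(all(v1$enh_ada$variant_id %in% v2$enh_ada$variant_id))
  }
})

test_that("evidence chain composes the three primitives exactly", {
  set.seed(23)
  for (seed in 1:5) {
    set.seed(seed)
    n_enh <- 50
    enh <- random_intervals(n_enh, chroms = "chr1", max_pos = 50000)
    genes <- sprintf("g%02d", 1:40)
    tg <- stats::setNames(
      replicate(n_enh, sample(genes, 3), simplify = FALSE), enh$name)
    net <- regulatory_network(
      data.frame(enhancer_id = enh$name, chrom = enh$chrom, start = enh$start,
                 end = enh$end, stringsAsFactors = FALSE), tg)
    perturbed <- sample(genes, 10)
    variants <- data.frame(
      variant_id = sprintf("v%03d", 1:60),
      chrom = "chr1",
      pos = sample.int(50000, 60),
      gene = sample(genes, 60, replace = TRUE),
      qvalue = runif(60), stringsAsFactors = FALSE)
    sites <- random_intervals(80, chroms = "chr1", max_pos = 50000)
    called <- sample(enh$name, 20)

    chain <- build_evidence_chain(net, called, perturbed, variants, sites)

    # independent set-logic oracle built from first principles
    for (k in seq_along(called)) {
      id <- called[k]
      row <- enh[enh$name == id, ]
      conc_oracle <- sort(intersect(tg[[id]], perturbed))
      vin_oracle <- variants$variant_id[
        variants$qvalue < 0.05 &
          variants$pos > row$start & variants$pos <= row$end]
      cons_oracle <- variants$variant_id[
        variants$variant_id %in% vin_oracle &
          variants$gene %in% conc_oracle]
      rec <- chain$records[chain$records$enhancer_id == id, ]
      expect_identical(rec$concordant_genes[[1]], conc_oracle)
      expect_setequal(rec$variant_ids[[1]], vin_oracle)
      expect_setequal(rec$consistent_variant_ids[[1]], cons_oracle)
      # every consistent variant's gene is concordant and perturbed
      cg <- variants$gene[variants$variant_id %in% cons_oracle]
      expect_true(all(cg %in% conc_oracle) && all(cg %in% perturbed))
    }
    # summary tallies equal the oracle-composed counts
    expect_equal(chain$summary$n_with_concordant_gene,
                 sum(vapply(called, function(id)
                   length(intersect(tg[[id]], perturbed)) > 0, logical(1))))
  }
})

test_that("worked variant-in-enhancer examples hold end to end", {
  net <- regulatory_network(
    data.frame(enhancer_id = c("enh_chr20", "enh_chr12"),
               chrom = c("chr20", "chr12"),
               start = c(44640671, 12713281),
               end = c(44653156, 12727320), stringsAsFactors = FALSE),
    list(enh_chr20 = c("ADA", "X1"), enh_chr12 = c("APOLD1", "X2")))
  variants <- data.frame(
    variant_id = c("eqtl_ada", "eqtl_apold1"),
    chrom = c("chr20", "chr12"),
    pos = c(44642751, 12726123),
    gene = c("ADA", "APOLD1"),
    qvalue = 0.01, stringsAsFactors = FALSE)
  chain <- build_evidence_chain(net, c("enh_chr20", "enh_chr12"),
                                perturbed_genes = c("ADA", "APOLD1"), variants)
  expect_equal(chain$records$consistent_variant_ids,
               list("eqtl_ada", "eqtl_apold1"))
  expect_equal(chain$summary$n_with_consistent_variant, 2)
})

test_that("gene-linked tier catches perturbed-gene variants outside enhancers", {
  net <- tiny_network()
  variants <- data.frame(
    variant_id = c("v_body", "v_ns"),
    chrom = "chr1", pos = c(9000, 9100),
    gene = c("gB", "gB"), qvalue = c(0.01, 0.5), stringsAsFactors = FALSE)
  chain <- build_evidence_chain(net, c("e1", "e2"), "gB", variants)
  expect_equal(chain$gene_linked$variant_id, "v_body")
  expect_true(all(lengths(chain$records$variant_ids) == 0))
})

test_that("annotation table writer flattens list columns", {
  net <- tiny_network()
  variants <- data.frame(variant_id = "v1", chrom = "chr1", pos = 150,
                         gene = "gA", qvalue = 0.01, stringsAsFactors = FALSE)
  chain <- build_evidence_chain(net, "e1", "gA", variants)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(chain, path)
  tab <- read.delim(path)
  expect_equal(tab$consistent_variant_ids, "v1")
})
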