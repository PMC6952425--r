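test_that("extend_reads anchors at the 5' end and clips at bounds", {
  r <- make_reads("chr1", c(100L, 500L, 950L), c(150L, 550L, 1000L),
                  c("+", "-", "+"), sizes = c(chr1 = 1000L))
  ext <- extend_reads(r, 200, c(chr1 = 1000L))
  expect_equal(ext$start, c(100L, 350L, 950L))
  expect_equal(ext$end, c(300L, 550L, 1000L)) # third clipped at chrom end
  expect_equal(total_mapped(ext), 3)
  # minus-strand read near the chromosome start clips at zero
  r2 <- make_reads("chr1", 10L, 60L, "-", sizes = c(chr1 = 1000L))
  e2 <- extend_reads(r2, 200, c(chr1 = 1000L))
  expect_equal(e2$start, 0L)
  expect_equal(e2$end, 60L)
})

test_that("bin_density counts a single fragment into exactly its bins", {
  genes <- make_genes(chrom = "chr1", start = 600L, end = 3000L,
                      strand = "+", gene_id = "g1", class = "x",
                      sizes = c(chr1 = 5000L))
  # one 200-bp fragment at [700, 900): overlaps TSS-relative bins
  # [60,120) .. [240,300)  (rel 100..300 from TSS at 600)
  reads <- make_reads("chr1", 700L, 900L, "+", sizes = c(chr1 = 5000L))
  prof <- bin_density(reads, genes, anchor = "tss", flank = 600,
                      bin_size = 60)
  expect_equal(nrow(prof), 20)
  hit <- prof$rel[prof$count == 1]
  expect_equal(hit, c(60, 120, 180, 240))
  expect_true(all(prof$count[!prof$rel %in% hit] == 0))
  expect_equal(prof$density[prof$rel == 60], 1 * 1e9 / (60 * 1))
})

test_that("minus-strand bins run in transcription direction", {
  genes <- make_genes(chrom = "chr1", start = 1000L, end = 4000L,
                      strand = "-", gene_id = "g1", class = "x",
                      sizes = c(chr1 = 5000L))
  # TSS = 3999; a fragment downstream of the TSS in transcription
  # direction sits genomically to the LEFT: [3799, 3899) is rel +100..+200
  reads <- make_reads("chr1", 3799L, 3899L, "-", sizes = c(chr1 = 5000L))
  prof <- bin_density(reads, genes, anchor = "tss")
  hit <- prof$rel[prof$count == 1]
  expect_equal(hit, c(60, 120, 180))
})

test_that("bins beyond chromosome bounds are flagged missing", {
  genes <- make_genes(chrom = "chr1", start = 100L, end = 2500L,
                      strand = "+", gene_id = "g1", class = "x",
                      sizes = c(chr1 = 5000L))
  reads <- make_reads("chr1", 150L, 350L, "+", sizes = c(chr1 = 5000L))
  prof <- bin_density(reads, genes, anchor = "tss")
  expect_true(all(is.na(prof$count[prof$rel < -100])))
  expect_true(all(!is.na(prof$count[prof$rel >= -100])))
})

test_that("binned counts match the brute-force pileup oracle", {
  cfg <- sim_config(chrom_length = 10000, n_genes = 3,
                    min_gene_length = 1200, mean_gene_length = 1500,
                    pause_center = 50, gene_classes = NULL, depth = 500,
                    seed = 4)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  reads <- simulate_reads(sim$genes, cfg, "control", "ip")
  prof <- bin_density(reads, sim$genes, anchor = "tss", flank = 600,
                      bin_size = 60)
  # reconstruct bin genomic coordinates independently
  tss <- ifelse(sim$genes$strand == "+", sim$genes$start,
                sim$genes$end - 1L)
  oracle <- numeric(0)
  for (i in seq_len(nrow(sim$genes))) {
    for (rel in seq(-600, 540, by = 60)) {
      if (sim$genes$strand[i] == "+") {
        b <- data.frame(chrom = "chr1", gstart = tss[i] + rel,
                        gend = tss[i] + rel + 60)
      } else {
        b <- data.frame(chrom = "chr1", gstart = tss[i] - rel - 59,
                        gend = tss[i] - rel + 1)
      }
      oracle <- c(oracle, oracle_bin_counts(as_tibble(reads), b))
    }
  }
  prof_ord <- prof[order(match(prof$gene_id, sim$genes$gene_id), prof$rel), ]
  ok <- !is.na(prof_ord$count)
  expect_equal(prof_ord$count[ok], as.integer(oracle[ok]))
})

test_that("gene-body bins tile the gene into n equal parts", {
  genes <- make_genes(chrom = "chr1", start = 1000L, end = 2000L,
                      strand = "+", gene_id = "g1", class = "x",
                      sizes = c(chr1 = 5000L))
  reads <- make_reads("chr1", 1400L, 1600L, "+", sizes = c(chr1 = 5000L))
  prof <- bin_density(reads, genes, anchor = "genebody", n_body_bins = 100)
  expect_equal(nrow(prof), 100)
  expect_equal(unique(prof$width), 10L)
  expect_equal(prof$rel, as.numeric(0:99))
  expect_equal(which(prof$count == 1) - 1L, 40:59)
  # a minus-strand gene reverses the direction of the percent axis
  genes$strand <- "-"
  prof2 <- bin_density(reads, genes, anchor = "genebody", n_body_bins = 100)
  expect_equal(which(prof2$count == 1) - 1L, 40:59)
})

test_that("density is invariant to duplicating the library", {
  cfg <- small_config(seed = 9)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  reads <- simulate_reads(sim$genes, cfg, "control", "ip")
  doubled <- read_set(bind_rows(as_tibble(reads), as_tibble(reads)),
                      total_mapped = 2 * total_mapped(reads))
  p1 <- bin_density(reads, sim$genes, anchor = "tss")
  p2 <- bin_density(doubled, sim$genes, anchor = "tss")
  expect_equal(p2$density, p1$density)
  expect_equal(p2$count, 2L * p1$count)
})

test_that("fold enrichment of a library against itself is exactly 1", {
  cfg <- small_config(seed = 10)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  reads <- simulate_reads(sim$genes, cfg, "control", "ip")
  prof <- bin_density(reads, sim$genes, anchor = "tss")
  fe <- fold_enrichment(prof, prof)
  expect_true(all(fe$enrichment == 1))
  fe_pg <- fold_enrichment(prof, prof, aggregate = "per_gene")
  expect_true(all(fe_pg$enrichment == 1))
})

test_that("doubling IP density doubles enrichment when pseudocount is 0", {
  genes <- make_genes(chrom = "chr1", start = 600L, end = 3000L,
                      strand = "+", gene_id = "g1", class = "x",
                      sizes = c(chr1 = 5000L))
  reads <- make_reads("chr1", 700L, 900L, "+", sizes = c(chr1 = 5000L))
  # same reads, but the input library declares twice the mapped total, so
  # its densities are exactly half
  input <- read_set(as_tibble(reads), total_mapped = 2)
  p_ip <- bin_density(reads, genes, anchor = "tss")
  p_in <- bin_density(input, genes, anchor = "tss")
  fe <- fold_enrichment(p_ip, p_in, pseudocount = 0)
  covered <- fe$ip_mean > 0
  expect_equal(fe$enrichment[covered], rep(2, sum(covered)))
  expect_true(all(is.nan(fe$enrichment[!covered]))) # 0/0 without guard
  # the default pseudocount turns empty bins into exactly 1
  fe1 <- fold_enrichment(p_ip, p_in, pseudocount = 1)
  expect_true(all(fe1$enrichment[!covered] == 1))
})

test_that("fold_enrichment validates matching profiles and gene sets", {
  cfg <- small_config(seed = 2)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  reads <- simulate_reads(sim$genes, cfg, "control", "ip")
  p1 <- bin_density(reads, sim$genes, anchor = "tss")
  p2 <- bin_density(reads, sim$genes, anchor = "tes")
  expect_error(fold_enrichment(p1, p2), "anchor parameters")
  expect_error(fold_enrichment(p1, p1, genes = "not_a_gene"), "absent")
  sub <- fold_enrichment(p1, p1, genes = sim$genes$gene_id[1:3])
  expect_true(all(sub$n_genes <= 3))
})

test_that("set_mean aggregation averages densities before the ratio", {
  # two genes with different coverage: mean-then-ratio differs from
  # ratio-then-mean, and the implementation must do the former
  genes <- make_genes(chrom = "chr1", start = c(1000L, 5000L),
                      end = c(4000L, 8000L), strand = "+",
                      gene_id = c("g1", "g2"), class = "x",
                      sizes = c(chr1 = 10000L))
  # bin rel=0 counts: ip (2, 1), input (1, 2); both libraries 3 reads
  ip <- make_reads("chr1", c(1000L, 1010L, 5000L), c(1060L, 1070L, 5060L),
                   "+", sizes = c(chr1 = 10000L))
  input <- make_reads("chr1", c(1000L, 5000L, 5010L),
                      c(1060L, 5060L, 5070L), "+",
                      sizes = c(chr1 = 10000L))
  p_ip <- bin_density(ip, genes, anchor = "tss", flank = 60, bin_size = 60)
  p_in <- bin_density(input, genes, anchor = "tss", flank = 60,
                      bin_size = 60)
  fe <- fold_enrichment(p_ip, p_in, pseudocount = 0)
  # mean-then-ratio: (2+1)/2 over (1+2)/2 = 1; ratio-then-mean would be
  # (2/1 + 1/2)/2 = 1.25
  expect_equal(fe$enrichment[fe$rel == 0], 1)
  pg <- fold_enrichment(p_ip, p_in, pseudocount = 0,
                        aggregate = "per_gene")
  expect_equal(mean(pg$enrichment[pg$rel == 0]), 1.25)
})
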