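test_that("simulate_genome places non-overlapping genes with 1-kb gaps", {
  cfg <- small_config()
  sim <- simulate_genome(cfg)
  g <- sim$genes
  expect_equal(nrow(g), 20)
  expect_true(all(g$end - g$start >= cfg$min_gene_length))
  expect_true(all(g$start >= 1000))
  expect_true(all(g$end <= cfg$chrom_length - 1000))
  ord <- g[order(g$start), ]
  expect_true(all(ord$start[-1] - ord$end[-nrow(ord)] >= 1000))
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_equal(sum(g$class == "coact"), 6)
  expect_equal(sum(g$class == "background"), 14)
  expect_equal(nrow(sim$truth), 20)
  expect_true(all(c("mult_control_up", "mult_smk1_up", "de_mutant_vs_wt",
                    "de_smk1_vs_control") %in% names(sim$truth)))
  # coact genes lose half their upstream component under smk1, nothing else
  tr <- sim$truth
  expect_true(all(tr$mult_smk1_up[tr$class == "coact"] == 0.5))
  expect_true(all(tr$mult_smk1_pause == 1))
  expect_true(all(tr$mult_control_up == 1))
})

test_that("simulate_genome is deterministic and sensitive to the seed", {
  a <- simulate_genome(small_config(seed = 7))
  b <- simulate_genome(small_config(seed = 7))
  c <- simulate_genome(small_config(seed = 8))
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$sequence), as.character(b$sequence))
  expect_false(identical(a$genes$start, c$genes$start))
})

test_that("simulate_genome handles zero genes and rejects a too-small genome", {
  empty <- simulate_genome(sim_config(n_genes = 0, chrom_length = 1e4,
                                      gene_classes = NULL))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(
    simulate_genome(sim_config(n_genes = 50, chrom_length = 5e4,
                               gene_classes = NULL)),
    "genome too small")
})

test_that("planted TATA instances sit at -30 +/- 5 on the sense strand", {
  sim <- simulate_genome(small_config(seed = 3))
  planted <- sim$genes[sim$truth$tata_planted, ]
  expect_gt(nrow(planted), 0)
  proms <- promoter_sequences(planted, sim$sequence, c(-60L, 0L))
  # the planted instance starts at -30..-25, i.e. within the sense-strand
  # 60-bp window at offset 31..36 (1-based)
  for (id in names(proms)) {
    s <- as.character(proms[[id]])
    pos <- regexpr("TATAAAAG", s, fixed = TRUE)
    expect_true(pos >= 26 && pos <= 36)
  }
})

test_that("read libraries are deterministic and conserve depth", {
  cfg <- small_config()
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  r1 <- simulate_reads(sim$genes, cfg, "control", "ip")
  r2 <- simulate_reads(sim$genes, cfg, "control", "ip")
  expect_identical(as_tibble(r1), as_tibble(r2))
  # dropping only happens for fragments entirely off-chromosome; with all
  # genes >= 1 kb from the edges, background is the only source and losses
  # are at most a handful
  expect_lte(nrow(r1), cfg$depth)
  expect_gte(nrow(r1), cfg$depth - 10)
  expect_equal(total_mapped(r1), nrow(r1))
  expect_true(all(r1$start >= 0 & r1$end <= cfg$chrom_length))
  expect_true(all(r1$end - r1$start <= cfg$fragment_length))
  # ip and input streams differ, as do conditions
  inp <- simulate_reads(sim$genes, cfg, "control", "input")
  smk <- simulate_reads(sim$genes, cfg, "smk1", "ip")
  expect_false(identical(r1$start, inp$start[seq_len(nrow(r1))]))
  expect_false(identical(nrow(r1) == nrow(smk) && all(r1$start == smk$start),
                         TRUE))
})

test_that("unknown conditions are rejected", {
  cfg <- small_config()
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  expect_error(simulate_reads(sim$genes, cfg, "nonsense", "ip"),
               "unknown condition")
})

test_that("input libraries are background-only and near-uniform", {
  cfg <- small_config()
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  inp <- simulate_reads(sim$genes, cfg, "control", "input")
  # 5' starts should be uniform over the chromosome: chi-square over 10
  # equal windows
  plus <- inp$strand == "+"
  s5 <- ifelse(plus, inp$start, inp$end - 1L)
  cnt <- table(cut(s5, breaks = seq(0, cfg$chrom_length, length.out = 11)))
  expect_gt(suppressWarnings(chisq.test(cnt)$p.value), 0.001)
})

test_that("halved recruitment shows up as the predicted upstream deficit", {
  # closed-form oracle: expected fragment count overlapping the upstream
  # window under each condition, compared to simulated counts within
  # binomial noise
  cfg <- small_config(seed = 11)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  coact <- sim$genes[sim$genes$class == "coact", ]
  win <- 200L # window half-width around the upstream centre
  bins <- do.call(rbind, lapply(seq_len(nrow(coact)), function(i) {
    tss <- if (coact$strand[i] == "+") coact$start[i] else coact$end[i] - 1L
    lo <- cfg$upstream_center - win; hi <- cfg$upstream_center + win
    if (coact$strand[i] == "+") {
      data.frame(chrom = coact$chrom[i], gstart = tss + lo, gend = tss + hi)
    } else {
      data.frame(chrom = coact$chrom[i], gstart = tss - hi + 1L,
                 gend = tss - lo + 1L)
    }
  }))
  for (cond in c("control", "smk1")) {
    rates <- oracle_start_rates(sim$genes, cfg, cond, "ip")
    expected <- oracle_expected_bin_counts(rates, bins, cfg$fragment_length)
    reads <- simulate_reads(sim$genes, cfg, cond, "ip")
    observed <- oracle_bin_counts(as_tibble(reads), bins)
    tot_exp <- sum(expected); tot_obs <- sum(observed)
    expect_lt(abs(tot_obs - tot_exp), 4 * sqrt(tot_exp))
  }
  # and the deficit itself: smk1 expectation is clearly below control
  r_ctl <- oracle_expected_bin_counts(
    oracle_start_rates(sim$genes, cfg, "control", "ip"), bins, 200)
  r_smk <- oracle_expected_bin_counts(
    oracle_start_rates(sim$genes, cfg, "smk1", "ip"), bins, 200)
  expect_lt(sum(r_smk), 0.9 * sum(r_ctl))
})

test_that("simulated DE tables plant effects at the configured power", {
  cfg <- small_config(seed = 5)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  de <- simulate_de_table(sim$truth, cfg)
  expect_setequal(names(de), c("gene_id", "log2fc_mutant_vs_wt",
                               "q_mutant_vs_wt", "log2fc_smk1_vs_control",
                               "q_smk1_vs_control"))
  expect_identical(de, simulate_de_table(sim$truth, cfg))
  planted <- sim$truth$class == "coact"
  # planted log2 fold-changes centred on the configured effects
  expect_lt(abs(mean(de$log2fc_mutant_vs_wt[planted]) - 2), 0.5)
  expect_lt(abs(mean(de$log2fc_smk1_vs_control[planted]) + 2), 0.5)
  expect_lt(abs(mean(de$log2fc_mutant_vs_wt[!planted])), 0.5)
})

test_that("phospho tables validate arguments and are deterministic", {
  expect_error(simulate_phospho_table(n_replicates = 1), "n_replicates")
  expect_error(simulate_phospho_table(n_peptides = 5, n_planted = 6),
               "n_planted")
  a <- simulate_phospho_table(n_peptides = 50, n_planted = 4, seed = 2)
  b <- simulate_phospho_table(n_peptides = 50, n_planted = 4, seed = 2)
  expect_identical(a, b)
  expect_equal(sum(a$truth$planted), 4)
  expect_true(all(grepl("^PLANT_", a$truth$protein_id[a$truth$planted])))
  # effect_fold = 1 plants nothing
  none <- simulate_phospho_table(n_peptides = 50, n_planted = 4,
                                 effect_fold = 1, seed = 2)
  expect_equal(sum(none$truth$planted), 0)
})

test_that("mirroring the genome mirrors the anchored read distribution", {
  # reflect all coordinates through the chromosome midpoint and flip
  # strands: the simulator sees an equivalent study, so anchor-relative 5'
  # start histograms must agree statistically
  cfg <- small_config(seed = 21)
  sim <- simulate_genome(cfg, with_sequence = FALSE)
  g <- sim$genes
  G <- cfg$chrom_length
  mirrored <- g
  mirrored$start <- G - g$end
  mirrored$end <- G - g$start
  mirrored$strand <- ifelse(g$strand == "+", "-", "+")
  attr(mirrored, "chrom_sizes") <- attr(g, "chrom_sizes")

  rel5 <- function(genes, reads) {
    out <- integer(0)
    tss <- polprof::tss_position(genes)
    for (i in seq_len(nrow(genes))) {
      same <- reads$chrom == genes$chrom[i]
      s5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
      rel <- if (genes$strand[i] == "+") s5 - tss[i] else tss[i] - s5
      out <- c(out, rel[same & rel >= -600 & rel < 600 &
                          reads$strand == genes$strand[i]])
    }
    out
  }
  ra <- rel5(g, as_tibble(simulate_reads(g, cfg, "control", "ip")))
  rb <- rel5(mirrored, as_tibble(simulate_reads(mirrored, cfg, "control", "ip")))
  brk <- seq(-600, 600, by = 120)
  tab <- rbind(table(cut(ra, brk)), table(cut(rb, brk)))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})
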