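small_config <- function(seed = 5, ...) {
  generator_config(seed = seed, reads_per_sample = 1500, error_rate = 0,
                   generations = 6, n_haplotypes = 4, n_snps = 6,
                   n_random_indels = 4, ...)
}

test_that("the generator is deterministic under its seed", {
  a <- generate_cage_dataset(small_config(seed = 9))
  b <- generate_cage_dataset(small_config(seed = 9))
  expect_identical(a$amplicon$sequence, b$amplicon$sequence)
  expect_identical(a$samples[[1]]$reads1, b$samples[[1]]$reads1)
  expect_identical(a$samples[[1]]$reads2, b$samples[[1]]$reads2)
  expect_identical(a$spectrum, b$spectrum)
  c <- generate_cage_dataset(small_config(seed = 10))
  expect_false(identical(a$samples[[1]]$reads1, c$samples[[1]]$reads1))
})

test_that("generated references carry a PAM and a usable microhomology pair", {
  for (seed in 1:5) {
    cfg <- generator_config(seed = seed)
    amp <- generate_reference(cfg)
    expect_equal(amp$length, 320)
    expect_equal(substring(amp$sequence, amp$cut_after + 5,
                           amp$cut_after + 6), "GG")
    expect_gte(nrow(enumerate_mmej(amp, min_mh = 2)), 1)
  }
  expect_error(generator_config(seed = 1, amplicon_length = 40),
               "degenerate")
  expect_error(generator_config(1, reads_per_sample = 0))
  expect_error(generator_config(), "seed is mandatory")
})

test_that("haplotype pools are distinct, frequency-normalised and clear of the cut", {
  cfg <- generator_config(seed = 3)
  amp <- generate_reference(cfg)
  pool <- generate_haplotype_pool(amp, cfg)
  expect_equal(nrow(pool$haplotypes), 12)
  expect_false(any(duplicated(pool$haplotypes$haplotype)))
  expect_equal(sum(pool$haplotypes$frequency), 1, tolerance = 1e-12)
  expect_equal(nchar(pool$haplotypes$haplotype[1]), 8)
  expect_true(all(abs(pool$snp_table$position - amp$cut_after) > 30))

  single <- generator_config(seed = 3, n_haplotypes = 1)
  p1 <- generate_haplotype_pool(generate_reference(single), single)
  expect_equal(nrow(p1$haplotypes), 1)
})

test_that("the resistance spectrum mixes MMEJ and random indels as configured", {
  cfg_all_mmej <- generator_config(seed = 4, w_mmej = 1)
  amp <- generate_reference(cfg_all_mmej)
  sp1 <- sample_resistance_spectrum(amp, cfg_all_mmej)
  expect_true(all(sp1$is_mmej))
  expect_true(all(sp1$kind == "deletion"))
  expect_equal(sum(sp1$weight), 1, tolerance = 1e-12)
  expect_equal(sp1$class, ifelse(sp1$frame_class == "in-frame", "R1", "R2"))

  # with w_mmej = 0 and geometric lengths roughly a third of distinct random
  # indel alleles are in-frame (the mod-3 argument; label deduplication
  # saturates the shortest lengths, so the band is loose)
  cfg_rand <- generator_config(seed = 6, w_mmej = 0, n_random_indels = 3000)
  sp0 <- sample_resistance_spectrum(generate_reference(cfg_rand), cfg_rand)
  got <- mean(sp0$frame_class == "in-frame")
  expect_gt(got, 0.2)
  expect_lt(got, 0.5)
  expect_false(any(sp0$is_mmej))
})

test_that("error-free single-generation data round-trips through the pipeline exactly", {
  cfg <- small_config(seed = 12)
  ds <- generate_cage_dataset(cfg)
  s <- ds$samples[[1]]
  res <- run_amplicon_pipeline(ds$amplicon, reads1 = s$reads1,
                               reads2 = s$reads2,
                               snp_table = ds$snp_table, pool = ds$pool,
                               min_reads = 1, threshold = 0)
  truth <- s$truth_alleles
  # with zero sequencing error every planted allele is recovered at exactly
  # its sampled frequency
  drawn <- tapply(s$provenance$allele, s$provenance$allele, length)
  for (lab in names(drawn)) {
    row <- res$alleles[res$alleles$label == lab, ]
    expect_equal(nrow(row), 1)
    expect_equal(row$count, unname(drawn[lab]))
  }
  expect_equal(sum(res$alleles$count), length(s$reads1))
  expect_equal(res$log$n_merge_failures, 0)

  # frame classes agree with the planted spectrum
  sp <- ds$spectrum
  for (i in seq_len(nrow(sp))) {
    row <- res$alleles[res$alleles$label == sp$label[i], ]
    if (nrow(row)) expect_equal(row$frame_class, sp$frame_class[i])
  }
})

test_that("planted chimeric haplotypes are detected as novel, clean data yield none", {
  cfg0 <- small_config(seed = 13, focal_haplotype_count = 3)
  ds0 <- generate_cage_dataset(cfg0)
  s0 <- ds0$samples[[1]]
  res0 <- run_amplicon_pipeline(ds0$amplicon, reads1 = s0$reads1,
                                reads2 = s0$reads2,
                                snp_table = ds0$snp_table, pool = ds0$pool,
                                min_reads = 1, threshold = 0)
  expect_equal(sum(res0$haplotypes$novel), 0)

  cfg1 <- small_config(seed = 13, focal_haplotype_count = 3,
                       plant_chimeras = TRUE, chimera_fraction = 0.2)
  ds1 <- generate_cage_dataset(cfg1)
  s1 <- ds1$samples[[1]]
  expect_true(any(s1$truth_haplotypes$novel))
  aligned <- align_collapsed(collapse_reads(
    merge_read_pairs(s1$reads1, s1$reads2)$sequence, min_reads = 1),
    ds1$amplicon)
  focal <- ds1$spectrum$label[which.max(ds1$spectrum$weight *
                                          (ds1$spectrum$class == "R1"))]
  haps <- assign_haplotypes(aligned, focal, ds1$snp_table, ds1$pool)
  expect_gte(sum(haps$novel), 1)
})

test_that("dataset files are written as plain text with matching read counts", {
  outdir <- withr::local_tempdir()
  ds <- generate_cage_dataset(small_config(seed = 14), outdir = outdir)
  expect_true(file.exists(file.path(outdir, "amplicon.fasta")))
  expect_true(file.exists(file.path(outdir, "g6_R1.fastq")))
  fq <- read_fastq(file.path(outdir, "g6_R1.fastq"))
  expect_equal(nrow(fq), length(ds$samples[[1]]$reads1))
  expect_equal(fq$sequence, ds$samples[[1]]$reads1)
  amp2 <- read_amplicon_fasta(file.path(outdir, "amplicon.fasta"),
                              cut_after = 208)
  expect_equal(amp2$sequence, ds$amplicon$sequence)
  panel <- read_snp_panel(file.path(outdir, "snp_panel.tsv"))
  expect_equal(panel$position, ds$snp_table$position)
  pool <- read_haplotype_pool(file.path(outdir, "haplotype_pool.tsv"))
  expect_equal(pool$haplotype, ds$pool$haplotype)
})

test_that("truth in-frame mass among resistant alleles equals the model's R1 share", {
  ds <- generate_cage_dataset(small_config(seed = 16))
  s <- ds$samples[[1]]
  row <- ds$trajectory[ds$trajectory$generation == s$generation, ]
  truth <- s$truth_alleles
  res <- truth[truth$label != "REF", ]
  inframe <- sum(res$frequency[res$class == "R1"])
  expect_equal(inframe / sum(res$frequency),
               row$nondrive_R1 / (row$nondrive_R1 + row$nondrive_R2),
               tolerance = 1e-12)
})

test_that("truth frequencies are normalised and reads trace back to alleles", {
  ds <- generate_cage_dataset(small_config(seed = 15))
  s <- ds$samples[[1]]
  expect_equal(sum(s$truth_alleles$frequency), 1, tolerance = 1e-9)
  expect_equal(nrow(s$provenance), length(s$reads1))
  expect_true(all(s$provenance$allele %in%
                    c("REF", ds$spectrum$label)))
})
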