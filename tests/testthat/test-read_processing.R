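# small end-to-end fixture shared across processing tests
proc_fixture <- function(n_targets = 4L, depth_mol = 1L, depth_reads = 4L,
                         error_rate = 0, n_snv = 0L, seed = 101L,
                         het_frac = 0.5) {
  tg <- toy_targets(n_targets)
  spec <- genome_spec(c(chr1 = 6000L), n_snv = n_snv, het_frac = het_frac,
                      variant_regions = tg[, c("contig", "start", "end")],
                      seed = seed)
  g <- generate_genome(spec)
  panel <- design_panel(g$reference, tg)
  cap <- simulate_capture(g, panel,
                          capture_model(p0 = 1, depth = depth_mol, seed = 2))
  tp <- amplify_rpe(cap, error_rate = error_rate, seed = 3)
  rd <- generate_reads(tp, depth = depth_reads, seed = 4)
  list(genome = g, panel = panel, captures = cap, templates = tp, reads = rd)
}

test_that("demultiplexing routes pairs by index within the mismatch budget", {
  fx <- proc_fixture(1L, depth_reads = 1L)
  tab <- data.frame(sample = c("s1", "s2"),
                    index = c("ACGTAC", "TGCATG"), stringsAsFactors = FALSE)
  dm <- demultiplex(fx$reads, tab, max_mismatch = 0L)
  expect_equal(length(dm$s1$r1), length(fx$reads$r1))
  expect_equal(length(dm$s2$r1), 0L)
  expect_equal(length(dm$undetermined$r1), 0L)
  # two mismatches exceed a zero budget
  tab2 <- data.frame(sample = "s1", index = "ACGGGC")
  dm2 <- demultiplex(fx$reads, tab2, max_mismatch = 0L)
  expect_equal(length(dm2$s1$r1), 0L)
  expect_equal(length(dm2$undetermined$r1), length(fx$reads$r1))
  expect_equal(length(demultiplex(fx$reads, tab2, 2L)$s1$r1),
               length(fx$reads$r1))
  # ambiguity: two samples within the budget of the observed index
  tab3 <- data.frame(sample = c("s1", "s2"), index = c("ACGTAA", "ACGTAT"))
  dm3 <- demultiplex(fx$reads, tab3, max_mismatch = 1L)
  expect_equal(length(dm3$undetermined$r1), length(fx$reads$r1))
  expect_error(demultiplex(fx$reads, data.frame(sample = c("a", "b"),
                                                index = c("AAAAAA", "AAAAAA"))),
               "duplicate")
})

test_that("noiseless classification recovers every read's amplicon and PCR group", {
  fx <- proc_fixture(4L, depth_reads = 2L)
  asg <- classify_reads(fx$reads, fx$panel$references, seed = 5)
  expect_true(all(asg$status == "assigned"))
  tr <- truth_from_read_ids(asg$id, fx$captures)
  expect_true(all(asg$amplicon == tr$amplicon_true))
  expect_true(all(asg$group == tr$pcr))
  expect_true(all(asg$mapq == 60L))
  expect_true(all(asg$evalue <= 1e-6))
  # matched intervals are on-amplicon and half-open
  m <- fx$panel$references$meta
  expect_true(all(asg$amp_start >= 0))
  expect_true(all(asg$amp_end <= m$amplicon_len[match(asg$amplicon, m$id)]))
  expect_true(all(asg$amp_end > asg$amp_start))
})

test_that("linker/adaptor-only reads are discarded at the insert filter", {
  fx <- proc_fixture(2L, depth_reads = 1L)
  ad <- default_adaptors()
  junk <- paste0(ad$P5, ad$linker_F)  # no captured sequence at all
  mk <- function(s) {
    x <- Biostrings::DNAStringSet(s); names(x) <- "junk:idx=ACGTAC"
    Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(strrep("I", nchar(s))))
  }
  rd <- list(r1 = mk(junk), r2 = mk(revcomp(junk)))
  asg <- classify_reads(rd, fx$panel$references, seed = 5)
  expect_true(all(asg$status == "stage1_fail"))
  expect_true(all(asg$group == "unassigned"))
})

test_that("score ties are broken by a seeded random draw, evenly across seeds", {
  # a reference with the same target sequence at two loci gives two amplicons
  # the read cannot distinguish
  base <- toy_reference(seed = 55)
  seg <- substr(base[["chr1"]], 1001L, 1400L)
  s <- base[["chr1"]]
  substr(s, 3001L, 3400L) <- seg
  ref <- c(chr1 = s)
  tg <- data.frame(contig = "chr1", start = c(1100L, 3100L),
                   end = c(1280L, 3280L), name = c("dupA", "dupB"))
  panel <- design_panel(ref, tg)
  skip_if_not(length(panel$designs) == 2L)
  rd_seq <- substr(seg, 120L, 250L)
  mk <- function(s) {
    x <- Biostrings::DNAStringSet(s); names(x) <- "r:idx=ACGTAC"
    Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(strrep("I", nchar(s))))
  }
  rd <- list(r1 = mk(rd_seq), r2 = mk(revcomp(rd_seq)))
  picks <- vapply(1:200, function(sd)
    classify_reads(rd, panel$references, seed = sd)$amplicon[1L], "")
  expect_setequal(unique(picks), c("dupA", "dupB"))
  # ~50/50 within 4 binomial sigma
  expect_lt(abs(mean(picks == "dupA") - 0.5), 4 * sqrt(0.25 / 200))
  # ties carry zero mapping confidence
  asg <- classify_reads(rd, panel$references, seed = 1)
  expect_true(all(asg$mapq == 0L))
  # fixed seed: deterministic
  expect_identical(classify_reads(rd, panel$references, seed = 7)$amplicon,
                   classify_reads(rd, panel$references, seed = 7)$amplicon)
})

test_that("group splitting conserves pairs and keeps 3-nt singleton placeholders", {
  fx <- proc_fixture(3L, depth_reads = 2L)
  asg <- classify_reads(fx$reads, fx$panel$references, seed = 5)
  gs <- split_groups(asg, fx$reads)
  n_in <- length(fx$reads$r1)
  expect_equal(gs$stats$pairs + gs$stats$singletons -
                 gs$stats$cross_amplicon + gs$stats$dropped, n_in)
  expect_equal(gs$stats$singletons, 0L)
  expect_equal(length(gs$A$r1) + length(gs$B$r1), n_in)
  expect_equal(length(gs$A$r1), length(gs$A$r2))
  # corrupt one mate-2 read so it fails the filter: its slot shrinks to the
  # first three nucleotides of the original mate
  r2 <- as.character(fx$reads$r2)
  r2[5] <- strrep("AC", nchar(r2[5]) / 2)  # same length, unmappable content
  x <- Biostrings::DNAStringSet(r2); names(x) <- names(fx$reads$r2)
  reads2 <- list(r1 = fx$reads$r1,
                 r2 = Biostrings::QualityScaledDNAStringSet(
                   x, Biostrings::quality(fx$reads$r2)))
  asg2 <- classify_reads(reads2, fx$panel$references, seed = 5)
  gs2 <- split_groups(asg2, reads2)
  expect_equal(gs2$stats$singletons, 1L)
  g <- asg2$group[asg2$id == names(fx$reads$r1)[5] & asg2$mate == 1L]
  ph <- as.character(gs2[[g]]$r2[names(gs2[[g]]$r2) == names(fx$reads$r1)[5]])
  expect_equal(unname(nchar(ph)), 3L)
  expect_identical(unname(ph), "ACA")
})

test_that("empty input splits into four empty read sets", {
  fx <- proc_fixture(1L, depth_reads = 1L)
  empty <- list(r1 = fx$reads$r1[0], r2 = fx$reads$r2[0])
  asg <- classify_reads(empty, fx$panel$references, seed = 1)
  expect_equal(nrow(asg), 0L)
  gs <- split_groups(asg, empty)
  expect_equal(length(gs$A$r1) + length(gs$A$r2) +
                 length(gs$B$r1) + length(gs$B$r2), 0L)
})

test_that("coverage counts reads by midpoint and masks low-quality bases", {
  fx <- proc_fixture(2L, depth_reads = 1L)
  asg <- classify_reads(fx$reads, fx$panel$references, seed = 5)
  cov <- compute_coverage(asg, fx$reads, fx$panel$references)
  # noiseless: depth inside each insert follows read geometry; A = assigned
  # midpoint-in-insert reads
  expect_equal(sum(cov$counts$count),
               sum(asg$status == "assigned"))
  for (a in names(cov$depth)) expect_true(all(cov$depth[[a]] >= 1))
  # base-quality masking removes bases from depth but reads still count
  lowq <- generate_reads(fx$templates, q0 = 10L, seed = 4)
  asg_l <- classify_reads(lowq, fx$panel$references, seed = 5)
  cov_l <- compute_coverage(asg_l, lowq, fx$panel$references, baseq_min = 20L)
  expect_true(all(unlist(cov_l$depth) == 0))
  expect_equal(sum(cov_l$counts$count), sum(asg_l$status == "assigned"))
  # mapping-score filtering removes reads entirely
  cov_m <- compute_coverage(asg, fx$reads, fx$panel$references,
                            mapq_min = 70L)
  expect_equal(sum(cov_m$counts$count), 0L)
  bad <- asg; bad$amplicon[1] <- "nonesuch"
  expect_error(compute_coverage(bad, fx$reads, fx$panel$references),
               "unknown amplicon")
})

test_that("tiled amplicons exclude their overlap columns from depth and counts", {
  ref <- setNames(rand_dna(9000, seed = 88), "chr1")
  tg <- data.frame(contig = "chr1", start = 2000L, end = 2700L, name = "big")
  panel <- design_panel(ref, tg)
  skip_if_not(length(panel$designs) == 2L)
  g <- generate_genome(genome_spec(c(chr1 = 9000L), seed = 88L))
  cap <- simulate_capture(g, panel, capture_model(p0 = 1, depth = 1, seed = 2))
  tp <- amplify_rpe(cap, seed = 3)
  rd <- generate_reads(tp, r1_len = 250L, r2_len = 250L, seed = 4)
  asg <- classify_reads(rd, panel$references, seed = 5)
  cov <- compute_coverage(asg, rd, panel$references)
  refs <- panel$references
  ov <- intersect(seq(refs$targets$start[1], refs$targets$end[1] - 1L),
                  seq(refs$targets$start[2], refs$targets$end[2] - 1L))
  expect_gt(length(ov), 0L)
  for (i in 1:2) {
    cols <- ov - refs$targets$start[i]
    expect_true(all(is.na(cov$depth[[refs$targets$name[i]]][cols + 1L])))
  }
})

test_that("the genotyper applies depth and allele-fraction thresholds", {
  # hand-built pileup: one amplicon, insert of 4 bases
  refs <- list(
    amplicons = c(a1 = paste0(strrep("G", 26), "ACGT", strrep("G", 29))),
    inserts = c(a1 = "ACGT"),
    targets = data.frame(contig = "chr1", start = 100L, end = 104L,
                         name = "a1", stringsAsFactors = FALSE),
    insert_offset = c(a1 = 26L),
    meta = data.frame(id = "a1"))
  class(refs) <- "clpp_panel_refs"
  al <- matrix(0L, 4L, 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
  al["A", 1] <- 30L                      # 30 reads, all ref: no call
  al["C", 2] <- 21L; al["T", 2] <- 19L   # 40 reads, 19 alt: het (0.475)
  al["G", 3] <- 30L                      # hom-ref at its own position: no call
  al["A", 4] <- 12L                      # depth 12 < 20: no call
  cov <- structure(list(
    depth = list(a1 = colSums(al)),
    alleles = list(a1 = al),
    indels = data.frame(amplicon = character(0), insert_pos = integer(0),
                        type = character(0), seq = character(0)),
    counts = data.frame(), excluded = list(a1 = integer(0))),
    class = "clpp_coverage")
  calls <- call_variants(cov, refs, min_depth = 20L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$genotype, "het")
  expect_equal(calls$pos, 101L)
  expect_equal(calls$alt, "T")
  # 30/30 alternate reads: hom
  al2 <- al; al2["A", 1] <- 0L; al2["T", 1] <- 30L
  cov$alleles$a1 <- al2; cov$depth$a1 <- colSums(al2)
  calls2 <- call_variants(cov, refs, min_depth = 20L)
  expect_equal(calls2$genotype[calls2$pos == 100L], "hom")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls2, vcf, contig_lengths = c(chr1 = 1000L))
  lines <- readLines(vcf)
  expect_equal(sum(!startsWith(lines, "#")), nrow(calls2))
  expect_true(any(grepl("\t101\t", lines)))  # VCF positions are 1-based
})

test_that("planted SNVs at adequate depth are recovered with high concordance", {
  fx <- proc_fixture(4L, depth_mol = 3L, depth_reads = 4L,
                     error_rate = 0.002, n_snv = 6L, seed = 202L)
  asg <- classify_reads(fx$reads, fx$panel$references, seed = 5)
  cov <- compute_coverage(asg, fx$reads, fx$panel$references)
  calls <- call_variants(cov, fx$panel$references)
  cc <- genotype_concordance(calls, fx$genome$variants, cov,
                             fx$panel$references)
  expect_gte(cc$n_eval, 4L)
  expect_gte(cc$concordance, 99)
})

test_that("uniformity windows follow the exhaustive sweep oracle", {
  expect_equal(uniformity_fraction(c(10, 20, 400, 600), 50), 0.75)
  expect_equal(uniformity_fraction(rep(7, 10), 50), 1)
  expect_equal(uniformity_fraction(c(1, 1000), 50), 0.5)
  expect_error(uniformity_fraction(c(1, 2), 1), "width")
})

test_that("metrics report perfect specificity and concordance on noiseless input", {
  fx <- proc_fixture(3L, depth_mol = 3L, depth_reads = 3L, n_snv = 3L,
                     seed = 17L)
  asg <- classify_reads(fx$reads, fx$panel$references, seed = 5)
  cov <- compute_coverage(asg, fx$reads, fx$panel$references)
  calls <- call_variants(cov, fx$panel$references)
  tr <- truth_from_read_ids(asg$id, fx$captures)
  m <- capture_metrics(cov, asg, fx$panel$references, calls = calls,
                       truth_variants = fx$genome$variants, truth_reads = tr,
                       other_counts = setNames(
                         tapply(cov$counts$count, cov$counts$amplicon, sum),
                         sort(unique(cov$counts$amplicon))))
  expect_equal(m$specificity, 100)
  expect_equal(m$concordance, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$reproducibility_spearman, 1)
  expect_true(m$uniformity_50fold >= m$uniformity_100fold - 100)
})
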