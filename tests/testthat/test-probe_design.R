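ref1 <- toy_reference(seed = 101)

test_that("select_arms slices the reference exactly flanking the target", {
  tgt <- genomic_interval("chr1", 100L, 300L, "t")
  arms <- select_arms(ref1, tgt, arm_len = 25L)
  skip_if_not(arms$status == "ok")
  expect_identical(arms$arm_up, substr(ref1[["chr1"]], 76L, 100L))
  expect_identical(arms$arm_down, substr(ref1[["chr1"]], 301L, 325L))
  expect_equal(arms$arm_up_iv$start, 75L)
  expect_equal(arms$arm_down_iv$end, 325L)
})

test_that("select_arms enforces arm-length bounds and flank availability", {
  tgt <- genomic_interval("chr1", 100L, 300L)
  expect_error(select_arms(ref1, tgt, arm_len = 17L), "18")
  expect_error(select_arms(ref1, tgt, arm_len = 29L), "28")
  near_edge <- genomic_interval("chr1", 10L, 200L)
  expect_identical(select_arms(ref1, near_edge, 25L)$status, "edge_too_close")
})

test_that("arms containing an undodgeable internal site fail the design", {
  ref <- ref1
  # plant an MlyI site 8 bases upstream of the target start: every candidate
  # arm length (18-28) contains it
  s <- ref[["chr1"]]
  substr(s, 493L, 497L) <- "GAGTC"
  ref[["chr1"]] <- s
  res <- select_arms(ref, genomic_interval("chr1", 500L, 700L), 25L)
  expect_identical(res$status, "arm_has_site")
})

test_that("precursor primers and lengths follow the designed layout", {
  tgt <- genomic_interval("chr1", 900L, 1080L, "t")
  arms <- select_arms(ref1, tgt, arm_len = 25L)
  skip_if_not(arms$status == "ok")
  bb <- default_backbone()
  pre <- build_precursor(arms, bb)
  expect_equal(nchar(pre$forward_primer), 60L)   # 10 + 25 + 25
  expect_equal(nchar(pre$reverse_primer), 60L)   # 7 + 25 + 28
  expect_equal(nchar(pre$precursor$top), 347L)   # 10 + 25 + 280 + 25 + 7
  # exactly one site per enzyme
  for (e in default_enzymes())
    expect_equal(nrow(find_sites(pre$precursor$top, e)), 1L)
  # the precursor is the simulated PCR product of the two primers
  expect_true(startsWith(pre$precursor$top, pre$forward_primer))
  expect_true(endsWith(pre$precursor$top, revcomp(pre$reverse_primer)))
})

test_that("a backbone carrying a recognition site is rejected", {
  tgt <- genomic_interval("chr1", 900L, 1080L, "t")
  arms <- select_arms(ref1, tgt, arm_len = 25L)
  skip_if_not(arms$status == "ok")
  bad <- paste0(substr(default_backbone(), 1, 100), "GAGTC",
                substr(default_backbone(), 106, 280))
  expect_error(build_precursor(arms, bad), "MlyI")
})

test_that("functional probe is the trimmed middle fragment with arm termini", {
  bb <- default_backbone()
  for (alen in c(20L, 25L)) {
    tgt <- genomic_interval("chr1", 900L, 1080L, "t")
    arms <- select_arms(ref1, tgt, arm_len = alen)
    skip_if_not(arms$status == "ok")
    pre <- build_precursor(arms, bb)
    probe <- make_functional_probe(pre$precursor, arms)
    # duplex span equals arm + backbone + arm (320 at arm 20, 330 at arm 25)
    expect_equal(nchar(probe$bottom), alen + 280L + alen)
    expect_true(startsWith(probe$top, arms$arm_up))
    expect_true(startsWith(probe$bottom, revcomp(arms$arm_down)))
    expect_true(endsWith(probe$bottom, revcomp(arms$arm_up)))
    # two complementary single-stranded probes per duplex
    expect_false(probe$top == probe$bottom)
    # trimmed ends are 5'-phosphorylated for ligation
    expect_true(probe$left$phos && probe$right$phos)
  }
})

test_that("a precursor with two MlyI sites is rejected", {
  tgt <- genomic_interval("chr1", 900L, 1080L, "t")
  arms <- select_arms(ref1, tgt, arm_len = 25L)
  skip_if_not(arms$status == "ok")
  pre <- build_precursor(arms, default_backbone())
  bad <- dna_duplex(paste0("AAGAGTCAA", pre$precursor$top))
  expect_error(make_functional_probe(bad, arms), "exactly one")
})

test_that("probe arms hybridized to the reference leave a gap equal to the target", {
  panel <- toy_panel(n_targets = 4L)
  for (d in panel$designs) {
    probe <- d$functional_probe
    ctg <- ref1[[d$contig]]
    # bottom strand captures the sense strand: its 3' terminus is the
    # complement of the upstream flank, its 5' terminus of the downstream
    up <- substr(ctg, d$arm_up_iv$start + 1L, d$arm_up_iv$end)
    dn <- substr(ctg, d$arm_down_iv$start + 1L, d$arm_down_iv$end)
    expect_true(endsWith(probe$bottom, revcomp(up)))
    expect_true(startsWith(probe$bottom, revcomp(dn)))
    # the flanks abut the target with no gap or overlap
    expect_equal(d$arm_up_iv$end, d$start)
    expect_equal(d$arm_down_iv$start, d$end)
  }
})

test_that("round trip: digesting each emitted precursor reproduces its probe", {
  panel <- toy_panel(n_targets = 4L)
  expect_gt(length(panel$designs), 0L)
  for (d in panel$designs) {
    frags <- digest(d$precursor, default_enzymes())
    expect_length(frags, 3L)
    expect_identical(frags[[2L]]$top, d$functional_probe$top)
    expect_identical(frags[[2L]]$bottom, d$functional_probe$bottom)
  }
})

test_that("tile_target splits oversize targets minimally with overlap", {
  t541 <- genomic_interval("chr1", 0L, 541L, "a")
  expect_length(tile_target(t541, 550L, 50L), 1L)
  t700 <- genomic_interval("chr1", 0L, 700L, "b")
  tiles <- tile_target(t700, 550L, 50L)
  expect_length(tiles, 2L)
  expect_equal(tiles[[1]]$start, 0L)
  expect_equal(tiles[[2]]$end, 700L)
  expect_gte(tiles[[1]]$end - tiles[[2]]$start, 50L)
  t100 <- genomic_interval("chr1", 5L, 105L, "c")
  expect_identical(tile_target(t100)[[1]], t100)
  expect_error(tile_target(t100, 50L, 50L), "overlap")
})

test_that("tiling jointly covers arbitrary target sizes within the gap bound", {
  withr::with_seed(31, {
    for (i in 1:40) {
      len <- sample(50:2500, 1)
      tg <- genomic_interval("chr1", 100L, 100L + len, "x")
      tiles <- tile_target(tg, 550L, 50L)
      widths <- vapply(tiles, function(t) t$end - t$start, integer(1))
      expect_true(all(widths <= 550L))
      expect_equal(tiles[[1]]$start, 100L)
      expect_equal(tiles[[length(tiles)]]$end, 100L + len)
      if (length(tiles) > 1L) {
        for (j in seq_len(length(tiles) - 1L))
          expect_gte(tiles[[j]]$end - tiles[[j + 1L]]$start, 50L)
        # minimality
        expect_equal(length(tiles), ceiling((len - 50) / 500))
      }
    }
  })
})

test_that("abundance weights ramp linearly above the GC threshold", {
  expect_equal(assign_weights(c(0.50, 0.65)), c(1, 1))
  expect_equal(assign_weights(0.80), 4)
  expect_equal(assign_weights(0.725), 2.5)
  expect_equal(assign_weights(0.95), 4)  # capped
  gc <- seq(0, 1, by = 0.01)
  expect_true(all(diff(assign_weights(gc)) >= 0))
})

test_that("build_references emits consistent records with coordinate order", {
  panel <- toy_panel(n_targets = 4L)
  refs <- panel$references
  n <- length(panel$designs)
  expect_equal(length(refs$amplicons), n)
  expect_equal(length(refs$inserts), n)
  expect_equal(nrow(refs$targets), n)
  expect_true(!is.unsorted(refs$targets$start))
  m <- refs$meta
  expect_equal(m$insert_len,
               m$amplicon_len - m$arm_up_len - m$arm_down_len -
                 m$flank_f_len - m$flank_r_len)
  dup <- panel$designs[c(1, 1)]
  expect_error(build_references(dup), "duplicate")
})

test_that("an empty panel designs to empty files without error", {
  panel <- design_panel(ref1, data.frame(contig = character(0),
                                         start = integer(0),
                                         end = integer(0)))
  expect_length(panel$designs, 0L)
  dir <- withr::local_tempdir()
  expect_no_error(write_panel(panel, dir))
})

test_that("every emitted gap fill respects the 550-base bound on a mixed panel", {
  ref <- setNames(rand_dna(30000, seed = 77), "chr1")
  widths <- round(seq(50, 700, length.out = 12))
  starts <- 400L + cumsum(c(0L, rep(2000L, 11L)))
  tg <- data.frame(contig = "chr1", start = starts, end = starts + widths,
                   name = sprintf("t%02d", seq_along(widths)))
  panel <- design_panel(ref, tg)
  expect_true(all(panel$report$gap_len <= 550L))
  # the 700 bp target was tiled into two designs
  expect_equal(sum(grepl("^t12\\.", panel$report$id)), 2L)
  ok <- panel$report[panel$report$status == "ok", ]
  expect_true(all(ok$gap_len <= 550L))
})

test_that("panel files are written in the documented formats", {
  panel <- toy_panel(n_targets = 3L)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  expect_true(all(file.exists(file.path(dir, c("amplicons.fa", "inserts.fa",
                                               "probes.fa", "primers.tsv",
                                               "targets.bed",
                                               "design_report.tsv")))))
  bed <- read.table(file.path(dir, "targets.bed"), sep = "\t")
  expect_equal(nrow(bed), length(panel$designs))
  expect_true(all(bed$V2 >= 0))
})
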