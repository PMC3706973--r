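#' Specification of a synthetic diploid genome
#'
#' Describes the genome the simulator builds: contig lengths, numbers of
#' planted SNVs and small indels, per-contig ploidy (e.g. a male X has ploidy
#' 1) and copy-number segments (a trisomy is one extra copy of a contig on one
#' haplotype; a focal deletion is copy 0 over the listed exons).
#'
#' @param contigs named integer vector of contig lengths.
#' @param n_snv number of planted SNVs.
#' @param het_frac fraction of planted variants that are heterozygous.
#' @param n_indel number of planted small indels.
#' @param indel_range length range of indels (bases).
#' @param cnv data.frame with columns \code{contig,start,end,hap,copies}
#'   (0-based half-open; \code{copies} replaces the default single copy of
#'   that haplotype over the segment).
#' @param contig_ploidy named integer vector; default 2 for every contig.
#' @param variant_regions optional data.frame (\code{contig,start,end}) to
#'   which planted variants are restricted.
#' @param seed random seed.
#' @return object of class \code{clpp_genome_spec}.
#' @export
genome_spec <- function(contigs, n_snv = 0L, het_frac = 0.5, n_indel = 0L,
                        indel_range = c(1L, 6L), cnv = NULL,
                        contig_ploidy = NULL, variant_regions = NULL,
                        seed = 1L) {
  stopifnot(length(contigs) >= 1L, !is.null(names(contigs)))
  if (is.null(contig_ploidy))
    contig_ploidy <- setNames(rep(2L, length(contigs)), names(contigs))
  if (!is.null(cnv) && any(cnv$copies < 0L))
    stop("copy numbers must be >= 0", call. = FALSE)
  structure(list(contigs = contigs, n_snv = as.integer(n_snv),
                 het_frac = het_frac, n_indel = as.integer(n_indel),
                 indel_range = as.integer(indel_range), cnv = cnv,
                 contig_ploidy = contig_ploidy,
                 variant_regions = variant_regions, seed = as.integer(seed)),
            class = "clpp_genome_spec")
}

#' Generate a synthetic diploid genome with planted variation
#'
#' Builds a random reference, then plants non-overlapping SNVs and indels
#' (het on one random haplotype, hom on both) and records the copy-number
#' truth. Deterministic for a fixed spec (seed included).
#'
#' @param spec a \code{clpp_genome_spec}.
#' @return object of class \code{clpp_genome}: \code{reference} (named
#'   character), \code{variants} (truth table), \code{cnv} truth table,
#'   \code{contig_ploidy}, and the spec.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "clpp_genome_spec"))
  with_seed(spec$seed, {
    reference <- vapply(spec$contigs, random_dna, "")
    vr <- spec$variant_regions
    if (is.null(vr)) {
      vr <- data.frame(contig = names(spec$contigs), start = 0L,
                       end = unname(spec$contigs), stringsAsFactors = FALSE)
    }
    # keep variants clear of region edges so arms/inserts slice cleanly
    pad <- max(spec$indel_range) + 2L
    vr <- vr[vr$end - vr$start > 2L * pad, , drop = FALSE]
    n_var <- spec$n_snv + spec$n_indel
    variants <- NULL
    if (n_var > 0L) {
      if (!nrow(vr)) stop("no usable variant regions", call. = FALSE)
      pool <- unlist(lapply(seq_len(nrow(vr)), function(i)
        which(names(spec$contigs) == vr$contig[i])[1L] * 10^9 +
          seq.int(vr$start[i] + pad, vr$end[i] - pad)))
      if (length(pool) < n_var * (pad + 1L))
        stop("variant regions too small for requested variant count",
             call. = FALSE)
      picked <- integer(0)
      cand <- sample(pool)
      for (p in cand) {
        if (length(picked) >= n_var) break
        if (!any(abs(picked - p) <= pad)) picked <- c(picked, p)
      }
      if (length(picked) < n_var)
        stop("could not place non-overlapping variants", call. = FALSE)
      ctg_i <- picked %/% 10^9
      pos <- as.integer(picked %% 10^9)
      type <- sample(rep(c("snv", "ins", "del"),
                         c(spec$n_snv,
                           ceiling(spec$n_indel / 2),
                           floor(spec$n_indel / 2))))
      rows <- lapply(seq_len(n_var), function(i) {
        ctg <- names(spec$contigs)[ctg_i[i]]
        haploid <- spec$contig_ploidy[[ctg]] < 2L
        gt <- if (!haploid && runif(1) < spec$het_frac) "het" else "hom"
        hap <- if (gt == "het") as.character(sample(1:2, 1L)) else "both"
        refb <- substr(reference[[ctg]], pos[i] + 1L, pos[i] + 1L)
        if (type[i] == "snv") {
          alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
          data.frame(contig = ctg, pos = pos[i], type = "snv", ref = refb,
                     alt = alt, len = 1L, genotype = gt, hap = hap,
                     stringsAsFactors = FALSE)
        } else if (type[i] == "ins") {
          len <- sample(seq(spec$indel_range[1L], spec$indel_range[2L]), 1L)
          data.frame(contig = ctg, pos = pos[i], type = "ins", ref = refb,
                     alt = paste0(refb, random_dna(len)), len = len,
                     genotype = gt, hap = hap, stringsAsFactors = FALSE)
        } else {
          len <- sample(seq(spec$indel_range[1L], spec$indel_range[2L]), 1L)
          refs <- substr(reference[[ctg]], pos[i] + 1L, pos[i] + 1L + len)
          data.frame(contig = ctg, pos = pos[i], type = "del", ref = refs,
                     alt = refb, len = len, genotype = gt, hap = hap,
                     stringsAsFactors = FALSE)
        }
      })
      variants <- do.call(rbind, rows)
      variants <- variants[order(variants$contig, variants$pos), ]
      rownames(variants) <- NULL
    } else {
      variants <- data.frame(contig = character(0), pos = integer(0),
                             type = character(0), ref = character(0),
                             alt = character(0), len = integer(0),
                             genotype = character(0), hap = character(0),
                             stringsAsFactors = FALSE)
    }
    cnv <- spec$cnv
    if (is.null(cnv))
      cnv <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), hap = integer(0),
                        copies = integer(0), stringsAsFactors = FALSE)
    structure(list(reference = reference, variants = variants, cnv = cnv,
                   contig_ploidy = spec$contig_ploidy, spec = spec),
              class = "clpp_genome")
  })
}

variants_on_hap <- function(genome, contig, hap) {
  v <- genome$variants
  v[v$contig == contig & (v$hap == "both" | v$hap == as.character(hap)), ,
    drop = FALSE]
}

#' Extract the haplotype sequence over a reference interval
#'
#' Returns the sequence of haplotype \code{hap} corresponding to the
#' 0-based half-open reference interval \code{[start, end)}, with planted
#' substitutions and indels applied.
#'
#' @param genome a \code{clpp_genome}.
#' @param contig contig name.
#' @param hap haplotype (1 or 2).
#' @param start,end reference coordinates.
#' @return DNA string.
#' @export
haplotype_slice <- function(genome, contig, hap, start, end) {
  refseq <- genome$reference[[contig]]
  if (is.null(refseq)) stop("unknown contig: ", contig, call. = FALSE)
  v <- variants_on_hap(genome, contig, hap)
  v <- v[v$pos >= start & v$pos < end, , drop = FALSE]
  if (!nrow(v)) return(substr(refseq, start + 1L, end))
  v <- v[order(v$pos), , drop = FALSE]
  out <- character(0)
  cur <- start
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    out <- c(out, substr(refseq, cur + 1L, p))
    if (v$type[i] == "snv") {
      out <- c(out, v$alt[i]); cur <- p + 1L
    } else if (v$type[i] == "ins") {
      out <- c(out, v$alt[i]); cur <- p + 1L
    } else {  # del: keep anchor base, skip len deleted bases
      out <- c(out, substr(v$ref[i], 1L, 1L))
      cur <- min(p + 1L + v$len[i], end)
    }
  }
  paste0(paste(out, collapse = ""), substr(refseq, cur + 1L, end))
}

#' Full haplotype sequences of a synthetic genome
#' @param genome a \code{clpp_genome}.
#' @return named character vector (\code{<contig>_hap1}, \code{<contig>_hap2}).
#' @export
haplotype_sequences <- function(genome) {
  out <- character(0)
  for (ctg in names(genome$reference)) {
    for (h in seq_len(max(1L, genome$contig_ploidy[[ctg]]))) {
      out[[paste0(ctg, "_hap", h)]] <-
        haplotype_slice(genome, ctg, h, 0L, nchar(genome$reference[[ctg]]))
    }
  }
  out
}

# copies of haplotype `hap` of `contig` spanning the probe target midpoint
copy_count <- function(genome, contig, hap, start, end) {
  base <- if (hap <= genome$contig_ploidy[[contig]]) 1L else 0L
  cn <- genome$cnv
  mid <- (start + end) %/% 2L
  sel <- cn$contig == contig & cn$hap == hap & cn$start <= mid & cn$end > mid
  if (any(sel)) cn$copies[which(sel)[1L]] else base
}

#' Capture efficiency model
#'
#' Event-level model of multiplex cLPP capture: each probe strand captures
#' each genome copy independently with probability
#' \code{p0 * exp(-k * max(0, GC - gc_threshold))}, where \code{k} is chosen
#' so that the configured GC excess halves the efficiency. In ssLPP mode only
#' the sense-capturing strand is active. The per-(probe, copy, strand) number
#' of molecules is Binomial(\code{depth * weight}, p).
#'
#' @param mode \code{"clpp"} (both strands) or \code{"sslpp"} (sense only).
#' @param p0 per-strand base capture efficiency in (0, 1].
#' @param gc_threshold GC fraction above which the penalty applies.
#' @param gc_halving GC excess at which efficiency is halved.
#' @param depth molecules attempted per (probe, copy, strand) at weight 1.
#' @param seed random seed for \code{\link{simulate_capture}}.
#' @return object of class \code{clpp_capture_model}.
#' @export
capture_model <- function(mode = c("clpp", "sslpp"), p0 = 0.9,
                          gc_threshold = 0.65, gc_halving = 0.15,
                          depth = 1L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(p0 > 0, p0 <= 1, gc_halving > 0, depth >= 1)
  structure(list(mode = mode, p0 = p0, gc_threshold = gc_threshold,
                 k = log(2) / gc_halving, depth = depth,
                 seed = as.integer(seed)),
            class = "clpp_capture_model")
}

#' Per-strand and duplex capture success probabilities
#'
#' @param p1,p2 per-strand capture probabilities.
#' @return named vector with per-strand and duplex (at least one strand
#'   circularizes) probabilities.
#' @export
duplex_success_prob <- function(p1, p2 = p1) {
  c(strand1 = p1, strand2 = p2, duplex = 1 - (1 - p1) * (1 - p2))
}

strand_capture_prob <- function(model, gc) {
  model$p0 * exp(-model$k * pmax(0, gc - model$gc_threshold))
}

#' Simulate multiplex cLPP capture on a synthetic genome
#'
#' For every probe x genome copy x active strand, draws the number of
#' successfully circularized molecules under the capture model. Inserts carry
#' the planted alleles of their haplotype of origin; deleted copies yield no
#' molecules; linear (failed) species are never emitted, mirroring the
#' exonuclease cleanup of the wet protocol.
#'
#' @param genome a \code{clpp_genome}.
#' @param panel a \code{clpp_panel} designed against \code{genome$reference}.
#' @param model a \code{clpp_capture_model}.
#' @return data.frame of circularized captures: \code{capture_id, probe_id,
#'   strand, hap, copy, arm_up, insert, arm_down} (arm and insert sequences in
#'   sense orientation, haplotype-derived).
#' @export
simulate_capture <- function(genome, panel, model = capture_model()) {
  stopifnot(inherits(genome, "clpp_genome"), inherits(panel, "clpp_panel"))
  strands <- if (model$mode == "clpp") c("sense", "antisense") else "sense"
  with_seed(model$seed, {
    rows <- list()
    for (d in panel$designs) {
      refseq <- genome$reference[[d$contig]]
      if (is.null(refseq) ||
          substr(refseq, d$arm_up_iv$start + 1L, d$arm_up_iv$end) != d$arm_up ||
          substr(refseq, d$arm_down_iv$start + 1L, d$arm_down_iv$end) !=
            d$arm_down)
        stop("probe ", d$id, ": arms do not match the reference",
             call. = FALSE)
      p <- strand_capture_prob(model, d$gc) * min(1, d$weight)
      n_trials <- max(1L, as.integer(round(model$depth * max(1, d$weight))))
      for (hap in 1:2) {
        copies <- copy_count(genome, d$contig, hap, d$start, d$end)
        if (copies < 1L) next
        arm_up_h <- haplotype_slice(genome, d$contig, hap,
                                    d$arm_up_iv$start, d$arm_up_iv$end)
        ins_h <- haplotype_slice(genome, d$contig, hap, d$start, d$end)
        arm_dn_h <- haplotype_slice(genome, d$contig, hap,
                                    d$arm_down_iv$start, d$arm_down_iv$end)
        for (cp in seq_len(copies)) for (st in strands) {
          k <- rbinom(1L, n_trials, p)
          if (k < 1L) next
          rows[[length(rows) + 1L]] <- data.frame(
            probe_id = d$id, strand = st, hap = hap, copy = cp,
            n_molecules = k, arm_up = arm_up_h, insert = ins_h,
            arm_down = arm_dn_h, stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(rows)) {
      return(data.frame(capture_id = character(0), probe_id = character(0),
                        strand = character(0), hap = integer(0),
                        copy = integer(0), arm_up = character(0),
                        insert = character(0), arm_down = character(0),
                        stringsAsFactors = FALSE))
    }
    agg <- do.call(rbind, rows)
    out <- agg[rep(seq_len(nrow(agg)), agg$n_molecules), , drop = FALSE]
    out$n_molecules <- NULL
    out <- cbind(capture_id = sprintf("c%06d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Per-amplicon molecule counts from a capture table
#' @param captures data.frame from \code{\link{simulate_capture}}.
#' @param panel optional \code{clpp_panel} to include zero-count amplicons.
#' @return data.frame \code{amplicon, count}.
#' @export
counts_from_captures <- function(captures, panel = NULL) {
  tab <- table(captures$probe_id)
  ids <- if (is.null(panel)) names(tab) else
    vapply(panel$designs, `[[`, "", "id")
  data.frame(amplicon = ids,
             count = as.integer(tab[ids]) |> (\(x) ifelse(is.na(x), 0L, x))(),
             stringsAsFactors = FALSE)
}

#' Molar probe-to-target ratio of a capture reaction
#'
#' @param probe_amount_fmol total probe amount (femtomoles) across the panel.
#' @param n_probes number of probes in the panel.
#' @param dna_mass_ng genomic DNA input (nanograms).
#' @param genome_mass_per_copy_pg mass of one genome copy (picograms);
#'   3.3 pg for a haploid human genome.
#' @return molar ratio of one probe to target copies.
#' @export
probe_target_ratio <- function(probe_amount_fmol, n_probes, dna_mass_ng,
                               genome_mass_per_copy_pg = 3.3) {
  if (any(c(probe_amount_fmol, n_probes, dna_mass_ng,
            genome_mass_per_copy_pg) <= 0))
    stop("all quantities must be positive", call. = FALSE)
  avogadro <- 6.02214076e23
  probe_mol <- probe_amount_fmol * 1e-15 / n_probes
  target_copies <- dna_mass_ng * 1e-9 / (genome_mass_per_copy_pg * 1e-12)
  probe_mol / (target_copies / avogadro)
}

#' Write genome truth files (haplotype FASTA, truth VCF, truth CNV BED)
#' @param genome a \code{clpp_genome}.
#' @param dir output directory.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome$reference, file.path(dir, "reference.fa"))
  write_fasta(haplotype_sequences(genome), file.path(dir, "haplotypes.fa"))
  v <- genome$variants
  gt <- ifelse(v$genotype == "hom", "1/1",
               ifelse(v$hap == "1", "1|0", "0|1"))
  vcf <- c("##fileformat=VCFv4.2",
           "##source=clppkit_truth",
           sprintf("##contig=<ID=%s,length=%d>", names(genome$reference),
                   nchar(genome$reference)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ttruth",
           sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                   v$contig, v$pos + 1L, v$ref, v$alt, gt))
  writeLines(vcf, file.path(dir, "truth.vcf"))
  cn <- genome$cnv
  writeLines(sprintf("%s\t%d\t%d\thap%d_copies%d", cn$contig, cn$start,
                     cn$end, cn$hap, cn$copies),
             file.path(dir, "truth_cnv.bed"))
  invisible(dir)
}
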